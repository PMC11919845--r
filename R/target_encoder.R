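#' @title Target encoder: fused sequence and contact-graph pathways
#'
#' @description
#' A protein is encoded along two pathways sharing the same per-residue input
#' embeddings: a sequential pathway (three stacked 1D convolutions with
#' windows 3, 5 and 7, combined multi-scale) and a spatial pathway (three
#' weighted graph convolutions over the residue contact graph). The two
#' residue-level feature matrices are projected, L2-normalized per residue,
#' summed, projected again and max-pooled over residues into the target
#' embedding.
#'
#' @name target_encoder
NULL

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
RESIDUE_EMBED_DIM <- 30L

#' Target encoder configuration
#'
#' @param channels hidden width C of both pathways (matches the drug encoder)
#' @param windows convolution window sizes of the three sequence layers
#' @param contact_threshold minimum contact probability for an off-backbone
#'   edge in the residue graph; 0 keeps the dense graph
#' @param use_graph logical; `FALSE` runs the sequence pathway alone
#' @param max_seq_len sequences longer than this are tail-truncated
#' @return a list of class `target_encoder_config`
#' @export
target_encoder_config <- function(channels = 128L, windows = c(3L, 5L, 7L),
                                  contact_threshold = 0.5, use_graph = TRUE,
                                  max_seq_len = 1000L) {
  stopifnot(length(windows) == 3L, all(windows >= 1L), all(windows %% 2L == 1L),
            contact_threshold >= 0, contact_threshold <= 1)
  structure(
    list(channels = as.integer(channels), windows = as.integer(windows),
         contact_threshold = contact_threshold, use_graph = isTRUE(use_graph),
         max_seq_len = as.integer(max_seq_len)),
    class = "target_encoder_config"
  )
}

#' Construct a protein record
#'
#' @param target_id identifier
#' @param sequence residue string; letters outside the 20-residue alphabet
#'   map to `X`
#' @param contact_map optional symmetric `[L x L]` matrix of contact
#'   probabilities in `[0, 1]`
#' @param max_seq_len truncation length
#' @return object of class `protein_record`
#' @export
protein_record <- function(target_id, sequence, contact_map = NULL,
                           max_seq_len = 1000L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("empty protein sequence for target '", target_id, "'")
  chars <- strsplit(sequence, "")[[1]]
  chars[!chars %in% AA_ALPHABET] <- "X"
  if (length(chars) > max_seq_len) {
    chars <- chars[seq_len(max_seq_len)]
    if (!is.null(contact_map)) contact_map <- contact_map[seq_len(max_seq_len), seq_len(max_seq_len)]
  }
  if (!is.null(contact_map)) {
    contact_map <- as.matrix(contact_map)
    if (nrow(contact_map) != length(chars) || ncol(contact_map) != length(chars)) {
      stop("contact map of target '", target_id, "' is ", nrow(contact_map), "x",
           ncol(contact_map), " but the sequence has ", length(chars), " residues")
    }
    if (max(abs(contact_map - t(contact_map))) > 1e-8) {
      stop("contact map of target '", target_id, "' is not symmetric")
    }
    if (min(contact_map) < 0 || max(contact_map) > 1) {
      stop("contact map of target '", target_id, "' has entries outside [0, 1]")
    }
  }
  structure(
    list(target_id = target_id, sequence = paste(chars, collapse = ""),
         residue_index = match(chars, AA_ALPHABET), contact_map = contact_map),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$target_id, ": ", length(x$residue_index),
      " residues, contact map ", if (is.null(x$contact_map)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Embed residues as 30-dimensional vectors
#'
#' The built-in embedder is a learned 21 x 30 lookup table (one row per
#' residue class including `X`), so repeated letters share a row. Any
#' function mapping a residue-index vector to an `[L x 30]` matrix can be
#' substituted, e.g. an adapter around a pretrained protein language model
#' projected to 30 dimensions.
#'
#' @param record a [protein_record()]
#' @param embed_table `[21 x 30]` lookup matrix (or autodiff node)
#' @return `[L x 30]` matrix (or autodiff node)
#' @export
embed_residues <- function(record, embed_table) {
  if (length(record$residue_index) < 1L) stop("empty sequence")
  ad_rows(embed_table, record$residue_index)
}

#' Multi-scale 1D convolution over a residue embedding matrix
#'
#' Three sequential same-padded 1D convolution layers with growing windows;
#' each layer output is ReLU-activated, the three outputs are concatenated
#' channel-wise and linearly projected to `C` channels, so features at all
#' three receptive-field scales reach the fused embedding.
#'
#' @param X `[L x 30]` residue embeddings (matrix or autodiff node)
#' @param params list with `conv` (three layers, each `W` of shape
#'   `[window * C_in, C_out]` and bias `b`) and `proj` (`W`, `b`)
#' @param windows integer window sizes (odd)
#' @return `[L x C]` matrix (or autodiff node)
#' @export
multiscale_cnn <- function(X, params, windows = c(3L, 5L, 7L)) {
  h <- X
  outs <- vector("list", length(windows))
  for (l in seq_along(windows)) {
    h <- conv1d_same(h, params$conv[[l]], windows[l])
    h <- ad_relu(h)
    outs[[l]] <- h
  }
  cat3 <- ad_cbind(ad_cbind(outs[[1]], outs[[2]]), outs[[3]])
  ad_add(ad_mm(cat3, params$proj$W), params$proj$b)
}

# Same-padded 1D convolution: unfold the sequence into shifted copies and
# apply one matrix multiplication with the [window * C_in, C_out] kernel.
conv1d_same <- function(X, layer_params, window) {
  ad_add(ad_mm(ad_unfold_rows(X, window), layer_params$W), layer_params$b)
}

#' Build the weighted residue graph of a protein
#'
#' Off-diagonal pairs with contact probability at or above `threshold` become
#' edges weighted by the probability. Backbone edges `(i, i+1)` are always
#' present with weight 1 so the graph stays connected under sparse maps; the
#' diagonal is excluded.
#'
#' @param record a [protein_record()] with a contact map
#' @param threshold contact-probability cutoff in `[0, 1]`
#' @return list of class `target_graph` with the weighted adjacency `W`,
#'   unweighted degrees `deg`, and the degree-normalized aggregation matrix
#'   `Anorm` with entries `M_ij / sqrt(deg_i * deg_j)`
#' @export
build_residue_graph <- function(record, threshold = 0.5) {
  M <- record$contact_map
  if (is.null(M)) stop("target '", record$target_id, "' has no contact map")
  stopifnot(threshold >= 0, threshold <= 1)
  if (max(abs(M - t(M))) > 1e-8) stop("contact map must be symmetric")
  L <- nrow(M)
  W <- M * (M >= threshold)
  diag(W) <- 0
  if (L > 1L) {
    bb <- cbind(seq_len(L - 1L), 2L:L)
    W[bb] <- 1
    W[bb[, 2:1, drop = FALSE]] <- 1
  }
  deg <- rowSums(W > 0)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Anorm <- W * (dinv %o% dinv)
  structure(list(W = W, deg = deg, Anorm = Anorm, n = L), class = "target_graph")
}

#' Weighted graph convolution layer
#'
#' Updates residue states as
#' `h_i' = sigma(h_i W1 + sum_j (M_ij / c_ij) h_j W2)` with
#' `c_ij = sqrt(deg_i) * sqrt(deg_j)` and degrees counted over unweighted
#' neighbors. Residues without neighbors keep only the self term.
#'
#' @param graph a `target_graph` from [build_residue_graph()]
#' @param states `[L x C_in]` matrix (or autodiff node)
#' @param layer_params list with `W1`, `W2`
#' @param activation `"relu"` or `"linear"`
#' @return `[L x C_out]` matrix (or autodiff node)
#' @export
wgcn_layer <- function(graph, states, layer_params, activation = "relu") {
  if (nrow(adv(states)) != graph$n) {
    stop("state row count (", nrow(adv(states)), ") does not match node count (", graph$n, ")")
  }
  out <- ad_add(ad_mm(states, layer_params$W1),
                ad_mm(ad_mm(graph$Anorm, states), layer_params$W2))
  if (activation == "relu") ad_relu(out) else out
}

#' Fuse the sequence and graph pathways into a target embedding
#'
#' `Tfused = (L2(Tseq Ws) + L2(Tgraph Wg)) Wt`, with L2 normalization applied
#' per residue row (zero rows pass through), followed by a channel-wise max
#' over residues. When `Tgraph` is `NULL` the graph term is dropped and the
#' sequence pathway alone is projected.
#'
#' @param Tseq `[L x C]` sequence-pathway features
#' @param Tgraph `[L x C]` graph-pathway features, or `NULL`
#' @param params list with projection matrices `Ws`, `Wg`, `Wt`
#' @return `1 x C_out` embedding row (matrix or autodiff node)
#' @export
fuse_target <- function(Tseq, Tgraph, params) {
  s <- ad_l2_rows(ad_mm(Tseq, params$Ws))
  fused <- if (is.null(Tgraph)) {
    s
  } else {
    if (nrow(adv(Tgraph)) != nrow(adv(Tseq))) {
      stop("sequence and graph pathways disagree on residue count")
    }
    ad_add(s, ad_l2_rows(ad_mm(Tgraph, params$Wg)))
  }
  ad_colmax(ad_mm(fused, params$Wt))
}

init_target_encoder_params <- function(cfg) {
  C <- cfg$channels
  conv_in <- c(RESIDUE_EMBED_DIM, C, C)
  list(
    E = glorot(length(AA_ALPHABET), RESIDUE_EMBED_DIM),
    conv = lapply(1:3, function(l) {
      list(W = glorot(cfg$windows[l] * conv_in[l], C), b = numeric(C))
    }),
    proj = list(W = glorot(3L * C, C), b = numeric(C)),
    wgcn = lapply(1:3, function(l) {
      nin <- if (l == 1L) RESIDUE_EMBED_DIM else C
      list(W1 = glorot(nin, C), W2 = glorot(nin, C))
    }),
    Ws = glorot(C, C), Wg = glorot(C, C), Wt = glorot(C, C)
  )
}

# Precompute per-target structures consumed by target_forward.
target_data <- function(record, cfg) {
  tg <- NULL
  if (cfg$use_graph) {
    if (is.null(record$contact_map)) {
      stop("target '", record$target_id, "' has no contact map but the graph ",
           "pathway is enabled; supply one or set use_graph = FALSE")
    }
    tg <- build_residue_graph(record, cfg$contact_threshold)
  }
  list(residue_index = record$residue_index, graph = tg)
}

target_forward <- function(params, tdata, cfg, train = FALSE) {
  X <- ad_rows(params$E, tdata$residue_index)
  Tseq <- multiscale_cnn(X, params, cfg$windows)
  Tgraph <- NULL
  if (!is.null(tdata$graph)) {
    h <- X
    for (l in 1:3) h <- wgcn_layer(tdata$graph, h, params$wgcn[[l]])
    Tgraph <- h
  }
  fuse_target(Tseq, Tgraph, params)
}

#' Encode a protein into a fixed-length embedding
#'
#' @param record a [protein_record()]
#' @param params target-encoder parameters (e.g. `model$params$target`)
#' @param cfg a [target_encoder_config()]
#' @return numeric embedding vector of length `cfg$channels`
#' @export
encode_target <- function(record, params, cfg) {
  as.numeric(target_forward(params, target_data(record, cfg), cfg))
}
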