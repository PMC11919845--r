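#' @title Drug encoder: stacked gated GNN blocks
#'
#' @description
#' The drug branch encodes a molecular graph with a fixed 3-layer initial
#' block (64 -> C channels) followed by `n_blocks` blocks of `n_layers` GNN
#' layers each. Every block doubles its last layer's output channels and
#' refines the expansion through a gated linear unit with a residual to the
#' penultimate layer ("feature enhancement"); GRU-style reset/update gates,
#' with weights shared across blocks, then filter the block output against
#' the block input. A channel-wise max over atoms reads out the graph
#' embedding, making the encoder invariant to atom order.
#'
#' @name drug_encoder
NULL

#' Drug encoder configuration
#'
#' @param channels hidden width C kept constant across blocks (required by the
#'   shared gating weights)
#' @param n_blocks number of blocks L after the initial 3-layer block
#' @param n_layers GNN layers N per block (N >= 2; the penultimate layer feeds
#'   the enhancement residual)
#' @param gnn_type one of `"gcn"`, `"gat"`, `"gin"`, `"gat_gcn"`; `"gat_gcn"`
#'   uses attention layers everywhere except a plain graph convolution as the
#'   last layer of each block
#' @param enhancement_scale scaling factor d on the gated-linear-unit term
#' @param dropout dropout rate applied after each block's enhancement during
#'   training
#' @return a list of class `drug_encoder_config`
#' @export
drug_encoder_config <- function(channels = 128L, n_blocks = 5L, n_layers = 2L,
                                gnn_type = c("gat_gcn", "gcn", "gat", "gin"),
                                enhancement_scale = 1.0, dropout = 0.2) {
  gnn_type <- match.arg(gnn_type)
  stopifnot(n_blocks >= 1L, channels >= 1L)
  if (n_layers < 2L) {
    stop("n_layers must be >= 2: the penultimate layer output is undefined otherwise")
  }
  structure(
    list(channels = as.integer(channels), n_blocks = as.integer(n_blocks),
         n_layers = as.integer(n_layers), gnn_type = gnn_type,
         enhancement_scale = enhancement_scale, dropout = dropout),
    class = "drug_encoder_config"
  )
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -s, s), nin, nout)
}

# Per-layer GNN type within a block: "gat_gcn" is attention everywhere but a
# plain graph convolution at the last layer.
block_layer_types <- function(gnn_type, n_layers) {
  switch(gnn_type,
    gcn = rep("gcn", n_layers),
    gin = rep("gin", n_layers),
    gat = rep("gat", n_layers),
    gat_gcn = c(rep("gat", n_layers - 1L), "gcn")
  )
}

init_gnn_layer_params <- function(nin, nout, type) {
  p <- list(W1 = glorot(nin, nout), W2 = glorot(nin, nout), b = numeric(nout))
  if (type == "gat") {
    p$a_src <- glorot(nout, 1L)
    p$a_dst <- glorot(nout, 1L)
  }
  p
}

init_block_params <- function(nin, channels, n_layers, gnn_type) {
  types <- block_layer_types(gnn_type, n_layers)
  dims_in <- c(nin, rep(channels, n_layers - 1L))
  dims_out <- c(rep(channels, n_layers - 1L), 2L * channels)
  lapply(seq_len(n_layers), function(i) {
    init_gnn_layer_params(dims_in[i], dims_out[i], types[i])
  })
}

init_gating_params <- function(channels) {
  list(
    W1r = glorot(channels, channels), W2r = glorot(channels, channels), br = numeric(channels),
    W1z = glorot(channels, channels), W2z = glorot(channels, channels), bz = numeric(channels),
    W1h = glorot(channels, channels), W2h = glorot(channels, channels), bh = numeric(channels)
  )
}

init_drug_encoder_params <- function(cfg, in_dim = ATOM_FEATURE_DIM) {
  list(
    init_block = init_block_params(in_dim, cfg$channels, 3L, cfg$gnn_type),
    blocks = lapply(seq_len(cfg$n_blocks), function(i) {
      init_block_params(cfg$channels, cfg$channels, cfg$n_layers, cfg$gnn_type)
    }),
    gating = init_gating_params(cfg$channels)
  )
}

#' Precompute message-passing structures for a molecular graph
#'
#' @param graph a `molecular_graph`
#' @return list with node features, edge index vectors, the 0/1 adjacency and
#'   its symmetric degree-normalized variant
#' @keywords internal
graph_data <- function(graph) {
  n <- graph$num_atoms
  A <- matrix(0, n, n)
  src <- integer(0); dst <- integer(0)
  if (nrow(graph$edges) > 0L) {
    src <- graph$edges[, 1L]; dst <- graph$edges[, 2L]
    A[cbind(dst, src)] <- 1  # row i aggregates from neighbors j
  }
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Agcn <- A * (dinv %o% dinv)
  list(X0 = graph$node_features, n = n, src = src, dst = dst, A = A, Agcn = Agcn)
}

#' Single GNN layer
#'
#' Updates node states as `sigma(X W1 + b + aggregate(X) W2)`. The neighbor
#' aggregate is the raw sum for `"gin"`, the symmetrically degree-normalized
#' sum for `"gcn"`, and an attention-weighted sum (single head, additive
#' attention with leaky-ReLU scores softmaxed over incoming edges) for
#' `"gat"`. Nodes without neighbors receive a zero aggregate, so only the
#' self term `sigma(X W1 + b)` survives.
#'
#' @param state node-state matrix (or autodiff node) `[n x C_in]`
#' @param gdata output of [graph_data()] (carries the edge structure)
#' @param layer_params list with `W1`, `W2`, `b` and, for attention layers,
#'   `a_src`, `a_dst`
#' @param gnn_type `"gcn"`, `"gat"` or `"gin"`
#' @param activation `"relu"` (hidden layers) or `"linear"` (last layer of a
#'   block, whose nonlinearity is supplied by the gated linear unit)
#' @return updated node-state matrix (or autodiff node)
#' @export
gnn_layer <- function(state, gdata, layer_params, gnn_type, activation = "relu") {
  if (ncol(adv(state)) != nrow(adv(layer_params$W1))) {
    stop("channel mismatch: state has ", ncol(adv(state)),
         " channels but layer expects ", nrow(adv(layer_params$W1)))
  }
  self <- ad_add(ad_mm(state, layer_params$W1), layer_params$b)
  agg <- NULL
  if (gnn_type %in% c("gcn", "gin")) {
    A <- if (gnn_type == "gcn") gdata$Agcn else gdata$A
    agg <- ad_mm(ad_mm(A, state), layer_params$W2)
  } else if (gnn_type == "gat") {
    if (length(gdata$src) > 0L) {
      Wx <- ad_mm(state, layer_params$W2)
      s1 <- ad_mm(Wx, layer_params$a_src)
      s2 <- ad_mm(Wx, layer_params$a_dst)
      sc <- ad_leaky_relu(ad_add(ad_rows(s1, gdata$src), ad_rows(s2, gdata$dst)))
      alpha <- ad_segment_softmax(sc, gdata$dst, gdata$n)
      agg <- ad_edge_aggregate(alpha, ad_rows(Wx, gdata$src), gdata$dst, gdata$n)
    }
  } else {
    stop("unknown gnn_type: ", gnn_type)
  }
  out <- if (is.null(agg)) self else ad_add(self, agg)
  if (activation == "relu") ad_relu(out) else out
}

#' Forward pass through one GNN block
#'
#' Runs the block's layers sequentially (ReLU on hidden layers, linear last
#' layer) and returns both the penultimate-layer output (C channels) and the
#' channel-doubled last-layer output (2C channels) that feeds the gated
#' linear unit of [feature_enhance()].
#'
#' @param state input node states `[n x C_in]`
#' @inheritParams gnn_layer
#' @param block_params list of per-layer parameter lists
#' @param gnn_type block GNN variant (including `"gat_gcn"`)
#' @return list with elements `penultimate` and `expanded`
#' @export
gnn_block_forward <- function(state, gdata, block_params, gnn_type) {
  n_layers <- length(block_params)
  if (n_layers < 2L) stop("a GNN block needs at least 2 layers")
  types <- block_layer_types(gnn_type, n_layers)
  h <- state
  penultimate <- NULL
  for (i in seq_len(n_layers)) {
    act <- if (i < n_layers) "relu" else "linear"
    h <- gnn_layer(h, gdata, block_params[[i]], types[i], activation = act)
    if (i == n_layers - 1L) penultimate <- h
  }
  list(penultimate = penultimate, expanded = h)
}

#' Feature enhancement: expansion then gated refinement
#'
#' The block's channel-doubled output is refined by a gated linear unit
#' (value half times the sigmoid of the gate half) and added back to the
#' penultimate-layer output scaled by `d`:
#' `h = penultimate + d * GLU(expanded)`. With `d = 0` the block reduces to
#' its penultimate layer.
#'
#' @param penultimate node states `[n x C]`
#' @param expanded node states `[n x 2C]`
#' @param d scaling factor on the refined term
#' @return node states `[n x C]`
#' @export
feature_enhance <- function(penultimate, expanded, d) {
  if (ncol(adv(expanded)) != 2L * ncol(adv(penultimate))) {
    stop("expanded states must have exactly twice the channels of the penultimate states")
  }
  ad_add(penultimate, ad_scale(ad_glu(expanded), d))
}

#' GRU-style gating between blocks
#'
#' Filters a block's enhanced output `new` against the block's input `prev`:
#' reset gate `R = sigmoid(new W1r + prev W2r + br)`, update gate `Z`
#' likewise, candidate `tanh(new W1h + R * (prev W2h) + bh)`, and output
#' `(1 - Z) * prev + Z * candidate`. The parameters are shared across all
#' blocks of an encoder.
#'
#' @param prev block input node states `[n x C]`
#' @param new block output node states `[n x C]`
#' @param params gating parameter list (`W1r`, `W2r`, `br`, `W1z`, `W2z`,
#'   `bz`, `W1h`, `W2h`, `bh`)
#' @return gated node states `[n x C]`
#' @export
gating_update <- function(prev, new, params) {
  R <- ad_sigmoid(ad_add(ad_add(ad_mm(new, params$W1r), ad_mm(prev, params$W2r)), params$br))
  Z <- ad_sigmoid(ad_add(ad_add(ad_mm(new, params$W1z), ad_mm(prev, params$W2z)), params$bz))
  cand <- ad_tanh(ad_add(ad_add(ad_mm(new, params$W1h),
                                ad_mul(R, ad_mm(prev, params$W2h))), params$bh))
  ad_add(ad_mul(ad_oneminus(Z), prev), ad_mul(Z, cand))
}

apply_dropout <- function(x, rate) {
  if (rate <= 0) return(x)
  xv <- adv(x)
  mask <- matrix(rbinom(length(xv), 1L, 1 - rate), nrow(xv), ncol(xv)) / (1 - rate)
  ad_mul(x, mask)
}

# Full drug-branch forward. `params` may hold plain matrices (inference) or
# autodiff leaves (training). `capture`, when an environment, collects the
# per-block node states (initial block + each gated block) under $states.
drug_forward <- function(params, gdata, cfg, train = FALSE, capture = NULL) {
  d <- cfg$enhancement_scale
  ib <- gnn_block_forward(gdata$X0, gdata, params$init_block, cfg$gnn_type)
  h <- feature_enhance(ib$penultimate, ib$expanded, d)
  if (train) h <- apply_dropout(h, cfg$dropout)
  if (!is.null(capture)) capture$states <- list(h)
  for (b in seq_len(cfg$n_blocks)) {
    prev <- h
    bl <- gnn_block_forward(h, gdata, params$blocks[[b]], cfg$gnn_type)
    enh <- feature_enhance(bl$penultimate, bl$expanded, d)
    if (train) enh <- apply_dropout(enh, cfg$dropout)
    h <- gating_update(prev, enh, params$gating)
    if (!is.null(capture)) capture$states[[b + 1L]] <- h
  }
  ad_colmax(h)
}

#' Encode a molecular graph into a fixed-length embedding
#'
#' @param graph a `molecular_graph`
#' @param params drug-encoder parameters (e.g. `model$params$drug`)
#' @param cfg a [drug_encoder_config()]
#' @return numeric embedding vector of length `cfg$channels`
#' @export
encode_drug <- function(graph, params, cfg) {
  if (graph$num_atoms < 1L) stop("cannot encode an empty graph")
  as.numeric(drug_forward(params, graph_data(graph), cfg, train = FALSE))
}
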