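#' @title Synthetic DTI data with a planted interaction rule
#'
#' @description
#' Generates fully self-contained datasets: a SMILES library assembled from a
#' fragment grammar, random protein sequences with lattice self-avoiding-walk
#' contact maps, and labeled pairs whose clean label follows a planted rule -
#' by default, a pair interacts iff the drug carries a trifluoromethyl motif
#' AND the target sequence contains a short residue motif. The conjunction
#' forces a model to use both branches; the drug motif sits inside a 2-hop
#' receptive field and the protein motif inside the convolution windows, so
#' the rule is learnable by the intended architecture.
#'
#' @name synthetic_data
NULL

# Chain-extension fragments: each is a valid SMILES continuation appended to
# the previous fragment's last atom. Deliberately fluorine-free so the CF3
# drug motif occurs only where planted.
FRAG_RINGS <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1", "c1ccsc1",
                "C1CCOC1", "C1CCCC1")
FRAG_CHAINS <- c("C", "CC", "CCC", "CO", "CCO", "CN", "CCN", "C(C)C",
                 "C(=O)N", "C(=O)O", "CS", "N(C)C", "OC", "C(C)O")

#' Synthetic dataset specification
#'
#' @param n_drugs,n_targets,n_pairs library and pair-table sizes
#' @param pos_fraction fraction of clean-positive pairs
#' @param drug_motif SMARTS pattern of the planted drug substructure
#' @param protein_motif planted residue substring
#' @param drug_motif_fraction,target_motif_fraction fraction of entities
#'   carrying the motif
#' @param label_noise independent label-flip probability in `[0, 0.5)`
#' @param contact_decay length scale (lattice units) of the contact-
#'   probability decay `exp(-dist / decay)`
#' @param min_len,max_len protein sequence length range
#' @param or_rule plant an OR rule (either motif suffices) instead of the
#'   default AND rule
#' @param seed master seed
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_drugs = 300L, n_targets = 100L, n_pairs = 1000L,
                           pos_fraction = 0.5, drug_motif = "C(F)(F)F",
                           protein_motif = "HWKY",
                           drug_motif_fraction = 0.5,
                           target_motif_fraction = 0.5,
                           label_noise = 0, contact_decay = 3,
                           min_len = 50L, max_len = 300L,
                           or_rule = FALSE, seed = 1L) {
  stopifnot(pos_fraction > 0, pos_fraction < 1,
            label_noise >= 0, label_noise < 0.5, contact_decay > 0,
            min_len >= nchar(protein_motif), max_len >= min_len)
  structure(
    list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
         n_pairs = as.integer(n_pairs), pos_fraction = pos_fraction,
         drug_motif = drug_motif, protein_motif = protein_motif,
         drug_motif_fraction = drug_motif_fraction,
         target_motif_fraction = target_motif_fraction,
         label_noise = label_noise, contact_decay = contact_decay,
         min_len = as.integer(min_len), max_len = as.integer(max_len),
         or_rule = isTRUE(or_rule), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic SMILES library
#'
#' Molecules are assembled by concatenating 2-4 fragments from a curated
#' grammar of rings and chains (every concatenation of the grammar is a valid
#' SMILES); a controlled fraction receives the drug motif as a terminal
#' trifluoromethyl fragment. Every generated SMILES is round-tripped through
#' [smiles_to_graph()] at generation time.
#'
#' @param spec a [synthetic_spec()]
#' @return data frame with `drug_id`, `smiles`, `has_motif`
#' @export
generate_drugs <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_drugs
  m <- round(spec$drug_motif_fraction * n)
  motif_ids <- sample.int(n, m)
  has_motif <- seq_len(n) %in% motif_ids
  frags <- c(FRAG_RINGS, FRAG_CHAINS)
  smiles <- character(n)
  for (i in seq_len(n)) {
    repeat {
      k <- sample(2:4, 1L)
      s <- paste0(c(sample(FRAG_RINGS, 1L), sample(frags, k - 1L, replace = TRUE)),
                  collapse = "")
      if (has_motif[i]) s <- paste0(s, "C(F)(F)F")
      ok <- tryCatch({
        smiles_to_graph(s)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
    }
    smiles[i] <- s
  }
  data.frame(drug_id = sprintf("D%04d", seq_len(n)), smiles = smiles,
             has_motif = has_motif, stringsAsFactors = FALSE)
}

# 3-D self-avoiding walk on the unit lattice; restarts on dead ends.
saw_coords <- function(len, max_attempts = 1000L) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (attempt in seq_len(max_attempts)) {
    coords <- matrix(0, len, 3L)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    assign("0,0,0", TRUE, envir = seen)
    ok <- TRUE
    for (i in seq_len(len - 1L)) {
      cand <- sweep(dirs, 2L, coords[i, ], "+")
      keys <- apply(cand, 1L, paste, collapse = ",")
      free <- !vapply(keys, exists, logical(1), envir = seen, inherits = FALSE)
      if (!any(free)) { ok <- FALSE; break }
      pick <- sample(which(free), 1L)
      coords[i + 1L, ] <- cand[pick, ]
      assign(keys[pick], TRUE, envir = seen)
    }
    if (ok) return(coords)
  }
  stop("self-avoiding walk failed after ", max_attempts, " attempts")
}

#' Generate synthetic protein records
#'
#' Random sequences over the 20 amino acids with lengths uniform in
#' `[min_len, max_len]`; a controlled fraction carries the planted motif
#' (inserted at a random position) and the rest are scrubbed of accidental
#' occurrences. Contact maps come from a 3-D lattice self-avoiding-walk
#' backbone: `M_ij = exp(-dist_ij / contact_decay)`, symmetric with unit
#' diagonal (the diagonal is excluded downstream).
#'
#' @param spec a [synthetic_spec()]
#' @return list with `table` (data frame `target_id`, `sequence`,
#'   `has_motif`) and `records` (named list of [protein_record()])
#' @export
generate_targets <- function(spec) {
  set.seed(spec$seed + 1L)
  n <- spec$n_targets
  m <- round(spec$target_motif_fraction * n)
  motif_ids <- sample.int(n, m)
  has_motif <- seq_len(n) %in% motif_ids
  aa20 <- AA_ALPHABET[1:20]
  motif <- spec$protein_motif
  seqs <- character(n)
  records <- vector("list", n)
  ids <- sprintf("T%03d", seq_len(n))
  for (i in seq_len(n)) {
    len <- sample(spec$min_len:spec$max_len, 1L)
    s <- paste(sample(aa20, len, replace = TRUE), collapse = "")
    # scrub chance occurrences so motif presence is exactly as constructed
    while (grepl(motif, s, fixed = TRUE)) {
      pos <- regexpr(motif, s, fixed = TRUE)[1]
      old <- substr(s, pos, pos)
      substr(s, pos, pos) <- sample(setdiff(aa20, old), 1L)
    }
    if (has_motif[i]) {
      at <- sample.int(len - nchar(motif) + 1L, 1L)
      substr(s, at, at + nchar(motif) - 1L) <- motif
    }
    coords <- saw_coords(len)
    D <- as.matrix(dist(coords))
    M <- exp(-D / spec$contact_decay)
    seqs[i] <- s
    records[[i]] <- protein_record(ids[i], s, contact_map = M,
                                   max_seq_len = spec$max_len)
  }
  list(
    table = data.frame(target_id = ids, sequence = seqs, has_motif = has_motif,
                       stringsAsFactors = FALSE),
    records = setNames(records, ids)
  )
}

#' Generate labeled drug-target pairs under the planted rule
#'
#' The clean label is 1 iff the drug carries the drug motif AND the target
#' contains the protein motif (or either, under `or_rule`). Pairs are
#' sampled without replacement to hit `pos_fraction` exactly before noise;
#' labels are then flipped independently with probability `label_noise`.
#'
#' @param drugs output of [generate_drugs()]
#' @param targets output of [generate_targets()]
#' @param spec a [synthetic_spec()]
#' @return data frame `drug_id`, `target_id`, `label`, `clean_label`
#' @export
generate_pairs <- function(drugs, targets, spec) {
  set.seed(spec$seed + 2L)
  ttab <- if (is.list(targets) && !is.data.frame(targets)) targets$table else targets
  combos <- expand.grid(di = seq_len(nrow(drugs)), ti = seq_len(nrow(ttab)))
  pos_mask <- if (spec$or_rule) {
    drugs$has_motif[combos$di] | ttab$has_motif[combos$ti]
  } else {
    drugs$has_motif[combos$di] & ttab$has_motif[combos$ti]
  }
  n_pos <- round(spec$pos_fraction * spec$n_pairs)
  n_neg <- spec$n_pairs - n_pos
  pos_pool <- which(pos_mask)
  neg_pool <- which(!pos_mask)
  if (length(pos_pool) < n_pos || length(neg_pool) < n_neg) {
    stop("requested pos_fraction is unreachable: ", length(pos_pool),
         " positive and ", length(neg_pool), " negative combinations available")
  }
  sel <- c(sample(pos_pool, n_pos), sample(neg_pool, n_neg))
  clean <- c(rep(1L, n_pos), rep(0L, n_neg))
  flip <- rbinom(spec$n_pairs, 1L, spec$label_noise) == 1L
  lab <- ifelse(flip, 1L - clean, clean)
  out <- data.frame(
    drug_id = drugs$drug_id[combos$di[sel]],
    target_id = ttab$target_id[combos$ti[sel]],
    label = lab, clean_label = clean, stringsAsFactors = FALSE
  )
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Generate a complete synthetic DTI dataset
#'
#' @param spec a [synthetic_spec()]
#' @return a [dti_dataset()] whose `pairs` carry a `clean_label` column;
#'   drug and target tables are attached as attributes `drug_table` and
#'   `target_table`
#' @export
generate_dti_data <- function(spec = synthetic_spec()) {
  drugs <- generate_drugs(spec)
  targets <- generate_targets(spec)
  pairs <- generate_pairs(drugs, targets, spec)
  graphs <- smiles_table_to_graphs(drugs)
  ds <- dti_dataset(pairs, graphs, targets$records)
  attr(ds, "drug_table") <- drugs
  attr(ds, "target_table") <- targets$table
  ds
}
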