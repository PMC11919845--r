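#' @title Dataset split strategies
#'
#' @description
#' Three families of train/validation/test splits over drug-target pair
#' tables, in increasing order of difficulty: pair-level random splits,
#' unseen-entity splits (all pairs of a held-out entity set form the test
#' set) and similarity-cluster splits (entities are clustered by chemical or
#' sequence similarity and whole clusters are held out, so near-duplicates
#' never straddle the train/test boundary).
#'
#' @name splits
NULL

#' Split specification
#'
#' @param strategy one of `"random"`, `"unseen_drug"`, `"unseen_target"`,
#'   `"cluster_drug"`, `"cluster_target"`
#' @param fractions train/validation/test fractions, positive, summing to 1
#' @param seed integer seed
#' @return list of class `split_spec`
#' @export
split_spec <- function(strategy = c("random", "unseen_drug", "unseen_target",
                                    "cluster_drug", "cluster_target"),
                       fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  structure(list(strategy = strategy, fractions = fractions,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Tanimoto coefficient between two fingerprint bit sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 by convention.
#' Accepts integer sets of on-bit positions, or logical bit vectors of equal
#' length.
#'
#' @param fp_a,fp_b fingerprints
#' @return similarity in `[0, 1]`
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (is.logical(fp_a) || is.logical(fp_b)) {
    stopifnot(length(fp_a) == length(fp_b))
    fp_a <- which(fp_a); fp_b <- which(fp_b)
  }
  fp_a <- unique(as.integer(fp_a)); fp_b <- unique(as.integer(fp_b))
  u <- length(union(fp_a, fp_b))
  if (u == 0L) return(0)
  length(intersect(fp_a, fp_b)) / u
}

#' Circular (ECFP4-class) fingerprints for a set of SMILES
#'
#' Radius-2 extended-connectivity fingerprints computed by OpenBabel via
#' ChemmineOB, folded from its native 4096 bits to `nbits` by modular OR.
#'
#' @param smiles named character vector of SMILES (names = drug ids)
#' @param nbits folded fingerprint length
#' @return named list of sorted integer on-bit sets (1-based)
#' @export
ecfp4_fingerprints <- function(smiles, nbits = 2048L) {
  stopifnot(!is.null(names(smiles)))
  sdf <- ChemmineR::smiles2sdf(smiles)
  fp <- ChemmineR::fingerprintOB(sdf, "ECFP4")
  out <- lapply(seq_along(smiles), function(i) {
    bits <- which(as.numeric(fp[[i]]) != 0)
    sort(unique(((bits - 1L) %% nbits) + 1L))
  })
  setNames(out, names(smiles))
}

#' Pairwise Tanimoto similarity matrix over drugs
#'
#' @param smiles named character vector of SMILES
#' @return symmetric similarity matrix with unit diagonal
#' @export
drug_similarity_matrix <- function(smiles) {
  fps <- ecfp4_fingerprints(smiles)
  n <- length(fps)
  nb <- max(c(1L, unlist(fps)))
  B <- matrix(0, n, nb)
  for (i in seq_len(n)) B[i, fps[[i]]] <- 1
  inter <- tcrossprod(B)
  sz <- rowSums(B)
  uni <- outer(sz, sz, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  diag(sim) <- 1
  dimnames(sim) <- list(names(fps), names(fps))
  sim
}

#' Pairwise sequence-identity similarity matrix over targets
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 and affine gaps
#' (open 10, extend 0.5); similarity is the fraction of identical positions
#' over the alignment length.
#'
#' @param sequences named character vector of protein sequences
#' @return symmetric similarity matrix with unit diagonal
#' @export
target_similarity_matrix <- function(sequences) {
  n <- length(sequences)
  sim <- diag(1, n)
  dimnames(sim) <- list(names(sequences), names(sequences))
  if (n < 2L) return(sim)
  seqs <- Biostrings::AAStringSet(gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", toupper(sequences)))
  for (i in seq_len(n - 1L)) {
    aln <- Biostrings::pairwiseAlignment(
      seqs[(i + 1L):n], seqs[[i]],
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global"
    )
    sim[i, (i + 1L):n] <- sim[(i + 1L):n, i] <- Biostrings::pid(aln, type = "PID1") / 100
  }
  sim
}

#' Cluster entities by average-linkage hierarchical clustering
#'
#' Clusters on distance `1 - similarity` and cuts the dendrogram into
#' `k = ceiling(granularity / target_test_fraction)` clusters. The minimum
#' viable cut is `granularity = 1` (just enough clusters to assemble a test
#' side of the requested size); the default cuts three times finer so that
#' whole-cluster packing can approach the requested fraction within a few
#' percentage points while near-duplicates still merge at low heights and
#' stay in one cluster.
#'
#' @param similarity symmetric similarity matrix in `[0, 1]`
#' @param target_test_fraction intended test fraction (sets the cluster count)
#' @param granularity multiplier on the minimum cluster count
#' @return named integer vector of cluster assignments
#' @export
cluster_entities <- function(similarity, target_test_fraction = 0.2,
                             granularity = 3) {
  stopifnot(nrow(similarity) == ncol(similarity),
            target_test_fraction > 0, target_test_fraction < 1)
  n <- nrow(similarity)
  k <- min(ceiling(granularity / target_test_fraction), n)
  if (n < 2L || all(similarity >= 1 - 1e-12)) {
    stop("all entities are identical: a similarity-based split is impossible")
  }
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
  stats::cutree(hc, k = k)
}

#' Split a pair table into train/validation/test sets
#'
#' * `random`: pair-level shuffle split at the requested fractions.
#' * `unseen_drug` / `unseen_target`: a test fraction of entities is drawn at
#'   random; all their pairs form the test set and the remaining pairs are
#'   shuffled into train/validation.
#' * `cluster_drug` / `cluster_target`: entities are clustered by similarity
#'   ([cluster_entities()]); clusters are shuffled and assigned whole to the
#'   test side until the test pair fraction is reached.
#'
#' Entity granularity makes the unseen/cluster test fraction approximate;
#' the achieved fraction is attached as attribute `test_fraction`.
#'
#' @param pairs data frame with `drug_id`, `target_id`, `label`
#' @param spec a [split_spec()]
#' @param drugs named SMILES vector (required for `cluster_drug`)
#' @param targets named sequence vector (required for `cluster_target`)
#' @param similarity optional precomputed entity similarity matrix
#'   (overrides `drugs`/`targets` for cluster strategies)
#' @return list with data frames `train`, `val`, `test`
#' @export
split_pairs <- function(pairs, spec, drugs = NULL, targets = NULL,
                        similarity = NULL) {
  stopifnot(inherits(spec, "split_spec"))
  set.seed(spec$seed)
  n <- nrow(pairs)
  fr <- spec$fractions

  if (spec$strategy == "random") {
    idx <- sample.int(n)
    n_tr <- round(fr[1] * n)
    n_va <- round(fr[2] * n)
    n_te <- n - n_tr - n_va
    sets <- list(train = pairs[idx[seq_len(n_tr)], , drop = FALSE],
                 val = pairs[idx[n_tr + seq_len(n_va)], , drop = FALSE],
                 test = pairs[idx[n_tr + n_va + seq_len(max(n_te, 0L))], , drop = FALSE])
    return(finish_split(sets, n))
  }

  on_drug <- spec$strategy %in% c("unseen_drug", "cluster_drug")
  ent_col <- if (on_drug) "drug_id" else "target_id"
  ents <- unique(as.character(pairs[[ent_col]]))

  test_ents <- if (spec$strategy %in% c("unseen_drug", "unseen_target")) {
    sample(ents, max(1L, round(fr[3] * length(ents))))
  } else {
    sim <- similarity
    if (is.null(sim)) {
      if (on_drug) {
        if (is.null(drugs)) stop("cluster_drug split needs SMILES (drugs=) or a similarity matrix")
        sim <- drug_similarity_matrix(drugs[ents])
      } else {
        if (is.null(targets)) stop("cluster_target split needs sequences (targets=) or a similarity matrix")
        sim <- target_similarity_matrix(targets[ents])
      }
    }
    sim <- sim[ents, ents]
    cl <- cluster_entities(sim, fr[3])
    pair_counts <- table(factor(as.character(pairs[[ent_col]]), levels = ents))
    target <- fr[3] * n
    order_cl <- sample(unique(cl))
    sizes <- vapply(order_cl, function(cid) sum(pair_counts[ents[cl == cid]]),
                    numeric(1))
    # fill the test side with whole clusters in shuffled order without
    # overshooting, then close the remaining gap with the single remaining
    # cluster that lands nearest the target (closest achievable split)
    taken <- logical(length(order_cl))
    got <- 0
    for (i in seq_along(order_cl)) {
      if (got + sizes[i] <= target) {
        taken[i] <- TRUE
        got <- got + sizes[i]
      }
    }
    if (got < target && any(!taken)) {
      cand <- which(!taken)
      best <- cand[which.min(abs(got + sizes[cand] - target))]
      if (abs(got + sizes[best] - target) < abs(got - target)) {
        taken[best] <- TRUE
      }
    }
    ents[cl %in% order_cl[taken]]
  }

  in_test <- as.character(pairs[[ent_col]]) %in% test_ents
  rest <- which(!in_test)
  if (length(rest) == 0L || all(in_test == FALSE)) {
    stop("degenerate split: test side would be empty or everything")
  }
  idx <- sample(rest)
  n_tr <- round(length(rest) * fr[1] / (fr[1] + fr[2]))
  sets <- list(train = pairs[idx[seq_len(n_tr)], , drop = FALSE],
               val = pairs[idx[(n_tr + 1L):length(idx)], , drop = FALSE],
               test = pairs[in_test, , drop = FALSE])
  finish_split(sets, n)
}

finish_split <- function(sets, n) {
  for (nm in names(sets)) rownames(sets[[nm]]) <- NULL
  attr(sets, "test_fraction") <- nrow(sets$test) / n
  sets
}
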