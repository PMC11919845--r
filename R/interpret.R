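#' @title Interpretability: feature diversity and gradient attribution
#'
#' @description
#' Two diagnostics for the drug encoder. The diversity metric quantifies how
#' distinct the node representations of a graph are at each block (a collapse
#' toward zero with depth is the over-smoothing signature of deep message
#' passing). Gradient-weighted attribution projects the gradient of the
#' predicted interaction probability onto each block's node-feature map,
#' yielding one importance value per atom per block.
#'
#' @name interpret
NULL

#' Node-feature diversity of one feature matrix
#'
#' Pairwise Euclidean distances `d_ij` between node feature vectors;
#' per-node diversity `DS_i = mean over j != i of d_ij`; graph diversity
#' `DS_G = mean over i of DS_i`.
#'
#' @param node_features `[n x C]` matrix, `n >= 2`
#' @return list with `per_node` (length-n vector of `DS_i`) and `ds_g`
#' @export
graph_diversity <- function(node_features) {
  node_features <- as.matrix(node_features)
  n <- nrow(node_features)
  if (n < 2L) stop("graph diversity is undefined for fewer than 2 nodes")
  d <- as.matrix(dist(node_features))
  per_node <- rowSums(d) / (n - 1)
  list(per_node = unname(per_node), ds_g = mean(per_node))
}

#' Per-block feature diversity of an encoded drug
#'
#' Runs the drug encoder, captures the node-state matrix exported by each
#' block (the initial block's enhanced output, then each block's post-gating
#' state) and applies [graph_diversity()] to every one.
#'
#' @param model a `dti_model` (trained or freshly initialized)
#' @param graph a `molecular_graph` with at least 2 atoms
#' @return object of class `diversity_report`: data frame `per_graph` with
#'   columns `block` (0 = initial block) and `ds_g`, plus list `per_node`
#' @export
diversity_by_block <- function(model, graph) {
  cap <- new.env()
  invisible(drug_forward(model$params$drug, graph_data(graph), model$cfg$drug,
                         train = FALSE, capture = cap))
  divs <- lapply(cap$states, function(s) graph_diversity(adv(s)))
  structure(
    list(
      per_graph = data.frame(block = seq_along(divs) - 1L,
                             ds_g = vapply(divs, `[[`, numeric(1), "ds_g")),
      per_node = lapply(divs, `[[`, "per_node"),
      drug_id = graph$drug_id
    ),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report> ", x$drug_id, "\n", sep = "")
  print(x$per_graph)
  invisible(x)
}

#' Gradient-weighted node attribution for one drug-target pair
#'
#' For each block `n` of the drug encoder, with node-feature map `H(n)` and
#' predicted probability `P`: channel weights
#' `alpha_k(n) = mean over nodes v of dP/dH_{v,k}(n)` and node importance
#' `W(n) = sum over k of alpha_k(n) H_{.,k}(n)`, one value per atom. No
#' rectification is applied, so negative importances are reported as-is.
#'
#' @param model a `dti_model`
#' @param graph a `molecular_graph`
#' @param record a [protein_record()]
#' @param use_logit differentiate the pre-sigmoid logit instead of the
#'   probability
#' @return object of class `attribution_map`: per block, `alpha` (channel
#'   weights) and `node_importance` (length = atom count); plus the
#'   predicted `probability`
#' @export
grad_attribution <- function(model, graph, record, use_logit = FALSE) {
  if (graph$num_atoms < 1L) stop("cannot attribute a graph with zero atoms")
  cfg <- model$cfg
  wrapped <- params_wrap(model$params)
  cap <- new.env()
  gd <- graph_data(graph)
  td <- target_data(record, cfg$target)
  demb <- drug_forward(wrapped$drug, gd, cfg$drug, train = FALSE, capture = cap)
  temb <- target_forward(wrapped$target, td, cfg$target, train = FALSE)
  p <- predict_interaction(demb, temb, wrapped$head, train = FALSE)
  pv <- as.numeric(adv(p))
  # seeding with 1/(p(1-p)) converts probability gradients to logit gradients
  seed <- if (use_logit) 1 / (pv * (1 - pv)) else 1
  ad_backward(p, seed = seed)
  blocks <- lapply(cap$states, function(s) {
    H <- adv(s)
    G <- s$grad
    if (is.null(G)) G <- matrix(0, nrow(H), ncol(H))
    alpha <- colMeans(G)
    list(alpha = alpha, node_importance = as.numeric(H %*% alpha))
  })
  structure(
    list(blocks = blocks, probability = pv, drug_id = graph$drug_id,
         target_id = record$target_id),
    class = "attribution_map"
  )
}

#' @export
print.attribution_map <- function(x, ...) {
  cat("<attribution_map> ", x$drug_id, " x ", x$target_id,
      sprintf(" (p = %.4f), %d blocks, %d atoms\n", x$probability,
              length(x$blocks), length(x$blocks[[1]]$node_importance)), sep = "")
  invisible(x)
}

#' Tabulate an attribution map
#'
#' @param x an `attribution_map`
#' @param ... unused
#' @return data frame with columns `block`, `atom`, `importance`
#' @export
as.data.frame.attribution_map <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$blocks), function(b) {
    w <- x$blocks[[b]]$node_importance
    data.frame(block = b - 1L, atom = seq_along(w), importance = w)
  }))
}
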