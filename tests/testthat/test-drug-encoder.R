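# Gated GNN-block drug encoder: layer arithmetic, enhancement, gating and
# the permutation-invariant readout.

ns <- asNamespace("blockdti")

test_that("gnn_layer reproduces the hand-computed message-passing update", {
  # two connected nodes, identity update functions, linear activation:
  # x_i' = x_i + sum of neighbors, so [1,0] and [0,1] both become [1,1]
  g <- structure(list(drug_id = "g", smiles = NA, num_atoms = 2L,
                      node_features = rbind(c(1, 0), c(0, 1)),
                      edges = cbind(c(1L, 2L), c(2L, 1L))),
                 class = "molecular_graph")
  gd <- ns$graph_data(g)
  lp <- list(W1 = diag(2), W2 = diag(2), b = c(0, 0))
  out <- gnn_layer(g$node_features, gd, lp, "gin", activation = "linear")
  expect_equal(out, rbind(c(1, 1), c(1, 1)))
  # gcn normalizes by sqrt(d_i d_j) = 1 here, so it agrees
  expect_equal(gnn_layer(g$node_features, gd, lp, "gcn", activation = "linear"),
               rbind(c(1, 1), c(1, 1)))
})

test_that("an isolated node sees only its self term", {
  g <- structure(list(drug_id = "g", smiles = NA, num_atoms = 1L,
                      node_features = matrix(c(2, -3), 1, 2),
                      edges = matrix(integer(0), 0, 2)),
                 class = "molecular_graph")
  gd <- ns$graph_data(g)
  set.seed(1)
  lp <- list(W1 = matrix(rnorm(4), 2, 2), W2 = matrix(rnorm(4), 2, 2),
             b = c(0.1, -0.2), a_src = matrix(1, 2, 1), a_dst = matrix(1, 2, 1))
  want <- pmax(g$node_features %*% lp$W1 + rep(lp$b, each = 1), 0)
  for (type in c("gcn", "gin", "gat")) {
    expect_equal(gnn_layer(g$node_features, gd, lp, type), want, label = type)
  }
})

test_that("identical features on a complete graph stay identical", {
  n <- 4L
  und <- t(combn(n, 2))
  g <- structure(list(drug_id = "g", smiles = NA, num_atoms = n,
                      node_features = matrix(1, n, 3),
                      edges = cbind(c(und[, 1], und[, 2]), c(und[, 2], und[, 1]))),
                 class = "molecular_graph")
  gd <- ns$graph_data(g)
  set.seed(2)
  lp <- ns$init_gnn_layer_params(3L, 5L, "gat")
  for (type in c("gcn", "gin", "gat")) {
    out <- gnn_layer(g$node_features, gd, lp, type)
    expect_equal(out, out[rep(1, n), , drop = FALSE], label = type)
  }
})

test_that("block forward returns penultimate C and expanded 2C channels", {
  set.seed(3)
  g <- random_graph(6L, n_feat = 8L)
  gd <- ns$graph_data(g)
  for (type in c("gcn", "gat", "gin", "gat_gcn")) {
    bp <- ns$init_block_params(8L, 5L, 3L, type)
    out <- gnn_block_forward(g$node_features, gd, bp, type)
    expect_equal(ncol(out$penultimate), 5L)
    expect_equal(ncol(out$expanded), 10L)
    expect_equal(ncol(out$expanded), 2L * ncol(out$penultimate))
  }
  # zero weights and biases give a zero expansion
  bp0 <- rapply(ns$init_block_params(8L, 5L, 2L, "gcn"),
                function(x) x * 0, how = "replace")
  out0 <- gnn_block_forward(g$node_features, gd, bp0, "gcn")
  expect_true(all(out0$expanded == 0))
  expect_error(gnn_block_forward(g$node_features, gd, bp0[1], "gcn"), "at least 2")
})

test_that("feature enhancement obeys its closed forms", {
  pen <- rbind(c(1, 1), c(0.5, -2))
  expanded <- cbind(pen * 0, pen * 0)

  # d = 0: exact residual identity regardless of the expansion
  set.seed(4)
  rnd <- matrix(rnorm(8), 2, 4)
  expect_equal(feature_enhance(pen, rnd, 0), pen)

  # saturated negative gate closes the unit
  sat <- cbind(matrix(5, 2, 2), matrix(-1e6, 2, 2))
  expect_lt(max(abs(feature_enhance(pen, sat, 1) - pen)), 1e-6)

  # hand case: value half [2,2], gate half 0 -> sigmoid 0.5
  ex <- cbind(matrix(2, 1, 2), matrix(0, 1, 2))
  expect_equal(feature_enhance(matrix(1, 1, 2), ex, 1), matrix(2, 1, 2))

  expect_error(feature_enhance(pen, rnd[, 1:3], 1), "twice the channels")
})

test_that("gating limits hold for arbitrary random states", {
  set.seed(5)
  C <- 6L
  for (rep in 1:10) {
    prev <- matrix(rnorm(5 * C), 5, C)
    new <- matrix(rnorm(5 * C), 5, C)
    gp <- ns$init_gating_params(C)

    open <- gp; open$bz <- rep(1e3, C)
    R <- 1 / (1 + exp(-(new %*% gp$W1r + prev %*% gp$W2r +
                          rep(gp$br, each = 5))))
    cand <- tanh(new %*% gp$W1h + R * (prev %*% gp$W2h) + rep(gp$bh, each = 5))
    expect_equal(gating_update(prev, new, open), cand, tolerance = 1e-10)

    closed <- gp; closed$bz <- rep(-1e3, C)
    expect_equal(gating_update(prev, new, closed), prev, tolerance = 1e-10)

    zero <- rapply(gp, function(x) x * 0, how = "replace")
    expect_equal(gating_update(prev, new, zero), 0.5 * prev, tolerance = 1e-12)
  }
})

test_that("drug embedding is invariant to atom permutation", {
  set.seed(6)
  cfg <- tiny_cfg(channels = 8L)$drug
  params <- ns$init_drug_encoder_params(cfg)
  for (rep in 1:20) {
    g <- random_graph(sample(3:12, 1))
    perm <- sample(g$num_atoms)
    e1 <- encode_drug(g, params, cfg)
    e2 <- encode_drug(permute_graph(g, perm), params, cfg)
    expect_lt(max(abs(e1 - e2)), 1e-5)
  }
})

test_that("single atoms and duplicated components pool as expected", {
  set.seed(7)
  cfg <- tiny_cfg(channels = 6L)$drug
  params <- ns$init_drug_encoder_params(cfg)

  g1 <- random_graph(1L)
  cap <- new.env()
  emb <- ns$drug_forward(params, ns$graph_data(g1), cfg, capture = cap)
  final_state <- ns$adv(cap$states[[length(cap$states)]])
  expect_equal(as.numeric(emb), as.numeric(final_state))

  # two identical disconnected copies pool to the same embedding as one copy
  g <- random_graph(5L)
  twin <- structure(list(
    drug_id = "twin", smiles = NA, num_atoms = 10L,
    node_features = rbind(g$node_features, g$node_features),
    edges = rbind(g$edges, g$edges + 5L)
  ), class = "molecular_graph")
  expect_equal(encode_drug(g, params, cfg), encode_drug(twin, params, cfg),
               tolerance = 1e-10)
})

test_that("every block's exported state keeps C channels", {
  set.seed(8)
  for (type in c("gcn", "gat", "gin", "gat_gcn")) {
    cfg <- tiny_cfg(channels = 5L, n_blocks = 3L, gnn_type = type)$drug
    params <- ns$init_drug_encoder_params(cfg)
    cap <- new.env()
    g <- random_graph(7L)
    ns$drug_forward(params, ns$graph_data(g), cfg, capture = cap)
    expect_length(cap$states, cfg$n_blocks + 1L)
    for (s in cap$states) expect_equal(ncol(ns$adv(s)), 5L)
  }
})

test_that("with d = 0 and open gates the encoder equals an independent plain stack", {
  # independent reference: plain matrix loops, no autodiff, no encoder code
  set.seed(9)
  cfg <- tiny_cfg(channels = 5L, n_blocks = 2L, gnn_type = "gin")$drug
  cfg$enhancement_scale <- 0
  params <- ns$init_drug_encoder_params(cfg)
  params$gating$br <- rep(1e3, 5L)  # R -> 1
  params$gating$bz <- rep(1e3, 5L)  # Z -> 1

  g <- random_graph(6L)
  gd <- ns$graph_data(g)

  plain_layer <- function(X, lp, act) {
    out <- X %*% lp$W1 + rep(lp$b, each = nrow(X)) + (gd$A %*% X) %*% lp$W2
    if (act) pmax(out, 0) else out
  }
  run_block <- function(X, bp) {
    h <- X
    for (i in seq_along(bp)) {
      if (i < length(bp)) h <- plain_layer(h, bp[[i]], TRUE)
      else pen <- h  # with d = 0 the block output is the penultimate state
    }
    pen
  }
  h <- run_block(g$node_features, params$init_block)
  for (b in 1:2) {
    prev <- h
    new <- run_block(h, params$blocks[[b]])
    # open gates: output = tanh(new W1h + 1 * (prev W2h) + bh)
    h <- tanh(new %*% params$gating$W1h + prev %*% params$gating$W2h +
                rep(params$gating$bh, each = nrow(new)))
  }
  ref <- apply(h, 2, max)
  expect_equal(encode_drug(g, params, cfg), ref, tolerance = 1e-6)
})
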