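# Feature-diversity metric and gradient-weighted node attribution.

ns <- asNamespace("blockdti")

test_that("graph diversity matches hand calculations", {
  # 3-4-5 triangle: two nodes at distance 5
  expect_equal(graph_diversity(rbind(c(0, 0), c(3, 4)))$ds_g, 5.0)
  expect_equal(graph_diversity(matrix(1, 4, 3))$ds_g, 0)
  # 1-D nodes at 0, 1, 2
  d <- graph_diversity(matrix(c(0, 1, 2), 3, 1))
  expect_equal(d$per_node, c(1.5, 1, 1.5))
  expect_equal(d$ds_g, 4 / 3)
  expect_error(graph_diversity(matrix(1, 1, 3)), "fewer than 2")
})

test_that("graph diversity equals a brute-force double loop on random matrices", {
  brute <- function(M) {
    n <- nrow(M)
    tot <- 0
    for (i in 1:n) {
      dsi <- 0
      for (j in 1:n) if (j != i) dsi <- dsi + sqrt(sum((M[i, ] - M[j, ])^2))
      tot <- tot + dsi / (n - 1)
    }
    tot / n
  }
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    M <- matrix(rnorm(n * sample(1:8, 1)), nrow = n)
    expect_lt(abs(graph_diversity(M)$ds_g - brute(M)), 1e-10)
  }
})

test_that("diversity is permutation- and translation-invariant and scales linearly", {
  set.seed(42)
  for (rep in 1:10) {
    M <- matrix(rnorm(30), 6, 5)
    base <- graph_diversity(M)$ds_g
    expect_equal(graph_diversity(M[sample(6), ])$ds_g, base, tolerance = 1e-12)
    shift <- matrix(rep(rnorm(5), each = 6), 6, 5)
    expect_equal(graph_diversity(M + shift)$ds_g, base, tolerance = 1e-10)
    c0 <- abs(rnorm(1)) + 0.1
    expect_equal(graph_diversity(M * c0)$ds_g, c0 * base, tolerance = 1e-10)
  }
})

test_that("per-block diversity report is self-consistent with captured states", {
  set.seed(43)
  cfg <- tiny_cfg(channels = 6L, n_blocks = 3L)
  model <- init_dti_model(cfg, seed = 2L)
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O", "asp")
  rep <- diversity_by_block(model, g)
  expect_equal(nrow(rep$per_graph), cfg$drug$n_blocks + 1L)
  expect_equal(rep$per_graph$block, 0:3)

  cap <- new.env()
  ns$drug_forward(model$params$drug, ns$graph_data(g), cfg$drug, capture = cap)
  manual <- vapply(cap$states, function(s) graph_diversity(ns$adv(s))$ds_g,
                   numeric(1))
  expect_equal(rep$per_graph$ds_g, manual, tolerance = 1e-12)
})

test_that("attribution vanishes when the prediction ignores the drug branch", {
  set.seed(44)
  cfg <- tiny_cfg(channels = 4L)
  model <- init_dti_model(cfg, seed = 3L)
  # zero the head weights on the drug half of the concatenated embedding:
  # P then cannot depend on any drug-branch state
  model$params$head$W1[seq_len(4L), ] <- 0
  g <- smiles_to_graph("CCO", "eth")
  r <- random_record(12L, "t")
  am <- grad_attribution(model, g, r)
  for (b in am$blocks) {
    expect_equal(b$alpha, rep(0, 4L), tolerance = 1e-12)
    expect_equal(b$node_importance, rep(0, g$num_atoms), tolerance = 1e-12)
  }
})

test_that("a frozen mean probe yields the analytic attribution", {
  # P = mean over nodes and channels of H(n) has dP/dH = 1/(|V| C) per entry,
  # so alpha_k = 1/(|V| C) and W = rowSums(H)/(|V| C)
  set.seed(45)
  cfg <- tiny_cfg(channels = 5L, n_blocks = 1L)
  model <- init_dti_model(cfg, seed = 4L)
  g <- smiles_to_graph("CCN(CC)CC", "d")
  gd <- ns$graph_data(g)
  wrapped <- ns$params_wrap(model$params$drug)
  cap <- new.env()
  ns$drug_forward(wrapped, gd, cfg$drug, capture = cap)
  s <- cap$states[[2]]
  probe <- ns$ad_mean(s)
  ns$ad_backward(probe)
  H <- ns$adv(s)
  alpha <- colMeans(s$grad)
  expect_equal(alpha, rep(1 / (nrow(H) * ncol(H)), ncol(H)), tolerance = 1e-12)
  expect_equal(as.numeric(H %*% alpha), rowSums(H) / (nrow(H) * ncol(H)),
               tolerance = 1e-12)
})

test_that("attribution gradients match finite differences through the model", {
  set.seed(46)
  cfg <- tiny_cfg(channels = 4L, n_blocks = 1L)
  model <- init_dti_model(cfg, seed = 5L)
  g <- smiles_to_graph("CCO", "eth")
  r <- random_record(10L, "t")
  gd <- ns$graph_data(g)
  td <- ns$target_data(r, cfg$target)

  # gradient of P with respect to the initial block's exported state,
  # via a tape whose leaf is that state
  cap <- new.env()
  base_states <- local({
    c2 <- new.env()
    ns$drug_forward(model$params$drug, gd, cfg$drug, capture = c2)
    lapply(c2$states, identity)
  })
  H0 <- base_states[[1]]

  # forward from a given initial-block state through the remaining blocks
  forward_from <- function(Hmat) {
    h <- Hmat
    prev <- h
    bl <- gnn_block_forward(h, gd, model$params$drug$blocks[[1]], cfg$drug$gnn_type)
    enh <- feature_enhance(bl$penultimate, bl$expanded, cfg$drug$enhancement_scale)
    h <- gating_update(prev, enh, model$params$drug$gating)
    demb <- ns$ad_colmax(h)
    temb <- ns$target_forward(model$params$target, td, cfg$target)
    as.numeric(ns$adv(predict_interaction(demb, temb, model$params$head)))
  }

  leaf <- ns$ad_leaf(H0)
  p <- local({
    h <- leaf
    prev <- h
    bl <- gnn_block_forward(h, gd, model$params$drug$blocks[[1]], cfg$drug$gnn_type)
    enh <- feature_enhance(bl$penultimate, bl$expanded, cfg$drug$enhancement_scale)
    h <- gating_update(prev, enh, model$params$drug$gating)
    predict_interaction(ns$ad_colmax(h), ns$target_forward(model$params$target, td, cfg$target),
                        model$params$head)
  })
  ns$ad_backward(p)
  G <- leaf$grad

  set.seed(47)
  h <- 1e-5
  for (trial in 1:10) {
    i <- sample(length(H0), 1)
    Hp <- H0; Hp[i] <- Hp[i] + h
    Hm <- H0; Hm[i] <- Hm[i] - h
    fd <- (forward_from(Hp) - forward_from(Hm)) / (2 * h)
    denom <- max(abs(fd), abs(G[i]), 1e-7)
    expect_lt(abs(fd - G[i]) / denom, 1e-3)
  }
})

test_that("attribution is equivariant under atom permutation", {
  set.seed(48)
  cfg <- tiny_cfg(channels = 5L)
  model <- init_dti_model(cfg, seed = 6L)
  r <- random_record(12L, "t")
  for (rep in 1:10) {
    g <- random_graph(sample(4:9, 1))
    perm <- sample(g$num_atoms)
    a1 <- grad_attribution(model, g, r)
    a2 <- grad_attribution(model, permute_graph(g, perm), r)
    for (b in seq_along(a1$blocks)) {
      expect_equal(a2$blocks[[b]]$node_importance,
                   a1$blocks[[b]]$node_importance[perm], tolerance = 1e-6)
    }
  }
})
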