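# Shared fixtures: tiny configurations and randomly generated graphs/records,
# all built in code under fixed seeds.

tiny_cfg <- function(channels = 4L, n_blocks = 2L, n_layers = 2L,
                     gnn_type = "gat_gcn", dropout = 0, ...) {
  dti_model_config(channels = channels, n_blocks = n_blocks,
                   n_layers = n_layers, gnn_type = gnn_type,
                   dropout = dropout, head_hidden = c(6L, 4L), ...)
}

# random connected graph in molecular_graph form (features one-hot-ish but
# arbitrary; the encoders only assume numeric features)
random_graph <- function(n_atoms, n_feat = 64L, p_edge = 0.3) {
  feat <- matrix(rbinom(n_atoms * n_feat, 1L, 0.1), n_atoms, n_feat)
  edges <- matrix(integer(0), 0L, 2L)
  if (n_atoms > 1L) {
    und <- cbind(seq_len(n_atoms - 1L), 2L:n_atoms)  # backbone keeps it connected
    extra <- which(upper.tri(matrix(0, n_atoms, n_atoms)) &
                     matrix(runif(n_atoms^2) < p_edge, n_atoms, n_atoms),
                   arr.ind = TRUE)
    und <- unique(rbind(und, extra))
    edges <- cbind(c(und[, 1], und[, 2]), c(und[, 2], und[, 1]))
  }
  colnames(edges) <- c("from", "to")
  structure(list(drug_id = "rnd", smiles = NA_character_, node_features = feat,
                 edges = edges, num_atoms = n_atoms),
            class = "molecular_graph")
}

# apply an atom permutation to a molecular_graph
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  edges <- graph$edges
  if (nrow(edges) > 0L) {
    edges <- cbind(inv[edges[, 1]], inv[edges[, 2]])
    colnames(edges) <- c("from", "to")
  }
  structure(list(drug_id = graph$drug_id, smiles = graph$smiles,
                 node_features = graph$node_features[perm, , drop = FALSE],
                 edges = edges, num_atoms = graph$num_atoms),
            class = "molecular_graph")
}

random_record <- function(len, id = "t", decay = 3, seed_offset = 0L) {
  s <- paste(sample(blockdti:::AA_ALPHABET[1:20], len, replace = TRUE),
             collapse = "")
  coords <- blockdti:::saw_coords(len)
  M <- exp(-as.matrix(dist(coords)) / decay)
  protein_record(id, s, contact_map = M)
}

tiny_dataset <- function(seed = 5L) {
  set.seed(seed)
  g1 <- smiles_to_graph("CC(=O)Oc1ccccc1", "d1")
  g2 <- smiles_to_graph("CCN(CC)CC", "d2")
  r1 <- random_record(15L, "t1")
  r2 <- random_record(12L, "t2")
  pairs <- data.frame(
    drug_id = c("d1", "d2", "d1", "d2"),
    target_id = c("t1", "t1", "t2", "t2"),
    label = c(1, 0, 0, 1)
  )
  dti_dataset(pairs, list(d1 = g1, d2 = g2), list(t1 = r1, t2 = r2))
}

# numeric gradient of a scalar function by central differences
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
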