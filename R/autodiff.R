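#' @title Reverse-mode automatic differentiation tape
#'
#' @description
#' A minimal reverse-mode autodiff engine over matrix-level operations. Every
#' op accepts either a plain numeric array or an `adnode`; when no argument is
#' a node the op computes eagerly and returns a plain value, so the same
#' forward code serves both training (tape on) and inference (tape off).
#'
#' Nodes are environments holding `value`, the list of `adnode` parents, and a
#' `back` closure mapping the incoming gradient to one gradient per parent.
#' [ad_backward()] topologically sorts the graph reachable from a scalar root
#' and accumulates gradients into every node's `grad` field, so gradients of
#' intermediate feature maps (needed for node attribution) come for free.
#'
#' @name autodiff
#' @keywords internal
NULL

is_adnode <- function(x) inherits(x, "adnode")

#' Wrap a value as a differentiable leaf node
#' @param value numeric vector or matrix
#' @return an `adnode`
#' @keywords internal
ad_leaf <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- list()
  e$back <- NULL
  e$grad <- NULL
  class(e) <- "adnode"
  e
}

# Internal node constructor. `parents` may contain non-nodes; those are
# dropped together with their entry in the gradient list returned by `back`.
ad_node <- function(value, parents, back) {
  keep <- vapply(parents, is_adnode, logical(1))
  e <- new.env(parent = emptyenv())
  e$value <- value
  if (any(keep)) {
    e$parents <- parents[keep]
    e$keep <- keep
    e$back <- back
  } else {
    e$parents <- list()
    e$back <- NULL
  }
  e$grad <- NULL
  class(e) <- "adnode"
  e
}

adv <- function(x) if (is_adnode(x)) x$value else x

any_node <- function(...) {
  for (x in list(...)) if (is_adnode(x)) return(TRUE)
  FALSE
}

#' Backpropagate gradients from a scalar root node
#'
#' @param root an `adnode` whose value is scalar
#' @param seed gradient seed at the root (default 1)
#' @return invisibly, the root
#' @keywords internal
ad_backward <- function(root, seed = 1) {
  stopifnot(is_adnode(root), length(root$value) == 1L)
  # iterative DFS post-order = topological order; preallocated stacks
  cap <- 1024L
  nodes <- vector("list", cap)
  stages <- integer(cap)
  order <- vector("list", cap)
  n_ord <- 0L
  top <- 1L
  nodes[[1L]] <- root
  stages[1L] <- 1L
  token <- new.env(parent = emptyenv())
  while (top > 0L) {
    nd <- nodes[[top]]
    if (stages[top] == 1L) {
      if (identical(nd$.seen, token)) {
        top <- top - 1L
        next
      }
      nd$.seen <- token
      stages[top] <- 2L
      for (p in nd$parents) {
        if (!identical(p$.seen, token)) {
          top <- top + 1L
          if (top > cap) {
            cap <- cap * 2L
            length(nodes) <- cap
            length(stages) <- cap
          }
          nodes[[top]] <- p
          stages[top] <- 1L
        }
      }
    } else {
      top <- top - 1L
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) length(order) <- 2L * length(order)
      order[[n_ord]] <- nd
    }
  }
  order <- order[seq_len(n_ord)]
  for (nd in order) nd$grad <- NULL
  root$grad <- seed
  for (i in rev(seq_len(n_ord))) {
    nd <- order[[i]]
    if (is.null(nd$back) || is.null(nd$grad)) next
    gs <- nd$back(nd$grad)
    gs <- gs[nd$keep]
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(root)
}

# ---- arithmetic ops ---------------------------------------------------------

#' @rdname autodiff
ad_mm <- function(a, b) {
  av <- adv(a); bv <- adv(b)
  v <- av %*% bv
  if (!any_node(a, b)) return(v)
  ad_node(v, list(a, b), function(g) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

# Add two same-shape arrays, or broadcast a length-ncol bias vector over rows.
#' @rdname autodiff
ad_add <- function(a, b) {
  av <- adv(a); bv <- adv(b)
  bias_b <- is.matrix(av) && !is.matrix(bv) && length(bv) == ncol(av)
  v <- if (bias_b) sweep(av, 2L, bv, "+") else av + bv
  if (!any_node(a, b)) return(v)
  ad_node(v, list(a, b), function(g) {
    gb <- if (bias_b) colSums(g) else g
    list(g, gb)
  })
}

#' @rdname autodiff
ad_mul <- function(a, b) {
  av <- adv(a); bv <- adv(b)
  v <- av * bv
  if (!any_node(a, b)) return(v)
  ad_node(v, list(a, b), function(g) list(g * bv, g * av))
}

#' @rdname autodiff
ad_scale <- function(a, k) {
  av <- adv(a)
  v <- av * k
  if (!is_adnode(a)) return(v)
  ad_node(v, list(a), function(g) list(g * k))
}

#' @rdname autodiff
ad_oneminus <- function(a) {
  av <- adv(a)
  v <- 1 - av
  if (!is_adnode(a)) return(v)
  ad_node(v, list(a), function(g) list(-g))
}

# ---- activations ------------------------------------------------------------

#' @rdname autodiff
ad_relu <- function(a) {
  av <- adv(a)
  v <- pmax(av, 0)
  if (!is_adnode(a)) return(v)
  ad_node(v, list(a), function(g) list(g * (av > 0)))
}

#' @rdname autodiff
ad_leaky_relu <- function(a, slope = 0.2) {
  av <- adv(a)
  v <- ifelse(av > 0, av, slope * av)
  if (!is_adnode(a)) return(v)
  ad_node(v, list(a), function(g) list(g * ifelse(av > 0, 1, slope)))
}

#' @rdname autodiff
ad_sigmoid <- function(a) {
  av <- adv(a)
  v <- 1 / (1 + exp(-av))
  if (!is_adnode(a)) return(v)
  ad_node(v, list(a), function(g) list(g * v * (1 - v)))
}

#' @rdname autodiff
ad_tanh <- function(a) {
  av <- adv(a)
  v <- tanh(av)
  if (!is_adnode(a)) return(v)
  ad_node(v, list(a), function(g) list(g * (1 - v^2)))
}

# Gated linear unit over columns: first half = value a, second half = gate b,
# output a * sigmoid(b). Errors on an odd channel count.
#' @rdname autodiff
ad_glu <- function(x) {
  xv <- adv(x)
  nc <- ncol(xv)
  if (nc %% 2L != 0L) stop("GLU input must have an even number of channels, got ", nc)
  h <- nc %/% 2L
  a <- xv[, seq_len(h), drop = FALSE]
  sb <- 1 / (1 + exp(-xv[, h + seq_len(h), drop = FALSE]))
  v <- a * sb
  if (!is_adnode(x)) return(v)
  ad_node(v, list(x), function(g) {
    list(cbind(g * sb, g * a * sb * (1 - sb)))
  })
}

# ---- structural ops ---------------------------------------------------------

#' @rdname autodiff
ad_cbind <- function(a, b) {
  av <- adv(a); bv <- adv(b)
  v <- cbind(av, bv)
  if (!any_node(a, b)) return(v)
  na <- ncol(av)
  ad_node(v, list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

# Gather rows by (possibly repeated) index; gradient scatter-adds.
#' @rdname autodiff
ad_rows <- function(x, idx) {
  xv <- adv(x)
  v <- xv[idx, , drop = FALSE]
  if (!is_adnode(x)) return(v)
  nr <- nrow(xv); nc <- ncol(xv)
  ad_node(v, list(x), function(g) {
    gx <- matrix(0, nr, nc)
    agg <- rowsum(g, group = idx)
    gx[as.integer(rownames(agg)), ] <- agg
    list(gx)
  })
}

# Shift rows by k (positive k moves content down), zero padding; the linear
# building block for same-padded 1D convolution along the sequence axis.
#' @rdname autodiff
ad_shift_rows <- function(x, k) {
  xv <- adv(x)
  n <- nrow(xv)
  v <- matrix(0, n, ncol(xv))
  if (k >= 0) {
    if (k < n) v[(k + 1L):n, ] <- xv[seq_len(n - k), , drop = FALSE]
  } else {
    if (-k < n) v[seq_len(n + k), ] <- xv[(1L - k):n, , drop = FALSE]
  }
  if (!is_adnode(x)) return(v)
  ad_node(v, list(x), function(g) {
    gx <- matrix(0, n, ncol(xv))
    if (k >= 0) {
      if (k < n) gx[seq_len(n - k), ] <- g[(k + 1L):n, , drop = FALSE]
    } else {
      if (-k < n) gx[(1L - k):n, ] <- g[seq_len(n + k), , drop = FALSE]
    }
    list(gx)
  })
}

# Unfold a sequence matrix for same-padded 1D convolution: column block t of
# the output holds the input shifted by t - 1 - (window-1)/2 rows (zero
# padded), so one matrix product with a [window*C_in, C_out] kernel applies
# the whole convolution. Single-allocation equivalent of binding
# ad_shift_rows() copies, which profiling showed dominating training time.
#' @rdname autodiff
ad_unfold_rows <- function(x, window) {
  xv <- adv(x)
  r <- (window - 1L) %/% 2L
  n <- nrow(xv); nc <- ncol(xv)
  v <- matrix(0, n, window * nc)
  for (t in seq_len(window)) {
    k <- t - 1L - r
    rows <- max(1L, 1L - k):min(n, n - k)
    if (length(rows) > 0L && rows[1] <= rows[length(rows)]) {
      v[rows, (t - 1L) * nc + seq_len(nc)] <- xv[rows + k, , drop = FALSE]
    }
  }
  if (!is_adnode(x)) return(v)
  ad_node(v, list(x), function(g) {
    gx <- matrix(0, n, nc)
    for (t in seq_len(window)) {
      k <- t - 1L - r
      rows <- max(1L, 1L - k):min(n, n - k)
      if (length(rows) > 0L && rows[1] <= rows[length(rows)]) {
        gx[rows + k, ] <- gx[rows + k, , drop = FALSE] +
          g[rows, (t - 1L) * nc + seq_len(nc), drop = FALSE]
      }
    }
    list(gx)
  })
}

# Column-wise max over rows (graph readout). Gradient routes to the first
# argmax row per column.
#' @rdname autodiff
ad_colmax <- function(x) {
  xv <- adv(x)
  if (!is.matrix(xv)) xv <- matrix(xv, nrow = 1L)
  am <- max.col(t(xv), ties.method = "first")
  v <- xv[cbind(am, seq_len(ncol(xv)))]
  v <- matrix(v, nrow = 1L)
  if (!is_adnode(x)) return(v)
  ad_node(v, list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[cbind(am, seq_len(ncol(xv)))] <- g
    list(gx)
  })
}

# Row-wise L2 normalization; rows with zero norm pass through unchanged.
#' @rdname autodiff
ad_l2_rows <- function(x) {
  xv <- adv(x)
  nrm <- sqrt(rowSums(xv^2))
  safe <- ifelse(nrm > 0, nrm, 1)
  v <- xv / safe
  if (!is_adnode(x)) return(v)
  ad_node(v, list(x), function(g) {
    dots <- rowSums(g * xv)
    list(g / safe - xv * (dots / safe^3))
  })
}

#' @rdname autodiff
ad_sum <- function(x) {
  xv <- adv(x)
  v <- sum(xv)
  if (!is_adnode(x)) return(v)
  ad_node(v, list(x), function(g) list(array(g, dim = dim(xv) %||% length(xv))))
}

#' @rdname autodiff
ad_mean <- function(x) {
  xv <- adv(x)
  v <- mean(xv)
  if (!is_adnode(x)) return(v)
  n <- length(xv)
  ad_node(v, list(x), function(g) list(array(g / n, dim = dim(xv) %||% length(xv))))
}

# Mean of a list of scalar nodes (the batch loss).
#' @rdname autodiff
ad_mean_scalars <- function(lst) {
  vals <- vapply(lst, function(x) as.numeric(adv(x)), numeric(1))
  v <- mean(vals)
  if (!any(vapply(lst, is_adnode, logical(1)))) return(v)
  n <- length(lst)
  ad_node(v, lst, function(g) rep(list(g / n), n))
}

# ---- graph-attention helpers ------------------------------------------------

# Softmax of a score vector within segments (one segment per destination
# node); used for attention coefficients over incoming edges.
#' @rdname autodiff
ad_segment_softmax <- function(s, seg, nseg) {
  sv <- as.numeric(adv(s))
  seg <- as.integer(seg)
  mx <- rep(-Inf, nseg)
  mxa <- tapply(sv, seg, max)
  mx[as.integer(names(mxa))] <- mxa
  ex <- exp(sv - mx[seg])
  tot <- rep(1, nseg)
  tota <- tapply(ex, seg, sum)
  tot[as.integer(names(tota))] <- tota
  v <- ex / tot[seg]
  if (!is_adnode(s)) return(v)
  ad_node(v, list(s), function(g) {
    g <- as.numeric(g)
    wg <- rep(0, nseg)
    wga <- tapply(g * v, seg, sum)
    wg[as.integer(names(wga))] <- wga
    list(v * (g - wg[seg]))
  })
}

# out[i, ] = sum over edges e with dst[e] == i of w[e] * xe[e, ].
#' @rdname autodiff
ad_edge_aggregate <- function(w, xe, dst, n_nodes) {
  wv <- as.numeric(adv(w)); xev <- adv(xe)
  dst <- as.integer(dst)
  v <- matrix(0, n_nodes, ncol(xev))
  if (length(dst) > 0L) {
    agg <- rowsum(xev * wv, group = dst)
    v[as.integer(rownames(agg)), ] <- agg
  }
  if (!any_node(w, xe)) return(v)
  ad_node(v, list(w, xe), function(g) {
    ge <- g[dst, , drop = FALSE]
    list(rowSums(ge * xev), ge * wv)
  })
}

# ---- loss -------------------------------------------------------------------

# Binary cross-entropy of one probability against a binary label, with the
# probability clamped to [eps, 1 - eps] before the logs.
#' @rdname autodiff
ad_bce <- function(p, y, eps = 1e-7) {
  pv <- as.numeric(adv(p))
  pc <- min(max(pv, eps), 1 - eps)
  v <- -(y * log(pc) + (1 - y) * log(1 - pc))
  if (!is_adnode(p)) return(v)
  ad_node(v, list(p), function(g) {
    d <- if (pv < eps || pv > 1 - eps) 0 else (pc - y) / (pc * (1 - pc))
    list(g * d)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
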