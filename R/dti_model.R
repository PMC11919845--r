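#' @title Joint drug-target interaction model
#'
#' @description
#' Couples the drug and target encoders through a three-layer MLP head that
#' maps the concatenated embeddings to an interaction probability, trained
#' with mini-batch Adam on binary cross-entropy. Training is fully seeded:
#' initialization, shuffling, dropout and undersampling all derive from one
#' master seed.
#'
#' @name dti_model
NULL

#' Full model configuration
#'
#' @inheritParams drug_encoder_config
#' @inheritParams target_encoder_config
#' @param head_hidden widths of the two hidden MLP layers
#' @return list of class `dti_model_config`
#' @export
dti_model_config <- function(channels = 128L, n_blocks = 5L, n_layers = 2L,
                             gnn_type = "gat_gcn", enhancement_scale = 1.0,
                             dropout = 0.2, windows = c(3L, 5L, 7L),
                             contact_threshold = 0.5, use_graph = TRUE,
                             max_seq_len = 1000L, head_hidden = c(512L, 128L)) {
  structure(
    list(
      drug = drug_encoder_config(channels, n_blocks, n_layers, gnn_type,
                                 enhancement_scale, dropout),
      target = target_encoder_config(channels, windows, contact_threshold,
                                     use_graph, max_seq_len),
      channels = as.integer(channels), dropout = dropout,
      head_hidden = as.integer(head_hidden)
    ),
    class = "dti_model_config"
  )
}

init_head_params <- function(in_dim, hidden) {
  list(
    W1 = glorot(in_dim, hidden[1]), b1 = numeric(hidden[1]),
    W2 = glorot(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
    W3 = glorot(hidden[2], 1L), b3 = numeric(1L)
  )
}

#' Initialize an untrained model
#'
#' @param cfg a [dti_model_config()]
#' @param seed integer seed driving parameter initialization
#' @return object of class `dti_model`
#' @export
init_dti_model <- function(cfg, seed = 1L) {
  set.seed(seed)
  params <- list(
    drug = init_drug_encoder_params(cfg$drug),
    target = init_target_encoder_params(cfg$target),
    head = init_head_params(2L * cfg$channels, cfg$head_hidden)
  )
  structure(list(cfg = cfg, params = params, history = NULL), class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  cat("<dti_model> C=", x$cfg$channels, ", L=", x$cfg$drug$n_blocks,
      " blocks x N=", x$cfg$drug$n_layers, " ", x$cfg$drug$gnn_type,
      " layers, graph pathway ", if (x$cfg$target$use_graph) "on" else "off",
      if (is.null(x$history)) ", untrained" else
        paste0(", trained ", nrow(x$history), " epochs"),
      "\n", sep = "")
  invisible(x)
}

#' Predict an interaction probability from a pair of embeddings
#'
#' Concatenates the two embeddings and applies the three-layer MLP head:
#' two ReLU layers (with dropout during training) and a final linear map
#' through a sigmoid.
#'
#' @param drug_emb `1 x C` embedding row (matrix or autodiff node)
#' @param target_emb `1 x C` embedding row (matrix or autodiff node)
#' @param head_params MLP parameters
#' @param train logical; enables dropout
#' @param dropout dropout rate used when `train = TRUE`
#' @return scalar probability in (0, 1) (autodiff node under the tape)
#' @export
predict_interaction <- function(drug_emb, target_emb, head_params,
                                train = FALSE, dropout = 0.2) {
  z <- ad_cbind(drug_emb, target_emb)
  h <- ad_relu(ad_add(ad_mm(z, head_params$W1), head_params$b1))
  if (train) h <- apply_dropout(h, dropout)
  h <- ad_relu(ad_add(ad_mm(h, head_params$W2), head_params$b2))
  if (train) h <- apply_dropout(h, dropout)
  ad_sigmoid(ad_add(ad_mm(h, head_params$W3), head_params$b3))
}

#' Binary cross-entropy loss
#'
#' `-(y log p + (1 - y) log(1 - p))` with the probability clamped to
#' `[eps, 1 - eps]` so the loss stays finite at confident predictions.
#'
#' @param y binary label (0 or 1)
#' @param p predicted probability
#' @param eps clamping constant
#' @return non-negative loss value
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  stopifnot(y %in% c(0, 1))
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# ---- dataset container ------------------------------------------------------

#' Bundle pairs, molecular graphs and protein records into a dataset
#'
#' @param pairs data frame with columns `drug_id`, `target_id`, `label`
#' @param graphs named list of `molecular_graph` objects
#' @param records named list of [protein_record()] objects
#' @return object of class `dti_dataset`
#' @export
dti_dataset <- function(pairs, graphs, records) {
  stopifnot(all(c("drug_id", "target_id", "label") %in% names(pairs)))
  pairs$drug_id <- as.character(pairs$drug_id)
  pairs$target_id <- as.character(pairs$target_id)
  missing_d <- setdiff(unique(pairs$drug_id), names(graphs))
  if (length(missing_d) > 0L) {
    stop("pairs reference drugs without graphs: ", paste(head(missing_d, 5L), collapse = ", "))
  }
  missing_t <- setdiff(unique(pairs$target_id), names(records))
  if (length(missing_t) > 0L) {
    stop("pairs reference targets without records: ", paste(head(missing_t, 5L), collapse = ", "))
  }
  if (!all(pairs$label %in% c(0, 1))) stop("labels must be 0 or 1")
  structure(list(pairs = pairs, graphs = graphs, records = records),
            class = "dti_dataset")
}

# Per-entity precomputation shared across epochs.
prepare_entities <- function(dataset, cfg) {
  list(
    drug = lapply(dataset$graphs, graph_data),
    target = lapply(dataset$records, target_data, cfg = cfg$target)
  )
}

# Forward one (drug, target) pair to a probability, optionally reusing
# already-computed embedding nodes (deduplicated within a batch).
forward_pair <- function(params, ddata, tdata, cfg, train = FALSE,
                         capture = NULL) {
  demb <- drug_forward(params$drug, ddata, cfg$drug, train = train, capture = capture)
  temb <- target_forward(params$target, tdata, cfg$target, train = train)
  predict_interaction(demb, temb, params$head, train = train, dropout = cfg$dropout)
}

# ---- parameter-tree utilities ----------------------------------------------

params_wrap <- function(p) {
  if (is.list(p)) lapply(p, params_wrap) else ad_leaf(p)
}

params_unwrap_grads <- function(w) {
  if (is.list(w)) return(lapply(w, params_unwrap_grads))
  g <- w$grad
  if (is.null(g)) g <- array(0, dim = dim(w$value) %||% length(w$value))
  g
}

params_map2 <- function(a, b, f) {
  if (is.list(a)) return(mapply(params_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b)
}

params_map <- function(a, f) {
  if (is.list(a)) return(lapply(a, params_map, f = f))
  f(a)
}

adam_init <- function(params) {
  list(m = params_map(params, function(x) x * 0),
       v = params_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- params_map2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  list(params = params_map2(params, upd, function(p, u) p - u), state = state)
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' @param batch_size mini-batch size
#' @param learning_rate Adam learning rate
#' @param max_epochs maximum number of epochs
#' @param patience epochs without validation AUROC improvement before early
#'   stopping
#' @param seed master seed for initialization, shuffling, dropout and
#'   undersampling
#' @param balance undersample the training split to a 1:1 class ratio
#'   (validation and test are never touched)
#' @return list of class `train_config`
#' @export
train_config <- function(batch_size = 64L, learning_rate = 5e-4,
                         max_epochs = 30L, patience = 20L, seed = 1L,
                         balance = FALSE) {
  stopifnot(batch_size >= 1L, learning_rate > 0, max_epochs >= 1L, patience >= 1L)
  if (is.null(seed)) stop("a seed is mandatory")
  structure(list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 seed = as.integer(seed), balance = isTRUE(balance)),
            class = "train_config")
}

undersample_to_balance <- function(pairs) {
  pos <- which(pairs$label == 1)
  neg <- which(pairs$label == 0)
  k <- min(length(pos), length(neg))
  keep <- sort(c(sample(pos, k), sample(neg, k)))
  pairs[keep, , drop = FALSE]
}

#' Train a DTI model
#'
#' Mini-batch Adam on mean binary cross-entropy. After each epoch the model
#' is evaluated on the validation split (AUROC, with per-entity embedding
#' caching) and the parameters of the best validation epoch are retained.
#' Within a batch, each unique drug and target is encoded once and its
#' embedding node shared across the batch's pairs, so encoder gradients
#' accumulate over all pairs touching the entity.
#'
#' @param dataset a [dti_dataset()] providing graphs and records
#' @param train_pairs,val_pairs disjoint pair data frames
#' @param model_cfg a [dti_model_config()]
#' @param cfg a [train_config()]
#' @param verbose print per-epoch progress
#' @return trained `dti_model` with a `history` data frame (per-epoch train
#'   loss and validation AUROC)
#' @export
train_dti <- function(dataset, train_pairs, val_pairs, model_cfg,
                      cfg = train_config(), verbose = FALSE) {
  if (nrow(train_pairs) == 0L) stop("empty training split")
  if (nrow(val_pairs) == 0L) stop("empty validation split")
  overlap <- intersect(
    paste(train_pairs$drug_id, train_pairs$target_id),
    paste(val_pairs$drug_id, val_pairs$target_id)
  )
  if (length(overlap) > 0L) stop("train and validation splits share pairs")

  set.seed(cfg$seed)
  model <- init_dti_model(model_cfg, seed = cfg$seed)
  if (cfg$balance) train_pairs <- undersample_to_balance(train_pairs)
  ent <- prepare_entities(dataset, model_cfg)

  opt <- adam_init(model$params)
  best <- list(auroc = -Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_auroc = numeric(0))
  n <- nrow(train_pairs)

  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      bidx <- idx[start:min(start + cfg$batch_size - 1L, n)]
      bp <- train_pairs[bidx, , drop = FALSE]
      wrapped <- params_wrap(model$params)

      ud <- unique(bp$drug_id)
      ut <- unique(bp$target_id)
      dembs <- setNames(lapply(ud, function(id) {
        drug_forward(wrapped$drug, ent$drug[[id]], model_cfg$drug, train = TRUE)
      }), ud)
      tembs <- setNames(lapply(ut, function(id) {
        target_forward(wrapped$target, ent$target[[id]], model_cfg$target, train = TRUE)
      }), ut)

      pair_losses <- lapply(seq_len(nrow(bp)), function(i) {
        p <- predict_interaction(dembs[[bp$drug_id[i]]], tembs[[bp$target_id[i]]],
                                 wrapped$head, train = TRUE, dropout = model_cfg$dropout)
        ad_bce(p, bp$label[i])
      })
      loss <- ad_mean_scalars(pair_losses)
      if (!is.finite(adv(loss))) {
        stop("non-finite training loss at epoch ", epoch,
             " (batch starting at pair ", start, "); learning diverged")
      }
      ad_backward(loss)
      grads <- params_unwrap_grads(wrapped)
      stepped <- adam_step(model$params, grads, opt, cfg$learning_rate)
      model$params <- stepped$params
      opt <- stepped$state
      losses <- c(losses, adv(loss))
    }

    val_scores <- predict_pairs_cached(model$params, model_cfg, ent, val_pairs)
    val_auroc <- if (length(unique(val_pairs$label)) > 1L) {
      auroc(val_scores, val_pairs$label)
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_auroc = val_auroc))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, val AUROC %.4f", epoch,
                      mean(losses), val_auroc))
    }
    if (!is.na(val_auroc) && val_auroc > best$auroc) {
      best <- list(auroc = val_auroc, params = model$params, epoch = epoch)
    }
    if (epoch - best$epoch >= cfg$patience) break
  }

  if (is.finite(best$auroc)) {
    model$params <- best$params
  } else {
    # validation AUROC was never defined (single-class split): keep the
    # final-epoch parameters
    best$epoch <- nrow(hist)
  }
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

# Score pairs in evaluation mode, encoding each unique entity once.
predict_pairs_cached <- function(params, cfg, ent, pairs) {
  ud <- unique(pairs$drug_id)
  ut <- unique(pairs$target_id)
  dembs <- setNames(lapply(ud, function(id) {
    drug_forward(params$drug, ent$drug[[id]], cfg$drug, train = FALSE)
  }), ud)
  tembs <- setNames(lapply(ut, function(id) {
    target_forward(params$target, ent$target[[id]], cfg$target, train = FALSE)
  }), ut)
  vapply(seq_len(nrow(pairs)), function(i) {
    as.numeric(predict_interaction(dembs[[pairs$drug_id[i]]],
                                   tembs[[pairs$target_id[i]]], params$head))
  }, numeric(1))
}

#' Score drug-target pairs with a trained model
#'
#' @param object a `dti_model`
#' @param dataset a [dti_dataset()] resolving the pair ids
#' @param pairs data frame of pairs to score (defaults to `dataset$pairs`)
#' @param ... unused
#' @return numeric vector of interaction probabilities
#' @export
predict.dti_model <- function(object, dataset, pairs = dataset$pairs, ...) {
  ent <- prepare_entities(dataset, object$cfg)
  predict_pairs_cached(object$params, object$cfg, ent, pairs)
}

# Mean evaluation-mode BCE over a set of pairs; `wrapped` may be autodiff
# leaves (for gradient computation) or plain parameter arrays.
dti_batch_loss <- function(params, model_cfg, ent, pairs) {
  pls <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- forward_pair(params, ent$drug[[pairs$drug_id[i]]],
                      ent$target[[pairs$target_id[i]]], model_cfg)
    ad_bce(p, pairs$label[i])
  })
  ad_mean_scalars(pls)
}
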