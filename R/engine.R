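# Training loop and inference rule. Only expert and fusion parameters are
# updated; encoder embeddings (queries and atlas supports) are frozen inputs.

# --- parameter-tree helpers -------------------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_clone <- function(a) rapply(a, identity, how = "replace")

# Decoupled weight decay skips layer-norm parameters and biases.
adamw_step <- function(params, grads, state, lr, step,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, wd = 1e-2) {
  walk <- function(p, g, m, v, name) {
    if (is.list(p)) {
      nms <- names(p)
      keys <- if (is.null(nms) || any(!nzchar(nms))) seq_along(p) else nms
      out_p <- p; out_m <- m; out_v <- v
      for (k in keys) {
        res <- walk(p[[k]], g[[k]], m[[k]], v[[k]], as.character(k))
        out_p[[k]] <- res$p; out_m[[k]] <- res$m; out_v[[k]] <- res$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^step)
      vhat <- v2 / (1 - beta2^step)
      decay <- if (grepl("^(ln[12]_[gb]|b[12])$", name)) 0 else wd
      p2 <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
      list(p = p2, m = m2, v = v2)
    }
  }
  res <- walk(params, grads, state$m, state$v, "root")
  list(params = res$p, state = list(m = res$m, v = res$v))
}

adamw_init <- function(params) {
  zero_tree <- function(p) if (is.list(p)) lapply(p, zero_tree) else p * 0
  list(m = zero_tree(params), v = zero_tree(params))
}

# --- configuration ----------------------------------------------------------

#' Training configuration
#'
#' Mirrors the training protocol: AdamW with decoupled weight decay 1e-2, a
#' learning-rate grid, at most `max_epochs` epochs and early stopping after
#' `patience` epochs without validation top-1 improvement.
#'
#' @param learning_rates grid of learning rates tried in turn; the
#'   checkpoint with the best validation metric across the grid is kept.
#' @param weight_decay decoupled weight decay (default 1e-2).
#' @param max_epochs maximum epochs per grid point (default 100).
#' @param patience early-stopping patience in epochs (default 20).
#' @param batch_size minibatch size.
#' @param seed seed governing shuffling and dropout.
#' @param lr_schedule `"constant"`, or `"cosine"` for a half-cosine decay of
#'   the learning rate from its initial value to (near) zero over
#'   `max_epochs`.
#' @param augment training-time query augmentation: expected norm of the
#'   isotropic Gaussian noise added to each query embedding (re-normalized
#'   afterwards) every epoch. 0 disables. Augmentation never touches
#'   validation or test queries.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rates = c(1e-3, 1e-4, 1e-5),
                         weight_decay = 1e-2, max_epochs = 100L,
                         patience = 20L, batch_size = 32L, seed = 1L,
                         lr_schedule = c("constant", "cosine"),
                         augment = 0) {
  stopifnot(length(learning_rates) >= 1L, patience <= max_epochs, augment >= 0)
  structure(list(learning_rates = learning_rates, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 lr_schedule = match.arg(lr_schedule), augment = augment),
            class = "train_config")
}

labels_to_index <- function(labels, class_ids) {
  yi <- match(labels, class_ids)
  if (anyNA(yi)) stop("label outside the atlas class set: ",
                      labels[which(is.na(yi))[1L]])
  yi
}

# --- training ---------------------------------------------------------------

#' Train the retrieval/fusion model by knowledge-enhanced contrastive learning
#'
#' Minimizes `local + lambda * global` by AdamW on the expert and fusion
#' parameters only. For each learning rate in the grid the model is trained
#' with early stopping on validation top-1 accuracy, and the best-validation
#' checkpoint across the grid is returned. Fully reproducible given the
#' seeds.
#'
#' @param atlas a [dx_atlas()].
#' @param train_set list with `embeddings` (N x d matrix of query
#'   embeddings) and `labels` (leaf class ids).
#' @param val_set same shape; used for model selection and early stopping.
#'   `NULL` trains for `max_epochs` and keeps the final parameters.
#' @param cfg a [train_config()].
#' @param model optional pre-initialized [init_model()]; by default a fresh
#'   model is initialized per grid point from `cfg$seed`.
#' @param ... passed to [init_model()] (e.g. `L`, `h`, `lambda`, `dropout`).
#' @return list of class `dx_fit`: `model` (best checkpoint), `history`
#'   (per-epoch data.frame), `best` (lr, epoch, validation top-1).
#' @export
train_model <- function(atlas, train_set, val_set = NULL,
                        cfg = train_config(), model = NULL, ...) {
  stopifnot(inherits(atlas, "dx_atlas"))
  N <- nrow(train_set$embeddings)
  if (is.null(N) || N < 1L) stop("empty training set")
  history <- list()
  best <- list(metric = -Inf, params = NULL, lr = NA_real_, epoch = NA_integer_)

  for (lr_i in seq_along(cfg$learning_rates)) {
    lr <- cfg$learning_rates[[lr_i]]
    m <- model %||% init_model(atlas, seed = cfg$seed, ...)
    check_model_atlas(m, atlas)
    y <- labels_to_index(train_set$labels, m$class_ids)
    state <- adamw_init(m$params)
    step <- 0L
    best_lr_metric <- -Inf
    best_lr_params <- tree_clone(m$params)
    best_lr_epoch <- 0L
    stall <- 0L
    set.seed(cfg$seed * 1009L + lr_i)

    for (epoch in seq_len(cfg$max_epochs)) {
      lr_now <- if (identical(cfg$lr_schedule, "cosine")) {
        lr * 0.5 * (1 + cos(pi * (epoch - 1L) / cfg$max_epochs))
      } else lr
      ord <- sample.int(N)
      splits <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- ep_local <- ep_global <- 0
      for (idx in splits) {
        Q <- train_set$embeddings[idx, , drop = FALSE]
        if (cfg$augment > 0) {
          Q <- l2_normalize(Q + rand_mat(nrow(Q), ncol(Q),
                                         sd = cfg$augment / sqrt(ncol(Q))))
        }
        fw <- enhance_forward(Q, atlas, m, training = TRUE, cache = TRUE)
        cg <- contrastive_grads(fw$Vhat, fw$Khat, y[idx],
                                tau = m$config$tau, lambda = m$config$lambda)
        if (!is.finite(cg$loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (lr=", lr, "); inspect inputs or lower the learning rate")
        }
        grads <- enhance_backward(Q, atlas, m, fw, cg$dVhat, cg$dKhat)
        step <- step + 1L
        upd <- adamw_step(m$params, grads, state, lr_now, step,
                          wd = cfg$weight_decay)
        m$params <- upd$params
        state <- upd$state
        w <- length(idx) / N
        ep_loss <- ep_loss + cg$loss * w
        ep_local <- ep_local + cg$local * w
        ep_global <- ep_global + cg$global * w
      }

      val_top1 <- NA_real_
      if (!is.null(val_set)) {
        pr <- predict_scores(m, atlas, val_set$embeddings)
        val_top1 <- mean(pr$predicted == val_set$labels)
        if (val_top1 > best_lr_metric + 1e-12) {
          best_lr_metric <- val_top1
          best_lr_params <- tree_clone(m$params)
          best_lr_epoch <- epoch
          stall <- 0L
        } else stall <- stall + 1L
      }
      history[[length(history) + 1L]] <- data.frame(
        lr = lr, epoch = epoch, loss_total = ep_loss, loss_local = ep_local,
        loss_global = ep_global, val_top1 = val_top1)
      if (!is.null(val_set) && stall >= cfg$patience) break
    }

    if (is.null(val_set)) {
      best_lr_metric <- -history[[length(history)]]$loss_total
      best_lr_params <- m$params
      best_lr_epoch <- cfg$max_epochs
    }
    if (best_lr_metric > best$metric) {
      best$metric <- best_lr_metric
      best$params <- best_lr_params
      best$lr <- lr
      best$epoch <- best_lr_epoch
    }
  }

  final <- model %||% init_model(atlas, seed = cfg$seed, ...)
  final$params <- best$params
  structure(list(model = final, history = do.call(rbind, history),
                 best = list(lr = best$lr, epoch = best$epoch,
                             val_top1 = if (is.null(val_set)) NA_real_ else best$metric)),
            class = "dx_fit")
}

# --- inference --------------------------------------------------------------

# Batched class scores: diagonal similarities sim(vhat_c, khat_c).
predict_scores <- function(model, atlas, Q) {
  check_model_atlas(model, atlas)
  if (!is.matrix(Q)) Q <- matrix(as.numeric(Q), nrow = 1L)
  fw <- enhance_forward(Q, atlas, model)
  V <- normalize_bcd(fw$Vhat)
  K <- normalize_bcd(fw$Khat)
  scores <- matrix(rowSums(matrix(V$N * K$N, nrow(Q) * length(model$class_ids))),
                   nrow = nrow(Q), dimnames = list(NULL, model$class_ids))
  pred_idx <- apply(scores, 1L, which.max)   # ties: lowest class index
  list(scores = scores, predicted = model$class_ids[pred_idx])
}

#' Predict the diagnosis for a query embedding
#'
#' Enhances the query against every class, scores class c by the cosine
#' similarity between its enhanced image and knowledge embeddings, and
#' predicts the argmax (ties broken by lowest class index). Retrieval
#' evidence (support indices and attention weights per class) is attached
#' for explainability.
#'
#' @param object a trained [init_model()] (`dx_model`).
#' @param query d-dim query embedding (or B x d matrix for a batch).
#' @param atlas a [dx_atlas()].
#' @param ... unused.
#' @return for a single query, a `dx_prediction`: list with `scores` (named
#'   length-C vector), `predicted` (leaf id), `evidence`; for a matrix, a
#'   list with `scores` matrix and `predicted` vector.
#' @export
predict.dx_model <- function(object, query, atlas, ...) {
  if (is.matrix(query) && nrow(query) > 1L) {
    return(predict_scores(object, atlas, query))
  }
  pr <- predict_scores(object, atlas, query)
  enh <- enhance(as.numeric(query), atlas, object)
  structure(list(scores = pr$scores[1L, ], predicted = pr$predicted[[1L]],
                 evidence = enh$evidence),
            class = "dx_prediction")
}

#' @export
print.dx_prediction <- function(x, ...) {
  cat("dx_prediction:", x$predicted, "\n")
  top <- sort(x$scores, decreasing = TRUE)[seq_len(min(3L, length(x$scores)))]
  for (nm in names(top)) cat(sprintf("  %s: %.4f\n", nm, top[[nm]]))
  invisible(x)
}

#' Binary melanoma/nonmelanoma prediction
#'
#' In `"mapped"` mode the multi-class argmax is mapped through the
#' taxonomy's severity grouping; in `"direct"` mode the model must have been
#' trained on a two-class atlas and the predicted leaf is mapped the same
#' way.
#'
#' @param query d-dim query embedding.
#' @param model a trained `dx_model`.
#' @param atlas the matching [dx_atlas()].
#' @param tax taxonomy supplying the binary map (defaults to the atlas's).
#' @param mode `"mapped"` or `"direct"`.
#' @return `"melanoma"` or `"nonmelanoma"`.
#' @export
predict_binary <- function(query, model, atlas, tax = atlas$taxonomy,
                           mode = c("mapped", "direct")) {
  mode <- match.arg(mode)
  if (mode == "direct" && length(model$class_ids) != 2L) {
    stop("direct mode requires a model trained on a two-class atlas")
  }
  pr <- predict_scores(model, atlas, query)
  to_binary(pr$predicted[[1L]], tax)
}

#' Stratified train/validation/test split
#'
#' Splits per class with the given fractions (default 70/15/15), keeping at
#' least one test item per class where the class size allows.
#'
#' @param labels class label vector.
#' @param fractions length-3 train/val/test fractions summing to 1.
#' @param seed seed for the per-class shuffles.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  out <- list(train = integer(), val = integer(), test = integer())
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      n <- length(idx)
      n_test <- max(if (n >= 3L) 1L else 0L, round(n * fractions[[3L]]))
      n_val <- round(n * fractions[[2L]])
      n_val <- min(n_val, n - n_test)
      n_train <- n - n_val - n_test
      out$train <- c(out$train, idx[seq_len(n_train)])
      if (n_val > 0L) out$val <- c(out$val, idx[n_train + seq_len(n_val)])
      if (n_test > 0L) out$test <- c(out$test, idx[n_train + n_val + seq_len(n_test)])
    }
  })
  out
}
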