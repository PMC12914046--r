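# Whole-slide pipeline: tiling, per-patch enhancement, gated attention-based
# multiple instance learning (ABMIL), and the few-shot protocol.

#' Tile a slide image into non-overlapping patches
#'
#' Produces the deterministic row-major grid of p x p tiles with 0-based
#' half-open coordinates. Partial tiles at the right/bottom edges are
#' dropped. An optional background filter removes tiles whose mean
#' saturation falls below a threshold (off by default for determinism).
#'
#' @param slide H x W (x 3) numeric array; an integer vector `c(H, W)` when
#'   only coordinates are needed; or the path to a (possibly multi-page
#'   pyramidal) TIFF file, read through the tiff package with `level`
#'   selecting the page.
#' @param p patch edge length in pixels (default 512, the size used at x10
#'   magnification).
#' @param level 1-based page index into a pyramidal TIFF (the page whose
#'   resolution corresponds to x10).
#' @param background_filter drop low-saturation tiles.
#' @param saturation_threshold minimum mean saturation kept when filtering.
#' @return list with `coords` (data.frame `x`, `y` of top-left corners,
#'   row-major) and, when pixel data was supplied, `patches` (list of p x p
#'   (x 3) arrays in the same order).
#' @export
tile_slide <- function(slide, p = 512L, level = 1L, background_filter = FALSE,
                       saturation_threshold = 0.05) {
  if (is.character(slide)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading slide files requires the 'tiff' package")
    }
    if (!file.exists(slide)) stop("unreadable slide: ", slide)
    pages <- tiff::readTIFF(slide, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (level > length(pages)) {
      stop("requested level ", level, " but slide has ", length(pages),
           " level(s)")
    }
    slide <- pages[[level]]
  }
  if (is.null(dim(slide))) {
    dims <- as.integer(slide)
    pixels <- NULL
  } else {
    dims <- dim(slide)[1:2]
    pixels <- slide
  }
  if (any(dims < p)) stop("slide smaller than one patch")
  ny <- dims[[1L]] %/% p
  nx <- dims[[2L]] %/% p
  coords <- expand.grid(x = (seq_len(nx) - 1L) * p, y = (seq_len(ny) - 1L) * p)
  coords <- coords[order(coords$y, coords$x), , drop = FALSE]  # row-major
  rownames(coords) <- NULL
  patches <- NULL
  if (!is.null(pixels)) {
    cut_patch <- function(x0, y0) {
      if (length(dim(pixels)) == 3L) {
        pixels[(y0 + 1L):(y0 + p), (x0 + 1L):(x0 + p), , drop = FALSE]
      } else {
        pixels[(y0 + 1L):(y0 + p), (x0 + 1L):(x0 + p), drop = FALSE]
      }
    }
    patches <- Map(cut_patch, coords$x, coords$y)
    if (background_filter && length(dim(pixels)) == 3L) {
      sat <- vapply(patches, function(pt) {
        mx <- pmax(pt[, , 1L], pt[, , 2L], pt[, , 3L])
        mn <- pmin(pt[, , 1L], pt[, , 2L], pt[, , 3L])
        mean(ifelse(mx > 0, (mx - mn) / mx, 0))
      }, numeric(1L))
      keep <- sat >= saturation_threshold
      coords <- coords[keep, , drop = FALSE]
      rownames(coords) <- NULL
      patches <- patches[keep]
    }
  }
  list(coords = coords, patches = patches)
}

#' Replace bag patches by their enhanced representations
#'
#' Each patch embedding is run through the retrieval/fusion model; the
#' per-patch enhanced vector is the softmax(score)-weighted average over
#' classes of the enhanced image embeddings (`"score_weighted"`, default) or
#' the enhanced image embedding of the top-scoring class (`"top1"`).
#'
#' @param bag list with `embeddings` (P x d), `slide_id`, `label`.
#' @param model a trained `dx_model`.
#' @param atlas the matching [dx_atlas()].
#' @param mode per-patch reduction over classes.
#' @return the bag with `embeddings` replaced by the enhanced P x d matrix.
#' @export
enhance_bag <- function(bag, model, atlas, mode = c("score_weighted", "top1")) {
  mode <- match.arg(mode)
  check_model_atlas(model, atlas)
  Q <- bag$embeddings
  fw <- enhance_forward(Q, atlas, model)
  V <- normalize_bcd(fw$Vhat)
  K <- normalize_bcd(fw$Khat)
  C <- dim(fw$Vhat)[[2L]]
  scores <- matrix(rowSums(matrix(V$N * K$N, nrow(Q) * C)), nrow = nrow(Q))
  P <- nrow(Q)
  out <- matrix(0, P, dim(fw$Vhat)[[3L]])
  for (b in seq_len(P)) {
    Vb <- matrix(fw$Vhat[b, , ], nrow = ncol(scores))
    if (mode == "score_weighted") {
      w <- softmax_vec(scores[b, ])
      out[b, ] <- as.vector(crossprod(Vb, w))
    } else {
      out[b, ] <- Vb[which.max(scores[b, ]), ]
    }
  }
  bag$embeddings <- out
  bag
}

#' Initialize gated-attention ABMIL parameters
#'
#' Two-branch gated attention (tanh and sigmoid branches of width `ha`) with
#' a linear scoring vector and a logistic classifier head.
#'
#' @param d patch embedding dimension.
#' @param ha attention hidden width (default 128).
#' @param seed initialization seed.
#' @return list of class `abmil_params`.
#' @export
abmil_init <- function(d, ha = 128L, seed = 1L) {
  with_seed(seed, structure(list(
    V = rand_mat(d, ha, sd = 1 / sqrt(d)),
    U = rand_mat(d, ha, sd = 1 / sqrt(d)),
    w = stats::rnorm(ha, sd = 1 / sqrt(ha)),
    Wc = stats::rnorm(d, sd = 1 / sqrt(d)),
    bc = 0
  ), class = "abmil_params"))
}

abmil_forward <- function(H, params) {
  Tm <- tanh(H %*% params$V)
  Sm <- stats::plogis(H %*% params$U)
  gate <- Tm * Sm
  gl <- as.vector(gate %*% params$w)
  a <- softmax_vec(gl)
  z <- as.vector(crossprod(H, a))
  u <- sum(z * params$Wc) + params$bc
  list(score = stats::plogis(u), attention = a, z = z, u = u,
       Tm = Tm, Sm = Sm, gate = gate)
}

abmil_backward <- function(H, params, fwd, dy_du) {
  # dy_du: dLoss/du at the logit
  a <- fwd$attention
  dz <- dy_du * params$Wc
  g <- list(Wc = dy_du * fwd$z, bc = dy_du)
  da <- as.vector(H %*% dz)
  dH <- outer(a, dz)
  dgl <- a * (da - sum(a * da))
  g$w <- as.vector(crossprod(fwd$gate, dgl))
  dgate <- outer(dgl, params$w)
  dT <- dgate * fwd$Sm
  dS <- dgate * fwd$Tm
  dpreT <- dT * (1 - fwd$Tm^2)
  dpreS <- dS * fwd$Sm * (1 - fwd$Sm)
  g$V <- crossprod(H, dpreT)
  g$U <- crossprod(H, dpreS)
  dH <- dH + dpreT %*% t(params$V) + dpreS %*% t(params$U)
  list(grads = g, dH = dH)
}

#' Aggregate a bag of patch embeddings into a slide score
#'
#' Gated attention weights over patches (non-negative, sum 1) pool the bag
#' into one embedding scored by a logistic head. Permutation-invariant in
#' the patches.
#'
#' @param bag list with `embeddings` (P x d matrix, P >= 1).
#' @param params an [abmil_init()] parameter set.
#' @return list with `score` (probability of the positive class) and
#'   `attention` (per-patch weights).
#' @export
abmil_aggregate <- function(bag, params) {
  H <- bag$embeddings
  if (!is.matrix(H) || nrow(H) < 1L) stop("empty bag")
  fwd <- abmil_forward(H, params)
  list(score = fwd$score, attention = fwd$attention)
}

#' Train an ABMIL slide classifier
#'
#' Per-bag Adam updates on the binary cross-entropy of the slide label, with
#' a learning-rate grid, early stopping on validation ROC AUC and a
#' best-checkpoint return.
#'
#' @param bags list of bags (`embeddings`, `label`).
#' @param val_bags validation bags for model selection (`NULL` keeps the
#'   final parameters).
#' @param positive positive label value.
#' @param learning_rates learning-rate grid (default {1e-2 .. 1e-6}).
#' @param max_epochs,patience training schedule (defaults 100 / 20).
#' @param ha attention hidden width.
#' @param seed seed for init and shuffling.
#' @return list of class `abmil_fit`: `params`, `history`, `best`.
#' @export
train_abmil <- function(bags, val_bags = NULL, positive = "melanoma",
                        learning_rates = 10^(-(2:6)), max_epochs = 100L,
                        patience = 20L, ha = 128L, seed = 1L) {
  stopifnot(length(bags) >= 1L)
  d <- ncol(bags[[1L]]$embeddings)
  y <- vapply(bags, function(b) as.numeric(b$label == positive), numeric(1L))
  history <- list()
  best <- list(metric = -Inf, params = NULL, lr = NA_real_)

  val_eval <- function(params) {
    sc <- vapply(val_bags, function(b) abmil_forward(b$embeddings, params)$score,
                 numeric(1L))
    roc_auc(sc, vapply(val_bags, `[[`, character(1L), "label"), positive)
  }

  for (lr in learning_rates) {
    params <- abmil_init(d, ha = ha, seed = seed)
    state <- adamw_init(params)
    step <- 0L
    set.seed(seed * 2003L + round(-log10(lr)))
    best_lr <- list(metric = -Inf, params = tree_clone(params))
    stall <- 0L
    for (epoch in seq_len(max_epochs)) {
      ep_loss <- 0
      for (i in sample(seq_along(bags))) {
        H <- bags[[i]]$embeddings
        fwd <- abmil_forward(H, params)
        pr <- min(max(fwd$score, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss - (y[[i]] * log(pr) + (1 - y[[i]]) * log(1 - pr))
        bwd <- abmil_backward(H, params, fwd, dy_du = fwd$score - y[[i]])
        step <- step + 1L
        upd <- adamw_step(params, bwd$grads, state, lr, step, wd = 0)
        params <- upd$params
        attr(params, "class") <- "abmil_params"
        state <- upd$state
      }
      val_auc <- NA_real_
      if (!is.null(val_bags)) {
        val_auc <- val_eval(params)
        if (val_auc > best_lr$metric + 1e-12) {
          best_lr <- list(metric = val_auc, params = tree_clone(params))
          stall <- 0L
        } else stall <- stall + 1L
      }
      history[[length(history) + 1L]] <- data.frame(
        lr = lr, epoch = epoch, loss = ep_loss / length(bags), val_auc = val_auc)
      if (!is.null(val_bags) && stall >= patience) break
    }
    if (is.null(val_bags)) best_lr <- list(metric = -ep_loss, params = params)
    if (best_lr$metric > best$metric) {
      best <- list(metric = best_lr$metric, params = best_lr$params, lr = lr)
    }
  }
  params <- best$params
  attr(params, "class") <- "abmil_params"
  structure(list(params = params, history = do.call(rbind, history),
                 best = list(lr = best$lr, metric = best$metric)),
            class = "abmil_fit")
}

#' Few-shot slide classification protocol
#'
#' Samples `shots` training bags per class from the training pool, trains
#' ABMIL, and evaluates the four-metric battery with bootstrap CIs on the
#' fixed test set. Validation and test sets stay fixed across shot counts.
#'
#' @param bags full list of bags.
#' @param shots training bags per class; must belong to the standard menu
#'   {2, 8, 32, 64, 96, 128} unless `allow_any`.
#' @param val_idx,test_idx fixed bag indices for validation and test.
#' @param seed seed for shot sampling and training.
#' @param positive positive label value.
#' @param allow_any permit shot counts outside the menu.
#' @param reps bootstrap replicates for the report.
#' @param ... passed to [train_abmil()].
#' @return list with `fit` (an `abmil_fit`), `report` (from
#'   [binary_eval_report()] on the test set), `train_idx`.
#' @export
few_shot_protocol <- function(bags, shots, val_idx, test_idx, seed = 1L,
                              positive = "melanoma", allow_any = FALSE,
                              reps = 1000L, ...) {
  menu <- c(2L, 8L, 32L, 64L, 96L, 128L)
  if (!allow_any && !(shots %in% menu)) {
    stop("shots must be one of {", paste(menu, collapse = ", "),
         "}; set allow_any = TRUE to override")
  }
  labs <- vapply(bags, `[[`, character(1L), "label")
  pool <- setdiff(seq_along(bags), c(val_idx, test_idx))
  train_idx <- integer()
  with_seed(seed + 13L, {
    for (cls in unique(labs)) {
      cand <- intersect(pool, which(labs == cls))
      if (length(cand) < shots) {
        stop("insufficient bags for class ", cls, ": have ", length(cand),
             ", need ", shots)
      }
      train_idx <- c(train_idx, sample(cand, shots))
    }
  })
  fit <- train_abmil(bags[train_idx], val_bags = bags[val_idx],
                     positive = positive, seed = seed, ...)
  test_scores <- vapply(bags[test_idx], function(b)
    abmil_forward(b$embeddings, fit$params)$score, numeric(1L))
  report <- binary_eval_report(test_scores, labs[test_idx],
                               positive = positive, reps = reps, seed = seed)
  list(fit = fit, report = report, train_idx = train_idx)
}
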