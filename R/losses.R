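#' Contrastive loss configuration
#'
#' @param tau temperature dividing every similarity before the softmax
#'   (default 0.07, the standard contrastive temperature).
#' @param lambda balance parameter weighting the global loss in
#'   `total = local + lambda * global` (0.01 in the multi-class setting;
#'   1.0 generic binary, with per-backbone overrides 0.75 / 0.9).
#' @return list of class `loss_config`.
#' @export
loss_config <- function(tau = 0.07, lambda = 0.01) {
  stopifnot(is.finite(tau), tau > 0, lambda >= 0)
  structure(list(tau = tau, lambda = lambda), class = "loss_config")
}

#' Image-knowledge similarity matrix of one enhanced pair set
#'
#' Entry (i, j) is the cosine similarity between the enhanced image
#' embedding of class i and the enhanced knowledge embedding of class j.
#' Only the diagonal entry of the ground-truth class is a positive in the
#' local loss.
#'
#' @param pairs a `dx_enhanced` (from [enhance()]) or a list with `Vhat` and
#'   `Khat` C x d matrices.
#' @return C x C similarity matrix.
#' @export
similarity_matrix <- function(pairs) {
  V <- l2_normalize(pairs$Vhat)
  K <- l2_normalize(pairs$Khat)
  V %*% t(K)
}

#' Local contrastive loss
#'
#' Cross-entropy of the ground-truth diagonal cell (y, y) against all C^2
#' cells of the similarity matrix at temperature tau, averaged over the
#' batch. Log-sum-exp stabilized.
#'
#' @param S a C x C similarity matrix, or a list of them (one per sample).
#' @param y ground-truth class index (1..C), recycled over the batch.
#' @param cfg a [loss_config()].
#' @return non-negative scalar.
#' @export
local_loss <- function(S, y, cfg = loss_config()) {
  if (is.matrix(S)) S <- list(S)
  y <- rep_len(y, length(S))
  per <- mapply(function(Sb, yb) {
    if (!all(is.finite(Sb))) stop("non-finite similarity matrix")
    C <- nrow(Sb)
    stopifnot(yb >= 1L, yb <= C)
    z <- Sb / cfg$tau
    logsumexp(as.vector(z)) - z[yb, yb]
  }, S, y)
  mean(per)
}

#' Assemble a batch of enhanced pair sets
#'
#' @param pairs_list list of `dx_enhanced` objects (same class set).
#' @param y ground-truth labels: leaf class ids or integer indices.
#' @return list of class `batch_enhanced` with `Vhat`, `Khat`
#'   (B x C x d arrays) and integer labels `y`.
#' @export
batch_enhanced <- function(pairs_list, y) {
  B <- length(pairs_list)
  stopifnot(B >= 1L, length(y) == B)
  class_ids <- pairs_list[[1L]]$class_ids
  C <- nrow(pairs_list[[1L]]$Vhat)
  d <- ncol(pairs_list[[1L]]$Vhat)
  Vhat <- array(0, c(B, C, d))
  Khat <- array(0, c(B, C, d))
  for (b in seq_len(B)) {
    if (nrow(pairs_list[[b]]$Vhat) != C) stop("inconsistent C across samples")
    Vhat[b, , ] <- pairs_list[[b]]$Vhat
    Khat[b, , ] <- pairs_list[[b]]$Khat
  }
  if (is.character(y)) {
    yi <- match(y, class_ids)
    if (anyNA(yi)) stop("label not among the batch class ids")
  } else yi <- as.integer(y)
  stopifnot(all(yi >= 1L & yi <= C))
  structure(list(Vhat = Vhat, Khat = Khat, y = yi, class_ids = class_ids),
            class = "batch_enhanced")
}

# Normalize the (b, c) slices of a B x C x d array; returns normalized array
# and the B x C norms.
normalize_bcd <- function(A) {
  B <- dim(A)[[1L]]; C <- dim(A)[[2L]]
  nrm <- matrix(sqrt(rowSums(matrix(A^2, B * C))), B, C)
  if (any(nrm < 1e-12)) stop("zero-norm enhanced embedding")
  list(N = A / as.vector(nrm), nrm = nrm)
}

# Mask bookkeeping for sample b: among the B*C flattened (q, c) columns
# (index (q-1)*C + c), exclude (q, y_b) for q != b.
global_unmasked <- function(B, C, b, yb) {
  excl <- (setdiff(seq_len(B), b) - 1L) * C + yb
  setdiff(seq_len(B * C), excl)
}

#' Global contrastive loss
#'
#' Batch-wide bidirectional cross-entropy: the ground-truth enhanced image
#' embedding of each sample must match its own ground-truth enhanced
#' knowledge embedding among all B*C knowledge embeddings in the batch,
#' after masking out knowledge embeddings of other samples that share the
#' sample's class (M_b, |M_b| = B - 1). The symmetric knowledge-to-image
#' direction is computed the same way and the two are averaged.
#'
#' @param batch a [batch_enhanced()].
#' @param cfg a [loss_config()].
#' @return non-negative scalar.
#' @export
global_loss <- function(batch, cfg = loss_config()) {
  global_loss_core(batch, cfg)$loss
}

global_loss_core <- function(batch, cfg, grad = FALSE) {
  V <- normalize_bcd(batch$Vhat)
  K <- normalize_bcd(batch$Khat)
  B <- dim(batch$Vhat)[[1L]]
  C <- dim(batch$Vhat)[[2L]]
  d <- dim(batch$Vhat)[[3L]]
  y <- batch$y
  Kall <- matrix(aperm(K$N, c(3L, 2L, 1L)), nrow = B * C, byrow = TRUE)
  Vall <- matrix(aperm(V$N, c(3L, 2L, 1L)), nrow = B * C, byrow = TRUE)
  # row (q-1)*C + c of Kall / Vall is the (q, c) embedding
  dV_flat <- if (grad) matrix(0, B * C, d) else NULL
  dK_flat <- if (grad) matrix(0, B * C, d) else NULL
  loss_i2k <- 0; loss_k2i <- 0
  for (b in seq_len(B)) {
    keep <- global_unmasked(B, C, b, y[[b]])
    pos_flat <- (b - 1L) * C + y[[b]]
    pos <- match(pos_flat, keep)
    vpos <- V$N[b, y[[b]], ]
    kpos <- K$N[b, y[[b]], ]

    z_i2k <- (Kall[keep, , drop = FALSE] %*% vpos) / cfg$tau
    loss_i2k <- loss_i2k + (logsumexp(z_i2k) - z_i2k[[pos]])
    z_k2i <- (Vall[keep, , drop = FALSE] %*% kpos) / cfg$tau
    loss_k2i <- loss_k2i + (logsumexp(z_k2i) - z_k2i[[pos]])

    if (grad) {
      scale <- 1 / (2 * B * cfg$tau)
      p <- softmax_vec(as.vector(z_i2k)); p[[pos]] <- p[[pos]] - 1
      dV_flat[pos_flat, ] <- dV_flat[pos_flat, ] +
        as.vector(crossprod(Kall[keep, , drop = FALSE], p)) * scale
      dK_flat[keep, ] <- dK_flat[keep, ] + (p * scale) %o% vpos
      p2 <- softmax_vec(as.vector(z_k2i)); p2[[pos]] <- p2[[pos]] - 1
      dK_flat[pos_flat, ] <- dK_flat[pos_flat, ] +
        as.vector(crossprod(Vall[keep, , drop = FALSE], p2)) * scale
      dV_flat[keep, ] <- dV_flat[keep, ] + (p2 * scale) %o% kpos
    }
  }
  # back to [b, c, d] arrays (flat rows are (q-1)*C + c, c fastest)
  unflatten <- function(m) {
    if (is.null(m)) return(NULL)
    aperm(array(t(m), c(d, C, B)), c(3L, 2L, 1L))
  }
  list(loss = (loss_i2k + loss_k2i) / (2 * B),
       dVn = unflatten(dV_flat), dKn = unflatten(dK_flat), Vn = V, Kn = K)
}

#' Total training loss
#'
#' `total = local + lambda * global` over a batch of enhanced pair sets.
#'
#' @param batch a [batch_enhanced()].
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
total_loss <- function(batch, cfg = loss_config()) {
  B <- dim(batch$Vhat)[[1L]]
  S_list <- lapply(seq_len(B), function(b) {
    similarity_matrix(list(Vhat = matrix(batch$Vhat[b, , ], nrow = dim(batch$Vhat)[[2L]]),
                           Khat = matrix(batch$Khat[b, , ], nrow = dim(batch$Khat)[[2L]])))
  })
  local_loss(S_list, batch$y, cfg) + cfg$lambda * global_loss(batch, cfg)
}

# Loss + gradients wrt the raw (unnormalized) enhanced embeddings.
# Used by the training loop. Returns local/global components too.
contrastive_grads <- function(Vhat, Khat, y, tau, lambda) {
  B <- dim(Vhat)[[1L]]; C <- dim(Vhat)[[2L]]; d <- dim(Vhat)[[3L]]
  V <- normalize_bcd(Vhat)
  K <- normalize_bcd(Khat)
  dVn <- array(0, c(B, C, d))
  dKn <- array(0, c(B, C, d))
  local <- 0
  for (b in seq_len(B)) {
    Vb <- matrix(V$N[b, , ], nrow = C)
    Kb <- matrix(K$N[b, , ], nrow = C)
    S <- Vb %*% t(Kb)
    z <- S / tau
    lse <- logsumexp(as.vector(z))
    local <- local + (lse - z[y[[b]], y[[b]]])
    P <- matrix(exp(as.vector(z) - lse), C, C)
    P[y[[b]], y[[b]]] <- P[y[[b]], y[[b]]] - 1
    dS <- P / (tau * B)
    dVn[b, , ] <- dVn[b, , ] + dS %*% Kb
    dKn[b, , ] <- dKn[b, , ] + t(dS) %*% Vb
  }
  local <- local / B

  gl <- global_loss_core(list(Vhat = Vhat, Khat = Khat, y = y), loss_config(tau, max(lambda, 0)),
                         grad = lambda > 0)
  if (lambda > 0) {
    dVn <- dVn + lambda * gl$dVn
    dKn <- dKn + lambda * gl$dKn
  }

  # through the normalization: dU = (dN - <N, dN> N) / |U|
  proj_back <- function(dN, Nrm) {
    inner <- rowSums(matrix(dN * Nrm$N, B * C))
    (dN - inner * Nrm$N) / as.vector(Nrm$nrm)
  }
  list(loss = local + lambda * gl$loss, local = local, global = gl$loss,
       dVhat = proj_back(dVn, V), dKhat = proj_back(dKn, K))
}
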