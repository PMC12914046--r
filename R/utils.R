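# Internal numeric helpers shared across modules.

#' L2-normalize rows of a matrix (or a single vector)
#'
#' @param x numeric vector or matrix (rows are vectors).
#' @param eps guard against division by zero; a row with norm < eps errors.
#' @return object of the same shape with unit-norm rows.
#' @keywords internal
l2_normalize <- function(x, eps = 1e-12) {
  if (is.matrix(x)) {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm < eps)) stop("cannot normalize zero-norm vector")
    x / nrm
  } else {
    nrm <- sqrt(sum(x^2))
    if (nrm < eps) stop("cannot normalize zero-norm vector")
    x / nrm
  }
}

#' Cosine similarity between vectors or matrix rows
#' @keywords internal
cosine_sim <- function(u, w) {
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu < 1e-12 || nw < 1e-12) stop("cosine similarity undefined for zero-norm vector")
  sum(u * w) / (nu * nw)
}

# Row-wise softmax with log-sum-exp stabilization.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# log(sum(exp(x))) stabilized
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Draw an n x d matrix of N(0, sd) entries (no global seed side effects
# beyond advancing the caller-set stream).
rand_mat <- function(n, d, sd = 1) {
  matrix(stats::rnorm(n * d, sd = sd), nrow = n, ncol = d)
}

# Random orthogonal matrix via QR of a Gaussian matrix (sign-fixed so the
# result is a deterministic function of the Gaussian draw).
random_orthogonal <- function(d) {
  qr_res <- qr(rand_mat(d, d))
  q <- qr.Q(qr_res)
  r <- qr.R(qr_res)
  q * rep(sign(diag(r)), each = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
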