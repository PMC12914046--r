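# Batched numerical core of the dual-arm architecture.
#
# Layout convention: a batch of B retrieved sets, each of k d-dim vectors, is
# a (B*k) x d matrix whose row (b-1)*k + i is element i of sample b. All
# forward functions cache what the matching *_backward function needs.
# Gradients flow to expert and fusion parameters only; support rows and
# queries come from frozen encoders and receive no updates.

# 0/1 selector mapping each of the d columns to its head (d x h), and the
# inverse expansion h -> d. Used to do all heads' score sums in one matmul.
head_selector <- function(d, h) {
  dh <- d %/% h
  hmap <- rep(seq_len(h), each = dh)
  sel <- matrix(0, d, h)
  sel[cbind(seq_len(d), hmap)] <- 1
  list(sel = sel, hmap = hmap, dh = dh)
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  inv <- cache$inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}

# sigmoid-approximation GELU (cheap and smooth)
gelu <- function(x) x * stats::plogis(1.702 * x)
gelu_grad <- function(x) {
  s <- stats::plogis(1.702 * x)
  s + 1.702 * x * s * (1 - s)
}

init_fusion_layer <- function(d, ff_mult = 4L) {
  f <- d * ff_mult
  list(
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wq = rand_mat(d, d, sd = 1 / sqrt(d)),
    Wk = rand_mat(d, d, sd = 1 / sqrt(d)),
    Wv = rand_mat(d, d, sd = 1 / sqrt(d)),
    # zero output/projection weights: each block starts as the identity
    # (residual path only), which stabilizes early training
    Wo = matrix(0, d, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    W1 = rand_mat(d, f, sd = 1 / sqrt(d)), b1 = rep(0, f),
    W2 = matrix(0, f, d), b2 = rep(0, d)
  )
}

zero_like <- function(p) lapply(p, function(x) x * 0)

# Self-attention + FFN pre-norm transformer block over sets of size k.
# X: (B*k) x d. Returns output and cache.
fusion_layer_fwd <- function(X, layer, k, h, dropout = 0, training = FALSE) {
  N <- nrow(X); d <- ncol(X); B <- N %/% k
  hs <- head_selector(d, h)
  ln1 <- layernorm_fwd(X, layer$ln1_g, layer$ln1_b)
  Xn <- ln1$y
  Qp <- Xn %*% layer$Wq
  Kp <- Xn %*% layer$Wk
  Vp <- Xn %*% layer$Wv
  rows_of <- lapply(seq_len(k), function(i) seq(i, by = k, length.out = B))
  # per-pair scores for all heads at once: S[[i]][[j]] is B x h
  S <- vector("list", k)
  for (i in seq_len(k)) {
    S[[i]] <- vector("list", k)
    Qi <- Qp[rows_of[[i]], , drop = FALSE]
    for (j in seq_len(k)) {
      S[[i]][[j]] <- ((Qi * Kp[rows_of[[j]], , drop = FALSE]) %*% hs$sel) /
        sqrt(hs$dh)
    }
  }
  # softmax over j per (sample, position i, head); P same shape as S
  P <- vector("list", k)
  O <- matrix(0, N, d)
  for (i in seq_len(k)) {
    mx <- Reduce(pmax, S[[i]])
    ex <- lapply(S[[i]], function(s) exp(s - mx))
    tot <- Reduce(`+`, ex)
    P[[i]] <- lapply(ex, function(e) e / tot)
    acc <- matrix(0, B, d)
    for (j in seq_len(k)) {
      acc <- acc + P[[i]][[j]][, hs$hmap, drop = FALSE] *
        Vp[rows_of[[j]], , drop = FALSE]
    }
    O[rows_of[[i]], ] <- acc
  }
  attn_out <- O %*% layer$Wo
  mask1 <- NULL
  if (training && dropout > 0) {
    mask1 <- matrix(stats::rbinom(N * d, 1L, 1 - dropout), N, d) / (1 - dropout)
    attn_out <- attn_out * mask1
  }
  X2 <- X + attn_out
  ln2 <- layernorm_fwd(X2, layer$ln2_g, layer$ln2_b)
  Hpre <- ln2$y %*% layer$W1 + rep(layer$b1, each = N)
  H <- gelu(Hpre)
  ff_out <- H %*% layer$W2 + rep(layer$b2, each = N)
  mask2 <- NULL
  if (training && dropout > 0) {
    mask2 <- matrix(stats::rbinom(N * d, 1L, 1 - dropout), N, d) / (1 - dropout)
    ff_out <- ff_out * mask2
  }
  Y <- X2 + ff_out
  list(Y = Y,
       cache = list(X = X, ln1 = ln1, Qp = Qp, Kp = Kp, Vp = Vp, P = P,
                    O = O, mask1 = mask1, X2 = X2, ln2 = ln2, Hpre = Hpre,
                    H = H, mask2 = mask2, k = k, h = h, rows_of = rows_of,
                    hs = hs))
}

fusion_layer_bwd <- function(dY, layer, cache) {
  k <- cache$k
  N <- nrow(dY); d <- ncol(dY)
  hs <- cache$hs
  rows_of <- cache$rows_of
  g <- list()

  # FFN branch
  dff <- dY
  if (!is.null(cache$mask2)) dff <- dff * cache$mask2
  g$W2 <- crossprod(cache$H, dff)
  g$b2 <- colSums(dff)
  dH <- tcrossprod(dff, layer$W2)
  dHpre <- dH * gelu_grad(cache$Hpre)
  g$W1 <- crossprod(cache$ln2$y, dHpre)
  g$b1 <- colSums(dHpre)
  dXn2 <- tcrossprod(dHpre, layer$W1)
  ln2b <- layernorm_bwd(dXn2, cache$ln2, layer$ln2_g)
  g$ln2_g <- ln2b$dg; g$ln2_b <- ln2b$db
  dX2 <- dY + ln2b$dx

  # attention branch
  dattn <- dX2
  if (!is.null(cache$mask1)) dattn <- dattn * cache$mask1
  g$Wo <- crossprod(cache$O, dattn)
  dO <- tcrossprod(dattn, layer$Wo)
  dQp <- matrix(0, N, d); dKp <- matrix(0, N, d); dVp <- matrix(0, N, d)
  inv_sdh <- 1 / sqrt(hs$dh)
  for (i in seq_len(k)) {
    dOi <- dO[rows_of[[i]], , drop = FALSE]
    P <- cache$P[[i]]
    # dP[[j]]: B x h; dV accumulation
    dP <- vector("list", k)
    for (j in seq_len(k)) {
      Vj <- cache$Vp[rows_of[[j]], , drop = FALSE]
      dP[[j]] <- (dOi * Vj) %*% hs$sel
      dVp[rows_of[[j]], ] <- dVp[rows_of[[j]], ] +
        P[[j]][, hs$hmap, drop = FALSE] * dOi
    }
    # softmax backward over j per head
    inner <- Reduce(`+`, Map(function(p, dp) p * dp, P, dP))
    Qi <- cache$Qp[rows_of[[i]], , drop = FALSE]
    dQacc <- matrix(0, nrow(Qi), d)
    for (j in seq_len(k)) {
      dS <- P[[j]] * (dP[[j]] - inner)            # B x h
      dSe <- dS[, hs$hmap, drop = FALSE] * inv_sdh  # expand to B x d
      dQacc <- dQacc + dSe * cache$Kp[rows_of[[j]], , drop = FALSE]
      dKp[rows_of[[j]], ] <- dKp[rows_of[[j]], ] + dSe * Qi
    }
    dQp[rows_of[[i]], ] <- dQp[rows_of[[i]], ] + dQacc
  }
  Xn <- cache$ln1$y
  g$Wq <- crossprod(Xn, dQp)
  g$Wk <- crossprod(Xn, dKp)
  g$Wv <- crossprod(Xn, dVp)
  dXn <- tcrossprod(dQp, layer$Wq) + tcrossprod(dKp, layer$Wk) +
    tcrossprod(dVp, layer$Wv)
  ln1b <- layernorm_bwd(dXn, cache$ln1, layer$ln1_g)
  g$ln1_g <- ln1b$dg; g$ln1_b <- ln1b$db
  dX <- dX2 + ln1b$dx
  list(dX = dX, grads = g)
}

fusion_fwd <- function(X, block, k, h, dropout = 0, training = FALSE) {
  caches <- vector("list", length(block))
  for (l in seq_along(block)) {
    res <- fusion_layer_fwd(X, block[[l]], k, h, dropout, training)
    X <- res$Y
    caches[[l]] <- res$cache
  }
  list(Y = X, caches = caches)
}

fusion_bwd <- function(dY, block, caches) {
  grads <- vector("list", length(block))
  for (l in rev(seq_along(block))) {
    res <- fusion_layer_bwd(dY, block[[l]], caches[[l]])
    dY <- res$dX
    grads[[l]] <- res$grads
  }
  list(dX = dY, grads = grads)
}

# Multi-head expert attention scores for a batch of queries against one
# class's support rows: scores[b, i] = mean_h <Wq q_b, Wk s_i>_h / sqrt(dh).
# Because the head scores are averaged *before* the softmax, the sum over
# heads collapses to the full projected dot product.
expert_scores_fwd <- function(Q, S, expert, h) {
  d <- ncol(Q)
  dh <- d %/% h
  Qp <- Q %*% expert$Wq
  Kp <- S %*% expert$Wk
  list(scores = tcrossprod(Qp, Kp) / (h * sqrt(dh)), Qp = Qp, Kp = Kp)
}

expert_scores_bwd <- function(dscores, Q, S, expert, h, cache) {
  d <- ncol(Q)
  sc <- 1 / (h * sqrt(d %/% h))
  dQp <- (dscores %*% cache$Kp) * sc
  dKp <- crossprod(dscores, cache$Qp) * sc
  list(dWq = crossprod(Q, dQp), dWk = crossprod(S, dKp))
}

# Top-n selection with renormalization; ties broken by lower row index.
select_topn <- function(alpha, top_n) {
  n <- ncol(alpha)
  k <- min(top_n, n)
  B <- nrow(alpha)
  if (k == n) {
    sel <- matrix(rep(seq_len(n), each = B), B, n)
  } else {
    sel <- matrix(0L, B, k)
    for (b in seq_len(B)) {
      sel[b, ] <- order(-alpha[b, ], seq_len(n))[seq_len(k)]
    }
  }
  w_raw <- matrix(alpha[cbind(rep(seq_len(B), k), as.vector(sel))], B, k)
  list(sel = sel, w = w_raw / rowSums(w_raw), w_raw_sum = rowSums(w_raw))
}

# One arm (image or knowledge) of the enhancement pass for one class,
# batched over B queries. S: support rows (n x d).
arm_forward <- function(Q, S, expert, block, cfg, training = FALSE) {
  es <- expert_scores_fwd(Q, S, expert, cfg$h)
  alpha <- softmax_rows(es$scores)
  ts <- select_topn(alpha, cfg$top_n)
  k <- ncol(ts$sel)
  B <- nrow(Q)
  idx <- as.vector(t(ts$sel))          # row (b-1)*k+i -> support sel[b,i]
  X0 <- S[idx, , drop = FALSE]
  fz <- fusion_fwd(X0, block, k, cfg$h, cfg$dropout, training)
  # aggregate with the renormalized original attention weights
  wvec <- as.vector(t(ts$w))
  Yw <- fz$Y * wvec
  V <- rowsum(Yw, group = rep(seq_len(B), each = k), reorder = FALSE)
  list(V = V, alpha = alpha, sel = ts$sel, w = ts$w,
       cache = list(es = es, ts = ts, k = k, idx = idx, X0 = X0,
                    fusion = fz, alpha = alpha))
}

arm_backward <- function(dV, Q, S, expert, block, cfg, cache) {
  B <- nrow(Q)
  k <- cache$k
  Y <- cache$fusion$Y
  w <- cache$ts$w
  # dY and dw from the weighted aggregation
  dVrep <- dV[rep(seq_len(B), each = k), , drop = FALSE]
  dY <- dVrep * as.vector(t(w))
  dw <- matrix(rowSums(Y * dVrep), B, k, byrow = TRUE)
  fb <- fusion_bwd(dY, block, cache$fusion$caches)
  # renormalization backward: w = a_sel / sum(a_sel)
  da_sel <- (dw - rowSums(dw * w)) / cache$ts$w_raw_sum
  dalpha <- matrix(0, B, ncol(cache$alpha))
  dalpha[cbind(rep(seq_len(B), k), as.vector(cache$ts$sel))] <-
    as.vector(da_sel)
  # softmax backward
  al <- cache$alpha
  dscores <- al * (dalpha - rowSums(al * dalpha))
  eg <- expert_scores_bwd(dscores, Q, S, expert, cfg$h, cache$es)
  list(expert = eg, fusion = fb$grads)
}
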