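test_that("expert retrieval: singleton and symmetric supports", {
  set.seed(1)
  d <- 16L
  expert <- list(Wq = diag(d), Wk = diag(d))
  q <- rnorm(d)
  one <- matrix(rnorm(d), 1L, d)
  r1 <- expert_retrieve(q, one, expert, h = 4L, top_n = 2L)
  expect_equal(r1$weights, 1.0)
  expect_equal(r1$indices, 1L)

  row <- rnorm(d)
  four <- matrix(rep(row, 4L), 4L, d, byrow = TRUE)
  r4 <- expert_retrieve(q, four, expert, h = 4L, top_n = 4L)
  expect_equal(r4$full_weights, rep(0.25, 4L), tolerance = 1e-12)
  # ties broken by lower support-row index
  r2 <- expert_retrieve(q, four, expert, h = 4L, top_n = 2L)
  expect_equal(r2$indices, c(1L, 2L))
  expect_equal(sum(r2$weights), 1, tolerance = 1e-9)
})

test_that("expert retrieval matches a brute-force attention oracle", {
  set.seed(2)
  d <- 16L; h <- 4L; n <- 6L
  expert <- list(Wq = matrix(rnorm(d * d, sd = 0.3), d),
                 Wk = matrix(rnorm(d * d, sd = 0.3), d))
  q <- rnorm(d)
  S <- matrix(rnorm(n * d), n, d)
  res <- expert_retrieve(q, S, expert, h = h, top_n = 2L)

  # oracle: per-head scaled dot products, averaged, then softmax
  dh <- d / h
  qp <- as.vector(q %*% expert$Wq)
  scores <- vapply(seq_len(n), function(i) {
    kp <- as.vector(S[i, ] %*% expert$Wk)
    mean(vapply(seq_len(h), function(hh) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      sum(qp[cols] * kp[cols]) / sqrt(dh)
    }, numeric(1)))
  }, numeric(1))
  alpha <- exp(scores - max(scores)); alpha <- alpha / sum(alpha)
  expect_equal(res$full_weights, alpha, tolerance = 1e-10)
  top <- order(-alpha)[1:2]
  expect_equal(res$indices, top)
  expect_equal(res$weights, alpha[top] / sum(alpha[top]), tolerance = 1e-10)
  # two retrieved items always carry a unit weight sum
  expect_equal(sum(res$weights), 1, tolerance = 1e-9)
})

test_that("freshly initialized fusion blocks are the identity (residual path)", {
  atlas <- toy_atlas()
  model <- toy_model(atlas)
  X <- random_unit_rows(3L, atlas$d, seed = 5L)
  expect_equal(fuse(X, model$params$fusion_img, h = model$config$h), X,
               tolerance = 1e-12)
})

test_that("fusion is permutation-equivariant (sets, not sequences)", {
  atlas <- toy_atlas()
  model <- perturb_fusion(toy_model(atlas))
  X <- random_unit_rows(4L, atlas$d, seed = 6L)
  perm <- c(3L, 1L, 4L, 2L)
  Y <- fuse(X, model$params$fusion_img, h = model$config$h)
  Yp <- fuse(X[perm, ], model$params$fusion_img, h = model$config$h)
  expect_equal(Yp, Y[perm, ], tolerance = 1e-10)
  expect_error(fuse(matrix(numeric(0), 0L, atlas$d),
                    model$params$fusion_img), "empty")
})

test_that("a fusion layer matches a step-by-step transformer oracle", {
  d <- 8L; h <- 2L; k <- 2L
  set.seed(11)
  layer <- atlasdx:::init_fusion_layer(d, ff_mult = 2L)
  layer$Wo <- matrix(rnorm(d * d, sd = 0.2), d)
  layer$W2 <- matrix(rnorm(2L * d * d, sd = 0.2), 2L * d, d)
  X <- matrix(rnorm(k * d), k, d)

  out <- atlasdx:::fusion_layer_fwd(X, layer, k = k, h = h)$Y

  # oracle: literal pre-norm block arithmetic on the k x d set
  ln <- function(x, g, b) {
    t(apply(x, 1L, function(r) g * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) + b))
  }
  Xn <- ln(X, layer$ln1_g, layer$ln1_b)
  Qp <- Xn %*% layer$Wq; Kp <- Xn %*% layer$Wk; Vp <- Xn %*% layer$Wv
  O <- matrix(0, k, d)
  dh <- d / h
  for (hh in seq_len(h)) {
    cols <- ((hh - 1) * dh + 1):(hh * dh)
    S <- Qp[, cols] %*% t(Kp[, cols]) / sqrt(dh)
    P <- t(apply(S, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    O[, cols] <- P %*% Vp[, cols]
  }
  X2 <- X + O %*% layer$Wo
  Xn2 <- ln(X2, layer$ln2_g, layer$ln2_b)
  Hp <- sweep(Xn2 %*% layer$W1, 2L, layer$b1, `+`)
  Hact <- Hp * plogis(1.702 * Hp)
  oracle <- X2 + sweep(Hact %*% layer$W2, 2L, layer$b2, `+`)
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("aggregation is the weighted sum under the retrieval weights", {
  set.seed(3)
  u <- rnorm(6L); w <- rnorm(6L)
  expect_equal(aggregate_retrieved(1.0, matrix(u, 1L)), u)
  expect_equal(aggregate_retrieved(c(0.5, 0.5), rbind(u, w)), (u + w) / 2)
  wts <- c(0.2, 0.3, 0.5)
  M <- matrix(rnorm(18L), 3L)
  expect_equal(aggregate_retrieved(wts, M),
               wts[1] * M[1, ] + wts[2] * M[2, ] + wts[3] * M[3, ])
  expect_error(aggregate_retrieved(c(0.5, 0.5), M), "match")
})

test_that("enhance composes retrieve -> fuse -> aggregate for every class", {
  atlas <- toy_atlas()
  model <- perturb_fusion(toy_model(atlas))
  q <- random_unit_rows(1L, atlas$d, seed = 9L)[1L, ]
  enh <- enhance(q, atlas, model)
  C <- n_classes(atlas$taxonomy)
  expect_equal(nrow(enh$Vhat), C)
  expect_equal(nrow(enh$Khat), C)
  expect_equal(length(enh$evidence), C)

  # oracle: compose the three exported single-query operations per class
  for (ci in seq_len(C)) {
    s <- atlas$supports[[model$class_ids[[ci]]]]
    for (arm in c("image", "knowledge")) {
      supp <- if (arm == "image") s$image_embeddings else s$knowledge_embeddings
      block <- if (arm == "image") model$params$fusion_img else model$params$fusion_know
      expert <- atlasdx:::expert_for(model, arm, ci)
      r <- expert_retrieve(q, supp, expert, h = model$config$h,
                           top_n = model$config$top_n)
      fused <- fuse(r$rows, block, h = model$config$h)
      got <- if (arm == "image") enh$Vhat[ci, ] else enh$Khat[ci, ]
      expect_equal(got, aggregate_retrieved(r$weights, fused),
                   tolerance = 1e-10)
    }
  }
})

test_that("with identity fusion the enhanced image embedding stays in the
           convex hull of the class supports", {
  atlas <- toy_atlas()
  model <- toy_model(atlas)   # identity fusion at init
  q <- random_unit_rows(1L, atlas$d, seed = 10L)[1L, ]
  enh <- enhance(q, atlas, model)
  for (ci in seq_along(model$class_ids)) {
    ev <- enh$evidence[[ci]]$image
    supp <- atlas$supports[[model$class_ids[[ci]]]]$image_embeddings
    recon <- crossprod(supp[ev$indices, , drop = FALSE], ev$weights)
    expect_equal(enh$Vhat[ci, ], as.vector(recon), tolerance = 1e-10)
    expect_true(all(ev$weights >= 0))
    expect_equal(sum(ev$weights), 1, tolerance = 1e-6)
    expect_equal(sum(enh$evidence[[ci]]$knowledge$weights), 1, tolerance = 1e-6)
  }
})

test_that("single-query enhancement equals the batched forward pass", {
  atlas <- toy_atlas()
  model <- perturb_fusion(toy_model(atlas))
  Q <- random_unit_rows(3L, atlas$d, seed = 12L)
  fw <- atlasdx:::enhance_forward(Q, atlas, model)
  for (b in 1:3) {
    enh <- enhance(Q[b, ], atlas, model)
    expect_equal(matrix(fw$Vhat[b, , ], nrow = length(model$class_ids)),
                 unname(enh$Vhat), tolerance = 1e-12)
    expect_equal(matrix(fw$Khat[b, , ], nrow = length(model$class_ids)),
                 unname(enh$Khat), tolerance = 1e-12)
  }
})

test_that("C = 1 with singleton supports reduces to the fused support rows", {
  tax <- dx_taxonomy(data.frame(
    node_id = c("r", "m", "leaf"), level = 1:3,
    parent_id = c(NA, "r", "m"), display_name = c("r", "m", "leaf"),
    stringsAsFactors = FALSE), c(leaf = "melanoma"))
  d <- 8L
  set.seed(21)
  supports <- list(leaf = list(image_embeddings = matrix(rnorm(d), 1L, d),
                               knowledge_embeddings = matrix(rnorm(d), 1L, d)))
  atlas <- dx_atlas(tax, supports, d = d, normalize = FALSE)
  model <- init_model(atlas, h = 2L, L = 2L, dropout = 0, seed = 3L)
  enh <- enhance(rnorm(d), atlas, model)
  expect_equal(enh$Vhat[1L, ], supports$leaf$image_embeddings[1L, ],
               tolerance = 1e-12)  # identity fusion at init
  expect_equal(enh$Khat[1L, ], supports$leaf$knowledge_embeddings[1L, ],
               tolerance = 1e-12)
})
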