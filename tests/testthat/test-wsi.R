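test_that("tiling arithmetic: grid counts, row-major order, exact coverage", {
  one <- tile_slide(c(512L, 512L), p = 512L)
  expect_equal(nrow(one$coords), 1L)
  expect_equal(one$coords$x, 0L)

  four <- tile_slide(c(1024L, 1024L), p = 512L)
  expect_equal(nrow(four$coords), 4L)
  expect_equal(four$coords$x, c(0L, 512L, 0L, 512L))   # row-major
  expect_equal(four$coords$y, c(0L, 0L, 512L, 512L))

  # brute-force double loop oracle on a non-square slide
  g <- tile_slide(c(96L, 64L), p = 16L)
  oracle <- list()
  for (y in seq(0L, 96L - 16L, by = 16L)) for (x in seq(0L, 64L - 16L, by = 16L)) {
    oracle[[length(oracle) + 1L]] <- c(x, y)
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(as.matrix(g$coords), oracle, ignore_attr = TRUE)
  expect_false(any(duplicated(g$coords)))
  expect_error(tile_slide(c(100L, 100L), p = 512L), "smaller")
})

test_that("tiling extracts the exact pixel blocks", {
  set.seed(51)
  img <- array(runif(32L * 32L * 3L), c(32L, 32L, 3L))
  t4 <- tile_slide(img, p = 16L)
  expect_length(t4$patches, 4L)
  expect_equal(t4$patches[[2L]], img[1:16, 17:32, , drop = FALSE])
  expect_equal(t4$patches[[3L]], img[17:32, 1:16, , drop = FALSE])

  # background filter drops an all-gray (zero saturation) region
  img2 <- img
  img2[1:16, 1:16, ] <- 0.5
  kept <- tile_slide(img2, p = 16L, background_filter = TRUE,
                     saturation_threshold = 0.05)
  expect_equal(nrow(kept$coords), 3L)
  expect_false(any(kept$coords$x == 0L & kept$coords$y == 0L))
})

test_that("tiling reads multi-page TIFF slides at a chosen level", {
  skip_if_not_installed("tiff")
  set.seed(53)
  hi <- array(runif(32L * 32L * 3L), c(32L, 32L, 3L))
  lo <- array(runif(16L * 16L * 3L), c(16L, 16L, 3L))
  f <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(list(hi, lo), f, bits.per.sample = 16L)
  t_hi <- tile_slide(f, p = 16L, level = 1L)
  expect_equal(nrow(t_hi$coords), 4L)
  expect_equal(t_hi$patches[[1L]], hi[1:16, 1:16, , drop = FALSE],
               tolerance = 1e-4)  # 16-bit TIFF quantization
  t_lo <- tile_slide(f, p = 16L, level = 2L)
  expect_equal(nrow(t_lo$coords), 1L)
  expect_error(tile_slide(f, p = 16L, level = 3L), "level")
  expect_error(tile_slide(file.path(tempdir(), "absent.tiff"), p = 16L),
               "unreadable")
})

test_that("ABMIL: singleton weight, permutation invariance, explicit oracle", {
  d <- 12L
  params <- abmil_init(d, ha = 8L, seed = 2L)
  set.seed(52)
  H1 <- matrix(rnorm(d), 1L)
  r1 <- abmil_aggregate(list(embeddings = H1), params)
  expect_equal(r1$attention, 1.0)

  H <- matrix(rnorm(6L * d), 6L)
  r <- abmil_aggregate(list(embeddings = H), params)
  expect_equal(sum(r$attention), 1, tolerance = 1e-9)
  expect_true(all(r$attention >= 0))
  perm <- sample(6L)
  rp <- abmil_aggregate(list(embeddings = H[perm, ]), params)
  expect_equal(rp$score, r$score, tolerance = 1e-12)
  expect_equal(rp$attention, r$attention[perm], tolerance = 1e-12)

  # explicit gated-attention arithmetic
  gate <- tanh(H %*% params$V) * plogis(H %*% params$U)
  gl <- as.vector(gate %*% params$w)
  a <- exp(gl - max(gl)); a <- a / sum(a)
  z <- as.vector(t(H) %*% a)
  expect_equal(r$attention, a, tolerance = 1e-12)
  expect_equal(r$score, plogis(sum(z * params$Wc) + params$bc),
               tolerance = 1e-12)
  expect_error(abmil_aggregate(list(embeddings = matrix(0, 0L, d)), params),
               "empty")
})

test_that("ABMIL training separates signal bags from background bags", {
  cfg <- synth_config(seed = 21L, d = 32L, roots = 2L, mids_per_root = 1L,
                      leaves_per_mid = 2L, n_bags = 60L, patches_per_bag = 15L,
                      signal_fraction = 0.4)
  gen <- gen_atlas(cfg)
  bags <- gen_bags(cfg, gen)
  idx <- seq_along(bags)
  test_idx <- idx[idx %% 3L == 0L]
  val_idx <- idx[idx %% 3L == 1L]
  train_idx <- setdiff(idx, c(test_idx, val_idx))
  fit <- train_abmil(bags[train_idx], val_bags = bags[val_idx],
                     learning_rates = 1e-3, max_epochs = 30L, patience = 10L,
                     ha = 32L, seed = 4L)
  labs <- vapply(bags, `[[`, character(1L), "label")
  sc <- vapply(bags[test_idx], function(b)
    abmil_aggregate(b, fit$params)$score, numeric(1L))
  expect_gt(roc_auc(sc, labs[test_idx]), 0.9)
})

test_that("few-shot protocol enforces the shot menu and report schema", {
  cfg <- synth_config(seed = 22L, d = 32L, roots = 2L, mids_per_root = 1L,
                      leaves_per_mid = 2L, n_bags = 30L, patches_per_bag = 10L,
                      signal_fraction = 0.5)
  gen <- gen_atlas(cfg)
  bags <- gen_bags(cfg, gen)
  # bags are generated positives-first; keep both classes in val and test
  val_idx <- c(1:2, 16:17)
  test_idx <- c(3:8, 18:23)
  expect_error(few_shot_protocol(bags, shots = 5L, val_idx = val_idx,
                                 test_idx = test_idx),
               "shots must be one of")
  res <- few_shot_protocol(bags, shots = 2L, val_idx = val_idx,
                           test_idx = test_idx,
                           seed = 3L, allow_any = FALSE, reps = 30L,
                           learning_rates = 1e-3, max_epochs = 10L,
                           patience = 5L, ha = 16L)
  expect_setequal(res$report$metric, c("roc_auc", "accuracy", "auprc", "f1"))
  expect_length(res$train_idx, 4L)     # 2 shots x 2 classes
  expect_false(any(res$train_idx %in% c(val_idx, test_idx)))
  expect_error(few_shot_protocol(bags, shots = 128L, val_idx = val_idx,
                                 test_idx = test_idx), "insufficient")
})

test_that("per-patch enhancement replaces embeddings with class-space vectors", {
  atlas <- toy_atlas(d = 16L)
  model <- toy_model(atlas)
  set.seed(23)
  bag <- list(slide_id = "s1", embeddings = random_unit_rows(3L, 16L, seed = 24L),
              label = "melanoma")
  eb <- enhance_bag(bag, model, atlas)
  expect_equal(dim(eb$embeddings), c(3L, 16L))
  expect_equal(eb$slide_id, "s1")

  # oracle: per-patch softmax(score)-weighted average over classes of Vhat
  for (p in 1:3) {
    enh <- enhance(bag$embeddings[p, ], atlas, model)
    s <- vapply(seq_along(model$class_ids), function(ci)
      sum(atlasdx:::l2_normalize(enh$Vhat[ci, ]) *
            atlasdx:::l2_normalize(enh$Khat[ci, ])), numeric(1L))
    w <- exp(s - max(s)); w <- w / sum(w)
    expect_equal(eb$embeddings[p, ], as.vector(crossprod(enh$Vhat, w)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # top-1 mode picks the argmax class's enhanced embedding
  eb1 <- enhance_bag(bag, model, atlas, mode = "top1")
  enh <- enhance(bag$embeddings[1L, ], atlas, model)
  s <- vapply(seq_along(model$class_ids), function(ci)
    sum(atlasdx:::l2_normalize(enh$Vhat[ci, ]) *
          atlasdx:::l2_normalize(enh$Khat[ci, ])), numeric(1L))
  expect_equal(eb1$embeddings[1L, ], unname(enh$Vhat[which.max(s), ]),
               tolerance = 1e-10)
})
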