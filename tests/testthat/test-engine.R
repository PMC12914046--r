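# Small training configurations keep these contract tests fast; the full
# synthetic-recovery run lives in test-acceptance.R.

tiny_gen <- function(seed = 13L) {
  gen_atlas(synth_config(seed = seed, d = 16L, roots = 2L, mids_per_root = 1L,
                         leaves_per_mid = 2L, n_images = 3L, m_knowledge = 3L,
                         queries_per_class = 4L))
}

tiny_sets <- function(gen) {
  n <- nrow(gen$queries$embeddings)
  idx <- seq_len(n)
  val <- idx[idx %% 4L == 0L]
  list(train = list(embeddings = gen$queries$embeddings[-val, , drop = FALSE],
                    labels = gen$queries$labels[-val]),
       val = list(embeddings = gen$queries$embeddings[val, , drop = FALSE],
                  labels = gen$queries$labels[val]))
}

test_that("one epoch produces a one-row history and a usable checkpoint", {
  gen <- tiny_gen()
  sets <- tiny_sets(gen)
  fit <- train_model(gen$atlas, sets$train, sets$val,
                     train_config(learning_rates = 1e-3, max_epochs = 1L,
                                  patience = 1L, batch_size = 4L, seed = 2L),
                     L = 1L, h = 4L, dropout = 0)
  expect_equal(nrow(fit$history), 1L)
  expect_s3_class(fit$model, "dx_model")
  pr <- predict(fit$model, gen$queries$embeddings[1L, ], gen$atlas)
  expect_true(pr$predicted %in% fit$model$class_ids)
})

test_that("training is deterministic given the seed", {
  gen <- tiny_gen()
  sets <- tiny_sets(gen)
  cfg <- train_config(learning_rates = 1e-3, max_epochs = 2L, patience = 2L,
                      batch_size = 4L, seed = 5L)
  f1 <- train_model(gen$atlas, sets$train, sets$val, cfg, L = 1L, h = 4L)
  f2 <- train_model(gen$atlas, sets$train, sets$val, cfg, L = 1L, h = 4L)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("training loss trends downward and never updates frozen inputs", {
  gen <- tiny_gen()
  sets <- tiny_sets(gen)
  atlas_before <- unserialize(serialize(gen$atlas, NULL))
  enc <- stub_encoder(d = 16L, seed = 1L)
  img <- array(runif(48L), c(4L, 4L, 3L))
  emb_before <- encode_image(enc, img)

  fit <- train_model(gen$atlas, sets$train, sets$val,
                     train_config(learning_rates = 1e-3, max_epochs = 6L,
                                  patience = 6L, batch_size = 4L, seed = 3L),
                     L = 1L, h = 4L, dropout = 0)
  h <- fit$history
  expect_lte(h$loss_total[nrow(h)], h$loss_total[1L])
  # frozen contract: atlas embeddings and encoder outputs are bit-identical
  expect_identical(gen$atlas, atlas_before)
  expect_identical(encode_image(enc, img), emb_before)
})

test_that("early stopping fires after the patience window", {
  gen <- tiny_gen()
  sets <- tiny_sets(gen)
  # learning rate 0: the validation metric can never improve after epoch 1
  fit <- train_model(gen$atlas, sets$train, sets$val,
                     train_config(learning_rates = 0, max_epochs = 50L,
                                  patience = 3L, batch_size = 4L, seed = 2L),
                     L = 1L, h = 4L, dropout = 0)
  expect_equal(nrow(fit$history), 4L)   # 1 best + 3 stalled epochs
  expect_error(train_model(gen$atlas,
                           list(embeddings = matrix(numeric(0), 0L, 16L),
                                labels = character()),
                           NULL, train_config(seed = 1L)),
               "empty training set")
})

test_that("prediction applies the argmax rule with index tie-breaking", {
  # identical supports for every class force exactly equal scores
  tax <- toy_taxonomy()
  d <- 16L
  set.seed(61)
  vi <- atlasdx:::l2_normalize(matrix(rnorm(2L * d), 2L, d))
  ki <- atlasdx:::l2_normalize(matrix(rnorm(2L * d), 2L, d))
  supports <- lapply(tax$leaf_classes, function(cls)
    list(image_embeddings = vi, knowledge_embeddings = ki))
  names(supports) <- tax$leaf_classes
  atlas <- dx_atlas(tax, supports, d = d)
  model <- init_model(atlas, h = 4L, L = 1L, dropout = 0, seed = 1L,
                      share_experts = TRUE)
  pr <- predict(model, random_unit_rows(1L, d, seed = 62L)[1L, ], atlas)
  expect_equal(diff(range(pr$scores)), 0, tolerance = 1e-12)
  expect_equal(pr$predicted, tax$leaf_classes[[1L]])

  # scores are the diagonal cosine similarities of the enhanced pairs
  gen <- tiny_gen()
  model2 <- perturb_fusion(toy_model(gen$atlas, L = 1L, h = 4L, seed = 2L))
  q <- gen$queries$embeddings[3L, ]
  pr2 <- predict(model2, q, gen$atlas)
  enh <- enhance(q, gen$atlas, model2)
  oracle <- vapply(seq_along(model2$class_ids), function(ci)
    sum(atlasdx:::l2_normalize(enh$Vhat[ci, ]) *
          atlasdx:::l2_normalize(enh$Khat[ci, ])), numeric(1L))
  expect_equal(unname(pr2$scores), oracle, tolerance = 1e-10)
  expect_equal(pr2$predicted, model2$class_ids[[which.max(oracle)]])
})

test_that("binary prediction modes agree on a mapped two-class atlas", {
  gen <- tiny_gen()
  atlas <- gen$atlas
  model <- toy_model(atlas, L = 1L, h = 4L)   # identity fusion
  q <- gen$queries$embeddings[1L, ]
  pred_leaf <- predict(model, q, atlas)$predicted
  expect_equal(predict_binary(q, model, atlas),
               to_binary(pred_leaf, atlas$taxonomy))

  # direct mode demands C = 2
  expect_error(predict_binary(q, model, atlas, mode = "direct"), "two-class")
})

test_that("stratified split respects fractions and the per-class test floor", {
  labels <- rep(c("a", "b", "c"), times = c(20L, 10L, 4L))
  sp <- stratified_split(labels, seed = 7L)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_along(labels))
  for (cls in c("a", "b", "c")) {
    expect_gte(sum(labels[sp$test] == cls), 1L)
  }
  expect_equal(sum(labels[sp$train] == "a"), 14L)
  expect_identical(sp, stratified_split(labels, seed = 7L))
})
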