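# Shared fixtures, all built in code.

# Minimal 3-level taxonomy: 2 roots, 2 mids under root 1, leaves arranged so
# every credit level is reachable.
toy_taxonomy <- function() {
  nodes <- data.frame(
    node_id = c("r1", "r2", "r1.m1", "r1.m2", "r2.m1",
                "l_a", "l_b", "l_c", "l_d"),
    level = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
    parent_id = c(NA, NA, "r1", "r1", "r2",
                  "r1.m1", "r1.m1", "r1.m2", "r2.m1"),
    display_name = c("root one", "root two", "mid 1.1", "mid 1.2", "mid 2.1",
                     "leaf a", "leaf b", "leaf c", "leaf d"),
    stringsAsFactors = FALSE
  )
  dx_taxonomy(nodes, c(l_a = "melanoma", l_b = "nonmelanoma",
                       l_c = "nonmelanoma", l_d = "melanoma"))
}

# Deterministic random atlas over the toy taxonomy (no encoder involved).
toy_atlas <- function(d = 16L, n = 3L, m = 2L, seed = 42L) {
  tax <- toy_taxonomy()
  set.seed(seed)
  supports <- lapply(tax$leaf_classes, function(cls) {
    list(image_embeddings = atlasdx:::l2_normalize(matrix(rnorm(n * d), n, d)),
         knowledge_embeddings = atlasdx:::l2_normalize(matrix(rnorm(m * d), m, d)))
  })
  names(supports) <- tax$leaf_classes
  dx_atlas(tax, supports, d = d, normalize = TRUE)
}

# An identity-fusion model: freshly initialized fusion layers have zero
# output projections, so every layer is the identity on the residual path.
toy_model <- function(atlas, L = 2L, h = 4L, top_n = 2L, seed = 7L, ...) {
  init_model(atlas, h = h, L = L, top_n = top_n, ff_mult = 2L,
             dropout = 0, seed = seed, ...)
}

# Perturb the zero-initialized projections so fusion is a nontrivial map.
perturb_fusion <- function(model, sd = 0.1, seed = 99L) {
  set.seed(seed)
  for (arm in c("fusion_img", "fusion_know")) {
    for (l in seq_along(model$params[[arm]])) {
      layer <- model$params[[arm]][[l]]
      layer$Wo <- layer$Wo + matrix(rnorm(length(layer$Wo), sd = sd),
                                    nrow(layer$Wo))
      layer$W2 <- layer$W2 + matrix(rnorm(length(layer$W2), sd = sd),
                                    nrow(layer$W2))
      model$params[[arm]][[l]] <- layer
    }
  }
  model
}

random_unit_rows <- function(n, d, seed = 1L) {
  set.seed(seed)
  atlasdx:::l2_normalize(matrix(rnorm(n * d), n, d))
}

# Plain-loop oracle for the local contrastive loss (Eq-by-eq brute force).
oracle_local <- function(S_list, y, tau) {
  per <- mapply(function(S, yb) {
    num <- exp(S[yb, yb] / tau)
    den <- 0
    for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
      den <- den + exp(S[i, j] / tau)
    }
    -log(num / den)
  }, S_list, y)
  mean(per)
}

# Plain-loop oracle for the global contrastive loss with mask M_b.
oracle_global <- function(Vhat, Khat, y, tau) {
  B <- dim(Vhat)[1]; C <- dim(Vhat)[2]
  cs <- function(u, w) sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  dir_loss <- function(anchor, bank) {
    tot <- 0
    for (b in seq_len(B)) {
      num <- exp(cs(anchor[b, y[b], ], bank[b, y[b], ]) / tau)
      den <- 0
      for (q in seq_len(B)) for (cc in seq_len(C)) {
        masked <- (q != b) && (cc == y[b])
        if (!masked) den <- den + exp(cs(anchor[b, y[b], ], bank[q, cc, ]) / tau)
      }
      tot <- tot - log(num / den)
    }
    tot / B
  }
  (dir_loss(Vhat, Khat) + dir_loss(Khat, Vhat)) / 2
}

# Wrap raw arrays as a batch_enhanced without going through enhance().
batch_enhanced_from <- function(rb) {
  structure(list(Vhat = rb$Vhat, Khat = rb$Khat, y = as.integer(rb$y)),
            class = "batch_enhanced")
}

random_batch <- function(B, C, d, seed) {
  set.seed(seed)
  list(Vhat = array(rnorm(B * C * d), c(B, C, d)),
       Khat = array(rnorm(B * C * d), c(B, C, d)),
       y = sample.int(C, B, replace = TRUE))
}
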