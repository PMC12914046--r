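#' Initialize the dual-arm retrieval/fusion model for an atlas
#'
#' Creates the trainable parameters: one class-specific multi-head attention
#' expert per (class, modality) pair — or a single shared expert per
#' modality in the one-expert ablation — plus two transformer fusion blocks
#' (image and knowledge arms). The frozen encoder embeddings in the atlas
#' are never part of the model.
#'
#' @param atlas a [dx_atlas()] the model will retrieve from.
#' @param h number of attention heads (default 8; must divide d).
#' @param L fusion depth in transformer layers (default 8).
#' @param top_n retrieval count kept after expert attention (default 2).
#' @param ff_mult feed-forward width multiplier (default 4).
#' @param dropout dropout rate inside fusion blocks during training.
#' @param tau contrastive temperature (default 0.07).
#' @param lambda balance between local and global losses (default 0.01, the
#'   multi-class setting; 1.0 is the generic binary setting).
#' @param share_experts single shared expert per modality (ablation).
#' @param seed seed for parameter initialization.
#' @return object of class `dx_model`.
#' @export
init_model <- function(atlas, h = 8L, L = 8L, top_n = 2L, ff_mult = 4L,
                       dropout = 0.1, tau = 0.07, lambda = 0.01,
                       share_experts = FALSE, seed = 1L) {
  stopifnot(inherits(atlas, "dx_atlas"))
  d <- atlas$d
  if (d %% h != 0L) stop("h must divide the embedding dimension d")
  class_ids <- atlas$taxonomy$leaf_classes
  C <- length(class_ids)
  n_experts <- if (share_experts) 1L else C

  params <- with_seed(seed, {
    init_expert <- function() list(
      # identity + small noise: retrieval starts out cosine-like
      Wq = diag(d) + rand_mat(d, d, sd = 0.02),
      Wk = diag(d) + rand_mat(d, d, sd = 0.02)
    )
    list(
      experts_img = replicate(n_experts, init_expert(), simplify = FALSE),
      experts_know = replicate(n_experts, init_expert(), simplify = FALSE),
      fusion_img = replicate(L, init_fusion_layer(d, ff_mult), simplify = FALSE),
      fusion_know = replicate(L, init_fusion_layer(d, ff_mult), simplify = FALSE)
    )
  })

  structure(
    list(
      config = list(d = d, h = as.integer(h), L = as.integer(L),
                    top_n = as.integer(top_n), ff_mult = as.integer(ff_mult),
                    dropout = dropout, tau = tau, lambda = lambda,
                    share_experts = share_experts, seed = as.integer(seed)),
      class_ids = class_ids,
      params = params
    ),
    class = "dx_model"
  )
}

#' @export
print.dx_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "dx_model: C=%d classes, d=%d, h=%d heads, L=%d fusion layers, top_n=%d%s\n",
    length(x$class_ids), cfg$d, cfg$h, cfg$L, cfg$top_n,
    if (cfg$share_experts) " (shared expert)" else ""))
  invisible(x)
}

expert_for <- function(model, modality, class_index) {
  bank <- if (modality == "image") model$params$experts_img else model$params$experts_know
  if (model$config$share_experts) bank[[1L]] else bank[[class_index]]
}

#' Class-specific expert retrieval
#'
#' Scores each support row against the query by multi-head scaled
#' dot-product attention (scores averaged over heads), applies a softmax
#' over the rows, keeps the `top_n` highest-weight rows, and renormalizes
#' the kept weights to sum to one.
#'
#' @param query d-dim query embedding.
#' @param support n x d matrix of support rows for one class/modality.
#' @param expert list with projection matrices `Wq`, `Wk` (d x d).
#' @param h number of heads.
#' @param top_n retrieval count.
#' @return list with `weights` (renormalized, sum 1), `indices` (retrieved
#'   support row ids in descending weight order; ties broken by lower
#'   index), `full_weights` (softmax over all n rows) and `rows` (the
#'   retrieved support rows).
#' @export
expert_retrieve <- function(query, support, expert, h = 8L, top_n = 2L) {
  if (!is.matrix(support) || nrow(support) < 1L) stop("empty support set")
  q <- matrix(as.numeric(query), nrow = 1L)
  if (ncol(q) != ncol(support)) stop("query/support dimension mismatch")
  es <- expert_scores_fwd(q, support, expert, h)
  alpha <- softmax_vec(as.vector(es$scores))
  ts <- select_topn(matrix(alpha, nrow = 1L), top_n)
  list(weights = as.vector(ts$w), indices = as.vector(ts$sel),
       full_weights = alpha,
       rows = support[as.vector(ts$sel), , drop = FALSE])
}

#' Transformer fusion of a retrieved set
#'
#' Refines a set of retrieved embeddings through `L` pre-norm transformer
#' encoder layers attending across the set. There is no positional encoding:
#' the input is a set, and the operation is permutation-equivariant.
#'
#' @param retrieved k x d matrix of retrieved embeddings.
#' @param block list of fusion layers (e.g. `model$params$fusion_img`).
#' @param h number of heads.
#' @return k x d matrix of refined embeddings, same row order.
#' @export
fuse <- function(retrieved, block, h = 8L) {
  if (!is.matrix(retrieved) || nrow(retrieved) < 1L) stop("empty retrieved set")
  fusion_fwd(retrieved, block, k = nrow(retrieved), h = h)$Y
}

#' Attention-weighted aggregation of a refined set
#'
#' The enhanced embedding is the convex combination of the refined vectors
#' under the (renormalized) original retrieval weights.
#'
#' @param weights retrieval weights (non-negative, sum 1).
#' @param refined k x d matrix of fused embeddings.
#' @return d-dim enhanced embedding.
#' @export
aggregate_retrieved <- function(weights, refined) {
  if (length(weights) != nrow(refined)) {
    stop("weights length must match number of refined vectors")
  }
  as.vector(crossprod(refined, weights))
}

#' Enhance a query against every class of the atlas
#'
#' Runs both arms for every class c: the image expert retrieves reference
#' image embeddings, the knowledge expert retrieves knowledge embeddings,
#' each retrieved set is refined by its fusion block, and the enhanced
#' embeddings v-hat_c / k-hat_c are the attention-weighted aggregates. The
#' attention weights are returned as retrieval evidence.
#'
#' @param query d-dim query embedding.
#' @param atlas a [dx_atlas()].
#' @param model a [init_model()] built for the same atlas.
#' @return object of class `dx_enhanced`: list with `class_ids`, `Vhat` and
#'   `Khat` (C x d matrices), and per-class `evidence` (retrieved indices,
#'   weights, provenance strings for both arms).
#' @export
enhance <- function(query, atlas, model) {
  check_model_atlas(model, atlas)
  fw <- enhance_forward(matrix(as.numeric(query), nrow = 1L), atlas, model)
  C <- length(model$class_ids)
  evidence <- vector("list", C)
  names(evidence) <- model$class_ids
  for (ci in seq_len(C)) {
    s <- atlas$supports[[model$class_ids[[ci]]]]
    img <- fw$arms_img[[ci]]
    kn <- fw$arms_know[[ci]]
    evidence[[ci]] <- list(
      image = list(indices = as.vector(img$sel), weights = as.vector(img$w),
                   meta = s$image_meta[as.vector(img$sel)]),
      knowledge = list(indices = as.vector(kn$sel), weights = as.vector(kn$w),
                       meta = s$knowledge_meta[as.vector(kn$sel)])
    )
  }
  structure(
    list(class_ids = model$class_ids,
         Vhat = matrix(fw$Vhat[1L, , ], nrow = C,
                       dimnames = list(model$class_ids, NULL)),
         Khat = matrix(fw$Khat[1L, , ], nrow = C,
                       dimnames = list(model$class_ids, NULL)),
         evidence = evidence),
    class = "dx_enhanced"
  )
}

check_model_atlas <- function(model, atlas) {
  stopifnot(inherits(model, "dx_model"), inherits(atlas, "dx_atlas"))
  if (!identical(model$class_ids, atlas$taxonomy$leaf_classes)) {
    stop("model was built for a different class set than this atlas")
  }
  if (model$config$d != atlas$d) stop("model/atlas dimension mismatch")
  invisible(TRUE)
}

# Batched enhancement: Q is B x d. Returns Vhat/Khat as B x C x d arrays plus
# per-class arm outputs (and caches when cache = TRUE, for the backward pass).
enhance_forward <- function(Q, atlas, model, training = FALSE, cache = FALSE) {
  cfg <- model$config
  B <- nrow(Q)
  class_ids <- model$class_ids
  C <- length(class_ids)
  Vhat <- array(0, c(B, C, cfg$d))
  Khat <- array(0, c(B, C, cfg$d))
  arms_img <- vector("list", C)
  arms_know <- vector("list", C)
  for (ci in seq_len(C)) {
    s <- atlas$supports[[class_ids[[ci]]]]
    ai <- arm_forward(Q, s$image_embeddings, expert_for(model, "image", ci),
                      model$params$fusion_img, cfg, training)
    ak <- arm_forward(Q, s$knowledge_embeddings, expert_for(model, "knowledge", ci),
                      model$params$fusion_know, cfg, training)
    Vhat[, ci, ] <- ai$V
    Khat[, ci, ] <- ak$V
    keep <- c("alpha", "sel", "w", if (cache) "cache")
    arms_img[[ci]] <- ai[keep]
    arms_know[[ci]] <- ak[keep]
  }
  list(Vhat = Vhat, Khat = Khat, arms_img = arms_img, arms_know = arms_know)
}

# Backward through the batched enhancement. dVhat/dKhat: B x C x d arrays.
# Returns gradients with the same structure as model$params.
enhance_backward <- function(Q, atlas, model, fw, dVhat, dKhat) {
  cfg <- model$config
  class_ids <- model$class_ids
  C <- length(class_ids)
  shared <- cfg$share_experts
  grads <- list(
    experts_img = lapply(model$params$experts_img, zero_like),
    experts_know = lapply(model$params$experts_know, zero_like),
    fusion_img = lapply(model$params$fusion_img, zero_like),
    fusion_know = lapply(model$params$fusion_know, zero_like)
  )
  add_into <- function(acc, g) {
    for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
    acc
  }
  for (ci in seq_len(C)) {
    s <- atlas$supports[[class_ids[[ci]]]]
    ei <- if (shared) 1L else ci
    bi <- arm_backward(matrix(dVhat[, ci, ], nrow = nrow(Q)),
                       Q, s$image_embeddings, expert_for(model, "image", ci),
                       model$params$fusion_img, cfg, fw$arms_img[[ci]]$cache)
    bk <- arm_backward(matrix(dKhat[, ci, ], nrow = nrow(Q)),
                       Q, s$knowledge_embeddings, expert_for(model, "knowledge", ci),
                       model$params$fusion_know, cfg, fw$arms_know[[ci]]$cache)
    grads$experts_img[[ei]] <- add_into(grads$experts_img[[ei]],
                                        list(Wq = bi$expert$dWq, Wk = bi$expert$dWk))
    grads$experts_know[[ei]] <- add_into(grads$experts_know[[ei]],
                                         list(Wq = bk$expert$dWq, Wk = bk$expert$dWk))
    for (l in seq_len(cfg$L)) {
      grads$fusion_img[[l]] <- add_into(grads$fusion_img[[l]], bi$fusion[[l]])
      grads$fusion_know[[l]] <- add_into(grads$fusion_know[[l]], bk$fusion[[l]])
    }
  }
  grads
}
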