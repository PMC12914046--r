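# Seeded synthetic generators: taxonomy, atlas + queries, and WSI bags.
# Class centroids are placed hierarchically so between-class distances
# respect the taxonomy, and knowledge embeddings live in a rotated copy of
# the image space so cross-modal alignment is learnable but not given.

#' Synthetic data configuration
#'
#' Defaults describe well-separated hierarchical clusters: orthogonal offset
#' directions with decreasing magnitudes delta1 > delta2 > delta3 per
#' taxonomy level and small isotropic within-class noise.
#'
#' @param seed master seed; all generators are pure functions of the config.
#' @param d embedding dimension.
#' @param roots,mids_per_root,leaves_per_mid hierarchy shape
#'   (C = roots * mids_per_root * leaves_per_mid).
#' @param n_images,m_knowledge support set sizes per class.
#' @param sigma within-class noise magnitude (image side and queries): the
#'   expected norm of the isotropic Gaussian perturbation, i.e. the
#'   per-coordinate sd is `sigma / sqrt(d)`, so `sigma` compares directly
#'   with the centroid separations regardless of dimension.
#' @param sigma_know knowledge-side noise magnitude, same convention.
#' @param delta1,delta2,delta3 centroid offset magnitudes per level
#'   (must be positive and strictly decreasing).
#' @param queries_per_class labelled query embeddings generated per class.
#' @param n_bags,patches_per_bag,signal_fraction WSI bag parameters.
#' @param melanoma_fraction fraction of leaves mapped to "melanoma".
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, d = 64L, roots = 3L, mids_per_root = 2L,
                         leaves_per_mid = 2L, n_images = 4L, m_knowledge = 4L,
                         sigma = 0.6, sigma_know = 0.6,
                         delta1 = 2.0, delta2 = 1.0, delta3 = 0.5,
                         queries_per_class = 40L,
                         n_bags = 200L, patches_per_bag = 30L,
                         signal_fraction = 0.3, melanoma_fraction = 0.5) {
  stopifnot(delta1 > delta2, delta2 > delta3, delta3 > 0, sigma > 0,
            roots >= 1L, mids_per_root >= 1L, leaves_per_mid >= 1L)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a deterministic three-level taxonomy
#'
#' Node ids are positional (`r1`, `r1.m1`, `r1.m1.l1`, ...); the first
#' `melanoma_fraction` of each mid-level group's leaves are mapped to
#' "melanoma" so both binary groups are populated.
#'
#' @param cfg a [synth_config()].
#' @return a [dx_taxonomy()] with C = roots * mids_per_root * leaves_per_mid
#'   leaves.
#' @export
gen_taxonomy <- function(cfg) {
  rows <- list()
  bmap <- character()
  for (r in seq_len(cfg$roots)) {
    rid <- paste0("r", r)
    rows[[length(rows) + 1L]] <- data.frame(
      node_id = rid, level = 1L, parent_id = NA_character_,
      display_name = paste("Root category", r), stringsAsFactors = FALSE)
    for (m in seq_len(cfg$mids_per_root)) {
      mid <- paste0(rid, ".m", m)
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = mid, level = 2L, parent_id = rid,
        display_name = paste0("Subtype group ", r, ".", m),
        stringsAsFactors = FALSE)
      for (l in seq_len(cfg$leaves_per_mid)) {
        lid <- paste0(mid, ".l", l)
        rows[[length(rows) + 1L]] <- data.frame(
          node_id = lid, level = 3L, parent_id = mid,
          display_name = paste0("Entity ", r, ".", m, ".", l),
          stringsAsFactors = FALSE)
        bmap[[lid]] <- if (l <= max(1L, ceiling(cfg$leaves_per_mid * cfg$melanoma_fraction)) &&
                           cfg$melanoma_fraction > 0) "melanoma" else "nonmelanoma"
      }
    }
  }
  dx_taxonomy(do.call(rbind, rows), bmap)
}

# Hierarchical centroids: mu_leaf = delta1*u_root + delta2*u_mid + delta3*u_leaf
# with u's distinct columns of one random orthogonal matrix, so every leaf
# centroid has identical norm and distances shrink with shared ancestry.
synth_centroids <- function(cfg, tax) {
  nd <- tax$nodes
  n_nodes <- nrow(nd)
  if (cfg$d < n_nodes) {
    stop("embedding dimension d=", cfg$d, " too small for the separation ",
         "construction (need at least ", n_nodes, " orthogonal directions)")
  }
  Qo <- random_orthogonal(cfg$d)
  dir_of <- stats::setNames(seq_len(n_nodes), nd$node_id)
  anc <- leaf_ancestors(tax)
  centroids <- matrix(0, nrow(anc), cfg$d, dimnames = list(anc$leaf, NULL))
  for (i in seq_len(nrow(anc))) {
    centroids[i, ] <- cfg$delta1 * Qo[, dir_of[[anc$level1[[i]]]]] +
      cfg$delta2 * Qo[, dir_of[[anc$level2[[i]]]]] +
      cfg$delta3 * Qo[, dir_of[[anc$leaf[[i]]]]]
  }
  centroids
}

#' Generate a synthetic atlas and held-out labelled queries
#'
#' Image supports and queries are drawn around the hierarchical class
#' centroids with noise `sigma`; knowledge embeddings are the centroids
#' mapped through a fixed random orthogonal transform plus independent noise
#' `sigma_know`. All embeddings are L2-normalized.
#'
#' @param cfg a [synth_config()].
#' @param tax taxonomy from [gen_taxonomy()] (regenerated from `cfg` if
#'   omitted).
#' @return list with `atlas` (a [dx_atlas()]), `queries` (list
#'   `embeddings` N x d, `labels`), `centroids`, and the knowledge-space
#'   rotation `rotation`.
#' @export
gen_atlas <- function(cfg, tax = gen_taxonomy(cfg)) {
  with_seed(cfg$seed, {
    centroids <- synth_centroids(cfg, tax)
    R <- random_orthogonal(cfg$d)
    sd_img <- cfg$sigma / sqrt(cfg$d)
    sd_know <- cfg$sigma_know / sqrt(cfg$d)
    supports <- list()
    q_emb <- list(); q_lab <- character()
    for (cls in tax$leaf_classes) {
      mu <- centroids[cls, ]
      vi <- l2_normalize(matrix(mu, cfg$n_images, cfg$d, byrow = TRUE) +
                           rand_mat(cfg$n_images, cfg$d, sd = sd_img))
      mu_k <- as.vector(R %*% mu)
      ki <- l2_normalize(matrix(mu_k, cfg$m_knowledge, cfg$d, byrow = TRUE) +
                           rand_mat(cfg$m_knowledge, cfg$d, sd = sd_know))
      supports[[cls]] <- list(image_embeddings = vi, knowledge_embeddings = ki)
      qe <- l2_normalize(matrix(mu, cfg$queries_per_class, cfg$d, byrow = TRUE) +
                           rand_mat(cfg$queries_per_class, cfg$d, sd = sd_img))
      q_emb[[cls]] <- qe
      q_lab <- c(q_lab, rep(cls, cfg$queries_per_class))
    }
    list(atlas = dx_atlas(tax, supports, d = cfg$d, normalize = TRUE),
         queries = list(embeddings = do.call(rbind, q_emb), labels = q_lab),
         centroids = centroids, rotation = R)
  })
}

#' Generate synthetic whole-slide bags
#'
#' Positive (melanoma) bags mix patches from a signal class with background
#' patches at `signal_fraction` (at least one signal patch per positive
#' bag); negative bags contain background patches only. Patches are drawn
#' like queries around the class centroids.
#'
#' @param cfg a [synth_config()].
#' @param gen output of [gen_atlas()] (regenerated from `cfg` if omitted).
#' @return list of bags, each `list(slide_id, embeddings (P x d), label)`,
#'   with an even split of positive and negative slides.
#' @export
gen_bags <- function(cfg, gen = gen_atlas(cfg)) {
  if (cfg$signal_fraction <= 0 || cfg$signal_fraction > 1) {
    stop("signal_fraction must be in (0, 1]")
  }
  tax <- gen$atlas$taxonomy
  mel <- names(tax$binary_map)[tax$binary_map == "melanoma"]
  non <- names(tax$binary_map)[tax$binary_map == "nonmelanoma"]
  if (!length(mel) || !length(non)) {
    stop("bag generation needs both melanoma and nonmelanoma leaves")
  }
  signal_cls <- mel[[1L]]
  with_seed(cfg$seed + 7L, {
    draw_patches <- function(cls, n) {
      mu <- gen$centroids[cls, ]
      l2_normalize(matrix(mu, n, cfg$d, byrow = TRUE) +
                     rand_mat(n, cfg$d, sd = cfg$sigma / sqrt(cfg$d)))
    }
    bags <- vector("list", cfg$n_bags)
    for (i in seq_len(cfg$n_bags)) {
      positive <- i <= ceiling(cfg$n_bags / 2)
      P <- cfg$patches_per_bag
      if (positive) {
        n_sig <- max(1L, stats::rbinom(1L, P, cfg$signal_fraction))
        emb <- rbind(
          draw_patches(signal_cls, n_sig),
          if (n_sig < P) draw_patches(sample(non, 1L), P - n_sig))
        emb <- emb[sample.int(P), , drop = FALSE]
      } else {
        emb <- draw_patches(sample(non, 1L), P)
      }
      bags[[i]] <- list(slide_id = sprintf("slide%03d", i), embeddings = emb,
                        label = if (positive) "melanoma" else "nonmelanoma")
    }
    bags
  })
}
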