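#' Multimodal vector atlas
#'
#' The atlas is the per-class vector database the framework retrieves from:
#' for every leaf class it stores n reference image embeddings (rows
#' `v_1..v_n`) and m knowledge-text embeddings (rows `k_1..k_m`), together
#' with the taxonomy that fixes the class order. All embeddings share one
#' dimension d; when `normalize` is on they are stored unit-norm so
#' retrieval never re-normalizes.
#'
#' @param taxonomy a [dx_taxonomy()] whose `leaf_classes` key the supports.
#' @param supports named list (one entry per leaf class, same order) of
#'   lists with elements `image_embeddings` (n x d matrix),
#'   `knowledge_embeddings` (m x d matrix), and optional `image_meta` /
#'   `knowledge_meta` provenance character vectors.
#' @param d embedding dimension.
#' @param normalize whether stored embeddings are L2-normalized.
#' @return object of class `dx_atlas`.
#' @export
dx_atlas <- function(taxonomy, supports, d, normalize = TRUE) {
  stopifnot(inherits(taxonomy, "dx_taxonomy"))
  if (!setequal(names(supports), taxonomy$leaf_classes)) {
    stop("supports must be keyed exactly by the taxonomy leaf classes")
  }
  supports <- supports[taxonomy$leaf_classes]
  for (cls in names(supports)) {
    s <- supports[[cls]]
    vi <- s$image_embeddings
    ki <- s$knowledge_embeddings
    if (!is.matrix(vi) || nrow(vi) < 1L) stop("class ", cls, " has no image embeddings")
    if (!is.matrix(ki) || nrow(ki) < 1L) stop("class ", cls, " has no knowledge embeddings")
    if (ncol(vi) != d || ncol(ki) != d) {
      stop("embedding dimension mismatch for class ", cls,
           " (expected d=", d, ")")
    }
    if (!all(is.finite(vi)) || !all(is.finite(ki))) {
      stop("non-finite embedding in class ", cls)
    }
    supports[[cls]]$image_meta <- s$image_meta %||%
      paste0(cls, "/img", seq_len(nrow(vi)))
    supports[[cls]]$knowledge_meta <- s$knowledge_meta %||%
      paste0(cls, "/know", seq_len(nrow(ki)))
  }
  structure(
    list(taxonomy = taxonomy, supports = supports, d = as.integer(d),
         normalize = normalize),
    class = "dx_atlas"
  )
}

#' @export
print.dx_atlas <- function(x, ...) {
  ns <- vapply(x$supports, function(s) nrow(s$image_embeddings), integer(1L))
  ms <- vapply(x$supports, function(s) nrow(s$knowledge_embeddings), integer(1L))
  cat(sprintf("dx_atlas: C=%d classes, d=%d, n per class [%d..%d], m per class [%d..%d]\n",
              length(x$supports), x$d, min(ns), max(ns), min(ms), max(ms)))
  invisible(x)
}

#' Per-class atlas statistics
#' @param atlas a [dx_atlas()].
#' @return data.frame with one row per class: `class_id`, `n_images`,
#'   `n_knowledge`.
#' @export
atlas_stats <- function(atlas) {
  data.frame(
    class_id = names(atlas$supports),
    n_images = vapply(atlas$supports, function(s) nrow(s$image_embeddings), integer(1L)),
    n_knowledge = vapply(atlas$supports, function(s) nrow(s$knowledge_embeddings), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Build a vector atlas from labelled images and knowledge texts
#'
#' Encodes every reference image and knowledge entry with the frozen
#' encoder, groups them by class, drops classes with fewer than `min_images`
#' reference images (with a warning naming them), and returns the validated
#' atlas. The taxonomy is restricted to the surviving leaves.
#'
#' @param images list of `list(label = leaf_id, image = HxWx3 array)`.
#' @param knowledge named list: leaf id -> character vector of knowledge
#'   entry texts (each class needs at least one).
#' @param encoder frozen encoder, e.g. [stub_encoder()].
#' @param tax a [dx_taxonomy()].
#' @param min_images classes with fewer reference images are excluded
#'   (default 3).
#' @param normalize L2-normalize embeddings before storage.
#' @return a [dx_atlas()].
#' @export
build_atlas <- function(images, knowledge, encoder, tax, min_images = 3L,
                        normalize = TRUE) {
  labels <- vapply(images, function(it) it$label, character(1L))
  unknown <- setdiff(labels, tax$leaf_classes)
  if (length(unknown)) stop("image label not in taxonomy: ", unknown[[1L]])

  counts <- table(factor(labels, levels = tax$leaf_classes))
  keep <- names(counts)[counts >= min_images]
  dropped <- setdiff(tax$leaf_classes, keep)
  if (length(dropped)) {
    warning("dropping classes with fewer than ", min_images, " images: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("no class has at least ", min_images, " images")

  supports <- list()
  for (cls in keep) {
    if (is.null(knowledge[[cls]]) || !length(knowledge[[cls]])) {
      stop("class with zero knowledge entries: ", cls)
    }
    imgs <- images[labels == cls]
    vi <- do.call(rbind, lapply(imgs, function(it) as.numeric(encode_image(encoder, it$image))))
    ki <- do.call(rbind, lapply(knowledge[[cls]], function(tx) as.numeric(encode_text(encoder, tx))))
    if (normalize) {
      vi <- l2_normalize(vi)
      ki <- l2_normalize(ki)
    }
    supports[[cls]] <- list(image_embeddings = vi, knowledge_embeddings = ki,
                            knowledge_meta = paste0(cls, "/know", seq_along(knowledge[[cls]])))
  }
  dx_atlas(subset_taxonomy(tax, keep), supports, d = encoder$d,
           normalize = normalize)
}

# Restrict a taxonomy to a subset of its leaves (internal ancestors kept).
subset_taxonomy <- function(tax, leaves) {
  stopifnot(all(leaves %in% tax$leaf_classes))
  anc <- leaf_ancestors(tax)
  anc <- anc[anc$leaf %in% leaves, , drop = FALSE]
  keep_ids <- unique(c(anc$level1, anc$level2, anc$leaf))
  nodes <- tax$nodes[tax$nodes$node_id %in% keep_ids, , drop = FALSE]
  rownames(nodes) <- NULL
  dx_taxonomy(nodes, tax$binary_map[leaves])
}

#' Save an atlas to disk / load it back
#'
#' Persistence uses R serialization, giving a lossless bit-exact round-trip
#' of all matrices, metadata, taxonomy and flags in a single portable file.
#'
#' @param atlas a [dx_atlas()].
#' @param path file path.
#' @return `save_atlas`: `path` invisibly; `load_atlas`: the [dx_atlas()].
#' @export
save_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "dx_atlas"))
  saveRDS(atlas, path, version = 3L)
  invisible(path)
}

#' @rdname save_atlas
#' @export
load_atlas <- function(path) {
  atlas <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read atlas container at ", path, ": ", conditionMessage(e))
  })
  if (!inherits(atlas, "dx_atlas")) stop("file is not an atlas container: ", path)
  # re-validate: a corrupted container must not yield a partial atlas
  dx_atlas(atlas$taxonomy, atlas$supports, atlas$d, atlas$normalize)
}
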