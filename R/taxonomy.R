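#' Three-tier disease taxonomy with severity-to-binary mapping
#'
#' A `dx_taxonomy` holds the WHO-style three-level hierarchy used for
#' melanocytic neoplasm diagnosis: level 1 are broad root categories,
#' level 2 intermediate clinical groupings, and level 3 the specific
#' diagnostic entities that form the classification task. Each leaf carries a
#' binary severity grouping (melanoma vs nonmelanoma) used for the binary
#' task.
#'
#' @param nodes data.frame with columns `node_id`, `level` (1-3),
#'   `parent_id` (`NA` for roots) and `display_name`.
#' @param binary_map named character vector mapping every leaf `node_id` to
#'   `"melanoma"` or `"nonmelanoma"`.
#' @return object of class `dx_taxonomy` with fields `nodes`,
#'   `leaf_classes` (level-3 ids in declaration order, fixing the class
#'   index 1..C) and `binary_map`.
#' @export
dx_taxonomy <- function(nodes, binary_map) {
  stopifnot(is.data.frame(nodes))
  req <- c("node_id", "level", "parent_id", "display_name")
  if (!all(req %in% names(nodes))) {
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  }
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$display_name <- as.character(nodes$display_name)
  nodes$level <- as.integer(nodes$level)

  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup)) stop("duplicate node id: ", dup[[1L]])
  if (!all(nodes$level %in% 1:3)) stop("node levels must be 1, 2 or 3")

  for (i in seq_len(nrow(nodes))) {
    lv <- nodes$level[[i]]
    pid <- nodes$parent_id[[i]]
    id <- nodes$node_id[[i]]
    if (lv == 1L) {
      if (!is.na(pid)) stop("level-1 node has a parent: ", id)
    } else {
      if (is.na(pid)) stop("non-root node without parent: ", id)
      j <- match(pid, nodes$node_id)
      if (is.na(j)) stop("orphan parent reference for node: ", id)
      if (nodes$level[[j]] != lv - 1L) {
        stop("parent of ", id, " is not one level above it")
      }
    }
  }

  # canonical depth-first node order (siblings keep declaration order) so
  # construction and YAML round-trips agree; leaf order follows it
  dfs <- character(0)
  visit <- function(id) {
    dfs[[length(dfs) + 1L]] <<- id
    kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == id]
    for (k in kids) visit(k)
  }
  for (r in nodes$node_id[nodes$level == 1L]) visit(r)
  nodes <- nodes[match(dfs, nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL

  leaf_classes <- nodes$node_id[nodes$level == 3L]
  if (!length(leaf_classes)) stop("taxonomy has no level-3 leaf classes")
  missing_bin <- setdiff(leaf_classes, names(binary_map))
  if (length(missing_bin)) {
    stop("missing binary mapping for leaf: ", missing_bin[[1L]])
  }
  binary_map <- binary_map[leaf_classes]
  if (!all(binary_map %in% c("melanoma", "nonmelanoma"))) {
    stop("binary mapping values must be 'melanoma' or 'nonmelanoma'")
  }

  structure(
    list(nodes = nodes, leaf_classes = leaf_classes, binary_map = binary_map),
    class = "dx_taxonomy"
  )
}

#' @export
print.dx_taxonomy <- function(x, ...) {
  cat(sprintf(
    "dx_taxonomy: %d roots / %d mid / %d leaf classes (%d melanoma, %d nonmelanoma)\n",
    sum(x$nodes$level == 1L), sum(x$nodes$level == 2L),
    length(x$leaf_classes),
    sum(x$binary_map == "melanoma"), sum(x$binary_map == "nonmelanoma")
  ))
  invisible(x)
}

#' Number of leaf classes
#' @param tax a [dx_taxonomy()].
#' @return integer C.
#' @export
n_classes <- function(tax) length(tax$leaf_classes)

# leaf -> c(level2 ancestor, level1 ancestor)
leaf_ancestors <- function(tax) {
  nd <- tax$nodes
  idx <- match(tax$leaf_classes, nd$node_id)
  l2 <- nd$parent_id[idx]
  l1 <- nd$parent_id[match(l2, nd$node_id)]
  data.frame(leaf = tax$leaf_classes, level2 = l2, level1 = l1,
             stringsAsFactors = FALSE)
}

#' Load a taxonomy from its YAML description file
#'
#' The file lists level-1 nodes under `classes:`, each with `id`, `name` and
#' nested `children`; leaves carry a `binary` key (`melanoma` /
#' `nonmelanoma`). Class index order is the file's declaration order and is
#' frozen at load.
#'
#' @param path path to the YAML taxonomy description.
#' @return a [dx_taxonomy()].
#' @export
load_taxonomy <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$classes)) stop("taxonomy file has no 'classes' key")
  rows <- list()
  bmap <- character()
  walk <- function(node, level, parent) {
    if (is.null(node$id)) stop("taxonomy node without id (level ", level, ")")
    id <- as.character(node$id)
    rows[[length(rows) + 1L]] <<- data.frame(
      node_id = id, level = level,
      parent_id = if (is.null(parent)) NA_character_ else parent,
      display_name = as.character(node$name %||% id),
      stringsAsFactors = FALSE
    )
    if (level == 3L) {
      if (is.null(node$binary)) stop("missing binary mapping for leaf: ", id)
      bmap[[id]] <<- as.character(node$binary)
    } else {
      kids <- node$children
      if (is.null(kids)) stop("non-leaf node without children: ", id)
      for (k in kids) walk(k, level + 1L, id)
    }
  }
  for (root in doc$classes) walk(root, 1L, NULL)
  dx_taxonomy(do.call(rbind, rows), bmap)
}

#' Write a taxonomy back to its YAML description format
#'
#' `load_taxonomy(save_taxonomy(tax, f))` reproduces `tax` exactly.
#'
#' @param tax a [dx_taxonomy()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_taxonomy <- function(tax, path) {
  nd <- tax$nodes
  build <- function(id) {
    i <- match(id, nd$node_id)
    node <- list(id = id, name = nd$display_name[[i]])
    if (nd$level[[i]] == 3L) {
      node$binary <- unname(tax$binary_map[[id]])
    } else {
      kid_ids <- nd$node_id[!is.na(nd$parent_id) & nd$parent_id == id]
      node$children <- lapply(kid_ids, build)
    }
    node
  }
  roots <- nd$node_id[nd$level == 1L]
  yaml::write_yaml(list(classes = lapply(roots, build)), path)
  invisible(path)
}

#' Partial credit for a prediction under the taxonomy
#'
#' Credit is determined by the deepest level at which prediction and truth
#' agree: exact leaf match scores 1.0; same level-2 parent scores 0.5; same
#' level-1 root only scores 0.25; different roots score 0.0.
#'
#' @param pred,truth leaf class ids (vectors are recycled to common length).
#' @param tax a [dx_taxonomy()].
#' @return numeric vector of credits in {0, 0.25, 0.5, 1}.
#' @export
hierarchical_credit <- function(pred, truth, tax) {
  anc <- leaf_ancestors(tax)
  ip <- match(pred, anc$leaf)
  it <- match(truth, anc$leaf)
  if (anyNA(ip)) stop("unknown leaf id: ", pred[which(is.na(ip))[1L]])
  if (anyNA(it)) stop("unknown leaf id: ", truth[which(is.na(it))[1L]])
  credit <- numeric(length(ip))
  credit[anc$level1[ip] == anc$level1[it]] <- 0.25
  credit[anc$level2[ip] == anc$level2[it]] <- 0.5
  credit[ip == it] <- 1.0
  credit
}

#' Map a leaf class to its melanoma/nonmelanoma grouping
#'
#' @param label leaf class id (vectorized).
#' @param tax a [dx_taxonomy()].
#' @return character vector of `"melanoma"` / `"nonmelanoma"`.
#' @export
to_binary <- function(label, tax) {
  out <- tax$binary_map[label]
  if (anyNA(out)) stop("label not mapped in taxonomy: ", label[which(is.na(out))[1L]])
  unname(out)
}
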