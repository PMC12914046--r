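# Frozen encoder contract. Real pathology vision-language backbones plug in
# as adapters implementing encode_image()/encode_text(); the deterministic
# stub below lets the whole framework run with no pretrained weights.

# Evaluate expr under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

N_IMG_FEATURES <- 35L
N_TXT_FEATURES <- 67L

#' Deterministic stub encoder
#'
#' A pure function of (seed, input): images are reduced to a fixed vector of
#' pixel statistics and texts to hashed character-trigram counts, then
#' projected by a seeded random linear map to dimension `d`. The stub stands
#' in for a frozen pathology vision-language backbone; it is never trained.
#'
#' @param d embedding dimension.
#' @param seed integer seed fixing the projection weights.
#' @param normalize L2-normalize outputs (the pipeline default).
#' @return object of class `stub_encoder` with fields `name`, `d`,
#'   `modalities`, projection weights and biases.
#' @export
stub_encoder <- function(d = 64L, seed = 1L, normalize = TRUE) {
  stopifnot(d >= 1L)
  params <- with_seed(seed, list(
    W_img = rand_mat(d, N_IMG_FEATURES, sd = 1 / sqrt(N_IMG_FEATURES)),
    b_img = stats::rnorm(d, sd = 0.1),
    W_txt = rand_mat(d, N_TXT_FEATURES, sd = 1 / sqrt(N_TXT_FEATURES)),
    b_txt = stats::rnorm(d, sd = 0.1)
  ))
  structure(
    c(list(name = "stub", d = as.integer(d), seed = as.integer(seed),
           modalities = c("image", "text"), normalize = normalize),
      params),
    class = "stub_encoder"
  )
}

# Fixed pixel-statistics feature map: per-channel moments and quantiles,
# gradient magnitudes, and an 8-bin gray histogram.
image_features <- function(image) {
  if (length(image) == 0L) stop("empty image")
  if (length(dim(image)) != 3L || dim(image)[[3L]] != 3L) {
    stop("expected an H x W x 3 RGB array, got channel count ",
         if (length(dim(image)) == 3L) dim(image)[[3L]] else "none")
  }
  feats <- numeric(0)
  for (ch in 1:3) {
    x <- image[, , ch]
    feats <- c(feats, mean(x), stats::sd(as.vector(x)), min(x), max(x),
               stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
    gh <- if (ncol(x) > 1L) mean(abs(x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE])) else 0
    gv <- if (nrow(x) > 1L) mean(abs(x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE])) else 0
    feats <- c(feats, gh, gv)
  }
  gray <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
  feats <- c(feats, vapply(1:8, function(k) mean(gray^k), numeric(1L)))
  feats
}

# Hashed character-trigram counts (64 buckets) + 3 length/composition stats.
text_features <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("text must be a non-empty string")
  }
  codes <- utf8ToInt(text)
  buckets <- numeric(64L)
  n <- length(codes)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      hsh <- (codes[i] * 31^2 + codes[i + 1L] * 31 + codes[i + 2L]) %% 64
      buckets[hsh + 1L] <- buckets[hsh + 1L] + 1
    }
    buckets <- buckets / (n - 2L)
  } else {
    buckets[(sum(codes) %% 64) + 1L] <- 1
  }
  c(buckets, log1p(n), mean(codes) / 128, sum(codes %in% utf8ToInt(" ")) / n)
}

#' Encode an RGB image into an embedding vector
#' @param encoder an encoder object, e.g. [stub_encoder()].
#' @param image H x W x 3 numeric array (values on any fixed scale).
#' @return numeric embedding of length `encoder$d` with attribute
#'   `modality = "image"`.
#' @export
encode_image <- function(encoder, image) UseMethod("encode_image")

#' @export
encode_image.stub_encoder <- function(encoder, image) {
  v <- as.vector(encoder$W_img %*% image_features(image)) + encoder$b_img
  if (encoder$normalize) v <- l2_normalize(v)
  structure(v, modality = "image")
}

#' Encode a text string into an embedding vector
#' @param encoder an encoder object, e.g. [stub_encoder()].
#' @param text non-empty character scalar.
#' @return numeric embedding of length `encoder$d` with attribute
#'   `modality = "text"`.
#' @export
encode_text <- function(encoder, text) UseMethod("encode_text")

#' @export
encode_text.stub_encoder <- function(encoder, text) {
  v <- as.vector(encoder$W_txt %*% text_features(text)) + encoder$b_txt
  if (encoder$normalize) v <- l2_normalize(v)
  structure(v, modality = "text")
}

#' Zero-shot class scores from a text prompt template
#'
#' Scores a query image embedding against each class name embedded through
#' the template `"An H&E image of {keyword}"`; the argmax is the zero-shot
#' prediction.
#'
#' @param query image embedding vector.
#' @param class_names character vector of class display names (length C).
#' @param encoder encoder used for the text side.
#' @param template prompt template containing `{keyword}`.
#' @return numeric vector of cosine similarities, one per class, named by
#'   `class_names`.
#' @export
zero_shot_score <- function(query, class_names, encoder,
                            template = "An H&E image of {keyword}") {
  stopifnot(length(class_names) >= 1L)
  scores <- vapply(class_names, function(nm) {
    t_emb <- encode_text(encoder, sub("{keyword}", nm, template, fixed = TRUE))
    cosine_sim(as.numeric(query), as.numeric(t_emb))
  }, numeric(1L))
  names(scores) <- class_names
  scores
}
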