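#' Parameters of the low-resolution DCT face descriptor
#'
#' A deliberately simple baseline standing in for the proprietary matcher:
#' the image is downsampled to a small square, optionally histogram
#' equalised, transformed with a 2-D discrete cosine transform, and the
#' top-left `dct_block` x `dct_block` low-frequency block is flattened and
#' unit-normalised. Dropping the DC coefficient makes the descriptor exactly
#' invariant to uniform brightness shifts.
#'
#' @param target_size side length the image is resized to (>= 16,
#'   default 64).
#' @param dct_block side K of the retained low-frequency block
#'   (K <= target_size, default 8).
#' @param exclude_dc drop the DC term (default TRUE); output dimension is
#'   then K^2 - 1, else K^2.
#' @param equalize apply histogram equalisation before the transform
#'   (default TRUE).
#' @param crop_to_content crop to the bounding box of foreground content
#'   before resizing (default TRUE). This is the usual face-crop
#'   normalisation: it makes the descriptor insensitive to global scale
#'   (e.g. the same face photographed larger or smaller), which a raw
#'   low-frequency DCT is not.
#' @return an object of class `descriptor_params`.
#' @export
descriptor_params <- function(target_size = 64L, dct_block = 8L,
                              exclude_dc = TRUE, equalize = TRUE,
                              crop_to_content = TRUE) {
  target_size <- as.integer(target_size)
  dct_block <- as.integer(dct_block)
  if (target_size < 16L) stop("target_size must be >= 16")
  if (dct_block < 1L || dct_block > target_size)
    stop("dct_block must satisfy 1 <= K <= target_size")
  structure(list(target_size = target_size, dct_block = dct_block,
                 exclude_dc = isTRUE(exclude_dc),
                 equalize = isTRUE(equalize),
                 crop_to_content = isTRUE(crop_to_content)),
            class = "descriptor_params")
}

# Bilinear resize of a numeric matrix to n x n.
resize_bilinear <- function(img, n) {
  h <- nrow(img); w <- ncol(img)
  if (h == n && w == n) return(img)
  # sample centres mapped into source pixel coordinates
  ry <- (seq_len(n) - 0.5) * h / n + 0.5
  rx <- (seq_len(n) - 0.5) * w / n + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(rx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ry - y0, 0), 1);   fx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  top <- a * (1 - fx)[col(a)] + b * fx[col(b)]
  bot <- c_ * (1 - fx)[col(c_)] + d * fx[col(d)]
  top * (1 - fy)[row(top)] + bot * fy[row(bot)]
}

# Histogram equalisation over `levels` gray levels on [0, 1].
hist_equalize <- function(img, levels = 256L) {
  q <- pmin(floor(pmin(pmax(img, 0), 1) * levels), levels - 1L)
  cdf <- cumsum(tabulate(q + 1L, nbins = levels)) / length(img)
  matrix(cdf[q + 1L], nrow(img), ncol(img))
}

# Crop to the bounding box of above-midrange pixels. The midrange threshold
# is invariant to uniform brightness shifts, so cropping never breaks the
# DC-exclusion invariance; a constant image is left untouched.
crop_content <- function(img) {
  thr <- (min(img) + max(img)) / 2
  fg <- img > thr
  if (!any(fg)) return(img)
  rr <- range(which(rowSums(fg) > 0))
  cc <- range(which(colSums(fg) > 0))
  img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
}

# Orthonormal DCT-II matrix of order n (cached).
dct_cache <- new.env(parent = emptyenv())
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(dct_cache[[key]])) return(dct_cache[[key]])
  j <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(j, 2 * j + 1) / (2 * n))
  C[1, ] <- 1 / sqrt(n)
  dct_cache[[key]] <- C
  C
}

# Separable 2-D DCT-II (orthonormal).
dct2 <- function(x) {
  C <- dct_matrix(nrow(x))
  Cc <- if (ncol(x) == nrow(x)) C else dct_matrix(ncol(x))
  C %*% x %*% t(Cc)
}

#' Embed a grayscale image as a unit-norm DCT descriptor
#'
#' @param img numeric matrix (grayscale, any range; values are used as-is)
#'   or a 3-d array whose channels are averaged to grayscale.
#' @param p a [descriptor_params()].
#' @return unit-norm numeric vector of length `K^2 - exclude_dc`.
#'   Deterministic: a pure function of the pixels and parameters.
#' @details A constant (featureless) image has no non-DC energy; with
#'   `exclude_dc = TRUE` this would yield the zero vector and is signalled
#'   as an error instead of being silently normalised.
#' @export
embed_image <- function(img, p = descriptor_params()) {
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop("img must be a non-empty numeric matrix")
  if (p$crop_to_content) img <- crop_content(img)
  x <- resize_bilinear(img, p$target_size)
  if (p$equalize) x <- hist_equalize(x)
  D <- dct2(x)
  K <- p$dct_block
  v <- as.vector(D[seq_len(K), seq_len(K)])
  if (p$exclude_dc) v <- v[-1L]   # column-major: first element is [1,1] DC
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-10)
    stop("featureless image: no non-DC energy to normalise")
  v / nrm
}

#' Embed a list of images
#'
#' @param imgs list of grayscale matrices.
#' @param p a [descriptor_params()].
#' @return matrix with one unit-norm descriptor row per image.
#' @export
embed_images <- function(imgs, p = descriptor_params()) {
  t(vapply(imgs, embed_image, numeric(
    p$dct_block^2 - as.integer(p$exclude_dc)), p = p))
}

#' Cosine similarity of two embeddings
#'
#' @param a,b numeric vectors of equal dimension.
#' @return their cosine similarity in \[-1, 1\]; equals the dot product on
#'   unit-norm inputs, is symmetric, and is 1 exactly for proportional
#'   (on unit vectors: equal) inputs.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("dimension mismatch: ", length(a), " vs ", length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-norm embedding")
  min(max(sum(a * b) / (na * nb), -1), 1)
}
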