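#' Raster image container
#'
#' The unit every augmenter maps to itself in shape: an `H x W x C` array of
#' real intensities stored in `[0, 1]` (8-bit only at the disk boundary).
#' `C` is 1 (grayscale) or 3 (RGB, linear-RGB assumed). All augmentation
#' methods preserve `H`, `W` and `C`.
#'
#' @param pixels Numeric matrix (`H x W`) or array (`H x W x C`).
#' @param clip Clip values into `[0, 1]` (default `TRUE`).
#' @return A `raster_image`: an `H x W x C` array with class attribute.
#' @examples
#' img <- raster_image(matrix(runif(16), 4, 4))
#' dim(img)
#' @export
raster_image <- function(pixels, clip = TRUE) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3)
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) stop("image must have H >= 1 and W >= 1")
  if (!d[3] %in% c(1L, 3L)) stop("channels must be 1 or 3, got ", d[3])
  if (!all(is.finite(pixels))) stop("image contains non-finite values")
  if (clip) pixels <- pmin(pmax(pixels, 0), 1)
  storage.mode(pixels) <- "double"
  structure(pixels, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %dx%dx%d, range [%.3f, %.3f]>\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' Number of channels of an image
#' @param image A [raster_image()].
#' @return Integer, 1 or 3.
#' @export
n_channels <- function(image) dim(image)[3]

#' Extract one channel as a plain matrix
#' @param image A [raster_image()].
#' @param c Channel index.
#' @return Numeric `H x W` matrix.
#' @export
channel <- function(image, c) {
  array(image[, , c], dim = dim(image)[1:2])
}

# Reassemble channels (list of H x W matrices) into a raster_image.
from_channels <- function(chans, clip = TRUE) {
  raster_image(array(unlist(chans, use.names = FALSE),
                     dim = c(dim(chans[[1]]), length(chans))),
               clip = clip)
}

# Apply f to each channel matrix and reassemble; f returns a same-size matrix.
map_channels <- function(image, f, clip = TRUE) {
  from_channels(lapply(seq_len(n_channels(image)), function(c)
    f(channel(image, c))), clip = clip)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Labeled image set
#'
#' An ordered collection of images with class labels; the source of
#' same-class peers for the class-conditional augmenters.
#'
#' @param images List of [raster_image()] objects, all with the same number
#'   of channels.
#' @param labels Character vector of class labels, one per image.
#' @return A `labeled_image_set` with fields `images`, `labels`, `classes`.
#' @export
labeled_image_set <- function(images, labels) {
  stopifnot(is.list(images), length(images) == length(labels))
  if (length(images) == 0) stop("image set is empty")
  labels <- as.character(labels)
  ch <- vapply(images, n_channels, integer(1))
  if (length(unique(ch)) > 1)
    stop("all images in a set must share the channel count")
  structure(list(images = images, labels = labels,
                 classes = sort(unique(labels))),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("<labeled_image_set: %d images, %d classes (%s), C=%d>\n",
              length(x$images), length(x$classes),
              paste(x$classes, collapse = ", "),
              n_channels(x$images[[1]])))
  invisible(x)
}

#' @export
length.labeled_image_set <- function(x) length(x$images)

# Indices of same-class peers, excluding `exclude` if given.
class_member_indices <- function(set, label, exclude = NULL) {
  idx <- which(set$labels == label)
  if (!is.null(exclude)) idx <- setdiff(idx, exclude)
  idx
}

# Draw n peer indices from the class `label`, excluding `exclude`.
# >= n other members: without replacement; 1..n-1: with replacement; 0: error.
draw_peer_indices <- function(set, rng, n, label, exclude = NULL) {
  idx <- class_member_indices(set, label, exclude)
  if (length(idx) == 0)
    stop("class '", label, "' has no other member to draw peers from")
  rng_sample(rng, idx, n, replace = length(idx) < n)
}
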