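#' Read a labeled image set
#'
#' Accepts either a folder-per-class directory (each subdirectory is a class,
#' containing PNG/JPEG/TIFF files) or a CSV manifest with header
#' `filepath,label`, paths relative to the manifest. Item order is
#' deterministic: classes and filenames sorted lexicographically (manifest:
#' row order). Pixels are normalized to `[0, 1]`; grayscale files yield
#' one-channel images and are never promoted to RGB.
#'
#' @param path Directory or manifest CSV path.
#' @return A [labeled_image_set()].
#' @export
read_image_set <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (dir.exists(path)) .read_set_dir(path) else .read_set_manifest(path)
}

.image_extensions <- c("png", "jpg", "jpeg", "tif", "tiff")

.read_set_dir <- function(path) {
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class subdirectories under ", path)
  files <- character(0); labels <- character(0)
  for (cl in classes) {
    fs <- sort(list.files(file.path(path, cl), full.names = TRUE))
    fs <- fs[tolower(tools::file_ext(fs)) %in% .image_extensions]
    if (length(fs) == 0) stop("class folder '", cl, "' contains no images")
    files <- c(files, fs)
    labels <- c(labels, rep(cl, length(fs)))
  }
  labeled_image_set(lapply(files, read_raster), labels)
}

.read_set_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("filepath", "label") %in% names(man)))
    stop("manifest must have columns 'filepath' and 'label': ", path)
  if (nrow(man) == 0) stop("manifest is empty: ", path)
  base <- dirname(normalizePath(path))
  files <- ifelse(grepl("^(/|[A-Za-z]:)", man$filepath),
                  man$filepath, file.path(base, man$filepath))
  labeled_image_set(lapply(files, read_raster), man$label)
}

#' Read a single image file
#'
#' PNG and TIFF are decoded natively; JPEG goes through EBImage. An alpha
#' channel, if present, is dropped.
#'
#' @param file Path to a PNG, JPEG or TIFF file.
#' @return A [raster_image()] with values in `[0, 1]`.
#' @export
read_raster <- function(file) {
  if (!file.exists(file)) stop("cannot read image file: ", file)
  ext <- tolower(tools::file_ext(file))
  px <- switch(ext,
    png  = png::readPNG(file),
    tif  = ,
    tiff = tiff::readTIFF(file),
    jpg  = ,
    jpeg = {
      img <- EBImage::readImage(file)
      a <- EBImage::imageData(img)
      # EBImage stores x (width) first; transpose into H x W [x C]
      if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
    },
    stop("unsupported image format '", ext, "': ", file)
  )
  if (length(dim(px)) == 3 && dim(px)[3] %in% c(2L, 4L))
    px <- px[, , seq_len(dim(px)[3] - 1L), drop = FALSE] # drop alpha
  raster_image(px)
}

#' Write a labeled image set to disk
#'
#' Writes folder-per-class 8-bit PNG files plus a CSV manifest
#' (`filepath,label`, relative paths). Reading the result back reproduces the
#' set up to 8-bit quantization (per-pixel error at most 1/255).
#'
#' @param set A [labeled_image_set()].
#' @param path Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Path of the written manifest, invisibly.
#' @export
write_image_set <- function(set, path, overwrite = FALSE) {
  stopifnot(inherits(set, "labeled_image_set"))
  if (dir.exists(path) && length(list.files(path)) > 0 && !overwrite)
    stop("directory exists and is not empty (use overwrite = TRUE): ", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  counts <- integer(0)
  rows <- character(length(set$images))
  for (i in seq_along(set$images)) {
    lab <- set$labels[i]
    counts[lab] <- if (is.na(counts[lab])) 1L else counts[lab] + 1L
    dir.create(file.path(path, lab), showWarnings = FALSE)
    rel <- file.path(lab, sprintf("img_%05d.png", counts[[lab]]))
    img <- set$images[[i]]
    px <- if (n_channels(img) == 1) array(img, dim = dim(img)[1:2]) else unclass(img)
    png::writePNG(px, file.path(path, rel))
    rows[i] <- paste(rel, lab, sep = ",")
  }
  manifest <- file.path(path, "manifest.csv")
  writeLines(c("filepath,label", rows), manifest)
  invisible(manifest)
}

#' Summarize an image set
#'
#' Per-class counts and a channel audit, as printed by the command-line
#' `inspect` subcommand.
#'
#' @param set A [labeled_image_set()].
#' @return Data frame with columns `class`, `n_images`, `channels`.
#' @export
inspect_image_set <- function(set) {
  stopifnot(inherits(set, "labeled_image_set"))
  ch <- vapply(set$images, n_channels, integer(1))
  data.frame(
    class = set$classes,
    n_images = vapply(set$classes, function(cl) sum(set$labels == cl),
                      integer(1)),
    channels = vapply(set$classes, function(cl)
      max(ch[set$labels == cl]), integer(1)),
    row.names = NULL
  )
}
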