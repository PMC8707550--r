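# Elastic deformation (App9): warp by per-pixel random displacement fields,
# either raw (three scale factors) or low-pass filtered (disk, Gaussian,
# Laplacian-of-Gaussian kernels) and scaled by a common factor.

#' Unit-scale random displacement field
#'
#' Every entry of both component matrices is i.i.d. Uniform(-1, 1); the
#' field's scale factor is 1.
#'
#' @param shape Integer `c(H, W)`.
#' @param rng A [rand_source()].
#' @return A `displacement_field` with matrices `dx`, `dy` and scale `alpha`.
#' @export
random_field <- function(shape, rng) {
  H <- shape[1]; W <- shape[2]
  structure(list(dx = matrix(rng_runif(rng, H * W, -1, 1), H, W),
                 dy = matrix(rng_runif(rng, H * W, -1, 1), H, W),
                 alpha = 1),
            class = "displacement_field")
}

#' Low-pass filter a displacement field
#'
#' Convolves both components with one of three rotationally symmetric
#' kernels — circular averaging disk, Gaussian low-pass, or Laplacian of
#' Gaussian — using symmetric boundary padding. Averaging kernels preserve
#' constant fields; the Laplacian-of-Gaussian kernel sums to zero and maps
#' constants to zero.
#'
#' @param f A `displacement_field`.
#' @param kind `"disk"`, `"gaussian"` or `"log"`.
#' @param config Configuration list (kernel sizes under `elastic.kernels.*`).
#' @return Filtered `displacement_field` (same shape and alpha).
#' @export
smooth_field <- function(f, kind = c("disk", "gaussian", "log"),
                         config = aug_config()) {
  kind <- match.arg(kind)
  kern <- switch(kind,
    disk = disk_kernel(config[["elastic.kernels.disk_radius"]]),
    gaussian = gaussian_kernel(config[["elastic.kernels.gaussian_size"]],
                               config[["elastic.kernels.gaussian_sigma"]]),
    log = log_kernel(config[["elastic.kernels.log_size"]],
                     config[["elastic.kernels.log_sigma"]])
  )
  structure(list(dx = conv2_same(f$dx, kern, "symmetric"),
                 dy = conv2_same(f$dy, kern, "symmetric"),
                 alpha = f$alpha),
            class = "displacement_field")
}

#' Warp an image by a displacement field
#'
#' Output pixel `(y, x)` is the bilinear sample of the input at
#' `(y + alpha * dy, x + alpha * dx)`, with sampling coordinates clamped to
#' the image rectangle. Bilinear interpolation of clipped inputs cannot
#' produce values outside the input's per-channel range.
#'
#' @param image A [raster_image()].
#' @param f A `displacement_field` whose matrices match the image's `H x W`.
#' @param alpha Scale factor applied to the field (defaults to `f$alpha`).
#' @return Warped [raster_image()].
#' @export
warp <- function(image, f, alpha = f$alpha) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (!identical(dim(f$dx), c(H, W)) || !identical(dim(f$dy), c(H, W)))
    stop("displacement field shape must match the image")
  ys <- matrix(rep(seq_len(H), times = W), H, W) + alpha * f$dy
  xs <- matrix(rep(seq_len(W), each = H), H, W) + alpha * f$dx
  map_channels(image, function(m) bilinear_sample(m, ys, xs))
}

#' Elastic deformation augmentation (App9)
#'
#' Produces six images. Three use raw random fields with scale factors 7000,
#' 1000 and 13000; three use one random field pair filtered by each of the
#' disk, Gaussian and Laplacian-of-Gaussian kernels, scaled by the common
#' factor 3000. By default each factor is normalized by the pixel count
#' (`alpha_eff = alpha / (H * W)`), giving displacements on the scale of a
#' few pixels for typical working resolutions; `elastic.alpha_mode =
#' "literal"` applies the factors unnormalized.
#'
#' @param image A [raster_image()].
#' @param rng A [rand_source()].
#' @param config Configuration list (`elastic.alphas_raw`,
#'   `elastic.alpha_filtered`, `elastic.alpha_mode`, `elastic.kernels.*`).
#' @return List of 6 augmented images.
#' @export
app9 <- function(image, rng, config = aug_config()) {
  H <- dim(image)[1]; W <- dim(image)[2]
  norm <- if (identical(config[["elastic.alpha_mode"]], "literal")) 1
          else H * W
  out <- vector("list", 6)
  for (i in seq_along(config[["elastic.alphas_raw"]])) {
    f <- random_field(c(H, W), rng)
    out[[i]] <- warp(image, f, config[["elastic.alphas_raw"]][i] / norm)
  }
  k <- length(config[["elastic.alphas_raw"]])
  for (kind in c("disk", "gaussian", "log")) {
    f <- smooth_field(random_field(c(H, W), rng), kind, config)
    k <- k + 1
    out[[k]] <- warp(image, f, config[["elastic.alpha_filtered"]] / norm)
  }
  out
}
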