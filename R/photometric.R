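# Photometric augmentation (App6-App8): contrast stretching, unsharp
# sharpening, RGB channel shifting, HSV jitter, Gaussian blur, histogram
# specification and Reinhard color transfer toward a same-class target.

#' Linear contrast stretch
#'
#' Maps intensities below `a` to 0 and above `b` to 255 (8-bit scale), with a
#' linear ramp between: `(v - a) / (b - a) * 255`. Internally the image stays
#' in `[0, 1]`; `a` and `b` are given on the 8-bit scale. The map is monotone
#' non-decreasing.
#'
#' @param image A [raster_image()].
#' @param a,b Lower and upper intensity bounds, `0 <= a < b <= 255`.
#' @return Stretched [raster_image()].
#' @export
contrast_stretch <- function(image, a, b) {
  if (!(a >= 0 && b <= 255 && a < b))
    stop("contrast bounds need 0 <= a < b <= 255")
  a1 <- a / 255; b1 <- b / 255
  raster_image(array((unclass(image) - a1) / (b1 - a1), dim = dim(image)))
}

#' Sharpen by blurred-image subtraction
#'
#' Blurs with a Gaussian of unit variance and adds the difference between
#' original and blurred back to the original (unsharp masking with unit
#' amount): `clip(img + (img - blur(img)))`. The literal variant — the bare
#' difference `img - blur(img)`, a near-black edge image — is available with
#' `literal = TRUE`.
#'
#' @param image A [raster_image()].
#' @param sigma Gaussian standard deviation (variance 1 by default).
#' @param literal Return the bare difference instead of unsharp masking.
#' @return Sharpened [raster_image()].
#' @export
sharpen_subtract <- function(image, sigma = 1, literal = FALSE) {
  blurred <- gaussian_blur(image, sigma)
  out <- if (literal) unclass(image) - unclass(blurred)
         else unclass(image) + (unclass(image) - unclass(blurred))
  raster_image(array(out, dim = dim(image)))
}

#' Constant per-channel color shift
#'
#' Adds one integer shift (8-bit scale) to each RGB channel, then clips.
#'
#' @param image A 3-channel [raster_image()].
#' @param shifts Integer vector of length 3 (R, G, B), 8-bit scale.
#' @return Shifted [raster_image()].
#' @export
color_shift <- function(image, shifts) {
  if (n_channels(image) != 3)
    stop("color_shift requires a 3-channel image")
  stopifnot(length(shifts) == 3)
  px <- unclass(image)
  for (c in 1:3) px[, , c] <- px[, , c] + shifts[c] / 255
  raster_image(px)
}

#' Contrast / sharpness / color-shift augmentation (App6)
#'
#' Produces three images: a contrast stretch with bounds drawn from the
#' configured ranges, a sharpened image, and a color-shifted image with
#' integer shifts drawn per channel.
#'
#' @param image A 3-channel [raster_image()].
#' @param rng A [rand_source()].
#' @param config Configuration list (`photo.contrast_a_range`,
#'   `photo.contrast_b_range`, `photo.shift_range`,
#'   `photo.sharpen_literal`).
#' @return List of 3 augmented images.
#' @export
app6 <- function(image, rng, config = aug_config()) {
  if (n_channels(image) != 3) stop("App6 requires a 3-channel image")
  ar <- config[["photo.contrast_a_range"]]
  br <- config[["photo.contrast_b_range"]]
  a <- floor(rng_runif(rng, 1, ar[1], ar[2] + 1))
  b <- floor(rng_runif(rng, 1, br[1], br[2] + 1))
  list(
    contrast_stretch(image, a, b),
    sharpen_subtract(image, sigma = 1,
                     literal = isTRUE(config[["photo.sharpen_literal"]])),
    color_shift(image, .draw_shifts(rng, config))
  )
}

.draw_shifts <- function(rng, config) {
  sr <- config[["photo.shift_range"]]
  floor(rng_runif(rng, 3, sr[1], sr[2] + 1))
}

# --- HSV jitter -----------------------------------------------------------

rgb_to_hsv_mat <- function(image) {
  px <- unclass(image)
  grDevices::rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                           as.vector(px[, , 3])), maxColorValue = 1)
}

hsv_to_rgb_image <- function(hsvm, dims) {
  h <- hsvm[1, ] * 6; s <- hsvm[2, ]; v <- hsvm[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  raster_image(array(c(r, g, b), dim = dims))
}

#' Jitter one HSV attribute
#'
#' Converts to HSV, perturbs one attribute and converts back. Hue offsets add
#' modulo 1; saturation and brightness offsets add and clip to `[0, 1]`;
#' contrast scales the value channel about mid-gray by the drawn factor.
#' Offsets are drawn from the configured ranges (`photo.jitter.*`); pass
#' `offset` to fix the value (used by the identity tests).
#'
#' @param image A 3-channel [raster_image()].
#' @param attribute One of `"hue"`, `"saturation"`, `"brightness"`,
#'   `"contrast"`.
#' @param rng A [rand_source()] (unused when `offset` is given).
#' @param config Configuration list.
#' @param offset Optional fixed offset/factor overriding the random draw.
#' @return Jittered [raster_image()].
#' @export
jitter_hsv <- function(image,
                       attribute = c("hue", "saturation", "brightness",
                                     "contrast"),
                       rng = NULL, config = aug_config(), offset = NULL) {
  attribute <- match.arg(attribute)
  if (n_channels(image) != 3) stop("HSV jitter requires a 3-channel image")
  if (is.null(offset)) {
    rr <- config[[paste0("photo.jitter.", attribute)]]
    offset <- rng_runif(rng, 1, rr[1], rr[2])
  }
  m <- rgb_to_hsv_mat(image)
  if (attribute == "hue") {
    m[1, ] <- (m[1, ] + offset) %% 1
  } else if (attribute == "saturation") {
    m[2, ] <- clip01(m[2, ] + offset)
  } else if (attribute == "brightness") {
    m[3, ] <- clip01(m[3, ] + offset)
  } else {
    m[3, ] <- clip01((m[3, ] - 0.5) * offset + 0.5)
  }
  hsv_to_rgb_image(m, dim(image))
}

#' HSV jitter / blur / sharpen / shift augmentation (App7)
#'
#' Produces seven images: four HSV jitters (hue, saturation, brightness,
#' contrast), a Gaussian blur with standard deviation drawn from `[1, 6]`, a
#' sharpened image (unsharp masking, radius 1, strength 2), and a color
#' shift as in App6.
#'
#' @param image A 3-channel [raster_image()].
#' @param rng A [rand_source()].
#' @param config Configuration list.
#' @return List of 7 augmented images.
#' @export
app7 <- function(image, rng, config = aug_config()) {
  if (n_channels(image) != 3) stop("App7 requires a 3-channel image")
  sr <- config[["photo.jitter.blur_sigma"]]
  radius <- config[["photo.jitter.sharpen_radius"]]
  strength <- config[["photo.jitter.sharpen_strength"]]
  sharp <- unclass(image) +
    strength * (unclass(image) - unclass(gaussian_blur(image, radius)))
  list(
    jitter_hsv(image, "hue", rng, config),
    jitter_hsv(image, "saturation", rng, config),
    jitter_hsv(image, "brightness", rng, config),
    jitter_hsv(image, "contrast", rng, config),
    gaussian_blur(image, rng_runif(rng, 1, sr[1], sr[2])),
    raster_image(array(sharp, dim = dim(image))),
    color_shift(image, .draw_shifts(rng, config))
  )
}

# --- histogram specification and Reinhard transfer ------------------------

#' Histogram specification toward a target image
#'
#' Per channel, remaps source intensities by the monotone CDF-matching map
#' sending the source histogram to the target histogram (256-bin, 8-bit
#' resolution). The map depends only on intensity values, so the pixel rank
#' order within each channel is preserved.
#'
#' @param source,target 3-channel [raster_image()]s.
#' @return Remapped [raster_image()] with the source's shape.
#' @export
histogram_specification <- function(source, target) {
  if (n_channels(source) != n_channels(target))
    stop("source and target must share the channel count")
  nbin <- 256L
  match_channel <- function(s, t) {
    sq <- pmin(floor(s * (nbin - 1) + 0.5), nbin - 1)   # 0..255
    tq <- pmin(floor(t * (nbin - 1) + 0.5), nbin - 1)
    s_cdf <- cumsum(tabulate(as.vector(sq) + 1L, nbin)) / length(sq)
    t_cdf <- cumsum(tabulate(as.vector(tq) + 1L, nbin)) / length(tq)
    # smallest target level whose CDF reaches the source CDF
    lut <- findInterval(s_cdf, t_cdf, left.open = TRUE)  # 0..255
    matrix(lut[sq + 1L] / (nbin - 1), nrow(s), ncol(s))
  }
  from_channels(lapply(seq_len(n_channels(source)), function(c)
    match_channel(channel(source, c), channel(target, c))))
}

# sRGB <-> Ruderman lab (log-opponent) conversion matrices.
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)

rgb_to_lab <- function(image) {
  px <- unclass(image)
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                as.vector(px[, , 3]))
  lms <- pmax(.rgb2lms %*% rgbm, 1e-6)   # avoid log(0)
  .lms2lab %*% log10(lms)
}

lab_to_rgb_image <- function(lab, dims) {
  lms <- 10^(.lab2lms %*% lab)
  rgbm <- .lms2rgb %*% lms
  raster_image(array(c(rgbm[1, ], rgbm[2, ], rgbm[3, ]), dim = dims))
}

#' Reinhard color transfer toward a target image
#'
#' Converts source and target to the decorrelated log-opponent lab space,
#' shifts and rescales each source channel to the target's per-channel mean
#' and standard deviation, and converts back (the stain-normalization
#' transfer used in microscopy). A channel with zero spread in the source is
#' mean-shifted with scale 1.
#'
#' @param source,target 3-channel [raster_image()]s.
#' @return Transferred [raster_image()] with the source's shape.
#' @export
reinhard_transfer <- function(source, target) {
  if (n_channels(source) != 3 || n_channels(target) != 3)
    stop("Reinhard transfer requires 3-channel images")
  ls <- rgb_to_lab(source); lt <- rgb_to_lab(target)
  out <- ls
  for (c in 1:3) {
    ms <- mean(ls[c, ]); ss <- stats::sd(ls[c, ])
    mt <- mean(lt[c, ]); st <- stats::sd(lt[c, ])
    scale <- if (is.finite(ss) && ss > 0) st / ss else 1
    out[c, ] <- (ls[c, ] - ms) * scale + mt
  }
  lab_to_rgb_image(out, dim(source))
}

#' Same-class histogram / color transfer augmentation (App8)
#'
#' Draws one target image uniformly from the image's class (excluding the
#' image itself) and produces two images: the histogram specification of the
#' image toward the target, and the Reinhard transfer toward the same
#' target.
#'
#' @param image A 3-channel [raster_image()].
#' @param set A [labeled_image_set()] supplying the target.
#' @param rng A [rand_source()].
#' @param index Index of `image` within `set`, excluded from the draw.
#' @return List of 2 augmented images.
#' @export
app8 <- function(image, set, rng, index = NULL) {
  if (n_channels(image) != 3) stop("App8 requires a 3-channel image")
  stopifnot(inherits(set, "labeled_image_set"))
  label <- .resolve_label(image, set, index)
  tgt <- set$images[[draw_peer_indices(set, rng, 1, label, exclude = index)]]
  list(histogram_specification(image, tgt), reinhard_transfer(image, tgt))
}
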