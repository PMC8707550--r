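# Shared low-level raster operations: bilinear sampling with edge clamping,
# 2-D convolution with symmetric padding, and the standard kernel shapes
# (Gaussian, circular averaging disk, Laplacian of Gaussian).

# Bilinear sample of matrix m at real coordinates (rows `ri`, cols `ci`),
# clamped to the image rectangle so out-of-frame samples replicate the
# nearest edge pixel. ri, ci are same-length vectors (or matrices).
bilinear_sample <- function(m, ri, ci) {
  H <- nrow(m); W <- ncol(m)
  d <- dim(ri)
  ri <- pmin(pmax(as.vector(ri), 1), H)
  ci <- pmin(pmax(as.vector(ci), 1), W)
  r0 <- floor(ri); c0 <- floor(ci)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- ri - r0; fc <- ci - c0
  v <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
       (1 - fr) * fc       * m[cbind(r0, c1)] +
       fr       * (1 - fc) * m[cbind(r1, c0)] +
       fr       * fc       * m[cbind(r1, c1)]
  if (!is.null(d)) dim(v) <- d
  v
}

# Symmetric (mirror-including-edge) padding by k rows/cols on each side.
pad_symmetric <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  refl <- function(i, n) {
    # half-point symmetric extension: ... 2 1 | 1 2 ... n | n n-1 ...
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1, 2 * n - i)
  }
  ri <- refl(seq(1 - k, H + k), H)
  ci <- refl(seq(1 - k, W + k), W)
  m[ri, ci, drop = FALSE]
}

# Replicate (clamp-to-edge) padding.
pad_replicate <- function(m, k) {
  ri <- pmin(pmax(seq(1 - k, nrow(m) + k), 1), nrow(m))
  ci <- pmin(pmax(seq(1 - k, ncol(m) + k), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

# 2-D correlation of m with square kernel kern (odd side), same-size output.
# padding: "symmetric" or "replicate".
conv2_same <- function(m, kern, padding = c("symmetric", "replicate")) {
  padding <- match.arg(padding)
  kH <- nrow(kern); kW <- ncol(kern)
  stopifnot(kH %% 2 == 1, kW %% 2 == 1)
  k <- max((kH - 1) %/% 2, (kW - 1) %/% 2)
  p <- if (padding == "symmetric") pad_symmetric(m, k) else pad_replicate(m, k)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  oy <- k - (kH - 1) %/% 2
  ox <- k - (kW - 1) %/% 2
  for (i in seq_len(kH)) {
    for (j in seq_len(kW)) {
      if (kern[i, j] == 0) next
      out <- out + kern[i, j] * p[oy + i + seq_len(H) - 1,
                                  ox + j + seq_len(W) - 1]
    }
  }
  out
}

# Normalized Gaussian kernel, side n (odd), standard deviation sigma.
gaussian_kernel <- function(n, sigma) {
  r <- (n - 1) / 2
  g <- outer(-r:r, -r:r, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

# Circular averaging kernel: normalized indicator of a disk of given radius.
disk_kernel <- function(radius) {
  r <- ceiling(radius)
  d <- outer(-r:r, -r:r, function(y, x) sqrt(x^2 + y^2))
  k <- (d <= radius) * 1
  k / sum(k)
}

# Laplacian-of-Gaussian kernel, side n, adjusted to sum exactly to zero so
# that constant fields map to zero.
log_kernel <- function(n, sigma) {
  r <- (n - 1) / 2
  s2 <- sigma^2
  h <- outer(-r:r, -r:r, function(y, x) {
    q <- (x^2 + y^2) / (2 * s2)
    ((x^2 + y^2 - 2 * s2) / s2^2) * exp(-q)
  })
  h <- h / sum(abs(h))
  h - mean(h)
}

# Gaussian blur of one channel matrix with replicate padding; kernel side
# 2*ceiling(2*sigma)+1.
gaussian_blur_channel <- function(m, sigma) {
  n <- 2 * ceiling(2 * sigma) + 1
  conv2_same(m, gaussian_kernel(n, sigma), padding = "replicate")
}

#' Gaussian blur of an image
#'
#' Channel-wise Gaussian smoothing with replicate boundary handling; used by
#' the sharpening and blur augmenters.
#'
#' @param image A [raster_image()].
#' @param sigma Standard deviation of the Gaussian in pixels.
#' @return A blurred [raster_image()] of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  map_channels(image, function(m) gaussian_blur_channel(m, sigma))
}
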