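#' Generate a synthetic class-structured image set
#'
#' Deterministic fixture generator standing in for real benchmark images.
#' Each class is a distinct texture family — an oriented sinusoidal grating
#' with class-specific orientation and spatial frequency, plus seeded
#' pixelwise noise — so that class-conditional operations (peer swaps,
#' histogram/color transfer toward a same-class target) are meaningful and a
#' small classifier can separate the classes. For three-channel output the
#' channels carry phase-shifted copies of the grating, giving each class a
#' distinct chromatic structure. The set is a pure function of the
#' arguments: the same seed reproduces identical pixels.
#'
#' @param n_classes Number of classes (at least 2).
#' @param per_class Images per class (at least 1).
#' @param size Integer `c(H, W)`.
#' @param channels 1 or 3.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the additive pixel noise.
#' @return A [labeled_image_set()] with `n_classes * per_class` images and
#'   labels `class01, class02, ...`.
#' @examples
#' s <- make_fixtures(3, 5, c(64, 64), channels = 3, seed = 7)
#' length(s$images)
#' @export
make_fixtures <- function(n_classes, per_class, size = c(64, 64),
                          channels = 3, seed = 1, noise_sd = 0.05) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (per_class < 1) stop("per_class must be >= 1")
  if (!channels %in% c(1, 3)) stop("channels must be 1 or 3")
  stopifnot(length(size) == 2, all(size >= 4))
  H <- as.integer(size[1]); W <- as.integer(size[2])
  rng <- rand_source(seed)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  images <- vector("list", n_classes * per_class)
  labels <- character(n_classes * per_class)
  k <- 0L
  for (cl in seq_len(n_classes)) {
    theta <- pi * (cl - 1) / n_classes           # class orientation
    freq <- 0.06 + 0.05 * (cl - 1)               # cycles per pixel
    proj <- xs * cos(theta) + ys * sin(theta)
    for (i in seq_len(per_class)) {
      irng <- rng_fork(rng)
      phase <- rng_runif(irng, 1, 0, 2 * pi)
      chans <- lapply(seq_len(channels), function(c) {
        ph <- phase + (c - 1) * 2 * pi / 3
        base <- 0.5 + 0.35 * sin(2 * pi * freq * proj + ph)
        noise <- matrix(rng_runif(irng, H * W, -1, 1) * noise_sd * sqrt(3),
                        H, W)
        base + noise
      })
      k <- k + 1L
      images[[k]] <- from_channels(chans)
      labels[k] <- sprintf("class%02d", cl)
    }
  }
  labeled_image_set(images, labels)
}
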