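# Geometric augmentation (App1-App3): random reflection, anisotropic
# upscaling with center crop, rotation, translation and shear, composed as a
# single centered affine map sampled bilinearly with edge replication.

#' Sample geometric augmentation parameters
#'
#' Draws one parameter vector for the requested method. App1 draws the two
#' reflections (independent fair coin flips by default) and two independent
#' axis scale factors from `[1, 2]`; App2 adds rotation in `[-10, 10]`
#' degrees, axis shifts in `[0, 5]` pixels and shear angles in `[0, 30]`
#' degrees; App3 is App2 with both shears pinned to zero. Fields outside a
#' method's scope are identity values.
#'
#' @param mode `"App1"`, `"App2"` or `"App3"`.
#' @param rng A [rand_source()].
#' @param config Configuration list ([aug_config()]).
#' @return A `geometric_params` list.
#' @export
sample_geometric_params <- function(mode = c("App1", "App2", "App3"), rng,
                                    config = aug_config()) {
  mode <- match.arg(mode)
  sr <- config[["geo.scale_range"]]
  p <- list(
    reflect_lr = rng_runif(rng, 1) < config[["geo.reflect_prob"]],
    reflect_tb = rng_runif(rng, 1) < config[["geo.reflect_prob"]],
    scale_x = rng_runif(rng, 1, sr[1], sr[2]),
    scale_y = rng_runif(rng, 1, sr[1], sr[2]),
    rotation_deg = 0, shift_x = 0, shift_y = 0,
    shear_x_deg = 0, shear_y_deg = 0
  )
  if (mode %in% c("App2", "App3")) {
    rr <- config[["geo.rot_range"]]; tr <- config[["geo.shift_range"]]
    p$rotation_deg <- rng_runif(rng, 1, rr[1], rr[2])
    p$shift_x <- rng_runif(rng, 1, tr[1], tr[2])
    p$shift_y <- rng_runif(rng, 1, tr[1], tr[2])
    if (isTRUE(config[["geo.shift_random_sign"]])) {
      p$shift_x <- p$shift_x * sign(rng_runif(rng, 1, -1, 1))
      p$shift_y <- p$shift_y * sign(rng_runif(rng, 1, -1, 1))
    }
  }
  if (mode == "App2") {
    hr <- config[["geo.shear_range"]]
    p$shear_x_deg <- rng_runif(rng, 1, hr[1], hr[2])
    p$shear_y_deg <- rng_runif(rng, 1, hr[1], hr[2])
  }
  structure(p, class = "geometric_params")
}

#' Identity geometric parameters
#'
#' @return A `geometric_params` object that makes [apply_geometric()] an
#'   exact no-op.
#' @export
identity_geometric_params <- function() {
  structure(list(reflect_lr = FALSE, reflect_tb = FALSE,
                 scale_x = 1, scale_y = 1, rotation_deg = 0,
                 shift_x = 0, shift_y = 0,
                 shear_x_deg = 0, shear_y_deg = 0),
            class = "geometric_params")
}

is_identity_params <- function(p) {
  !p$reflect_lr && !p$reflect_tb && p$scale_x == 1 && p$scale_y == 1 &&
    p$rotation_deg == 0 && p$shift_x == 0 && p$shift_y == 0 &&
    p$shear_x_deg == 0 && p$shear_y_deg == 0
}

#' Apply a geometric transform to an image
#'
#' Composes reflect, scale, rotate, shear, translate (in that order) about
#' the image center and resamples with bilinear interpolation. The output
#' keeps the input's `H x W x C`; since scale factors are at least 1 this
#' amounts to an implicit center crop after upscaling. Samples falling
#' outside the frame replicate the nearest edge pixel, so the transform can
#' never produce values outside the input's range.
#'
#' @param image A [raster_image()].
#' @param p A `geometric_params` object.
#' @return Transformed [raster_image()].
#' @export
apply_geometric <- function(image, p) {
  stopifnot(inherits(p, "geometric_params"))
  if (is_identity_params(p)) return(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  # forward map M: centered (x right, y down) input coords -> output coords
  deg <- pi / 180
  Rf <- diag(c(if (p$reflect_lr) -1 else 1, if (p$reflect_tb) -1 else 1, 1))
  Sc <- diag(c(p$scale_x, p$scale_y, 1))
  th <- p$rotation_deg * deg
  Ro <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Sh <- matrix(c(1, tan(p$shear_y_deg * deg), 0,
                 tan(p$shear_x_deg * deg), 1, 0, 0, 0, 1), 3, 3)
  Tr <- diag(3); Tr[1, 3] <- p$shift_x; Tr[2, 3] <- p$shift_y
  M <- Tr %*% Sh %*% Ro %*% Sc %*% Rf
  Minv <- solve(M)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xo <- matrix(rep(seq_len(W), each = H), H, W) - cx
  yo <- matrix(rep(seq_len(H), times = W), H, W) - cy
  xi <- Minv[1, 1] * xo + Minv[1, 2] * yo + Minv[1, 3] + cx
  yi <- Minv[2, 1] * xo + Minv[2, 2] * yo + Minv[2, 3] + cy
  map_channels(image, function(m) bilinear_sample(m, yi, xi))
}

#' Geometric augmentation methods
#'
#' `app1()` reflects the image at random in the left-right and top-bottom
#' directions and scales it anisotropically by two factors drawn from
#' `[1, 2]`, producing 3 images. `app2()` adds random rotation, translation
#' and shear (6 images). `app3()` is `app2()` without shear (4 images). Each
#' output comes from an independent parameter draw.
#'
#' @param image A [raster_image()].
#' @param rng A [rand_source()].
#' @param config Configuration list ([aug_config()]).
#' @return List of augmented images (3, 6 and 4 respectively).
#' @export
app1 <- function(image, rng, config = aug_config()) {
  lapply(seq_len(3), function(i)
    apply_geometric(image, sample_geometric_params("App1", rng, config)))
}

#' @rdname app1
#' @export
app2 <- function(image, rng, config = aug_config()) {
  lapply(seq_len(6), function(i)
    apply_geometric(image, sample_geometric_params("App2", rng, config)))
}

#' @rdname app1
#' @export
app3 <- function(image, rng, config = aug_config()) {
  lapply(seq_len(4), function(i)
    apply_geometric(image, sample_geometric_params("App3", rng, config)))
}
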