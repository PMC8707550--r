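#' Default augmentation configuration
#'
#' Flat key-value list of every tunable the augmenters expose. Ranges are on
#' the scales the methods are specified in: intensities on the 8-bit scale
#' where noted, geometry in pixels and degrees.
#'
#' @param ... Named overrides, e.g. `aug_config("geo.reflect_prob" = 1)`.
#' @return Named list of configuration values.
#' @export
aug_config <- function(...) {
  cfg <- list(
    # geometric (App1-App3)
    "geo.scale_range"   = c(1, 2),
    "geo.rot_range"     = c(-10, 10),
    "geo.shift_range"   = c(0, 5),
    "geo.shear_range"   = c(0, 30),
    "geo.reflect_prob"  = 0.5,
    "geo.shift_random_sign" = FALSE,
    # subspace (App4-App5)
    "sub.p_zero"  = 0.5,
    "sub.p_swap"  = 0.05,
    "sub.n_peers" = 5,
    # photometric (App6-App8)
    "photo.contrast_a_range" = c(0, 50),     # 8-bit scale
    "photo.contrast_b_range" = c(205, 255),
    "photo.shift_range"      = c(-30, 30),   # integer 8-bit shifts
    "photo.sharpen_literal"  = FALSE,
    "photo.jitter.hue"        = c(0.05, 0.15),
    "photo.jitter.saturation" = c(-0.4, -0.1),
    "photo.jitter.brightness" = c(-0.3, -0.1),
    "photo.jitter.contrast"   = c(1.2, 1.4),
    "photo.jitter.blur_sigma" = c(1, 6),
    "photo.jitter.sharpen_radius"   = 1,
    "photo.jitter.sharpen_strength" = 2,
    # elastic (App9)
    "elastic.alphas_raw"     = c(7000, 1000, 13000),
    "elastic.alpha_filtered" = 3000,
    "elastic.alpha_mode"     = "per_pixel",  # or "literal"
    "elastic.kernels.disk_radius"    = 5,
    "elastic.kernels.gaussian_size"  = 7,
    "elastic.kernels.gaussian_sigma" = 1.5,
    "elastic.kernels.log_size"       = 7,
    "elastic.kernels.log_sigma"      = 0.5,
    # spectral (App10-App11)
    "spectral.wavelet" = "db1",
    "spectral.p_zero"  = 0.5,
    "spectral.p_swap"  = 0.05,
    "spectral.cqt_bins_per_octave" = 12,
    "spectral.cqt_axis" = "columns",         # or "rows"
    "spectral.cqt_perturb_domain" = "complex" # or "magnitude"
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; numeric vectors are
#' comma-separated; anything non-numeric is kept as a string, with
#' `true`/`false` mapped to logicals. Unknown keys are rejected.
#'
#' @param path File path.
#' @return A configuration list as from [aug_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    raw <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(raw))
    val <- if (!anyNA(num)) num
           else if (all(tolower(raw) %in% c("true", "false")))
             tolower(raw) == "true"
           else raw
    over[[key]] <- val
  }
  do.call(aug_config, over)
}
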