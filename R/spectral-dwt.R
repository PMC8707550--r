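# Single-level Haar (db1) 2-D wavelet analysis with half-point symmetric
# boundary extension, the transform behind the wavelet-coefficient
# perturbation augmenter (App10). For a channel of side n each subband has
# side ceiling(n/2) (227 -> 114), and the synthesis is an exact inverse.

# 1-D analysis along columns of matrix X: returns list(lo, hi), each
# ceiling(n/2) x ncol. Odd n: last sample is paired with its mirror copy.
.haar_analyze_cols <- function(X) {
  n <- nrow(X)
  if (n %% 2 == 1) X <- rbind(X, X[n, , drop = FALSE])
  odd <- seq(1, nrow(X), by = 2)
  lo <- (X[odd, , drop = FALSE] + X[odd + 1, , drop = FALSE]) / sqrt(2)
  hi <- (X[odd, , drop = FALSE] - X[odd + 1, , drop = FALSE]) / sqrt(2)
  list(lo = lo, hi = hi)
}

# Inverse of .haar_analyze_cols, cropped to n rows.
.haar_synthesize_cols <- function(lo, hi, n) {
  m <- nrow(lo)
  X <- matrix(0, 2 * m, ncol(lo))
  odd <- seq(1, 2 * m, by = 2)
  X[odd, ] <- (lo + hi) / sqrt(2)
  X[odd + 1, ] <- (lo - hi) / sqrt(2)
  X[seq_len(n), , drop = FALSE]
}

#' Single-level db1 wavelet analysis of one channel
#'
#' Separable single-level discrete wavelet transform with the length-2
#' Daubechies db1 (Haar) filter pair and half-band downsampling. Produces
#' the approximation subband `cA` and the horizontal, vertical and diagonal
#' detail subbands `cH`, `cV`, `cD`, each of size
#' `ceiling(H/2) x ceiling(W/2)`. Odd sizes use half-point symmetric
#' boundary extension, so [dwt_inverse()] is exact.
#'
#' @param channel Numeric `H x W` matrix, `H, W >= 2`.
#' @return A `wavelet_coefficients` list with matrices `cA`, `cH`, `cV`,
#'   `cD` and the original `shape`.
#' @export
dwt_forward <- function(channel) {
  stopifnot(is.matrix(channel), nrow(channel) >= 2, ncol(channel) >= 2)
  rows <- .haar_analyze_cols(channel)                 # along H
  colsL <- .haar_analyze_cols(t(rows$lo))             # along W
  colsH <- .haar_analyze_cols(t(rows$hi))
  structure(list(cA = t(colsL$lo), cH = t(colsL$hi),
                 cV = t(colsH$lo), cD = t(colsH$hi),
                 shape = dim(channel)),
            class = "wavelet_coefficients")
}

#' Single-level db1 wavelet synthesis
#'
#' Exact inverse of [dwt_forward()]; the output is cropped to
#' `target_shape` (defaults to the shape recorded at analysis).
#'
#' @param coeffs A `wavelet_coefficients` object.
#' @param target_shape Integer `c(H, W)`.
#' @return Numeric `H x W` matrix.
#' @export
dwt_inverse <- function(coeffs, target_shape = coeffs$shape) {
  H <- target_shape[1]; W <- target_shape[2]
  lo <- t(.haar_synthesize_cols(t(coeffs$cA), t(coeffs$cH), W))
  hi <- t(.haar_synthesize_cols(t(coeffs$cV), t(coeffs$cD), W))
  .haar_synthesize_cols(lo, hi, H)
}

#' Perturb wavelet coefficients
#'
#' The three coefficient perturbations of the wavelet augmenter, applied to
#' all four subband matrices. `zero`: each element is set to zero
#' independently with probability `p_zero`. `additive`: one constant
#' `c = channel_sd + Uniform(-0.5, 0.5)` is added to every element of all
#' four matrices. `swap`: each element is replaced, with probability
#' `p_swap`, by the matching element of one of five same-class peers'
#' coefficient sets (peer chosen uniformly per element).
#'
#' @param coeffs A `wavelet_coefficients` object.
#' @param mode `"zero"`, `"additive"` or `"swap"`.
#' @param rng A [rand_source()].
#' @param channel_sd Standard deviation of the original channel (additive
#'   mode).
#' @param peers List of peer `wavelet_coefficients` (swap mode), matching
#'   shapes.
#' @param p_zero,p_swap Perturbation probabilities.
#' @return Perturbed `wavelet_coefficients`.
#' @export
perturb_wavelet <- function(coeffs, mode = c("zero", "additive", "swap"),
                            rng, channel_sd = NULL, peers = NULL,
                            p_zero = 0.5, p_swap = 0.05) {
  mode <- match.arg(mode)
  bands <- c("cA", "cH", "cV", "cD")
  if (mode == "zero") {
    for (b in bands) {
      hit <- matrix(rng_runif(rng, length(coeffs[[b]])) < p_zero,
                    nrow(coeffs[[b]]))
      coeffs[[b]][hit] <- 0
    }
  } else if (mode == "additive") {
    stopifnot(!is.null(channel_sd))
    const <- channel_sd + rng_runif(rng, 1, -0.5, 0.5)
    for (b in bands) coeffs[[b]] <- coeffs[[b]] + const
  } else {
    if (is.null(peers) || length(peers) < 1)
      stop("swap mode requires peer coefficient sets")
    for (p in peers)
      for (b in bands)
        if (!identical(dim(p[[b]]), dim(coeffs[[b]])))
          stop("peer wavelet coefficients must match the original's shape")
    for (b in bands) {
      m <- coeffs[[b]]
      hit <- rng_runif(rng, length(m)) < p_swap
      which_peer <- rng_rint(rng, length(m), length(peers))
      if (any(hit)) {
        P <- vapply(peers, function(p) as.vector(p[[b]]),
                    numeric(length(m)))
        m[hit] <- P[cbind(which(hit), which_peer[hit])]
        coeffs[[b]] <- m
      }
    }
  }
  coeffs
}

#' Wavelet-coefficient perturbation augmentation (App10)
#'
#' For each channel: single-level db1 analysis, one of the three coefficient
#' perturbations ([perturb_wavelet()]), synthesis, clip. Produces three
#' images, one per perturbation mode; swap peers are five images drawn from
#' the image's class and analyzed with the same transform.
#'
#' @param image A [raster_image()].
#' @param set A [labeled_image_set()] supplying peers.
#' @param rng A [rand_source()].
#' @param index Index of `image` within `set`, excluded from its peer pool.
#' @param config Configuration list (`spectral.p_zero`, `spectral.p_swap`,
#'   `sub.n_peers`).
#' @return List of 3 augmented images.
#' @export
app10 <- function(image, set, rng, index = NULL, config = aug_config()) {
  stopifnot(inherits(set, "labeled_image_set"))
  label <- .resolve_label(image, set, index)
  peer_idx <- draw_peer_indices(set, rng, config[["sub.n_peers"]], label,
                                exclude = index)
  C <- n_channels(image)
  pz <- config[["spectral.p_zero"]]; ps <- config[["spectral.p_swap"]]
  one <- function(perturb) {
    from_channels(lapply(seq_len(C), function(c) {
      m <- channel(image, c)
      dwt_inverse(perturb(dwt_forward(m), m, c))
    }))
  }
  list(
    one(function(w, m, c) perturb_wavelet(w, "zero", rng, p_zero = pz)),
    one(function(w, m, c) perturb_wavelet(w, "additive", rng,
                                          channel_sd = stats::sd(as.vector(m)))),
    one(function(w, m, c) {
      peers <- lapply(peer_idx, function(i)
        dwt_forward(channel(set$images[[i]], c)))
      perturb_wavelet(w, "swap", rng, peers = peers, p_swap = ps)
    })
  )
}
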