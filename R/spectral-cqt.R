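# Column-wise constant-Q analysis (App11). Each image column is treated as a
# 1-D signal and expanded on a frame of Hann-windowed complex exponentials
# whose center frequencies are geometrically spaced (constant
# center-frequency-to-bandwidth ratio Q) with a lowpass (DC) band appended so
# the frame is complete. Analysis is an explicit matrix product; synthesis is
# the least-squares inverse via a cached QR factorization, which makes the
# round trip exact to machine precision. Plans are cached per (length,
# bins-per-octave) pair.

.cqt_cache <- new.env(parent = emptyenv())

#' Build (or fetch) a constant-Q analysis plan for signals of length `n`
#'
#' Frequencies run from `4/n` cycles per sample up to Nyquist in steps of
#' `2^(1/bins_per_octave)`, preceded by one DC (f = 0) band; window length
#' for bin `k` is `min(n, Q / f_k)` samples of a squared-cosine (Hann)
#' window, frames are spaced `floor(n/8)` samples apart. The number of bins
#' is a consequence of `n` and `bins_per_octave`, not a fixed constant.
#'
#' @param n Signal (column) length; at least 16.
#' @param bins_per_octave Frequency resolution (default 12).
#' @return A `cqt_plan` with the analysis matrix, its QR least-squares
#'   inverse, and the block geometry `n_bins x n_frames`.
#' @export
cqt_plan <- function(n, bins_per_octave = 12) {
  if (n < 16)
    stop("constant-Q analysis needs columns of at least 16 samples, got ", n)
  key <- paste(n, bins_per_octave, sep = "_")
  if (!is.null(.cqt_cache[[key]])) return(.cqt_cache[[key]])
  Q <- 1 / (2^(1 / bins_per_octave) - 1)
  fmin <- 4 / n
  K <- floor(bins_per_octave * log2(0.5 / fmin)) + 1
  freqs <- c(0, fmin * 2^((seq_len(K) - 1) / bins_per_octave))
  hop <- max(1L, floor(n / 8))
  centers <- seq(1, n, by = hop)
  idx <- seq_len(n)
  rows <- vector("list", length(freqs) * length(centers))
  r <- 0L
  for (j in seq_along(centers)) {
    for (k in seq_along(freqs)) {
      f <- freqs[k]
      L <- if (f == 0) n else min(n, round(Q / f))
      d <- idx - centers[j]
      w <- ifelse(abs(d) <= L / 2, cos(pi * d / L)^2, 0)
      r <- r + 1L
      rows[[r]] <- w * exp(-2i * pi * f * d) / L
    }
  }
  A <- do.call(rbind, rows)
  M <- rbind(Re(A), Im(A))
  qrM <- qr(M)
  if (qrM$rank < n)
    stop("constant-Q frame is rank-deficient for n = ", n)
  plan <- structure(list(A = A, qrM = qrM, n = n,
                         n_bins = length(freqs), n_frames = length(centers),
                         bins_per_octave = bins_per_octave),
                    class = "cqt_plan")
  .cqt_cache[[key]] <- plan
  plan
}

#' Column-wise constant-Q analysis of one channel
#'
#' Transforms every image column (length `H`) into an
#' `n_bins x n_frames` complex coefficient matrix; the stack holds one block
#' per column, plus the plan needed for exact inversion. Set
#' `spectral.cqt_axis = "rows"` to transform rows instead.
#'
#' @param channel Numeric `H x W` matrix.
#' @param bins_per_octave Frequency resolution (default 12).
#' @param axis `"columns"` (default) or `"rows"`.
#' @return A `cqt_stack` with fields `blocks` (list of complex matrices),
#'   `plan`, `shape`, `axis`.
#' @export
cqt_forward <- function(channel, bins_per_octave = 12,
                        axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  X <- if (axis == "columns") channel else t(channel)
  plan <- cqt_plan(nrow(X), bins_per_octave)
  Cmat <- plan$A %*% X                       # (n_bins*n_frames) x W
  blocks <- lapply(seq_len(ncol(X)), function(w)
    matrix(Cmat[, w], plan$n_bins, plan$n_frames))
  structure(list(blocks = blocks, plan = plan, shape = dim(channel),
                 axis = axis),
            class = "cqt_stack")
}

#' Constant-Q synthesis
#'
#' Least-squares inversion of [cqt_forward()] using the plan's cached QR
#' factorization; exact (to machine precision) when the coefficients are
#' unperturbed. The imaginary part of the solution is discarded implicitly
#' by solving the stacked real system.
#'
#' @param stack A `cqt_stack`.
#' @param target_shape Integer `c(H, W)` (defaults to the analyzed shape).
#' @return Numeric `H x W` matrix.
#' @export
cqt_inverse <- function(stack, target_shape = stack$shape) {
  if (is.null(stack$plan)) stop("cqt_stack is missing its transform plan")
  plan <- stack$plan
  Cmat <- vapply(stack$blocks, as.vector,
                 complex(plan$n_bins * plan$n_frames))
  X <- qr.coef(plan$qrM, rbind(Re(Cmat), Im(Cmat)))
  out <- if (stack$axis == "columns") X else t(X)
  out[seq_len(target_shape[1]), seq_len(target_shape[2]), drop = FALSE]
}

# Perturb a cqt_stack in place: zero / additive / swap on complex
# coefficients. Additive adds the real constant to the real parts (or to the
# magnitudes when domain = "magnitude").
perturb_cqt <- function(stack, mode, rng, channel_sd = NULL, peers = NULL,
                        p_zero = 0.5, p_swap = 0.05, domain = "complex") {
  nb <- length(stack$blocks)
  if (mode == "zero") {
    for (i in seq_len(nb)) {
      m <- stack$blocks[[i]]
      hit <- matrix(rng_runif(rng, length(m)) < p_zero, nrow(m))
      m[hit] <- 0+0i
      stack$blocks[[i]] <- m
    }
  } else if (mode == "additive") {
    stopifnot(!is.null(channel_sd))
    const <- channel_sd + rng_runif(rng, 1, -0.5, 0.5)
    for (i in seq_len(nb)) {
      m <- stack$blocks[[i]]
      if (identical(domain, "magnitude")) {
        mag <- Mod(m); ph <- Arg(m)
        stack$blocks[[i]] <- complex(modulus = pmax(mag + const, 0),
                                     argument = ph)
        dim(stack$blocks[[i]]) <- dim(m)
      } else {
        stack$blocks[[i]] <- m + const
      }
    }
  } else if (mode == "swap") {
    if (is.null(peers) || length(peers) < 1)
      stop("swap mode requires peer coefficient stacks")
    for (p in peers)
      if (length(p$blocks) != nb ||
          !identical(dim(p$blocks[[1]]), dim(stack$blocks[[1]])))
        stop("peer constant-Q stacks must match the original's geometry")
    for (i in seq_len(nb)) {
      m <- stack$blocks[[i]]
      hit <- rng_runif(rng, length(m)) < p_swap
      which_peer <- rng_rint(rng, length(m), length(peers))
      if (any(hit)) {
        P <- vapply(peers, function(p) as.vector(p$blocks[[i]]),
                    complex(length(m)))
        m[hit] <- P[cbind(which(hit), which_peer[hit])]
        stack$blocks[[i]] <- m
      }
    }
  } else stop("unknown perturbation mode: ", mode)
  stack
}

#' Constant-Q-coefficient perturbation augmentation (App11)
#'
#' For each channel: column-wise constant-Q analysis, one of the three
#' coefficient perturbations (zero with p = 0.5; one additive constant
#' `channel_sd + Uniform(-0.5, 0.5)` added to every block; element swaps
#' with p = 0.05 against five same-class peers), least-squares synthesis,
#' real part, clip. Produces three images, one per perturbation mode.
#'
#' @param image A [raster_image()].
#' @param set A [labeled_image_set()] supplying peers.
#' @param rng A [rand_source()].
#' @param index Index of `image` within `set`, excluded from its peer pool.
#' @param config Configuration list (`spectral.p_zero`, `spectral.p_swap`,
#'   `spectral.cqt_bins_per_octave`, `spectral.cqt_axis`,
#'   `spectral.cqt_perturb_domain`, `sub.n_peers`).
#' @return List of 3 augmented images.
#' @export
app11 <- function(image, set, rng, index = NULL, config = aug_config()) {
  stopifnot(inherits(set, "labeled_image_set"))
  label <- .resolve_label(image, set, index)
  peer_idx <- draw_peer_indices(set, rng, config[["sub.n_peers"]], label,
                                exclude = index)
  C <- n_channels(image)
  bpo <- config[["spectral.cqt_bins_per_octave"]]
  axis <- config[["spectral.cqt_axis"]]
  dom <- config[["spectral.cqt_perturb_domain"]]
  pz <- config[["spectral.p_zero"]]; ps <- config[["spectral.p_swap"]]
  one <- function(perturb) {
    from_channels(lapply(seq_len(C), function(c) {
      m <- channel(image, c)
      cqt_inverse(perturb(cqt_forward(m, bpo, axis), m, c))
    }))
  }
  list(
    one(function(s, m, c) perturb_cqt(s, "zero", rng, p_zero = pz)),
    one(function(s, m, c) perturb_cqt(s, "additive", rng,
                                      channel_sd = stats::sd(as.vector(m)),
                                      domain = dom)),
    one(function(s, m, c) {
      peers <- lapply(peer_idx, function(i)
        cqt_forward(channel(set$images[[i]], c), bpo, axis))
      perturb_cqt(s, "swap", rng, peers = peers, p_swap = ps)
    })
  )
}
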