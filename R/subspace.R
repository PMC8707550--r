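# Subspace-coefficient augmentation (App4-App5): project a channel into a
# PCA basis fit on the training set, or an orthonormal 2-D DCT basis, apply
# one of three coefficient perturbations (random zeroing, bounded uniform
# noise scaled to the coefficients' spread, element swaps with same-class
# peers), and reconstruct.

#' Fit a PCA basis on one channel of a training set
#'
#' Standard PCA of the vectorized channel data, mean-centered, via singular
#' value decomposition. All components with eigenvalue above `1e-10` times
#' the leading eigenvalue are retained, which gives near-lossless
#' reconstruction of the training images. The sign of each component is
#' fixed so its largest-magnitude entry is positive, making the basis
#' invariant to the order of the training images.
#'
#' @param training A [labeled_image_set()] (at least two images, equal sizes).
#' @param channel Channel index.
#' @return A `subspace_basis` with fields `mean` (length `H*W`),
#'   `components` (`H*W x n_components`, orthonormal columns),
#'   `n_components`, `shape`.
#' @export
fit_pca <- function(training, channel = 1) {
  stopifnot(inherits(training, "labeled_image_set"))
  if (length(training$images) < 2) stop("PCA needs at least 2 training images")
  shapes <- vapply(training$images, function(im) dim(im)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("PCA training images must all share one size")
  X <- vapply(training$images, function(im) as.vector(channel(im, channel)),
              numeric(prod(shapes[, 1])))      # H*W x n
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc)
  ev <- sv$d^2
  keep <- which(ev > 1e-10 * max(ev[1], .Machine$double.eps))
  comp <- sv$u[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude entry of each component positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = mu, components = comp, n_components = ncol(comp),
                 shape = shapes[, 1]),
            class = "subspace_basis")
}

# Fit one basis per channel of the set.
fit_pca_bases <- function(training) {
  lapply(seq_len(n_channels(training$images[[1]])),
         function(c) fit_pca(training, c))
}

#' Project a channel into a PCA basis and reconstruct from scores
#'
#' @param basis A `subspace_basis` from [fit_pca()].
#' @param m Numeric `H x W` channel matrix matching the basis shape.
#' @param v Numeric score vector of length `basis$n_components`.
#' @return `pca_project()`: the score vector; `pca_reconstruct()`: the
#'   reconstructed channel matrix.
#' @export
pca_project <- function(basis, m) {
  as.vector(crossprod(basis$components, as.vector(m) - basis$mean))
}

#' @rdname pca_project
#' @export
pca_reconstruct <- function(basis, v) {
  matrix(basis$mean + as.vector(basis$components %*% v),
         basis$shape[1], basis$shape[2])
}

# --- orthonormal type-II DCT ---------------------------------------------

dct_matrix <- function(n) {
  k <- seq_len(n) - 1
  D <- sqrt(2 / n) * cos(outer(k, k + 0.5) * pi / n)
  D[1, ] <- sqrt(1 / n)
  D
}

#' Orthonormal 2-D discrete cosine transform and its inverse
#'
#' Type-II DCT applied separably via orthonormal basis matrices; `dct2()`
#' followed by `idct2()` is an exact round trip. The `(1, 1)` entry of the
#' coefficient matrix is the DC coefficient, proportional to the channel
#' mean.
#'
#' @param m Numeric matrix (spatial domain).
#' @param cm Numeric matrix of DCT coefficients.
#' @return The coefficient matrix (`dct2`) or the reconstructed spatial
#'   matrix (`idct2`).
#' @export
dct2 <- function(m) dct_matrix(nrow(m)) %*% m %*% t(dct_matrix(ncol(m)))

#' @rdname dct2
#' @export
idct2 <- function(cm) t(dct_matrix(nrow(cm))) %*% cm %*% dct_matrix(ncol(cm))

# --- the three coefficient perturbations ---------------------------------

#' Coefficient perturbation operators
#'
#' The three perturbations shared by the PCA and DCT augmenters, operating on
#' a numeric coefficient vector. An optional `dc` index marks a protected
#' element (the DCT zero-frequency coefficient) that is never modified.
#'
#' `perturb_zero()` sets each unprotected element to zero independently with
#' probability `p`. `perturb_noise()` adds independent uniform noise
#' `(u - 0.5) * a` with amplitude `a = sd(v) / 2`. `perturb_swap()` replaces
#' each unprotected element, with probability `p`, by the same-index element
#' of one of the peer vectors (peer chosen uniformly per element).
#'
#' @param v Numeric coefficient vector.
#' @param p Replacement probability in `[0, 1]`.
#' @param rng A [rand_source()].
#' @param dc Optional index of the protected (DC) element.
#' @param peers List of peer coefficient vectors, all the same length as `v`.
#' @return Perturbed coefficient vector.
#' @export
perturb_zero <- function(v, p, rng, dc = NULL) {
  stopifnot(p >= 0, p <= 1)
  hit <- rng_runif(rng, length(v)) < p
  if (!is.null(dc)) hit[dc] <- FALSE
  v[hit] <- 0
  v
}

#' @rdname perturb_zero
#' @export
perturb_noise <- function(v, rng, dc = NULL) {
  a <- stats::sd(v) / 2
  if (!is.finite(a)) a <- 0
  delta <- (rng_runif(rng, length(v)) - 0.5) * a
  if (!is.null(dc)) delta[dc] <- 0
  v + delta
}

#' @rdname perturb_zero
#' @export
perturb_swap <- function(v, peers, p, rng, dc = NULL) {
  stopifnot(p >= 0, p <= 1, length(peers) >= 1)
  if (any(vapply(peers, length, integer(1)) != length(v)))
    stop("peer coefficient vectors must match the original's length")
  hit <- rng_runif(rng, length(v)) < p
  which_peer <- rng_rint(rng, length(v), length(peers))
  if (!is.null(dc)) hit[dc] <- FALSE
  if (any(hit)) {
    P <- matrix(unlist(peers, use.names = FALSE), nrow = length(v))
    v[hit] <- P[cbind(which(hit), which_peer[hit])]
  }
  v
}

# --- App4 / App5 ----------------------------------------------------------

#' PCA-subspace augmentation (App4)
#'
#' Projects each channel onto a PCA basis fit on the training set, applies
#' one of the three coefficient perturbations, and reconstructs, producing
#' three augmented images (one per perturbation). Swap peers are five images
#' drawn from the image's own class.
#'
#' @param image A [raster_image()].
#' @param set The training [labeled_image_set()] supplying peers.
#' @param rng A [rand_source()].
#' @param bases Per-channel list of [fit_pca()] bases; fitted from `set`
#'   when `NULL`.
#' @param index Index of `image` within `set`, excluded from its peer pool.
#' @param config Configuration list (`sub.p_zero`, `sub.p_swap`,
#'   `sub.n_peers`).
#' @return List of 3 augmented images.
#' @export
app4 <- function(image, set, rng, bases = NULL, index = NULL,
                 config = aug_config()) {
  stopifnot(inherits(set, "labeled_image_set"))
  if (is.null(bases)) bases <- fit_pca_bases(set)
  stopifnot(length(bases) == n_channels(image))
  label <- .resolve_label(image, set, index)
  peer_idx <- draw_peer_indices(set, rng, config[["sub.n_peers"]], label,
                                exclude = index)
  project <- function(img, c) pca_project(bases[[c]], channel(img, c))
  back <- function(v, c) pca_reconstruct(bases[[c]], v)
  .subspace_outputs(image, set, peer_idx, rng, config, project, back,
                    dc_of = function(c) NULL)
}

#' DCT-domain augmentation (App5)
#'
#' Same three perturbations as [app4()], applied to the orthonormal 2-D DCT
#' coefficients of each channel instead of PCA scores. The DC (zero
#' frequency) coefficient is never changed by any perturbation.
#'
#' @inheritParams app4
#' @return List of 3 augmented images.
#' @export
app5 <- function(image, set, rng, index = NULL, config = aug_config()) {
  stopifnot(inherits(set, "labeled_image_set"))
  label <- .resolve_label(image, set, index)
  peer_idx <- draw_peer_indices(set, rng, config[["sub.n_peers"]], label,
                                exclude = index)
  H <- dim(image)[1]; W <- dim(image)[2]
  project <- function(img, c) as.vector(dct2(channel(img, c)))
  back <- function(v, c) idct2(matrix(v, H, W))
  .subspace_outputs(image, set, peer_idx, rng, config, project, back,
                    dc_of = function(c) 1L)  # (0,0) coefficient
}

# Label of the image: by index if given, else by pixel-identical match.
.resolve_label <- function(image, set, index) {
  if (!is.null(index)) return(set$labels[[index]])
  for (i in seq_along(set$images))
    if (identical(dim(set$images[[i]]), dim(image)) &&
        isTRUE(all.equal(as.vector(set$images[[i]]), as.vector(image),
                         tolerance = 0)))
      return(set$labels[[i]])
  stop("image not found in set; pass `index` or include the image in `set`")
}

# Shared App4/App5 core: three outputs, one per perturbation operator,
# channels perturbed independently.
.subspace_outputs <- function(image, set, peer_idx, rng, config,
                              project, back, dc_of) {
  C <- n_channels(image)
  pz <- config[["sub.p_zero"]]; ps <- config[["sub.p_swap"]]
  one <- function(perturb) {
    from_channels(lapply(seq_len(C), function(c) {
      v <- project(image, c)
      back(perturb(v, c), c)
    }))
  }
  out_zero <- one(function(v, c) perturb_zero(v, pz, rng, dc = dc_of(c)))
  out_noise <- one(function(v, c) perturb_noise(v, rng, dc = dc_of(c)))
  out_swap <- one(function(v, c) {
    peers <- lapply(peer_idx, function(i) project(set$images[[i]], c))
    perturb_swap(v, peers, ps, rng, dc = dc_of(c))
  })
  list(out_zero, out_noise, out_swap)
}
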