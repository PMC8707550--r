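#' Registry of the eleven augmentation methods
#'
#' One row per method: the number of artificial images generated per input
#' image, whether the method needs three color channels, and whether it draws
#' same-class peer images. The counts are the contract every `appN()`
#' function satisfies: App1..App11 produce 3, 6, 4, 3, 3, 3, 7, 2, 6, 3, 3
#' images respectively.
#'
#' @return Data frame with columns `id`, `images_per_input`, `requires_color`,
#'   `requires_peers`.
#' @export
augmentation_methods <- function() {
  data.frame(
    id = paste0("App", 1:11),
    images_per_input = c(3L, 6L, 4L, 3L, 3L, 3L, 7L, 2L, 6L, 3L, 3L),
    requires_color = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                       TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    requires_peers = c(FALSE, FALSE, FALSE, TRUE, TRUE,
                       FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

method_row <- function(id) {
  tab <- augmentation_methods()
  i <- match(id, tab$id)
  if (is.na(i)) stop("unknown augmentation method: ", id)
  tab[i, ]
}

#' Apply one augmentation method to one image
#'
#' Dispatches to the `app1()` ... `app11()` implementations. Peer-using
#' methods (App4, App5, App8, App10, App11) need `set` (and use `index` to
#' exclude the image itself from its own peer pool); App4 additionally needs
#' per-channel PCA bases fitted on the training set (fitted on the fly from
#' `set` when not supplied).
#'
#' @param image A [raster_image()].
#' @param method Method id, `"App1"` to `"App11"`.
#' @param rng A [rand_source()].
#' @param set Optional [labeled_image_set()] supplying peers.
#' @param index Index of `image` within `set`, if it is a member.
#' @param bases Optional per-channel list of [fit_pca()] bases (App4).
#' @param config Configuration list from [aug_config()].
#' @return List of augmented [raster_image()]s; length per
#'   [augmentation_methods()].
#' @export
augment_image <- function(image, method, rng, set = NULL, index = NULL,
                          bases = NULL, config = aug_config()) {
  row <- method_row(method)
  if (row$requires_color && n_channels(image) != 3)
    stop(method, " requires a 3-channel image")
  if (row$requires_peers && is.null(set))
    stop(method, " requires a labeled image set to draw peers from")
  label <- if (!is.null(index)) set$labels[[index]] else NULL
  out <- switch(method,
    App1  = app1(image, rng, config),
    App2  = app2(image, rng, config),
    App3  = app3(image, rng, config),
    App4  = app4(image, set, rng, bases = bases, index = index,
                 config = config),
    App5  = app5(image, set, rng, index = index, config = config),
    App6  = app6(image, rng, config),
    App7  = app7(image, rng, config),
    App8  = app8(image, set, rng, index = index),
    App9  = app9(image, rng, config),
    App10 = app10(image, set, rng, index = index, config = config),
    App11 = app11(image, set, rng, index = index, config = config)
  )
  stopifnot(length(out) == row$images_per_input)
  out
}
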