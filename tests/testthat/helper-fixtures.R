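# Shared small fixtures, built once per test run.

# 3 classes x 6 RGB 32x32 images: the default peer-rich color set.
fix_rgb <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_fixtures(3, 6, c(32, 32), 3, seed = 101)
    val
  }
})

# 2 classes x 4 grayscale 32x32 images.
fix_gray <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_fixtures(2, 4, c(32, 32), 1, seed = 202)
    val
  }
})

# Low-contrast smooth set: values well inside (0, 1) so transform-domain
# reconstructions do not clip (used by the DC-conservation and Reinhard
# moment checks).
fix_smooth <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      base <- make_fixtures(2, 6, c(32, 32), 3, seed = 303, noise_sd = 0.01)
      imgs <- lapply(base$images, function(im)
        raster_image(0.5 + 0.12 * (unclass(im) - 0.5)))
      val <<- labeled_image_set(imgs, base$labels)
    }
    val
  }
})

expect_same_shape <- function(out, input) {
  for (o in out) expect_identical(dim(o), dim(input))
}
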