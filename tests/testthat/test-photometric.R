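test_that("contrast stretch follows the piecewise-linear 8-bit map", {
  img <- fix_rgb()$images[[1]]
  expect_equal(unclass(contrast_stretch(img, 0, 255)), unclass(img),
               tolerance = 1e-12)
  px <- raster_image(array(c(50, 150, 250) / 255, c(1, 3, 1)))
  out <- contrast_stretch(px, 100, 200)
  expect_equal(as.vector(out), c(0, 127.5 / 255, 1), tolerance = 1e-12)
  expect_error(contrast_stretch(img, 200, 100), "a < b")
  # monotone non-decreasing in input intensity
  v <- raster_image(array(seq(0, 1, length.out = 64), c(1, 64, 1)))
  sv <- as.vector(contrast_stretch(v, 30, 220))
  expect_true(all(diff(sv) >= 0))
})

test_that("sharpening fixes constants and overshoots at edges", {
  flat <- raster_image(array(0.37, c(8, 8, 3)))
  expect_equal(unclass(sharpen_subtract(flat)), unclass(flat),
               tolerance = 1e-12)
  # 1-D step edge 0.3 -> 0.7: unsharp masking overshoots both sides
  step <- raster_image(array(rep(c(0.3, 0.7), each = 4), c(1, 8, 1)))
  out <- sharpen_subtract(step)
  expect_identical(dim(out), dim(step))
  expect_gt(max(out), 0.7)
  expect_lt(min(out), 0.3)
  # literal variant: bare difference is a near-zero edge image
  lit <- sharpen_subtract(flat, literal = TRUE)
  expect_lt(max(lit), 1e-10)
})

test_that("color shift adds per-channel constants with clipping", {
  gray <- raster_image(array(0.5, c(4, 4, 3)))
  out <- color_shift(gray, c(51, 0, 0))
  expect_equal(out[1, 1, 1], 0.5 + 51 / 255, tolerance = 1e-12)
  expect_equal(out[1, 1, 2], 0.5, tolerance = 1e-12)
  expect_identical(color_shift(gray, c(0, 0, 0)), gray)
  hot <- raster_image(array(250 / 255, c(2, 2, 3)))
  expect_equal(max(color_shift(hot, c(20, 20, 20))), 1, tolerance = 1e-12)
  g1 <- fix_gray()$images[[1]]
  expect_error(color_shift(g1, c(1, 2, 3)), "3-channel")
})

test_that("App6 emits three images of unchanged shape, deterministically", {
  img <- fix_rgb()$images[[1]]
  out <- app6(img, rand_source(1))
  expect_length(out, 3)
  expect_same_shape(out, img)
  expect_identical(app6(img, rand_source(2)), app6(img, rand_source(2)))
  expect_error(app6(fix_gray()$images[[1]], rand_source(1)), "3-channel")
})

test_that("HSV jitter has the stated identities and ranges", {
  img <- fix_rgb()$images[[2]]
  for (attr in c("saturation", "brightness")) {
    out <- jitter_hsv(img, attr, offset = 0)
    expect_lt(max(abs(unclass(out) - unclass(img))), 1e-6)
  }
  out <- jitter_hsv(img, "contrast", offset = 1)
  expect_lt(max(abs(unclass(out) - unclass(img))), 1e-6)
  # hue jitter leaves pure gray unchanged (hue undefined at S = 0)
  gray <- raster_image(array(0.5, c(4, 4, 3)))
  out <- jitter_hsv(gray, "hue", rand_source(1))
  expect_lt(max(abs(unclass(out) - 0.5)), 1e-12)
  # drawn hue offsets stay inside [0.05, 0.15]
  rng <- rand_source(2)
  cfg <- aug_config()
  hr <- cfg[["photo.jitter.hue"]]
  draws <- rng_runif(rng, 10000, hr[1], hr[2])
  expect_gte(min(draws), 0.05); expect_lte(max(draws), 0.15)
})

test_that("App7 emits seven images; its blur stays inside the input range", {
  img <- fix_rgb()$images[[3]]
  out <- app7(img, rand_source(3))
  expect_length(out, 7)
  expect_same_shape(out, img)
  blur <- out[[5]]
  expect_gte(min(blur), min(img) - 1e-12)
  expect_lte(max(blur), max(img) + 1e-12)
  expect_identical(app7(img, rand_source(4)), app7(img, rand_source(4)))
})

test_that("histogram specification matches CDFs monotonically", {
  src <- fix_rgb()$images[[1]]
  # self-target is the identity up to quantization
  out <- histogram_specification(src, src)
  expect_lte(max(abs(unclass(out) - unclass(src))), 1 / 255)
  # constant target collapses every pixel to the target value
  tgt <- raster_image(array(0.4, c(8, 8, 3)))
  out2 <- histogram_specification(src, tgt)
  expect_lte(max(abs(unclass(out2) - 0.4)), 1 / 255 + 1e-12)
  # rank order within each channel is preserved (monotone map)
  other <- fix_rgb()$images[[10]]
  out3 <- histogram_specification(src, other)
  for (c in 1:3) {
    s <- as.vector(channel(src, c)); o <- as.vector(channel(out3, c))
    ord <- order(s)
    expect_true(all(diff(o[ord]) >= -1e-12))
  }
  # the map depends only on values, not pixel positions
  perm <- c(seq(2, 32 * 32, by = 2), seq(1, 32 * 32, by = 2))
  src_p <- raster_image(array(apply(unclass(src), 3, function(m)
    matrix(as.vector(m)[perm], 32, 32)), dim = dim(src)))
  out_p <- histogram_specification(src_p, other)
  for (c in 1:3)
    expect_identical(as.vector(channel(out_p, c)),
                     as.vector(channel(out3, c))[perm])
})

test_that("Reinhard transfer matches target moments in log-opponent space", {
  src <- fix_smooth()$images[[1]]
  tgt <- fix_smooth()$images[[8]]
  expect_lt(max(abs(unclass(reinhard_transfer(src, src)) - unclass(src))),
            1e-4)
  out <- reinhard_transfer(src, tgt)
  # result stays inside (0,1): clipping did not bite, so lab moments of the
  # output must equal the target's
  expect_gt(min(out), 0); expect_lt(max(out), 1)
  lo <- augforge:::rgb_to_lab(out); lt <- augforge:::rgb_to_lab(tgt)
  for (c in 1:3) {
    expect_equal(mean(lo[c, ]), mean(lt[c, ]), tolerance = 1e-4)
    expect_equal(sd(lo[c, ]), sd(lt[c, ]), tolerance = 1e-4)
  }
  expect_error(reinhard_transfer(fix_gray()$images[[1]],
                                 fix_gray()$images[[2]]), "3-channel")
})

test_that("lab color conversion round trips mid-range pixels", {
  img <- fix_smooth()$images[[2]]
  lab <- augforge:::rgb_to_lab(img)
  back <- augforge:::lab_to_rgb_image(lab, dim(img))
  expect_lt(max(abs(unclass(back) - unclass(img))), 1e-6)
})

test_that("App8 draws one same-class target and emits two images", {
  set <- fix_rgb()
  out <- app8(set$images[[1]], set, rand_source(5), index = 1)
  expect_length(out, 2)
  expect_same_shape(out, set$images[[1]])
  expect_identical(app8(set$images[[1]], set, rand_source(6), index = 1),
                   app8(set$images[[1]], set, rand_source(6), index = 1))
  # a class with a single member has no valid target
  lone <- labeled_image_set(set$images[1:3],
                            c("solo", "other", "other"))
  expect_error(app8(lone$images[[1]], lone, rand_source(1), index = 1),
               "no other member")
})
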