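test_that("single-level db1 analysis matches the 2x2 Haar block oracle", {
  m <- matrix(c(1, 3, 2, 4, 5, 7, 6, 8, 9, 11, 10, 12, 13, 15, 14, 16), 4, 4)
  w <- dwt_forward(m)
  # explicit 2x2-block oracle: for block [[a,b],[c,d]] (rows y, cols x)
  blocks <- list(m[1:2, 1:2], m[3:4, 1:2], m[1:2, 3:4], m[3:4, 3:4])
  oracle <- function(f) matrix(vapply(blocks, f, numeric(1)), 2, 2)
  expect_equal(w$cA, oracle(function(b) sum(b) / 2), tolerance = 1e-12)
  # cH: difference along columns (horizontal detail), cV along rows
  expect_equal(w$cH, oracle(function(b) (b[1,1]+b[2,1]-b[1,2]-b[2,2]) / 2),
               tolerance = 1e-12)
  expect_equal(w$cV, oracle(function(b) (b[1,1]-b[2,1]+b[1,2]-b[2,2]) / 2),
               tolerance = 1e-12)
  expect_equal(w$cD, oracle(function(b) (b[1,1]-b[2,1]-b[1,2]+b[2,2]) / 2),
               tolerance = 1e-12)
})

test_that("db1 subband geometry is ceiling(n/2), 227 -> 114", {
  w <- dwt_forward(matrix(runif(227 * 227), 227, 227))
  for (b in c("cA", "cH", "cV", "cD"))
    expect_identical(dim(w[[b]]), c(114L, 114L))
  w2 <- dwt_forward(matrix(runif(15 * 8), 15, 8))
  expect_identical(dim(w2$cA), c(8L, 4L))
})

test_that("db1 analysis/synthesis is a perfect-reconstruction pair", {
  set.seed(1)
  for (d in list(c(31, 45), c(32, 32), c(227, 113))) {
    m <- matrix(runif(prod(d)), d[1], d[2])
    expect_lt(max(abs(dwt_inverse(dwt_forward(m)) - m)), 1e-10)
  }
  # constant channel: details vanish, approximation is constant
  w <- dwt_forward(matrix(0.5, 16, 16))
  expect_lt(max(abs(w$cH)), 1e-12)
  expect_lt(max(abs(w$cV)), 1e-12)
  expect_lt(max(abs(w$cD)), 1e-12)
  expect_lt(max(abs(w$cA - 1)), 1e-12)  # 0.5 * 2 (two sqrt(2) gains)
  # all-zero coefficients -> all-zero channel; synthesis is linear
  w0 <- dwt_forward(matrix(runif(100), 10, 10))
  wz <- w0; for (b in c("cA", "cH", "cV", "cD")) wz[[b]] <- wz[[b]] * 0
  expect_true(all(dwt_inverse(wz) == 0))
  wa <- w0; for (b in c("cA", "cH", "cV", "cD")) wa[[b]] <- wa[[b]] * 2.5
  expect_equal(dwt_inverse(wa), 2.5 * dwt_inverse(w0), tolerance = 1e-12)
})

test_that("wavelet perturbations follow their contracts", {
  w <- dwt_forward(matrix(runif(227 * 227), 227, 227))
  # zero mode at the binomial rate; never increases subband energy
  wz <- perturb_wavelet(w, "zero", rand_source(1))
  frac <- mean(unlist(lapply(c("cA", "cH", "cV", "cD"),
                             function(b) wz[[b]] == 0)))
  expect_lt(abs(frac - 0.5), 0.02)
  for (b in c("cA", "cH", "cV", "cD"))
    expect_lte(sum(wz[[b]]^2), sum(w[[b]]^2))
  # forced p = 0 is the identity
  expect_identical(perturb_wavelet(w, "zero", rand_source(2), p_zero = 0), w)
  # additive: one shared constant; for a zero-spread channel |c| <= 0.5
  wa <- perturb_wavelet(w, "additive", rand_source(3), channel_sd = 0)
  consts <- unique(round(as.vector(wa$cA - w$cA), 12))
  expect_length(consts, 1)
  expect_lte(abs(consts), 0.5)
  # swap closure: with p = 1 every element comes from some peer
  peers <- lapply(1:5, function(k) {
    p <- w; for (b in c("cA", "cH", "cV", "cD")) p[[b]][] <- k; p
  })
  ws <- perturb_wavelet(w, "swap", rand_source(4), peers = peers, p_swap = 1)
  expect_true(all(ws$cD %in% 1:5))
  ws2 <- perturb_wavelet(w, "swap", rand_source(5), peers = peers,
                         p_swap = 0.05)
  frac <- mean(ws2$cA != w$cA)
  expect_lt(abs(frac - 0.05), 0.01)
  bad <- list(dwt_forward(matrix(0, 10, 10)))
  expect_error(perturb_wavelet(w, "swap", rand_source(6), peers = bad),
               "shape")
})

test_that("wavelet augmentation emits three images, identity when disabled", {
  set <- fix_rgb()
  out <- app10(set$images[[1]], set, rand_source(1), index = 1)
  expect_length(out, 3)
  expect_same_shape(out, set$images[[1]])
  expect_identical(app10(set$images[[1]], set, rand_source(2), index = 1),
                   app10(set$images[[1]], set, rand_source(2), index = 1))
  cfg <- aug_config("spectral.p_zero" = 0, "spectral.p_swap" = 0)
  out0 <- app10(set$images[[2]], set, rand_source(3), index = 2,
                config = cfg)
  expect_lt(max(abs(unclass(out0[[1]]) - unclass(set$images[[2]]))), 1e-6)
  expect_lt(max(abs(unclass(out0[[3]]) - unclass(set$images[[2]]))), 1e-6)
})

test_that("constant-Q analysis yields one block per column and inverts", {
  ch <- matrix(runif(64 * 64), 64, 64)
  s <- cqt_forward(ch)
  expect_length(s$blocks, 64)
  expect_identical(dim(s$blocks[[1]]), c(s$plan$n_bins, s$plan$n_frames))
  rel <- sqrt(sum((cqt_inverse(s) - ch)^2)) / sqrt(sum(ch^2))
  expect_lt(rel, 1e-6)
  # zero channel -> zero coefficients -> zero reconstruction
  z <- cqt_forward(matrix(0, 32, 20))
  expect_true(all(vapply(z$blocks, function(b) all(b == 0), logical(1))))
  expect_true(all(cqt_inverse(z) == 0))
  # linearity of the synthesis
  s2 <- s; s2$blocks <- lapply(s$blocks, function(b) 2 * b)
  expect_equal(cqt_inverse(s2), 2 * cqt_inverse(s), tolerance = 1e-9)
  # columns shorter than the minimum support are refused, naming the bound
  expect_error(cqt_forward(matrix(0, 8, 8)), "16")
})

test_that("constant-Q geometry derives from column length, not a constant", {
  s32 <- cqt_forward(matrix(runif(32 * 10), 32, 10))
  s64 <- cqt_forward(matrix(runif(64 * 10), 64, 10))
  expect_gt(s64$plan$n_bins, s32$plan$n_bins)
  # rows-axis option transposes the role of rows and columns
  ch <- matrix(runif(40 * 64), 40, 64)
  sr <- cqt_forward(ch, axis = "rows")
  expect_length(sr$blocks, 40)
  expect_lt(max(abs(cqt_inverse(sr) - ch)), 1e-8)
})

test_that("constant-Q augmentation emits three images with exact plumbing", {
  set <- fix_rgb()
  out <- app11(set$images[[1]], set, rand_source(1), index = 1)
  expect_length(out, 3)
  expect_same_shape(out, set$images[[1]])
  expect_identical(app11(set$images[[4]], set, rand_source(7), index = 4),
                   app11(set$images[[4]], set, rand_source(7), index = 4))
  cfg <- aug_config("spectral.p_zero" = 0, "spectral.p_swap" = 0)
  out0 <- app11(set$images[[2]], set, rand_source(3), index = 2,
                config = cfg)
  expect_lt(max(abs(unclass(out0[[1]]) - unclass(set$images[[2]]))), 1e-4)
  expect_lt(max(abs(unclass(out0[[3]]) - unclass(set$images[[2]]))), 1e-4)
})
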