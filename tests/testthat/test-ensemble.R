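test_that("training-set assembly follows the size formula with labels kept", {
  base <- make_fixtures(2, 3, c(16, 16), 3, seed = 41)   # 6 images
  for (m in c("App1", "App7")) {
    aug <- build_training_set(base, m, rand_source(1))
    per <- augmentation_methods()$images_per_input[
      augmentation_methods()$id == m]
    expect_length(aug$images, 6 * (1 + per))
    # originals first, unchanged, then augmented blocks per source image
    expect_identical(aug$images[1:6], base$images)
    expect_identical(aug$labels[1:6], base$labels)
    expect_identical(aug$labels[-(1:6)],
                     rep(base$labels, each = per))
  }
  # 10-image base under the seven-image method: 80 items
  base10 <- make_fixtures(2, 5, c(16, 16), 3, seed = 42)
  expect_length(build_training_set(base10, "App7", rand_source(2))$images,
                80)
})

test_that("color methods refuse grayscale sets; applicability reflects it", {
  gray <- fix_gray()
  expect_error(build_training_set(gray, "App6", rand_source(1)),
               "grayscale")
  expect_identical(applicable_methods(fix_rgb()), paste0("App", 1:11))
  expect_identical(applicable_methods(gray),
                   paste0("App", c(1:5, 9:11)))
})

test_that("named ensemble configurations resolve to the right members", {
  rgb <- fix_rgb(); gray <- fix_gray()
  expect_identical(ensemble_spec("ensda_all", rgb)$members,
                   paste0("App", 1:11))
  expect_identical(ensemble_spec("ensda_all", gray)$members,
                   paste0("App", c(1:5, 9:11)))
  expect_identical(ensemble_spec("ensda_5", rgb)$members, paste0("App", 1:5))
  expect_identical(ensemble_spec("ensbase", rgb)$members, rep("App3", 11))
  expect_identical(ensemble_spec("ensbase_5", rgb)$members, rep("App3", 5))
  expect_true(is.na(ensemble_spec("noda", rgb)$members))
})

test_that("the tiny backbone separates distinct texture classes", {
  train <- make_fixtures(2, 10, c(32, 32), 1, seed = 51)
  test <- make_fixtures(2, 8, c(32, 32), 1, seed = 52)
  fit <- train_member(train, test, train_config(), rand_source(1))
  expect_identical(dim(fit$scores), c(16L, 2L))
  expect_lt(max(abs(rowSums(fit$scores) - 1)), 1e-6)
  acc <- mean(predict_labels(fit$scores) == test$labels)
  expect_gt(acc, 0.9)
  # fixed seed reproduces the score matrix bit for bit
  fit2 <- train_member(train, test, train_config(), rand_source(1))
  expect_identical(fit$scores, fit2$scores)
  # a test class missing from training is refused
  test_bad <- labeled_image_set(test$images, rep("classXX", 16))
  expect_error(train_member(train, test_bad, train_config(),
                            rand_source(1)), "absent")
  expect_error(train_member(train, test, train_config("reference"),
                            rand_source(1)), "tiny")
})

test_that("sum-rule fusion sums scores, breaks ties low, ignores order", {
  mk <- function(m) {
    dimnames(m) <- list(sprintf("s%04d", seq_len(nrow(m))), c("a", "b"))
    class(m) <- c("score_matrix", class(m))
    m
  }
  s1 <- mk(matrix(c(0.6, 0.4), 1)); s2 <- mk(matrix(c(0.3, 0.7), 1))
  fused <- sum_rule_fusion(list(s1, s2))
  expect_equal(as.vector(fused), c(0.9, 1.1), tolerance = 1e-12)
  expect_identical(predict_labels(fused), "b")
  expect_identical(predict_labels(sum_rule_fusion(list(s1))), "a")
  # exact tie goes to the lowest class index
  tie <- mk(matrix(c(0.5, 0.5), 1))
  expect_identical(predict_labels(tie), "a")
  # permutation invariance and positive homogeneity
  many <- list(s1, s2, mk(matrix(c(0.2, 0.1), 1)))
  f1 <- sum_rule_fusion(many); f2 <- sum_rule_fusion(rev(many))
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-12)
  scaled <- sum_rule_fusion(lapply(many, function(m) mk(unclass(m) * 3)))
  expect_identical(predict_labels(scaled), predict_labels(f1))
  # misaligned members are refused
  s3 <- matrix(c(0.1, 0.9), 1)
  dimnames(s3) <- list("s9999", c("a", "b"))
  class(s3) <- c("score_matrix", class(s3))
  expect_error(sum_rule_fusion(list(s1, s3)), "share")
})

test_that("ensemble evaluation reports members and fused accuracy", {
  train <- make_fixtures(3, 4, c(32, 32), 1, seed = 61)
  test <- make_fixtures(3, 4, c(32, 32), 1, seed = 62)
  cfg <- train_config(epochs = 100, hidden = 8)
  spec <- ensemble_spec("ensbase_5", train)
  res <- evaluate_ensemble(spec, train, test, cfg, rand_source(3))
  expect_named(res, c("fused_accuracy", "member_accuracies",
                      "fused_scores", "report"))
  expect_identical(nrow(res$report), 6L)       # 5 members + fused
  expect_identical(res$report$member[6], "fused")
  expect_true(all(res$report$accuracy >= 0 & res$report$accuracy <= 1))
  expect_identical(res$fused_accuracy, res$report$accuracy[6])
  # NoDA baseline: a single unaugmented member
  noda <- evaluate_ensemble(ensemble_spec("noda", train), train, test, cfg,
                            rand_source(3))
  expect_identical(nrow(noda$report), 2L)
  expect_identical(noda$report$member[1], "NoDA")
})

test_that("fusing a random member with a perfect member keeps sanity", {
  # perfect member: one-hot on the truth; random member: seeded noise scores
  labels <- rep(c("a", "b"), each = 10)
  perfect <- nnet::class.ind(factor(labels))
  dimnames(perfect) <- list(sprintf("s%04d", 1:20), c("a", "b"))
  class(perfect) <- c("score_matrix", class(perfect))
  rng <- rand_source(77)
  noise <- matrix(rng_runif(rng, 40), 20, 2)
  noise <- noise / rowSums(noise)
  dimnames(noise) <- dimnames(perfect)
  class(noise) <- c("score_matrix", class(noise))
  fused <- sum_rule_fusion(list(perfect, noise))
  expect_gte(mean(predict_labels(fused) == labels), 0.5)
  # all members perfect: fused accuracy 1
  allp <- sum_rule_fusion(list(perfect, perfect, perfect))
  expect_identical(mean(predict_labels(allp) == labels), 1)
})
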