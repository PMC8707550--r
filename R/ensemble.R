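# Ensemble harness: per-method training-set assembly, a small pluggable
# classifier backbone, sum-rule score fusion, and the named ensemble
# configurations (EnsDA_all, EnsDA_5, EnsBase, EnsBase_5, NoDA baseline).

#' Assemble the augmented training set for one method
#'
#' Runs one augmentation method over every image in the base set and returns
#' the originals plus all generated images, labels preserved, so the output
#' size is `|base| * (1 + images_per_input)` (a 1000-image base under App1
#' becomes 4000 images). Each image gets its own forked random sub-stream,
#' so processing order cannot change results.
#'
#' @param base The base training [labeled_image_set()].
#' @param method Method id, `"App1"` to `"App11"`.
#' @param rng A [rand_source()].
#' @param config Configuration list ([aug_config()]).
#' @return A [labeled_image_set()] with originals followed by augmented
#'   images.
#' @export
build_training_set <- function(base, method, rng, config = aug_config()) {
  stopifnot(inherits(base, "labeled_image_set"))
  row <- method_row(method)
  if (row$requires_color && n_channels(base$images[[1]]) != 3)
    stop(method, " requires color images; the set is grayscale")
  bases <- if (method == "App4") fit_pca_bases(base) else NULL
  aug_images <- list(); aug_labels <- character(0)
  for (i in seq_along(base$images)) {
    sub <- rng_fork(rng)
    out <- augment_image(base$images[[i]], method, sub, set = base,
                         index = i, bases = bases, config = config)
    aug_images <- c(aug_images, out)
    aug_labels <- c(aug_labels, rep(base$labels[i], length(out)))
  }
  labeled_image_set(c(base$images, aug_images), c(base$labels, aug_labels))
}

#' Methods applicable to an image set
#'
#' All eleven methods for 3-channel sets; for grayscale sets the three
#' color-based methods (App6, App7, App8) are excluded, mirroring how
#' color augmentation is dropped for gray-level benchmarks.
#'
#' @param set A [labeled_image_set()].
#' @return Character vector of method ids in App1..App11 order.
#' @export
applicable_methods <- function(set) {
  tab <- augmentation_methods()
  if (n_channels(set$images[[1]]) == 3) tab$id
  else tab$id[!tab$requires_color]
}

#' Named ensemble configuration
#'
#' `ensda_all`: one member per applicable method (all eleven; the color
#' methods drop out on grayscale sets). `ensda_5`: App1..App5. `ensbase` /
#' `ensbase_5`: eleven / five members all trained on App3, the
#' same-method control. `noda`: a single member with no augmentation.
#'
#' @param name One of `"ensda_all"`, `"ensda_5"`, `"ensbase"`,
#'   `"ensbase_5"`, `"noda"`.
#' @param set The training set (decides method applicability).
#' @return An `ensemble_spec` with fields `name` and `members` (character
#'   vector of method ids; `NA` denotes an unaugmented member).
#' @export
ensemble_spec <- function(name = c("ensda_all", "ensda_5", "ensbase",
                                   "ensbase_5", "noda"), set) {
  name <- match.arg(name)
  members <- switch(name,
    ensda_all = applicable_methods(set),
    ensda_5   = paste0("App", 1:5),
    ensbase   = rep("App3", 11),
    ensbase_5 = rep("App3", 5),
    noda      = NA_character_
  )
  structure(list(name = name, members = members), class = "ensemble_spec")
}

# --- backbone -------------------------------------------------------------

# Texture features of one image: block-averaged log magnitude spectrum
# (translation/phase invariant, separates oriented frequency content) plus
# block-averaged intensities, per channel, each pooled to grid x grid.
.pool_features <- function(image, grid = 8) {
  d <- dim(image)
  ri <- pmin(floor((seq_len(d[1]) - 1) * grid / d[1]) + 1, grid)
  ci <- pmin(floor((seq_len(d[2]) - 1) * grid / d[2]) + 1, grid)
  cnt <- tcrossprod(tabulate(ri, grid), tabulate(ci, grid))
  pool <- function(m) as.vector(t(rowsum(t(rowsum(m, ri)), ci)) / cnt)
  unlist(lapply(seq_len(d[3]), function(c) {
    m <- channel(image, c)
    c(pool(m), pool(log1p(Mod(stats::fft(m)))))
  }), use.names = FALSE)
}

feature_matrix <- function(set, grid = 8) {
  t(vapply(set$images, .pool_features, grid = grid,
           numeric(2 * grid * grid * n_channels(set$images[[1]]))))
}

#' Training configuration for ensemble members
#'
#' @param backbone `"tiny"` — a single-hidden-layer softmax network on
#'   block-averaged pixel features, the test-scale stand-in for a deep
#'   backbone. `"reference"` (an ImageNet-pretrained deep network) is
#'   accepted by the interface but not provided by this package.
#' @param batch_size,learning_rate Optimizer settings (defaults 30 and
#'   0.001, the finetuning defaults of the reference pipeline; the tiny
#'   backbone's BFGS fit uses `epochs` as its iteration cap).
#' @param epochs Training iterations.
#' @param hidden Hidden units of the tiny backbone.
#' @param feature_grid Pooling grid side for the tiny backbone's features.
#' @return A `train_config` list.
#' @export
train_config <- function(backbone = c("tiny", "reference"), batch_size = 30,
                         learning_rate = 0.001, epochs = 200, hidden = 12,
                         feature_grid = 8) {
  backbone <- match.arg(backbone)
  structure(list(backbone = backbone, batch_size = batch_size,
                 learning_rate = learning_rate, epochs = epochs,
                 hidden = hidden, feature_grid = feature_grid),
            class = "train_config")
}

#' Train one ensemble member and score a test set
#'
#' Fits the configured backbone on the training set and returns the model
#' handle plus a score matrix of per-test-sample softmax class scores (rows
#' sum to 1). Deterministic for a fixed random source.
#'
#' @param trainset,testset [labeled_image_set()]s sharing a class set.
#' @param cfg A [train_config()].
#' @param rng A [rand_source()].
#' @return List with `model` and `scores` (an `n_test x n_classes` matrix,
#'   class `score_matrix`, with sample ids as row names and class order as
#'   column names).
#' @export
train_member <- function(trainset, testset, cfg = train_config(), rng) {
  stopifnot(inherits(trainset, "labeled_image_set"),
            inherits(testset, "labeled_image_set"))
  extra <- setdiff(testset$classes, trainset$classes)
  if (length(extra))
    stop("test classes absent from training set: ",
         paste(extra, collapse = ", "))
  if (cfg$backbone == "reference")
    stop("the reference deep backbone is not bundled with this package; ",
         "use backbone = \"tiny\"")
  Xtr <- feature_matrix(trainset, cfg$feature_grid)
  Xte <- feature_matrix(testset, cfg$feature_grid)
  mu <- colMeans(Xtr); sdev <- pmax(apply(Xtr, 2, stats::sd), 1e-8)
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdev, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdev, "/")
  classes <- trainset$classes
  Y <- nnet::class.ind(factor(trainset$labels, levels = classes))
  fit <- with_rng(rng, nnet::nnet(
    Xtr, Y, size = cfg$hidden, softmax = TRUE, maxit = cfg$epochs,
    decay = 1e-3, MaxNWts = 100000, trace = FALSE))
  scores <- predict(fit, Xte, type = "raw")
  if (length(classes) == 1) scores <- matrix(1, nrow(Xte), 1)
  dimnames(scores) <- list(sprintf("s%04d", seq_len(nrow(Xte))), classes)
  class(scores) <- c("score_matrix", class(scores))
  list(model = fit, scores = scores)
}

# --- fusion and evaluation ------------------------------------------------

#' Sum-rule fusion of classifier score matrices
#'
#' Elementwise sum of the members' per-class scores. All members must share
#' sample ids and class order. Fusion is invariant to member order and to
#' scaling all members by a positive constant.
#'
#' @param members List of `score_matrix` objects.
#' @return Fused `score_matrix`.
#' @export
sum_rule_fusion <- function(members) {
  stopifnot(is.list(members), length(members) >= 1)
  ref <- members[[1]]
  for (m in members[-1]) {
    if (!identical(dimnames(m), dimnames(ref)))
      stop("score matrices to fuse must share sample ids and class order")
  }
  fused <- Reduce(`+`, lapply(members, unclass))
  class(fused) <- c("score_matrix", class(fused))
  fused
}

#' Predicted labels from a score matrix
#'
#' Row-wise argmax; ties break toward the lowest class index.
#'
#' @param scores A `score_matrix`.
#' @return Character vector of predicted class labels.
#' @export
predict_labels <- function(scores) {
  colnames(scores)[max.col(unclass(scores), ties.method = "first")]
}

score_accuracy <- function(scores, truth) {
  mean(predict_labels(scores) == truth)
}

#' Evaluate an ensemble configuration
#'
#' For each member of the spec: build the member's augmented training set
#' (or use the base set unchanged for an unaugmented member), train a
#' backbone, and score the test set. Members are fused by sum rule; accuracy
#' is the fraction of test samples whose fused argmax equals the true label.
#'
#' @param spec An [ensemble_spec()].
#' @param base_train Base training [labeled_image_set()].
#' @param test Test [labeled_image_set()].
#' @param cfg A [train_config()].
#' @param rng A [rand_source()].
#' @param config Augmentation configuration ([aug_config()]).
#' @return List with `fused_accuracy`, `member_accuracies`, `fused_scores`,
#'   and a `report` data frame (one row per member plus one fused row).
#' @export
evaluate_ensemble <- function(spec, base_train, test, cfg = train_config(),
                              rng, config = aug_config()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (length(test$images) == 0) stop("test set is empty")
  members <- spec$members
  scores <- vector("list", length(members))
  accs <- numeric(length(members))
  for (k in seq_along(members)) {
    sub <- rng_fork(rng)
    trainset <- if (is.na(members[k])) base_train
                else build_training_set(base_train, members[k], sub, config)
    fit <- train_member(trainset, test, cfg, sub)
    scores[[k]] <- fit$scores
    accs[k] <- score_accuracy(fit$scores, test$labels)
  }
  fused <- sum_rule_fusion(scores)
  fused_acc <- score_accuracy(fused, test$labels)
  member_names <- ifelse(is.na(members), "NoDA", members)
  list(
    fused_accuracy = fused_acc,
    member_accuracies = stats::setNames(accs, member_names),
    fused_scores = fused,
    report = data.frame(
      member = c(member_names, "fused"),
      accuracy = c(accs, fused_acc),
      stringsAsFactors = FALSE
    )
  )
}
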