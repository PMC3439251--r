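# helper: sequences from two composition-separable synthetic classes
composition_classes <- function(n_per_class, len = 120, tilt = 2) {
  profiles <- list(
    stable = local({
      p <- rep(1, 20); names(p) <- stabnet:::AA20
      p[c("E", "D", "K", "N")] <- tilt; p / sum(p)
    }),
    unstable = local({
      p <- rep(1, 20); names(p) <- stabnet:::AA20
      p[c("W", "C", "L", "T")] <- tilt; p / sum(p)
    }))
  labels <- rep(c("stable", "unstable"), each = n_per_class)
  seqs <- vapply(labels, function(cl)
    paste(sample(stabnet:::AA20, len, replace = TRUE, prob = profiles[[cl]]),
          collapse = ""), character(1))
  names(seqs) <- sprintf("q%04d", seq_along(seqs))
  list(sequences = seqs, labels = stats::setNames(labels, names(seqs)))
}

test_that("spectrum features count residues and the kernel is order-invariant", {
  f <- spectrum_features("AAA")
  expect_equal(unname(f["A"]), 3)
  expect_equal(sum(f), 3)
  expect_equal(spectrum_kernel("AC", "CA"), 2)
  set.seed(2)
  for (i in 1:50) {
    a <- random_aa_seq(sample(1:30, 1))
    b <- random_aa_seq(sample(1:30, 1))
    expect_equal(spectrum_kernel(a, b), oracle_spectrum_kernel(a, b))
  }
})

test_that("the calibrated SVM separates composition-separable classes", {
  set.seed(5)
  train <- composition_classes(80)
  test <- composition_classes(60)
  fit <- train_calibrated_svm(train$sequences, train$labels, seed = 1)
  sc <- svm_decision_scores(fit, test$sequences)
  expect_gt(roc_auc(sc, test$labels == "stable"), 0.9)
})

test_that("label shuffling drives held-out AUC to chance", {
  aucs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    pool <- composition_classes(100)
    shuffled <- sample(pool$labels)       # null: stability unrelated to sequence
    names(shuffled) <- names(pool$labels)
    tr <- sample(length(shuffled), 120)
    fit <- train_calibrated_svm(pool$sequences[tr], shuffled[tr], seed = s)
    roc_auc(svm_decision_scores(fit, pool$sequences[-tr]),
            shuffled[-tr] == "stable")
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("no-signal degeneracy yields near-identical class Gaussians", {
  set.seed(6)
  seqs <- vapply(1:60, function(i) random_aa_seq(80), character(1))
  names(seqs) <- sprintf("r%03d", 1:60)
  seqs <- c(seqs, stats::setNames(seqs, sprintf("r%03d", 61:120)))
  labels <- stats::setNames(rep(c("stable", "unstable"), each = 60),
                            names(seqs))
  fit <- train_calibrated_svm(seqs, labels, seed = 2)
  expect_equal(fit$gaussians$stable$mean, fit$gaussians$unstable$mean,
               tolerance = 0.2)
})

test_that("a half-split without both classes is refused", {
  seqs <- c(a = "AAAA", b = "CCCC", c = "DDDD")
  labels <- c(a = "stable", b = "unstable", c = "unstable")
  expect_error(train_calibrated_svm(seqs, labels, seed = 1), "one class only")
})

test_that("the Gaussian posterior has its closed forms and complement identity", {
  model <- structure(list(
    weights = stats::setNames(rep(0, 20), stabnet:::AA20), offset = 0,
    gaussians = list(stable = list(mean = 1, var = 1),
                     unstable = list(mean = -1, var = 1)),
    priors = c(stable = 0.5, unstable = 0.5), normalize = TRUE),
    class = "calibrated_svm")
  expect_equal(svm_posterior(0, model), 0.5)
  expect_equal(svm_posterior(1, model), 1 / (1 + exp(-2)), tolerance = 1e-12)
  # monotone in the score for equal variances
  sc <- seq(-4, 4, length.out = 50)
  post <- svm_posterior(sc, model)
  expect_true(all(diff(post) > 0))
  # stable and unstable posteriors are exact complements
  model_u <- model
  model_u$gaussians <- model$gaussians[c("unstable", "stable")]
  names(model_u$gaussians) <- c("stable", "unstable")
  expect_equal(svm_posterior(sc, model) + svm_posterior(sc, model_u),
               rep(1, 50), tolerance = 1e-12)

  model_eq <- model
  model_eq$gaussians$unstable <- model$gaussians$stable
  expect_equal(svm_posterior(sc, model_eq), rep(0.5, 50))
})

test_that("the SVM-only network variant reduces to the Gaussian posterior", {
  spec <- build_model("svm")
  model <- structure(list(
    gaussians = list(stable = list(mean = 0.8, var = 0.5),
                     unstable = list(mean = -0.6, var = 1.2)),
    priors = c(stable = 0.45, unstable = 0.55)), class = "calibrated_svm")
  params <- structure(list(
    cpt = list(stability = unname(model$priors["stable"])),
    noisy_or = list(),
    gdt = list(svm_score = list(
      mean = c(model$gaussians$unstable$mean, model$gaussians$stable$mean),
      var = c(model$gaussians$unstable$var, model$gaussians$stable$var)))),
    class = "bn_params")
  sc <- seq(-3, 3, length.out = 21)
  bn_path <- infer_stability(spec, params, data.frame(svm_score = sc))
  expect_equal(bn_path, svm_posterior(sc, model), tolerance = 1e-12)
})
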