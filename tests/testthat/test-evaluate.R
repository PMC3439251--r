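test_that("AUC follows the rank formulation with tie half-credit", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)   # 3 of 4 pos-neg pairs concordant
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(1)
  for (i in 1:20) {
    sc <- round(runif(30), 1)             # force ties
    lab <- runif(30) < 0.5
    if (!any(lab) || all(lab)) next
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab), tolerance = 1e-12)
    # complement identity
    expect_equal(roc_auc(sc, lab) + roc_auc(sc, !lab), 1, tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(exp(3 * sc), lab), roc_auc(sc, lab),
                 tolerance = 1e-12)
  }
})

test_that("threshold metrics reproduce hand-computed identities", {
  m <- threshold_metrics(c(TP = 9, FP = 1, TN = 9, FN = 1))
  expect_equal(unname(m[c("precision", "recall", "F", "specificity")]),
               rep(0.9, 4))
  expect_equal(unname(m["MCC"]), 0.8)     # (81-1)/sqrt(10^4)

  perfect <- threshold_metrics(c(TP = 5, FP = 0, TN = 7, FN = 0))
  expect_equal(unname(perfect["F"]), 1)
  expect_equal(unname(perfect["MCC"]), 1)

  # F is the harmonic mean of precision and recall
  set.seed(3)
  for (i in 1:20) {
    cts <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
             TN = sample(0:20, 1), FN = sample(0:20, 1))
    m <- threshold_metrics(cts)
    if (m["precision"] + m["recall"] > 0)
      expect_equal(unname(m["F"]),
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]), tolerance = 1e-12)
    # inverting predictions flips the MCC sign
    inv <- threshold_metrics(cts[c("FN", "TN", "FP", "TP")])
    names_inv <- threshold_metrics(c(TP = cts[["FN"]], FP = cts[["TN"]],
                                     TN = cts[["FP"]], FN = cts[["TP"]]))
    expect_equal(unname(names_inv["MCC"]), -unname(m["MCC"]),
                 tolerance = 1e-12)
  }

  flagged <- threshold_metrics(c(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_equal(unname(flagged["precision"]), 0)
  expect_true("precision" %in% attr(flagged, "zero_denominator"))
})

test_that("random predictions have MCC centred on zero", {
  set.seed(7)
  mccs <- replicate(1000, {
    lab <- runif(40) < 0.5
    pred <- runif(40) < 0.5
    threshold_metrics(c(TP = sum(pred & lab), FP = sum(pred & !lab),
                        TN = sum(!pred & !lab), FN = sum(!pred & lab)))[["MCC"]]
  })
  expect_lt(abs(mean(mccs)), 0.02)
})

test_that("the max-F threshold agrees with exhaustive search", {
  set.seed(9)
  for (i in 1:15) {
    sc <- round(runif(40), 2)
    lab <- runif(40) < 0.4
    if (!any(lab) || all(lab)) next
    got <- max_f_threshold(sc, lab)
    want <- oracle_max_f(sc, lab)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$F, want$F, tolerance = 1e-12)
  }
  # separable scores: lowest candidate attaining F = 1
  got <- max_f_threshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(got$threshold, 0.8)
  expect_equal(got$F, 1)
  # single positive with the top score
  got1 <- max_f_threshold(c(0.9, 0.5, 0.3), c(TRUE, FALSE, FALSE))
  expect_equal(got1$F, 1)
})

test_that("cross-validation is reproducible and handles leave-one-out", {
  df <- data.frame(x = c(rnorm(10, 2), rnorm(10, -2)),
                   label = rep(c("stable", "unstable"), each = 10))
  builder <- function(train) {
    m <- tapply(train$x, train$label, mean)
    function(test) ifelse(m["stable"] > m["unstable"], 1, -1) * test$x
  }
  r1 <- cross_validate(builder, df, folds = 5, repeats = 1, seed = 42)
  r2 <- cross_validate(builder, df, folds = 5, repeats = 1, seed = 42)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_gt(r1$summary$mean[r1$summary$metric == "AUC"], 0.9)

  loo <- cross_validate(builder, df[c(1:5, 11:15), ],
                        folds = 10, repeats = 1, seed = 1)
  expect_true(all(is.finite(loo$summary$mean)))
})

test_that("the nearest-neighbour baseline scores by cosine margins", {
  x <- rbind(c(1, 0, 0), c(0.9, 0.1, 0), c(0, 1, 0), c(0, 0.9, 0.2))
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  nn <- nn_baseline(x, lab)
  # identical to a positive training vector: D+ = 0, score = D- >= 0
  s <- nn_score(nn, c(1, 0, 0))
  expect_gte(s, 0)
  expect_equal(s, min(1 - x[3:4, ] %*% c(1, 0, 0) /
                        sqrt(rowSums(x[3:4, ]^2))), tolerance = 1e-12)
  # a query exactly mirror-symmetric between one positive and one negative
  # training vector scores zero
  sym <- nn_baseline(rbind(c(1, 0), c(0, 1)), c(TRUE, FALSE))
  expect_equal(nn_score(sym, c(1, 1)), 0, tolerance = 1e-12)
  expect_error(nn_score(nn, c(0, 0, 0)), "zero-norm")
  expect_error(nn_baseline(rbind(c(0, 0, 0), c(1, 0, 0)), c(TRUE, FALSE)),
               "zero-norm")

  set.seed(13)
  xtr <- matrix(runif(20 * 6, 0.1, 1), 20)
  ltr <- rep(c(TRUE, FALSE), 10)
  nn2 <- nn_baseline(xtr, ltr)
  for (i in 1:50) {
    q <- runif(6, 0.1, 1)
    d <- apply(xtr, 1, function(v)
      1 - sum(v * q) / sqrt(sum(v^2) * sum(q^2)))
    expect_equal(nn_score(nn2, q), min(d[!ltr]) - min(d[ltr]),
                 tolerance = 1e-12)
  }
})
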