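test_that("model variants have the mandated structure", {
  full <- build_model("bn_svm")
  expect_length(full$discrete, 20L)
  expect_length(full$continuous, 3L)
  expect_identical(full$parents$stability,
                   c("n_term_stab", "ptm", "domain", "disorder"))
  expect_length(full$parents$ptm, 4L)
  expect_length(full$parents$domain, 9L)
  expect_length(full$parents$disorder, 2L)
  set.seed(1)
  expect_length(random_bn_params(full)$cpt$stability, 16L)  # 2^4 configs

  bn <- build_model("bn")
  expect_false("svm_score" %in% bn$order)
  expect_length(bn$order, 22L)

  svm <- build_model("svm")
  expect_length(svm$order, 2L)
  expect_identical(svm$parents$svm_score, "stability")
})

test_that("cyclic or malformed specifications are rejected", {
  expect_error(bn_spec(c(a = "cpt", b = "cpt"),
                       list(a = "b", b = "a")), "cycle")
  expect_error(bn_spec(c(a = "cpt", g = "gaussian", b = "cpt"),
                       list(a = character(0), g = "a", b = "g")),
               "leaves")
  expect_error(build_model("nonsense"))
})

test_that("noisy-OR combines active parents independently", {
  p0 <- list(q = c(0.2, 0.5), c0 = 0)
  expect_equal(noisy_or_prob(p0, c(FALSE, FALSE)), 0)
  expect_equal(noisy_or_prob(list(q = 0.2, c0 = 0), TRUE), 0.8)
  expect_equal(noisy_or_prob(list(q = c(0.5, 0.5), c0 = 0), c(TRUE, TRUE)),
               0.75)
  expect_equal(noisy_or_prob(list(q = c(0.5, 0.5), c0 = 0.2), c(TRUE, TRUE)),
               1 - 0.8 * 0.25)
})

test_that("the joint factorizes and normalizes", {
  spec1 <- bn_spec(c(x = "cpt"), list(x = character(0)))
  p1 <- structure(list(cpt = list(x = 0.3), noisy_or = list(), gdt = list()),
                  class = "bn_params")
  expect_equal(joint_log_prob(spec1, p1, list(x = TRUE)), log(0.3))
  expect_error(joint_log_prob(spec1, p1, list()), "every discrete node")

  for (s in 1:3) {
    spec <- random_chain_spec(6, seed = s)
    set.seed(s)
    params <- random_bn_params(spec)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6), KEEP.OUT.ATTRS = FALSE)
    names(grid) <- spec$discrete
    lp <- vapply(seq_len(64), function(i)
      joint_log_prob(spec, params, as.list(grid[i, ])), numeric(1))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-9)
    # factorization equals the product of independently computed conditionals
    asn <- as.list(grid[17, ])
    manual <- 0
    for (nd in spec$discrete) {
      pst <- matrix(vapply(spec$parents[[nd]], function(x) asn[[x]],
                           logical(1)), nrow = 1)
      pr <- stabnet:::node_prob_true(spec, params, nd, pst)
      manual <- manual + log(ifelse(asn[[nd]], pr, 1 - pr))
    }
    expect_equal(joint_log_prob(spec, params, asn), manual, tolerance = 1e-12)
  }
})

test_that("a fully symmetric network is indifferent (posterior 1/2)", {
  spec <- build_model("bn")
  params <- structure(list(
    cpt = lapply(stats::setNames(nm = names(spec$kind)[spec$kind == "cpt"]),
                 function(nd) rep(0.5, 2^length(spec$parents[[nd]]))),
    noisy_or = list(ptm = list(q = rep(0.5, 4), c0 = 0.5),
                    domain = list(q = rep(0.5, 9), c0 = 0.5)),
    gdt = list(pwm_tyr = list(mean = c(0, 0), var = c(1, 1)),
               pwm_ser_thr = list(mean = c(0, 0), var = c(1, 1)))),
    class = "bn_params")
  ev <- as.data.frame(stats::setNames(rep(list(NA), 20), spec$discrete))
  expect_equal(infer_stability(spec, params, ev), 0.5, tolerance = 1e-12)
})

test_that("inference matches the enumeration oracle on random cases", {
  spec <- build_model("bn_svm")
  set.seed(99)
  for (i in 1:6) {
    params <- random_bn_params(spec)
    hidden <- c("ptm", "domain", "disorder", "stability")
    observable <- setdiff(spec$discrete, hidden)
    observed <- sample(observable, sample(10:15, 1))
    ev <- as.list(stats::setNames(rep(NA, length(spec$discrete)), spec$discrete))
    for (nd in observed) ev[[nd]] <- sample(c(TRUE, FALSE), 1)
    for (nd in spec$continuous)
      ev[[nd]] <- if (runif(1) < 0.6) rnorm(1) else NA_real_
    got <- infer_stability(spec, params, as.data.frame(ev))
    want <- oracle_infer(spec, params, ev)
    expect_lt(abs(got - want), 1e-9)
  }
})

test_that("uninformative continuous evidence leaves the posterior unchanged", {
  spec <- build_model("bn_svm")
  set.seed(12)
  params <- random_bn_params(spec)
  params$gdt$svm_score <- list(mean = c(0.4, 0.4), var = c(1.3, 1.3))
  ev <- data.frame(n_term_stab = TRUE, transmembrane = TRUE, tyr_phos = FALSE)
  with_leaf <- cbind(ev, svm_score = 2.2)
  expect_equal(infer_stability(spec, params, with_leaf),
               infer_stability(spec, params, ev), tolerance = 1e-12)
})

test_that("equal sequence-leaf Gaussians collapse the hybrid onto the plain network", {
  full <- build_model("bn_svm")
  plain <- build_model("bn")
  set.seed(77)
  params <- random_bn_params(full)
  params$gdt$svm_score <- list(mean = c(0.1, 0.1), var = c(0.9, 0.9))
  params_plain <- params
  params_plain$gdt$svm_score <- NULL
  ds <- simulate_dataset(fixture_config(n_stable = 15, n_unstable = 15),
                         seed = 2)
  fv <- build_feature_vectors(ds$data$sequences, ds$data$annotations)
  ev <- fv[, intersect(names(fv), full$order)]
  ev$svm_score <- rnorm(nrow(ev))
  got_full <- infer_stability(full, params, ev)
  got_plain <- infer_stability(plain, params_plain,
                               ev[, setdiff(names(ev), "svm_score")])
  expect_equal(got_full, got_plain, tolerance = 1e-12)
})

test_that("every schema-legal evidence pattern scores strictly inside (0,1)", {
  cfg <- fixture_config(n_stable = 40, n_unstable = 40)
  rec <- simulate_bn_records(cfg, seed = 8)
  spec <- build_model("bn")
  ev <- stabnet:::features_to_evidence(spec, rec, rec$label)
  fit <- em_train(spec, ev, em_control(max_iter = 25, seed = 3))
  # extreme corner patterns never seen in training
  grid <- expand.grid(n_term_stab = c(TRUE, FALSE),
                      transmembrane = c(TRUE, FALSE),
                      glycosylation = c(TRUE, FALSE),
                      cadherin = TRUE, rrm = TRUE, ig_c = TRUE,
                      dis_coils_high = c(TRUE, FALSE))
  sc <- infer_stability(spec, fit, grid)
  expect_true(all(sc > 0 & sc < 1))
})
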