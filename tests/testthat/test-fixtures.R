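test_that("the GPSP simulator honours quotas, labels and the seed", {
  cfg <- fixture_config(n_stable = 12, n_unstable = 15, n_nonassigned = 20)
  a <- simulate_gpsp(cfg, seed = 3)
  b <- simulate_gpsp(cfg, seed = 3)
  expect_identical(a, b)
  expect_identical(nrow(a$records), 47L)
  expect_identical(as.vector(table(a$labels)[c("stable", "unstable")]),
                   c(12L, 15L))
  expect_true(all(abs(rowSums(a$records[, -1]) - 1) < 1e-9))

  none <- simulate_gpsp(fixture_config(n_stable = 0, n_unstable = 5,
                                       n_nonassigned = 5), seed = 1)
  expect_false("stable" %in% none$labels)

  bad <- fixture_config(alpha = 0)
  expect_error(simulate_gpsp(bad, seed = 1))
})

test_that("record sampling fills class quotas and respects deterministic CPTs", {
  cfg <- fixture_config(n_stable = 30, n_unstable = 45)
  rec <- simulate_bn_records(cfg, seed = 6)
  expect_identical(sum(rec$label == "stable"), 30L)
  expect_identical(sum(rec$label == "unstable"), 45L)
  expect_identical(rec, simulate_bn_records(cfg, seed = 6))

  # all-deterministic conditionals: sampled records satisfy the implied logic
  spec <- bn_spec(c(a = "cpt", b = "cpt", g = "gaussian"),
                  list(a = character(0), b = "a", g = "b"))
  params <- structure(list(cpt = list(a = 1, b = c(0, 1)), noisy_or = list(),
                           gdt = list(g = list(mean = c(-5, 5),
                                               var = c(1e-4, 1e-4)))),
                      class = "bn_params")
  set.seed(2)
  d <- bn_sample(spec, params, 200)
  expect_true(all(d$a))
  expect_identical(d$b, d$a)
  expect_true(all(d$g[d$b] > 0))
})

test_that("empirical marginals converge to the exact marginal", {
  spec <- build_model("bn_svm")
  truth <- fixture_bn_params(spec)
  exact <- bn_marginal(spec, truth, "stability")
  set.seed(123)
  d <- bn_sample(spec, truth, 10000)
  expect_lt(abs(mean(d$stability) - exact), 0.02)
})

test_that("sequences follow the class composition profile", {
  cfg <- fixture_config()
  cfg$composition$stable <- stats::setNames(c(rep(0, 3), 1, rep(0, 16)),
                                            stabnet:::AA20)   # all E
  rec <- data.frame(protein_id = "p1", label = "stable", n_term_stab = TRUE,
                    tyr_phos = FALSE, ser_thr_phos = FALSE,
                    stringsAsFactors = FALSE)
  s <- simulate_sequences(cfg, rec, seed = 5)
  expect_true(grepl("^E+$", s[["p1"]]))
})

test_that("the synthesized N-terminus encodes the planted degron flag", {
  cfg <- fixture_config(n_stable = 60, n_unstable = 60)
  ds <- simulate_dataset(cfg, seed = 17)
  got <- mapply(function(s, cp) {
    classify_n_degron(mature_n_terminus(s, if (is.na(cp)) NULL else cp))
  }, ds$data$sequences[ds$records$protein_id],
     ds$records$signal_cleavage_pos)
  expect_identical(unname(got == "stabilizing"), ds$records$n_term_stab)
})

test_that("planted motifs raise PWM scan scores (rank test)", {
  cfg <- fixture_config(n_stable = 100, n_unstable = 100)
  ds <- simulate_dataset(cfg, seed = 23)
  pw <- stabnet:::train_pwm_sets(ds$pwm_windows, ds$data$sequences)
  sc <- vapply(ds$data$sequences, scan_sequence, numeric(1),
               pwms = pw$tyrosine)
  flag <- ds$records$tyr_phos[match(names(sc), ds$records$protein_id)]
  wt <- stats::wilcox.test(sc[flag], sc[!flag], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  # offsets recorded for planted windows
  offs <- attr(ds$data$sequences, "plant_offsets")
  planted <- vapply(offs, function(o) !is.null(o$tyrosine), logical(1))
  expect_gt(sum(planted), 0)
})

test_that("simulated annotations stay inside the schema", {
  cfg <- fixture_config(n_stable = 50, n_unstable = 50, unknown_rate = 0.2)
  rec <- simulate_bn_records(cfg, seed = 2)
  ann <- simulate_annotations(cfg, rec, seed = 3)
  expect_true(all(ann$dis_loops_coils >= 0 & ann$dis_loops_coils <= 1))
  expect_identical(disorder_level(ann$dis_loops_coils) == 5L,
                   unname(rec$dis_coils_high))
  expect_gt(mean(is.na(ann$tyr_phos)), 0.05)   # unknown state present
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$tyr_phos, ann$tyr_phos)
  expect_equal(back$signal_cleavage_pos, ann$signal_cleavage_pos)
})

test_that("the simulate-train-evaluate loop closes at reduced scale", {
  cfg <- fixture_config(n_stable = 90, n_unstable = 90)
  ds <- simulate_dataset(cfg, seed = 41)
  cv <- cross_validate(stability_model_builder("bn", control = em_control(max_iter = 40)),
                       ds$data, folds = 4, repeats = 1, seed = 13)
  expect_gt(cv$summary$mean[cv$summary$metric == "AUC"], 0.75)
})
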