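test_that("mature N-terminus honours Met removal and cleavage coordinates", {
  expect_identical(mature_n_terminus("MCDEF"), "C")
  expect_identical(mature_n_terminus("MLDEF"), "M")
  seq21 <- paste0(strrep("A", 20), "RDDDD")
  expect_identical(mature_n_terminus(seq21, cleavage_pos = 20), "R")
  expect_error(mature_n_terminus("MA", cleavage_pos = 2), "sequence length")
  expect_identical(mature_n_terminus("XADEF"), NA_character_)  # non-standard
})

test_that("exactly 8 of the 20 residues are destabilizing", {
  cls <- vapply(stabnet:::AA20, classify_n_degron, character(1))
  expect_identical(sum(cls == "destabilizing"), 8L)
  expect_identical(classify_n_degron("R"), "destabilizing")
  expect_identical(classify_n_degron("G"), "stabilizing")
  expect_identical(classify_n_degron("X"), NA_character_)
})

test_that("N-end-rule processing is total over random sequences", {
  set.seed(11)
  for (i in 1:50) {
    s <- random_aa_seq(sample(5:40, 1))
    r <- mature_n_terminus(s)
    expect_true(classify_n_degron(r) %in% c("stabilizing", "destabilizing"))
  }
})

test_that("disorder levels follow the 20% bands with closed upper bounds", {
  expect_identical(disorder_level(0), 1L)
  expect_identical(disorder_level(0.2), 1L)
  expect_identical(disorder_level(0.21), 2L)
  expect_identical(disorder_level(0.55), 3L)
  expect_identical(disorder_level(0.8), 4L)
  expect_identical(disorder_level(1.0), 5L)
  expect_error(disorder_level(1.3), "\\[0, 1\\]")
})

test_that("feature vectors reproduce the planted ground truth", {
  cfg <- fixture_config(n_stable = 40, n_unstable = 40)
  ds <- simulate_dataset(cfg, seed = 21)
  fv <- build_feature_vectors(ds$data$sequences, ds$data$annotations)
  rec <- ds$records
  expect_identical(fv$protein_id, rec$protein_id)
  expect_equal(fv$n_term_stab, rec$n_term_stab)
  for (col in c("tyr_phos", "acetylation", "transmembrane", "cadherin"))
    expect_equal(fv[[col]], rec[[col]])
  expect_equal(fv$dis_coils_high, rec$dis_coils_high)
  expect_equal(fv$dis_hot_loops_high, rec$dis_hot_loops_high)

  # protein with a missing sequence: sequence-derived fields unknown
  fv2 <- build_feature_vectors(ds$data$sequences[-1], ds$data$annotations)
  expect_true(is.na(fv2$n_term_stab[1]))
  expect_false(anyNA(fv2$n_term_stab[-1]))
})

test_that("Fisher enrichment matches the exhaustive hypergeometric oracle", {
  labels <- rep(c("unstable", "stable"), each = 10)
  presence <- labels == "unstable"        # [[10,0],[0,10]]
  r <- enrichment_test(labels, presence, "unstable", n_tests = 1)
  expect_equal(r$p_value, oracle_fisher_p(r$contingency), tolerance = 1e-10)
  expect_identical(r$direction, "over")

  presence2 <- rep(c(TRUE, FALSE), 10)    # [[5,5],[5,5]]
  r2 <- enrichment_test(labels, presence2, "unstable")
  expect_equal(r2$p_value, 1)
  expect_true(is.na(r2$direction))

  r3 <- enrichment_test(labels, presence, "unstable", n_tests = 30)
  expect_equal(r3$e_value, r3$p_value * 30)

  set.seed(4)
  for (i in 1:10) {
    lab <- sample(c("stable", "unstable"), 40, replace = TRUE)
    pres <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (length(unique(lab)) < 2) next
    r <- enrichment_test(lab, pres, "stable")
    expect_equal(r$p_value, oracle_fisher_p(r$contingency), tolerance = 1e-9)
    # simultaneous row and column swap leaves p unchanged
    r_swap <- enrichment_test(lab, !pres, "unstable")
    expect_equal(r_swap$p_value, r$p_value, tolerance = 1e-9)
  }
})

test_that("a strongly planted feature is reported at E < 1e-6", {
  set.seed(9)
  n <- 500
  labels <- rep(c("unstable", "other"), c(150, 350))
  presence <- ifelse(labels == "unstable", runif(n) < 0.8, runif(n) < 0.1)
  r <- enrichment_test(labels, presence, "unstable", n_tests = 29)
  expect_identical(r$direction, "over")
  expect_lt(r$e_value, 1e-6)
})

test_that("the enrichment scan covers domains, PTMs, N-degron and 15 disorder classes", {
  cfg <- fixture_config(n_stable = 120, n_unstable = 120)
  ds <- simulate_dataset(cfg, seed = 31)
  fv <- build_feature_vectors(ds$data$sequences, ds$data$annotations)
  scan <- enrichment_scan(fv, ds$data$annotations, ds$records$label,
                          target = "unstable")
  expect_identical(nrow(scan), 9L + 1L + 4L + 15L)
  expect_true(all(scan$e_value >= scan$p_value))
  # ground truth plants destabilizing N-termini and TM domains in unstable
  expect_identical(scan$direction[scan$feature_name == "n_degron"], "over")
  expect_identical(scan$direction[scan$feature_name == "transmembrane"], "over")
  expect_identical(scan$direction[scan$feature_name == "acetylation"], "under")
})
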