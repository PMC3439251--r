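# Synthetic-data generator. Emits every input the pipeline consumes --
# 7-bin stability distributions, annotation tables, protein sequences and
# phosphosite foreground windows -- with planted ground truth, so the full
# train/evaluate loop is testable without any external data.

#' Configuration of the synthetic-data generator
#'
#' Defaults mirror the shape of the study data the pipeline targets:
#' 743 stable and 794 unstable training proteins with 2442 non-assigned
#' background proteins; three 7-bin prototypes concentrated in the
#' unstable (R1/R2), intermediate (R3/R4) and stable (R5--R7) bins; a
#' ground-truth network whose qualitative directions match the published
#' enrichment findings (PTMs enriched among stable proteins,
#' transmembrane/signal-peptide domains and destabilizing N-termini among
#' unstable ones); class-specific residue composition (E/D/K/N enriched in
#' stable, W/C/L/T in unstable sequences); and a small set of
#' phosphosite motifs planted in sequences of phosphorylated proteins.
#'
#' @param n_stable,n_unstable,n_nonassigned Group sizes.
#' @param alpha Dirichlet concentration around the bin prototypes.
#' @param plant_prob Probability that a motif window is planted in a
#'   sequence whose corresponding phosphorylation flag is true.
#' @param unknown_rate Fraction of PTM annotations masked to the unknown
#'   state.
#' @param cleavage_rate Fraction of signal-peptide-positive proteins given
#'   an explicit cleavage position.
#' @param length_meanlog,length_sdlog Log-normal sequence-length
#'   parameters.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_stable = 743L, n_unstable = 794L,
                           n_nonassigned = 2442L, alpha = 200,
                           plant_prob = 0.9, unknown_rate = 0,
                           cleavage_rate = 0.3,
                           length_meanlog = log(300), length_sdlog = 0.25) {
  prototypes <- rbind(
    unstable     = c(0.42, 0.34, 0.11, 0.06, 0.04, 0.02, 0.01),
    non_assigned = c(0.05, 0.10, 0.34, 0.30, 0.11, 0.06, 0.04),
    stable       = c(0.01, 0.02, 0.05, 0.12, 0.25, 0.30, 0.25))
  base <- rep(1 / 20, 20)
  names(base) <- AA20
  stable_prof <- base; stable_prof[c("E", "D", "K", "N")] <- base[c("E", "D", "K", "N")] * 1.7
  unstable_prof <- base; unstable_prof[c("W", "C", "L", "T")] <- base[c("W", "C", "L", "T")] * 1.7
  structure(list(
    n_stable = as.integer(n_stable), n_unstable = as.integer(n_unstable),
    n_nonassigned = as.integer(n_nonassigned),
    prototypes = prototypes, alpha = alpha,
    composition = list(stable = stable_prof / sum(stable_prof),
                       unstable = unstable_prof / sum(unstable_prof)),
    motifs = list(tyrosine = c("EDYEEVA", "NGYIDPA", "SDYENPQ"),
                  ser_thr = c("RRASVAG", "TPSPKKA", "LDSGDEE")),
    n_windows_per_motif = 40L, window_mutation = 0.15,
    plant_mutation = 0.05, plant_prob = plant_prob,
    unknown_rate = unknown_rate, cleavage_rate = cleavage_rate,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog),
    class = "fixture_config")
}

#' Ground-truth network parameters of the generator
#'
#' Two documented parameterizations from which synthetic feature records
#' are sampled.
#'
#' The `"study"` regime (default) emulates realistic data: sparse domain
#' and disorder flags, moderate noisy-OR inhibitions, and a Stability CPT
#' that increases with a stabilizing N-terminus and the PTM latent and
#' decreases with the Domain latent.
#'
#' The `"recovery"` regime is the well-conditioned parameterization used
#' for parameter-recovery experiments: root priors are set so that every
#' Stability parent configuration is populated, the latent aggregators
#' are near-deterministic (tiny inhibitions and leaks, a sharp Disorder
#' CPT) so the latent states are pinned by their observed parents, and
#' the Stability CPT is a steep logistic in its four parents so its
#' entries sit away from 1/2, where binomial noise is largest. Under the
#' realistic regime several configurations receive too few samples for
#' their CPT entries to be estimable, so recovery there measures sampling
#' scarcity rather than the learner.
#'
#' @param spec A `bn_spec` from [build_model()] (variant `bn_svm` or
#'   `bn`).
#' @param regime `"study"` or `"recovery"`.
#' @return A `bn_params`.
#' @export
fixture_bn_params <- function(spec = build_model("bn_svm"),
                              regime = c("study", "recovery")) {
  regime <- match.arg(regime)
  sch <- bn_node_schema()
  params <- list(cpt = list(), noisy_or = list(), gdt = list())
  grid <- pa_config_grid(4)   # parents: n_term_stab, ptm, domain, disorder
  if (regime == "study") {
    priors <- c(n_term_stab = 0.75,
                tyr_phos = 0.25, ser_thr_phos = 0.45, acetylation = 0.20,
                glycosylation = 0.05,
                transmembrane = 0.30, signal_peptide = 0.22,
                loops_coils_motif = 0.10, immunoglobulin = 0.04,
                ig_like = 0.04, ig_c = 0.03, zinc_finger_c2 = 0.04,
                cadherin = 0.02, rrm = 0.04,
                dis_coils_high = 0.08, dis_hot_loops_high = 0.06)
    for (nd in names(priors)) params$cpt[[nd]] <- priors[[nd]]
    params$noisy_or$ptm <- list(q = c(0.25, 0.25, 0.30, 0.60), c0 = 0.05)
    params$noisy_or$domain <- list(q = c(0.20, 0.25, rep(0.60, 7)), c0 = 0.05)
    params$cpt$disorder <- c(0.08, 0.80, 0.80, 0.95)  # configs FF, TF, FT, TT
    params$cpt$stability <- stats::plogis(-1.0 + 2.2 * grid[, 1] +
                                          1.9 * grid[, 2] - 2.6 * grid[, 3] +
                                          0.8 * grid[, 4])
  } else {
    params$cpt[[sch$nterm]] <- 0.5
    for (nd in sch$ptm_obs) params$cpt[[nd]] <- 0.16
    for (nd in sch$domain_obs) params$cpt[[nd]] <- 0.09
    for (nd in sch$disorder_obs) params$cpt[[nd]] <- 0.35
    params$noisy_or$ptm <- list(q = rep(0.03, 4), c0 = 0.01)
    params$noisy_or$domain <- list(q = rep(0.03, 9), c0 = 0.01)
    params$cpt$disorder <- c(0.02, 0.95, 0.95, 0.98)
    params$cpt$stability <- stats::plogis(-1.6 + 3.2 * grid[, 1] +
                                          3.2 * grid[, 2] - 3.2 * grid[, 3] +
                                          3.2 * grid[, 4])
  }
  if ("svm_score" %in% spec$continuous)
    params$gdt$svm_score <- list(mean = c(-1, 1), var = c(1, 1))
  params$gdt$pwm_tyr <- list(mean = c(1.0, 3.5), var = c(1, 1))
  params$gdt$pwm_ser_thr <- list(mean = c(1.0, 3.5), var = c(1, 1))
  structure(params, class = "bn_params")
}

rdirichlet1 <- function(alpha_vec) {
  g <- stats::rgamma(length(alpha_vec), shape = alpha_vec, rate = 1)
  g / sum(g)
}

#' Simulate a 7-bin stability distribution table
#'
#' Draws each protein's bin vector from a Dirichlet distribution centred
#' on its group's prototype with concentration `alpha`.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed.
#' @return List: `records` (data.frame `protein_id`, `R1`..`R7`) and
#'   `labels` (planted group per protein, named).
#' @export
simulate_gpsp <- function(config = fixture_config(), seed = 1L) {
  stopifnot(config$alpha > 0)
  set.seed(seed)
  sizes <- c(unstable = config$n_unstable,
             non_assigned = config$n_nonassigned,
             stable = config$n_stable)
  sizes <- sizes[sizes > 0]
  rows <- list(); labels <- character(0)
  for (grp in names(sizes)) {
    proto <- config$prototypes[grp, ]
    draws <- t(replicate(sizes[[grp]], rdirichlet1(config$alpha * proto)))
    rows[[grp]] <- draws
    labels <- c(labels, rep(grp, sizes[[grp]]))
  }
  bins <- do.call(rbind, rows)
  ids <- sprintf("P%05d", seq_len(nrow(bins)))
  records <- data.frame(protein_id = ids, bins, stringsAsFactors = FALSE)
  names(records) <- c("protein_id", gpsp_bin_cols())
  list(records = records, labels = stats::setNames(labels, ids))
}

#' Simulate feature records from the ground-truth network
#'
#' Ancestral samples of the full hybrid network. Either a fixed total `n`
#' is drawn, or sampling continues (in batches, rejecting the surplus
#' class) until the per-class quotas of the configuration are met, giving
#' exactly `n_stable` stable and `n_unstable` unstable records.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed.
#' @param n Total number of ancestral samples; `NULL` (default) uses the
#'   per-class quotas instead.
#' @return Data.frame of node columns plus `protein_id` and `label`
#'   (`stable` / `unstable` from the sampled stability node).
#' @export
simulate_bn_records <- function(config = fixture_config(), seed = 1L,
                                n = NULL) {
  set.seed(seed)
  spec <- build_model("bn_svm")
  truth <- fixture_bn_params(spec)
  if (!is.null(n)) {
    out <- bn_sample(spec, truth, n)
  } else {
    want <- c(stable = config$n_stable, unstable = config$n_unstable)
    got <- list(stable = NULL, unstable = NULL)
    while (is.null(got$stable) || nrow(got$stable) < want["stable"] ||
           nrow(got$unstable) < want["unstable"]) {
      batch <- bn_sample(spec, truth, sum(want))
      got$stable <- rbind(got$stable, batch[batch$stability, , drop = FALSE])
      got$unstable <- rbind(got$unstable, batch[!batch$stability, , drop = FALSE])
    }
    out <- rbind(got$stable[seq_len(want["stable"]), , drop = FALSE],
                 got$unstable[seq_len(want["unstable"]), , drop = FALSE])
    rownames(out) <- NULL
  }
  out$label <- ifelse(out$stability, "stable", "unstable")
  out$protein_id <- sprintf("S%05d", seq_len(nrow(out)))
  out
}

mutate_window <- function(window, rate) {
  chars <- strsplit(window, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Foreground phosphosite windows for the fixture motifs
#'
#' Generates, per motif, a foreground set of windows: copies of the
#' consensus with positions mutated at the configured rate (emulating the
#' site collections a motif is scanned against).
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed.
#' @return List with elements `tyrosine` and `ser_thr`, each a named list
#'   of character vectors (one per motif).
#' @export
fixture_pwm_windows <- function(config = fixture_config(), seed = 1L) {
  set.seed(seed)
  out <- lapply(config$motifs, function(consensi) {
    wins <- lapply(consensi, function(cs)
      vapply(seq_len(config$n_windows_per_motif),
             function(i) mutate_window(cs, config$window_mutation),
             character(1)))
    names(wins) <- consensi
    wins
  })
  out
}

# draw one residue from a set, honouring class composition weights
draw_from_set <- function(set, profile) {
  w <- profile[set]
  sample(set, 1L, prob = w / sum(w))
}

#' Simulate protein sequences consistent with planted feature records
#'
#' Residues are drawn from the class composition profile. A motif window
#' is planted (consensus lightly mutated, uniform position away from the
#' N-terminus) with probability `plant_prob` when the record's
#' corresponding phosphorylation flag is true. The N-terminus is
#' constructed so that N-end-rule processing recovers the record's
#' `n_term_stab` flag: the mature residue is drawn from the stabilizing or
#' destabilizing set, optionally behind an initiator methionine that the
#' removal rule strips, or at `cleavage_pos + 1` when the record carries a
#' cleavage position.
#'
#' @param config A [fixture_config()].
#' @param records Records from [simulate_bn_records()]; a
#'   `signal_cleavage_pos` column, when present, is honoured.
#' @param seed Integer seed.
#' @return Named character vector of sequences; planted motif offsets in
#'   attribute `plant_offsets` (list per protein).
#' @export
simulate_sequences <- function(config = fixture_config(), records,
                               seed = 1L) {
  set.seed(seed)
  n <- nrow(records)
  stab_set <- setdiff(setdiff(AA20, DESTABILIZING_SET), "M")
  seqs <- character(n)
  plants <- vector("list", n)
  cleav <- records$signal_cleavage_pos %||% rep(NA_integer_, n)
  for (i in seq_len(n)) {
    prof <- config$composition[[records$label[i]]]
    len <- max(50L, round(stats::rlnorm(1, config$length_meanlog,
                                        config$length_sdlog)))
    chars <- sample(AA20, len, replace = TRUE, prob = prof)
    mature <- draw_from_set(if (records$n_term_stab[i]) stab_set
                            else DESTABILIZING_SET, prof)
    if (!is.na(cleav[i])) {
      # mature N-terminus sits behind the signal peptide
      chars[cleav[i] + 1L] <- mature
      if (chars[1] == "M") chars[1] <- "A"
    } else if (mature %in% MET_REMOVAL_SET && stats::runif(1) < 0.5) {
      chars[1] <- "M"; chars[2] <- mature
    } else {
      chars[1] <- mature
      if (chars[2] %in% MET_REMOVAL_SET && chars[1] == "M")
        chars[2] <- "E"    # unreachable guard: mature is never M
    }
    offs <- list()
    for (kind in c("tyrosine", "ser_thr")) {
      flag <- if (kind == "tyrosine") records$tyr_phos[i] else
        records$ser_thr_phos[i]
      if (isTRUE(flag) && stats::runif(1) < config$plant_prob) {
        cs <- sample(config$motifs[[kind]], 1L)
        win <- mutate_window(cs, config$plant_mutation)
        w <- nchar(win)
        if (w <= len - 2L) {
          pos <- sample(3L:(len - w + 1L), 1L)
          chars[pos:(pos + w - 1L)] <- strsplit(win, "")[[1]]
          offs[[kind]] <- pos
        } else warning("motif longer than sequence; planting skipped")
      }
    }
    plants[[i]] <- offs
    seqs[i] <- paste(chars, collapse = "")
  }
  names(seqs) <- records$protein_id
  names(plants) <- records$protein_id
  attr(seqs, "plant_offsets") <- plants
  seqs
}

#' Annotation table consistent with simulated records
#'
#' Converts sampled node states into the annotation-table schema: PTM and
#' domain flags are copied (with a configurable fraction of PTM cells
#' masked to unknown), disorder fractions are drawn inside the level-5
#' band (80--100%) when the corresponding high-disorder flag is true and
#' below it otherwise, and a fraction of signal-peptide-positive proteins
#' receive an explicit cleavage position.
#'
#' @param config A [fixture_config()].
#' @param records Records from [simulate_bn_records()].
#' @param seed Integer seed.
#' @return Annotation data.frame (schema of [read_annotations()]).
#' @export
simulate_annotations <- function(config = fixture_config(), records,
                                 seed = 1L) {
  set.seed(seed)
  sc <- annotation_schema()
  n <- nrow(records)
  out <- data.frame(protein_id = records$protein_id, stringsAsFactors = FALSE)
  for (col in sc$ptm) {
    v <- records[[col]]
    mask <- stats::runif(n) < config$unknown_rate
    v[mask] <- NA
    out[[col]] <- v
  }
  for (col in sc$domain) out[[col]] <- records[[col]]
  out$dis_loops_coils <- ifelse(records$dis_coils_high,
                                stats::runif(n, 0.82, 0.98),
                                stats::runif(n, 0.0, 0.75))
  out$dis_hot_loops <- ifelse(records$dis_hot_loops_high,
                              stats::runif(n, 0.82, 0.98),
                              stats::runif(n, 0.0, 0.75))
  out$dis_rem465 <- stats::runif(n, 0.0, 0.6)
  out$signal_cleavage_pos <- ifelse(
    records$signal_peptide & stats::runif(n) < config$cleavage_rate,
    sample(15:25, n, replace = TRUE), NA_integer_)
  out
}

#' Simulate a complete training data set
#'
#' Chains the generators: ancestral feature records, consistent
#' annotations, consistent sequences, and the foreground windows for PWM
#' training.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed (sub-generators are seeded deterministically
#'   from it).
#' @return List: `records` (with planted truth), `data` (a
#'   [stability_data()]), `pwm_windows`.
#' @export
simulate_dataset <- function(config = fixture_config(), seed = 1L) {
  records <- simulate_bn_records(config, seed = seed)
  annotations <- simulate_annotations(config, records, seed = seed + 1L)
  records$signal_cleavage_pos <- annotations$signal_cleavage_pos
  sequences <- simulate_sequences(config, records, seed = seed + 2L)
  windows <- fixture_pwm_windows(config, seed = seed + 3L)
  labels <- stats::setNames(records$label, records$protein_id)
  list(records = records,
       data = stability_data(sequences, annotations, labels),
       pwm_windows = windows)
}
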