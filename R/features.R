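# Feature extraction: N-end-rule processing of the mature N-terminus,
# disorder binning, assembly of the 19-component per-protein feature
# vectors, and Fisher-exact enrichment statistics.

# Residues whose presence as the second residue triggers removal of the
# initiator methionine, and the destabilizing set of the original N-end rule.
MET_REMOVAL_SET <- c("C", "G", "A", "S", "T", "V", "P")
DESTABILIZING_SET <- c("R", "K", "H", "F", "L", "W", "I", "Y")

#' Mature N-terminal residue of a protein
#'
#' Determines the residue exposed at the N-terminus of the mature peptide.
#' When a signal-peptide cleavage position is supplied (1-based index of
#' the last residue of the signal peptide), the mature peptide starts at
#' `cleavage_pos + 1`. Otherwise the initiator methionine is removed when
#' the second residue is one of C, G, A, S, T, V or P; if it is not
#' removed (or the sequence does not start with M), the first residue is
#' returned.
#'
#' @param sequence Amino-acid string (length >= 2).
#' @param cleavage_pos Optional positive integer; must be smaller than the
#'   sequence length.
#' @return Single residue symbol; `NA` if the exposed symbol is not one of
#'   the 20 standard residues.
#' @examples
#' mature_n_terminus("MCDEF")  # "C": Met removed, second residue in the set
#' mature_n_terminus("MLDEF")  # "M": L is not in the removal set
#' @export
mature_n_terminus <- function(sequence, cleavage_pos = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 2L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!is.null(cleavage_pos) && !is.na(cleavage_pos)) {
    cleavage_pos <- as.integer(cleavage_pos)
    if (cleavage_pos < 1L || cleavage_pos >= length(chars))
      stop("cleavage position must satisfy 1 <= pos < sequence length")
    res <- chars[cleavage_pos + 1L]
  } else if (chars[1] == "M" && chars[2] %in% MET_REMOVAL_SET) {
    res <- chars[2]
  } else {
    res <- chars[1]
  }
  if (!res %in% AA20) return(NA_character_)
  res
}

#' Classify an N-terminal residue under the original N-end rule
#'
#' A residue is destabilizing iff it is one of R, K, H, F, L, W, I or Y;
#' every other standard residue is stabilizing.
#'
#' @param residue Single residue symbol (may be `NA`).
#' @return `"stabilizing"`, `"destabilizing"`, or `NA` for a non-standard
#'   or unknown symbol.
#' @export
classify_n_degron <- function(residue) {
  if (is.na(residue) || !residue %in% AA20) return(NA_character_)
  if (residue %in% DESTABILIZING_SET) "destabilizing" else "stabilizing"
}

#' Discretize a disorder fraction into one of five levels
#'
#' Level 1 covers 0--20% of the sequence disordered (inclusive at both
#' ends), level 2 covers (20, 40\]%, level 3 (40, 60\]%, level 4 (60, 80\]%
#' and level 5 (80, 100\]%.
#'
#' @param fraction Numeric vector of disorder fractions in \[0, 1\].
#' @return Integer level(s) in 1..5.
#' @export
disorder_level <- function(fraction) {
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1))
    stop("disorder fraction must lie in [0, 1]")
  pmax(1L, as.integer(ceiling(fraction / 0.2 - 1e-12)))
}

#' Assemble per-protein feature vectors
#'
#' Joins sequences and annotations into the 19-component observation
#' record the stability models consume: the N-end-rule indicator, four
#' tri-state PTM flags, nine domain flags, two high-disorder indicators
#' (loops/coils and hot loops each at 80--100% disorder), two PWM maximum
#' match scores (tyrosine and serine/threonine phosphorylation), and the
#' sequence-SVM score when a trained SVM is supplied.
#'
#' A protein present in the annotation table but missing a sequence is
#' still emitted, with all sequence-derived fields unknown (`NA`).
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param annotations Annotation data.frame (see [read_annotations()]).
#' @param pwms Optional list with elements `tyrosine` and `ser_thr`, each a
#'   PWM set from [build_pwm()]; when `NULL` the PWM score columns are `NA`.
#' @param svm_model Optional calibrated SVM from [train_calibrated_svm()].
#' @return Data.frame with one row per annotated protein: `protein_id`,
#'   `n_term_stab`, the four PTM columns, the nine domain columns,
#'   `dis_coils_high`, `dis_hot_loops_high`, `pwm_tyr`, `pwm_ser_thr` and
#'   (if `svm_model` given) `svm_score`.
#' @export
build_feature_vectors <- function(sequences, annotations, pwms = NULL,
                                  svm_model = NULL) {
  sc <- annotation_schema()
  n <- nrow(annotations)
  out <- data.frame(protein_id = annotations$protein_id,
                    stringsAsFactors = FALSE)
  seqs <- sequences[annotations$protein_id]
  has_seq <- !is.na(seqs) & nchar(seqs) >= 2

  nterm <- rep(NA_character_, n)
  nterm[has_seq] <- mapply(mature_n_terminus, seqs[has_seq],
                           annotations$signal_cleavage_pos[has_seq],
                           USE.NAMES = FALSE)
  degron <- vapply(nterm, classify_n_degron, character(1), USE.NAMES = FALSE)
  out$n_term_stab <- ifelse(is.na(degron), NA, degron == "stabilizing")

  for (col in c(sc$ptm, sc$domain)) out[[col]] <- annotations[[col]]
  out$dis_coils_high <- disorder_level(annotations$dis_loops_coils) == 5L
  out$dis_hot_loops_high <- disorder_level(annotations$dis_hot_loops) == 5L

  out$pwm_tyr <- NA_real_
  out$pwm_ser_thr <- NA_real_
  if (!is.null(pwms)) {
    out$pwm_tyr[has_seq] <- vapply(seqs[has_seq], scan_sequence, numeric(1),
                                   pwms = pwms$tyrosine, USE.NAMES = FALSE)
    out$pwm_ser_thr[has_seq] <- vapply(seqs[has_seq], scan_sequence, numeric(1),
                                       pwms = pwms$ser_thr, USE.NAMES = FALSE)
  }
  if (!is.null(svm_model)) {
    out$svm_score <- NA_real_
    out$svm_score[has_seq] <- svm_decision_scores(svm_model, seqs[has_seq])
  }
  out
}

#' Fisher-exact enrichment of a feature in a stability class
#'
#' Builds the 2x2 contingency table (membership in the target class vs all
#' other proteins, against feature presence vs absence), computes the
#' two-sided Fisher exact p-value, calls the direction from the sample
#' odds ratio, and reports a Bonferroni-style E-value `p * n_tests`.
#'
#' @param labels Class label per protein (any vector; compared to `target`).
#' @param presence Logical feature-presence indicator per protein (`NA`
#'   rows are dropped).
#' @param target The class whose enrichment is being tested.
#' @param n_tests Number of tests in the family (E-value multiplier).
#' @param feature_name Label carried through to the result.
#' @return List of class `enrichment_result`: `feature_name`, `direction`
#'   (`"over"`, `"under"` or `NA`), `contingency` (2x2 integer matrix),
#'   `p_value`, `e_value`.
#' @export
enrichment_test <- function(labels, presence, target, n_tests = 1L,
                            feature_name = "feature") {
  keep <- !is.na(presence) & !is.na(labels)
  labels <- labels[keep]; presence <- presence[keep]
  in_class <- labels == target
  if (!any(in_class) || all(in_class))
    stop("need at least one protein inside and outside the target class")
  tab <- matrix(c(sum(in_class & presence), sum(in_class & !presence),
                  sum(!in_class & presence), sum(!in_class & !presence)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "other"), c("present", "absent")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- 1
    direction <- NA_character_
  } else {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    # sample odds ratio of (present | target) vs (present | other)
    or_num <- tab[1, 1] * tab[2, 2]
    or_den <- tab[1, 2] * tab[2, 1]
    direction <- if (or_num == or_den) NA_character_
                 else if (or_num > or_den) "over" else "under"
  }
  structure(list(feature_name = feature_name, direction = direction,
                 contingency = tab, p_value = p,
                 e_value = p * n_tests),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: %s-represented, p = %.3g, E = %.3g\n", x$feature_name,
              x$direction %||% "not", x$p_value, x$e_value))
  invisible(x)
}

#' Enrichment scan over all annotated features
#'
#' Tests, against one stability class, the nine domain flags, the N-degron
#' indicator, the four PTM flags and the fifteen disorder type-by-level
#' classes (3 disorder types x 5 levels), all with a common Bonferroni
#' E-value multiplier equal to the number of tests performed.
#'
#' @param features Feature-vector data.frame from [build_feature_vectors()].
#' @param annotations Annotation data.frame (for the disorder fractions).
#' @param labels Stability class per protein, aligned with `features`.
#' @param target Class tested for enrichment (default `"unstable"`).
#' @return Data.frame with columns `feature_name`, `direction`, `p_value`,
#'   `e_value`, ordered by p-value.
#' @export
enrichment_scan <- function(features, annotations, labels,
                            target = "unstable") {
  sc <- annotation_schema()
  tests <- list()
  for (col in sc$domain) tests[[col]] <- features[[col]]
  tests[["n_degron"]] <- !features$n_term_stab      # presence of a destabilizing N-terminus
  for (col in sc$ptm) tests[[col]] <- features[[col]]
  for (dcol in sc$disorder) {
    lev <- disorder_level(annotations[[dcol]])
    for (l in 1:5)
      tests[[sprintf("%s_level%d", dcol, l)]] <- lev == l
  }
  n_tests <- length(tests)
  rows <- lapply(names(tests), function(nm) {
    r <- enrichment_test(labels, tests[[nm]], target, n_tests, nm)
    data.frame(feature_name = nm, direction = r$direction %||% NA_character_,
               p_value = r$p_value, e_value = r$e_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), ]
}
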