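# Readers and writers for the tabular and sequence formats consumed and
# produced by the pipeline: 7-bin stability distributions, per-protein
# annotation tables, FASTA sequence sets and prediction tables.

#' Column schema of the annotation table
#'
#' Names of the columns an annotation table must carry: one protein
#' identifier, four tri-state post-translational-modification flags, nine
#' Boolean domain/architecture flags, three structural-disorder fractions
#' and an optional 1-based signal-peptide cleavage position (index of the
#' last residue of the signal peptide).
#'
#' @return Named list of character vectors: `id`, `ptm`, `domain`,
#'   `disorder`, `optional`.
#' @export
annotation_schema <- function() {
  list(
    id = "protein_id",
    ptm = c("tyr_phos", "ser_thr_phos", "acetylation", "glycosylation"),
    domain = c("transmembrane", "signal_peptide", "loops_coils_motif",
               "immunoglobulin", "ig_like", "ig_c", "zinc_finger_c2",
               "cadherin", "rrm"),
    disorder = c("dis_loops_coils", "dis_hot_loops", "dis_rem465"),
    optional = "signal_cleavage_pos"
  )
}

gpsp_bin_cols <- function() paste0("R", 1:7)

#' Read a 7-bin protein stability distribution table
#'
#' Reads a tab-separated table with one identifier column followed by seven
#' non-negative bin weights per protein (the proportions of cells observed
#' in each of the seven FACS sub-populations R1--R7). Rows are renormalized
#' to sum exactly to one; a row whose weights sum further than `tol` from
#' one, contain a negative value, or sum to zero is a hard error.
#'
#' @param path Path to a TSV file with header `protein_id, R1, ..., R7`.
#' @param tol Maximum tolerated deviation of a row sum from 1 before
#'   renormalization is refused.
#' @return A `data.frame` with columns `protein_id` and `R1`..`R7`; every
#'   row's bins are non-negative and sum to 1 within 1e-6.
#' @export
read_gpsp_table <- function(path, tol = 0.05) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) != 8L)
    stop("expected 7 bins: GPSP table must have 1 id column + 7 numeric columns, got ",
         ncol(x) - 1L, " data columns")
  names(x) <- c("protein_id", gpsp_bin_cols())
  bins <- as.matrix(x[, gpsp_bin_cols()])
  storage.mode(bins) <- "double"
  if (anyNA(bins)) stop("GPSP table contains non-numeric or missing bin weights")
  neg <- which(apply(bins < 0, 1, any))
  if (length(neg))
    stop("negative bin weight in row ", neg[1], " (", x$protein_id[neg[1]], ")")
  s <- rowSums(bins)
  if (any(s == 0))
    stop("row ", which(s == 0)[1], " (", x$protein_id[which(s == 0)[1]],
         ") has bin weights summing to 0")
  off <- which(abs(s - 1) > tol)
  if (length(off))
    stop("row ", off[1], " (", x$protein_id[off[1]], ") sums to ",
         format(s[off[1]]), ", outside the renormalization tolerance ", tol)
  bins <- bins / s
  out <- data.frame(protein_id = as.character(x$protein_id), bins,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a 7-bin stability distribution table
#'
#' @param x A data.frame as returned by [read_gpsp_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_gpsp_table <- function(x, path) {
  stopifnot(all(c("protein_id", gpsp_bin_cols()) %in% names(x)))
  utils::write.table(x[, c("protein_id", gpsp_bin_cols())], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-protein annotation table
#'
#' Reads the TSV carrying the Boolean/tri-state observations the network
#' consumes: four PTM flags (0/1/`NA`; `NA` is loaded as an *unknown* state,
#' not as absence), nine domain/architecture flags (0/1), three disorder
#' fractions in \[0, 1\] and an optional signal-peptide cleavage position.
#'
#' @param path Path to a TSV file whose header matches [annotation_schema()].
#' @return A `data.frame`; PTM and domain flags as `logical` (PTMs may be
#'   `NA` = unknown), disorder fractions as `numeric`, cleavage position as
#'   `integer` (`NA` when absent).
#' @export
read_annotations <- function(path) {
  sc <- annotation_schema()
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  required <- c(sc$id, sc$ptm, sc$domain, sc$disorder)
  accepted <- c(required, sc$optional)
  unknown <- setdiff(names(x), accepted)
  if (length(unknown))
    stop("unknown column(s) ", paste(unknown, collapse = ", "),
         "; accepted schema: ", paste(accepted, collapse = ", "))
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(protein_id = as.character(x[[sc$id]]),
                    stringsAsFactors = FALSE)
  for (col in sc$ptm) {
    v <- x[[col]]
    if (!all(v %in% c(0, 1, NA)))
      stop("PTM column '", col, "' must contain only 0, 1 or NA")
    out[[col]] <- as.logical(v)           # NA stays NA = unknown state
  }
  for (col in sc$domain) {
    v <- x[[col]]
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("domain column '", col, "' must contain only 0 or 1")
    out[[col]] <- as.logical(v)
  }
  for (col in sc$disorder) {
    v <- as.numeric(x[[col]])
    if (anyNA(v) || any(v < 0 | v > 1))
      stop("disorder column '", col, "' must lie in [0, 1]")
    out[[col]] <- v
  }
  if (sc$optional %in% names(x)) {
    v <- x[[sc$optional]]
    if (!all(is.na(v) | (v == as.integer(v) & v >= 1)))
      stop("signal_cleavage_pos must be a positive integer or NA")
    out[[sc$optional]] <- as.integer(v)
  } else {
    out[[sc$optional]] <- NA_integer_
  }
  out
}

#' Write a per-protein annotation table
#'
#' @param x Annotation data.frame (as from [read_annotations()] or the
#'   simulator).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(x, path) {
  sc <- annotation_schema()
  cols <- c(sc$id, sc$ptm, sc$domain, sc$disorder, sc$optional)
  y <- x[, intersect(cols, names(x))]
  for (col in intersect(c(sc$ptm, sc$domain), names(y)))
    y[[col]] <- as.integer(y[[col]])
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-protein stability predictions
#'
#' Writes a TSV with columns `protein_id`, `score` (6 decimals) and
#' `class` (one of `stable`, `unstable`, `non-assigned`), preserving the
#' input order.
#'
#' @param records Data.frame with columns `protein_id`, `score` in \[0, 1\]
#'   and `class`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(records, path) {
  stopifnot(all(c("protein_id", "score", "class") %in% names(records)))
  if (nrow(records) > 0) {
    if (any(!is_prob(records$score)))
      stop("prediction scores must lie in [0, 1]")
    if (!all(records$class %in% c("stable", "unstable", "non-assigned")))
      stop("class labels must be stable, unstable or non-assigned")
  }
  out <- data.frame(protein_id = records$protein_id,
                    score = sprintf("%.6f", records$score),
                    class = records$class, stringsAsFactors = FALSE)
  if (nrow(records) == 0)
    out <- data.frame(protein_id = character(), score = character(),
                      class = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' A run configuration carries the reproducibility knobs of a pipeline
#' run: `seed`, `cv_folds`, `cv_repeats`, `model_variant` (one of `svm`,
#' `bn`, `bn_svm`), `thresholds` (pair `unstable_lt`, `stable_gt` with
#' `0 <= unstable_lt < stable_gt <= 1`), an `em` block (`max_iter`,
#' `tol`, `pseudocount`) and optional file `paths`. Missing fields take
#' the defaults shown in the return value.
#'
#' @param path YAML file path (`NULL` returns the defaults).
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(seed = 1L, cv_folds = 10L, cv_repeats = 5L,
              model_variant = "bn_svm", thresholds = c(0.2, 0.75),
              em = list(max_iter = 200L, tol = 1e-6, pseudocount = 1),
              paths = list())
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      if (nm == "em") cfg$em[names(user$em)] <- user$em
      else cfg[[nm]] <- user[[nm]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$cv_folds <- as.integer(cfg$cv_folds)
  cfg$cv_repeats <- as.integer(cfg$cv_repeats)
  cfg$thresholds <- as.numeric(unlist(cfg$thresholds))
  if (!cfg$model_variant %in% c("svm", "bn", "bn_svm"))
    stop("model_variant must be svm, bn or bn_svm")
  if (!(length(cfg$thresholds) == 2L && cfg$thresholds[1] >= 0 &&
        cfg$thresholds[1] < cfg$thresholds[2] && cfg$thresholds[2] <= 1))
    stop("thresholds must satisfy 0 <= unstable_lt < stable_gt <= 1")
  structure(cfg, class = "run_config")
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
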