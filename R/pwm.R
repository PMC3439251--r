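# Motif-anchored position-weight matrices for phosphosite scoring: built
# from foreground windows of known modification sites, scanned over a
# query sequence for the maximum ungapped match score.

#' Build a position-weight matrix from foreground windows
#'
#' Column-wise residue frequencies `F` are estimated over the foreground
#' windows; every cell is the log ratio `log((F + P) / BG)` with pseudocount
#' `P = BG / 10`, where `BG` is the background frequency of the residue.
#' Natural logarithms are used throughout.
#'
#' @param motif_id Identifier carried in the model.
#' @param windows Character vector of equal-length amino-acid windows
#'   (the foreground set; at least one).
#' @param background Named numeric vector of 20 strictly positive
#'   background frequencies (names = residues), summing to 1.
#' @return Object of class `pwm_model`: `motif_id`, `width`, `cells`
#'   (20 x width matrix, rows named by residue), `background`,
#'   `n_foreground`.
#' @export
build_pwm <- function(motif_id, windows, background) {
  stopifnot(length(windows) >= 1L)
  widths <- nchar(windows)
  if (length(unique(widths)) != 1L)
    stop("foreground windows must all have the same length")
  w <- widths[1]
  background <- background[AA20]
  if (anyNA(background) || any(background <= 0))
    stop("background must assign a strictly positive frequency to all 20 residues")
  enc <- t(vapply(windows, aa_encode, integer(w), USE.NAMES = FALSE))
  if (anyNA(enc)) stop("foreground windows contain non-standard residues")
  counts <- vapply(seq_len(w), function(j) tabulate(enc[, j], nbins = 20L),
                   integer(20L))
  f <- counts / length(windows)
  cells <- log((f + background / 10) / background)
  dimnames(cells) <- list(AA20, NULL)
  structure(list(motif_id = motif_id, width = w, cells = cells,
                 background = background, n_foreground = length(windows)),
            class = "pwm_model")
}

#' Maximum PWM match score over a sequence
#'
#' Slides every model in `pwms` over all ungapped windows of the sequence
#' and returns the maximum summed cell score. Windows containing a
#' non-standard residue are skipped. If no model fits the sequence (or
#' every window is skipped), returns `NA` as the absent-score sentinel.
#'
#' @param sequence Amino-acid string (length >= 1).
#' @param pwms A `pwm_set` (see [pwm_set()]) or a single `pwm_model`.
#' @return Maximum match score, or `NA` when undefined.
#' @export
scan_sequence <- function(sequence, pwms) {
  if (inherits(pwms, "pwm_model")) pwms <- pwm_set("adhoc", list(pwms))
  stopifnot(inherits(pwms, "pwm_set"), nchar(sequence) >= 1L)
  enc <- aa_encode(sequence)
  n <- length(enc)
  best <- NA_real_
  for (m in pwms$models) {
    w <- m$width
    if (n < w) next
    starts <- seq_len(n - w + 1L)
    sc <- numeric(length(starts))
    for (j in seq_len(w))      # cells is 20 x w; linear index per column
      sc <- sc + m$cells[enc[starts + j - 1L] + 20L * (j - 1L)]
    if (all(is.na(sc))) next   # every window hit a non-standard residue
    mx <- max(sc, na.rm = TRUE)
    if (is.na(best) || mx > best) best <- mx
  }
  best
}

#' Bundle PWM models into a set
#'
#' @param kind `"tyrosine"` or `"ser_thr"` (free-form allowed for ad-hoc
#'   sets).
#' @param models Non-empty list of `pwm_model` objects.
#' @return Object of class `pwm_set`.
#' @export
pwm_set <- function(kind, models) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "pwm_model")))
  structure(list(kind = kind, models = models), class = "pwm_set")
}

#' Background residue frequencies of a sequence collection
#'
#' Pooled residue frequencies over all supplied sequences with a half-count
#' added to every residue so the background is strictly positive.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
background_frequencies <- function(sequences) {
  enc <- unlist(lapply(sequences, aa_encode), use.names = FALSE)
  counts <- tabulate(enc[!is.na(enc)], nbins = 20L) + 0.5
  stats::setNames(counts / sum(counts), AA20)
}

#' Read foreground windows from a plain-text file
#'
#' One window per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of windows.
#' @export
read_windows <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Serialize / deserialize PWM sets as JSON
#'
#' @param pwms A `pwm_set` or a named list of `pwm_set`s (e.g. the
#'   `tyrosine` / `ser_thr` pair).
#' @param path JSON file path.
#' @return `write_pwm_sets()` returns `path` invisibly; `read_pwm_sets()`
#'   the reconstructed object.
#' @export
write_pwm_sets <- function(pwms, path) {
  single <- inherits(pwms, "pwm_set")
  if (single) pwms <- list(only = pwms)
  doc <- lapply(pwms, function(set) list(
    kind = set$kind,
    models = lapply(set$models, function(m) list(
      motif_id = m$motif_id, width = m$width,
      cells = m$cells, background = as.list(m$background),
      n_foreground = m$n_foreground))))
  jsonlite::write_json(list(single = single, sets = doc), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pwm_sets
#' @export
read_pwm_sets <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  sets <- lapply(doc$sets, function(set) {
    models <- lapply(set$models, function(m) {
      cells <- do.call(rbind, lapply(m$cells, function(r) unlist(r)))
      dimnames(cells) <- list(AA20, NULL)
      structure(list(motif_id = m$motif_id, width = m$width, cells = cells,
                     background = unlist(m$background)[AA20],
                     n_foreground = m$n_foreground),
                class = "pwm_model")
    })
    pwm_set(set$kind, models)
  })
  if (isTRUE(doc$single)) sets[[1]] else sets
}
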