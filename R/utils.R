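# Internal helpers shared across modules.

# Fixed one-letter alphabet of the 20 standard amino acids (alphabetical).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(x, y) if (is.null(x)) y else x

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Encode an amino-acid string as integer indices into AA20; non-standard
# symbols (including X) become NA.
aa_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  match(chars, AA20)
}

# Stratified fold assignment: each class is split as evenly as possible
# across `folds`. Returns an integer vector aligned with `labels`.
stratified_folds <- function(labels, folds) {
  stopifnot(folds >= 2L)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds && length(idx) < 1L)
      stop("class '", cl, "' has no members")
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

is_prob <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x <= 1

stop_if_not_flag <- function(x, what) {
  if (!(is.logical(x) && length(x) == 1L && !is.na(x)))
    stop(what, " must be TRUE or FALSE")
  invisible(x)
}
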