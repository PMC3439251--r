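# Sequence-composition SVM: the 1-spectrum kernel maps a protein to its
# amino-acid composition vector; a soft-margin linear SVM separates stable
# from unstable compositions, and its decision score is calibrated into
# class-conditional Gaussian densities on a held-out half of the training
# data.

#' 1-spectrum feature vector of a sequence
#'
#' Counts of each of the 20 standard residues, optionally normalized to
#' frequencies. Non-standard symbols are ignored; their number is attached
#' as the attribute `n_ignored`.
#'
#' @param sequence Amino-acid string (length >= 1).
#' @param normalize Divide counts by the number of counted residues.
#' @return Named numeric vector of length 20.
#' @export
spectrum_features <- function(sequence, normalize = FALSE) {
  enc <- aa_encode(sequence)
  n_ignored <- sum(is.na(enc))
  counts <- tabulate(enc[!is.na(enc)], nbins = 20L)
  names(counts) <- AA20
  out <- if (normalize && sum(counts) > 0) counts / sum(counts) else counts
  attr(out, "n_ignored") <- n_ignored
  out
}

#' 1-spectrum kernel between two sequences
#'
#' Dot product of the length-1 substring (residue) count vectors; invariant
#' to residue order within each sequence.
#'
#' @param a,b Amino-acid strings.
#' @return Kernel value (numeric scalar).
#' @export
spectrum_kernel <- function(a, b) {
  sum(spectrum_features(a) * spectrum_features(b))
}

spectrum_matrix <- function(sequences, normalize = TRUE) {
  m <- t(vapply(sequences, function(s) as.numeric(spectrum_features(s, normalize)),
                numeric(20L), USE.NAMES = FALSE))
  colnames(m) <- AA20
  m
}

#' Train and calibrate the composition SVM
#'
#' The training samples are halved by a seeded stratified split: the first
#' half trains a soft-margin linear SVM on (length-normalized) composition
#' vectors; the decision scores of the second half fit one Gaussian per
#' class by maximum likelihood. Class priors are the class proportions of
#' the full training input. The decision function is oriented so that
#' larger scores favour the stable class.
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param labels Factor/character per sequence, values `stable` /
#'   `unstable`.
#' @param seed Integer seed for the stratified half split.
#' @param cost Soft-margin cost of the linear SVM.
#' @param normalize Use composition frequencies rather than raw counts.
#' @param var_floor Lower bound applied to the calibration variances.
#' @return Object of class `calibrated_svm`: residue `weights`, `offset`,
#'   `gaussians` (per-class mean/var), `priors`, `normalize`, `seed`.
#' @export
train_calibrated_svm <- function(sequences, labels, seed = 1L, cost = 1,
                                 normalize = TRUE, var_floor = 1e-6) {
  labels <- as.character(labels)
  stopifnot(length(sequences) == length(labels),
            all(labels %in% c("stable", "unstable")))
  x <- spectrum_matrix(sequences, normalize)
  half <- local({
    set.seed(seed)
    h <- integer(length(labels))
    for (cl in c("stable", "unstable")) {
      idx <- sample(which(labels == cl))
      h[idx] <- rep_len(1:2, length(idx))
    }
    h
  })
  for (h in 1:2)
    if (length(unique(labels[half == h])) < 2L)
      stop("a half of the split contains one class only; re-split with a ",
           "different seed")
  y <- factor(labels[half == 1], levels = c("unstable", "stable"))
  fit <- e1071::svm(x[half == 1, , drop = FALSE], y, kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient: larger score => stable
  sc_train <- as.numeric(x[half == 1, , drop = FALSE] %*% w + b)
  if (mean(sc_train[y == "stable"]) < mean(sc_train[y == "unstable"])) {
    w <- -w; b <- -b
  }
  sc_cal <- as.numeric(x[half == 2, , drop = FALSE] %*% w + b)
  lab_cal <- labels[half == 2]
  gauss <- lapply(c(stable = "stable", unstable = "unstable"), function(cl) {
    s <- sc_cal[lab_cal == cl]
    list(mean = mean(s), var = max(var_floor, mean((s - mean(s))^2)))
  })
  priors <- c(stable = mean(labels == "stable"),
              unstable = mean(labels == "unstable"))
  structure(list(weights = stats::setNames(w, AA20), offset = b,
                 gaussians = gauss, priors = priors, normalize = normalize,
                 cost = cost, seed = seed, var_floor = var_floor),
            class = "calibrated_svm")
}

#' Raw decision scores of a calibrated SVM
#'
#' @param model A `calibrated_svm`.
#' @param sequences Character vector of amino-acid sequences.
#' @return Numeric decision scores (larger = more stable-like).
#' @export
svm_decision_scores <- function(model, sequences) {
  x <- spectrum_matrix(sequences, model$normalize)
  as.numeric(x %*% model$weights + model$offset)
}

#' Class posterior from the calibrated SVM score
#'
#' `P(stable | score)` under the two calibration Gaussians and the class
#' priors: `pi_s N(score; mu_s, var_s) / sum_c pi_c N(score; mu_c, var_c)`.
#'
#' @param score Numeric vector of decision scores.
#' @param model A `calibrated_svm`.
#' @return Posterior probability of the stable class, same length as
#'   `score`.
#' @export
svm_posterior <- function(score, model) {
  g <- model$gaussians
  ds <- model$priors["stable"] *
    stats::dnorm(score, g$stable$mean, sqrt(g$stable$var))
  du <- model$priors["unstable"] *
    stats::dnorm(score, g$unstable$mean, sqrt(g$unstable$var))
  tot <- ds + du
  if (any(tot == 0)) stop("zero total density at a queried score")
  as.numeric(ds / tot)
}
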