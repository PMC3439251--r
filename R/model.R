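# The user-facing fitting surface: stability_model() trains the requested
# model variant (sequence SVM, Bayesian network, or the hybrid of the two)
# and returns a classed object with the usual accessor methods.

#' Bundle raw inputs for model fitting and cross-validation
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param annotations Annotation data.frame (see [read_annotations()]).
#' @param labels Class per protein (`stable` / `unstable`), named by
#'   protein identifier or aligned with `annotations`; may be `NULL` for
#'   prediction-only data.
#' @return List of class `stability_data`.
#' @export
stability_data <- function(sequences, annotations, labels = NULL) {
  if (!is.null(labels) && is.null(names(labels)) && !is.null(annotations))
    names(labels) <- annotations$protein_id
  structure(list(sequences = sequences, annotations = annotations,
                 labels = labels), class = "stability_data")
}

subset_stability_data <- function(data, ids) {
  stability_data(data$sequences[intersect(names(data$sequences), ids)],
                 data$annotations[data$annotations$protein_id %in% ids, ,
                                  drop = FALSE],
                 data$labels[ids])
}

# Build the PWM-set pair (tyrosine / ser-thr) from foreground window lists,
# with a background estimated from the supplied sequences.
train_pwm_sets <- function(pwm_windows, sequences) {
  if (is.null(pwm_windows)) return(NULL)
  bg <- background_frequencies(sequences)
  build_set <- function(kind) {
    wins <- pwm_windows[[kind]]
    if (is.null(wins)) return(NULL)
    if (!is.list(wins)) wins <- list(wins)
    ids <- names(wins) %||% paste0(kind, "_", seq_along(wins))
    pwm_set(kind, mapply(build_pwm, ids, wins,
                         MoreArgs = list(background = bg), SIMPLIFY = FALSE))
  }
  out <- list(tyrosine = build_set("tyrosine"), ser_thr = build_set("ser_thr"))
  if (is.null(out$tyrosine) && is.null(out$ser_thr)) NULL else out
}

# Map a feature data.frame to the evidence columns of a spec.
features_to_evidence <- function(spec, features, labels = NULL) {
  ev <- features[, intersect(names(features), spec$order), drop = FALSE]
  if (!is.null(labels)) ev$stability <- labels == "stable"
  ev
}

#' Fit a protein stability classifier
#'
#' Fits one of three model variants: `"svm"` (a 1-spectrum-kernel sequence
#' SVM whose calibrated score is the only observation), `"bn"` (the
#' Bayesian network over N-terminal degron status, PTM, domain and
#' disorder features, with PWM phosphosite scores as continuous leaves),
#' or `"bn_svm"` (the network extended with the SVM score as a further
#' continuous leaf). Network parameters are learned by EM with the PTM,
#' Domain and Disorder nodes latent.
#'
#' Inputs may be given either as raw data (`sequences`, `annotations`,
#' plus optional `pwm_windows` with foreground phosphosite windows), from
#' which the SVM and PWMs are trained and feature vectors assembled, or as
#' a prebuilt feature data.frame (`features`) from
#' [build_feature_vectors()].
#'
#' @param labels Class per protein: `stable` / `unstable`.
#' @param features Optional feature data.frame (one row per protein).
#' @param sequences,annotations Raw inputs (used when `features` is
#'   `NULL`).
#' @param pwm_windows Optional list with elements `tyrosine` and
#'   `ser_thr`, each a list of foreground-window character vectors (one
#'   per motif).
#' @param variant Model variant.
#' @param thresholds Classification thresholds `(unstable_lt, stable_gt)`.
#' @param control An [em_control()]; its `seed` drives the EM
#'   initialization and the SVM calibration split.
#' @return Object of class `stability_model`.
#' @export
stability_model <- function(labels, features = NULL, sequences = NULL,
                            annotations = NULL, pwm_windows = NULL,
                            variant = c("bn_svm", "bn", "svm"),
                            thresholds = c(0.2, 0.75),
                            control = em_control()) {
  variant <- match.arg(variant)
  cl <- match.call()
  labels <- as.character(labels)
  svm_model <- NULL
  pwms <- NULL
  if (is.null(features)) {
    if (is.null(sequences))
      stop("supply either `features` or raw `sequences` (+ `annotations`)")
    if (is.null(names(labels))) names(labels) <- names(sequences)
    if (variant %in% c("svm", "bn_svm")) {
      ids <- names(sequences)
      svm_model <- train_calibrated_svm(sequences, labels[ids],
                                        seed = control$seed)
    }
    if (variant == "svm" && is.null(annotations)) {
      features <- data.frame(protein_id = names(sequences),
                             svm_score = svm_decision_scores(svm_model, sequences),
                             stringsAsFactors = FALSE)
    } else {
      if (is.null(annotations)) stop("variant '", variant, "' needs annotations")
      pwms <- train_pwm_sets(pwm_windows, sequences)
      features <- build_feature_vectors(sequences, annotations, pwms, svm_model)
    }
    labels <- labels[features$protein_id]
  }
  if (length(labels) != nrow(features))
    stop("labels and features are not aligned")
  if (!all(labels %in% c("stable", "unstable")))
    stop("labels must be 'stable' or 'unstable'")

  spec <- build_model(variant)
  train_ev <- features_to_evidence(spec, features, labels)
  params <- em_train(spec, train_ev, control)
  obj <- structure(list(spec = spec, params = params, variant = variant,
                        thresholds = thresholds, svm = svm_model, pwms = pwms,
                        control = control, features = features,
                        labels = labels,
                        loglik = attr(params, "loglik"),
                        loglik_trace = attr(params, "loglik_trace"),
                        call = cl),
                   class = "stability_model")
  obj$fitted_scores <- predict(obj, type = "prob")
  obj
}

#' Score and classify a set of feature vectors
#'
#' Computes the posterior stability probability of every record by exact
#' inference and partitions the scores at the given thresholds: `unstable`
#' below the first, `stable` above the second, `non-assigned` between.
#'
#' @param spec A `bn_spec`.
#' @param params A `bn_params`.
#' @param vectors Feature data.frame with a `protein_id` column.
#' @param thresholds Numeric pair `(unstable_lt, stable_gt)`,
#'   `unstable_lt < stable_gt`.
#' @return Data.frame `protein_id`, `score`, `class`.
#' @export
predict_proteome <- function(spec, params, vectors, thresholds = c(0.2, 0.75)) {
  ev <- features_to_evidence(spec, vectors)
  scores <- infer_stability(spec, params, ev)
  classify_scores(vectors$protein_id, scores, thresholds)
}

#' @export
predict.stability_model <- function(object, newdata = NULL,
                                    type = c("prob", "class", "table"), ...) {
  type <- match.arg(type)
  features <- if (is.null(newdata)) object$features
  else if (inherits(newdata, "stability_data")) {
    build_feature_vectors(newdata$sequences, newdata$annotations,
                          object$pwms, object$svm)
  } else if (is.data.frame(newdata)) newdata
  else stop("newdata must be a feature data.frame or a stability_data object")
  tab <- predict_proteome(object$spec, object$params, features,
                          object$thresholds)
  switch(type, prob = tab$score, class = tab$class, table = tab)
}

#' @export
print.stability_model <- function(x, ...) {
  cat("Protein stability classifier (variant: ", x$variant, ")\n", sep = "")
  cat("  ", length(x$spec$discrete), " Boolean nodes, ",
      length(x$spec$continuous), " continuous leaves\n", sep = "")
  cat("  trained on ", nrow(x$features), " proteins (",
      sum(x$labels == "stable"), " stable / ",
      sum(x$labels == "unstable"), " unstable)\n", sep = "")
  cat("  final log-likelihood: ", format(x$loglik), " after ",
      attr(x$params, "iterations"), " EM iterations\n", sep = "")
  cat("  thresholds: unstable < ", x$thresholds[1], ", stable > ",
      x$thresholds[2], "\n", sep = "")
  invisible(x)
}

#' @export
summary.stability_model <- function(object, ...) {
  scores <- object$fitted_scores
  auc <- roc_auc(scores, object$labels == "stable")
  mf <- max_f_threshold(scores, object$labels == "stable")
  structure(list(model = object, auc = auc,
                 metrics = threshold_metrics(mf$counts),
                 f_threshold = mf$threshold),
            class = "summary.stability_model")
}

#' @export
print.summary.stability_model <- function(x, ...) {
  print(x$model)
  cat("\nTraining-set performance:\n")
  cat(sprintf("  AUC %.3f | at max-F threshold %.3f: F %.3f, MCC %.3f, ",
              x$auc, x$f_threshold, x$metrics["F"], x$metrics["MCC"]))
  cat(sprintf("sens %.3f, spec %.3f\n", x$metrics["sensitivity"],
              x$metrics["specificity"]))
  invisible(x)
}

#' @export
coef.stability_model <- function(object, ...) object$params

#' @export
logLik.stability_model <- function(object, ...) {
  structure(object$loglik, df = NA_integer_, class = "logLik")
}

#' @export
fitted.stability_model <- function(object, ...) object$fitted_scores

#' @export
residuals.stability_model <- function(object, ...) {
  as.numeric(object$labels == "stable") - object$fitted_scores
}

#' @export
simulate.stability_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  bn_sample(object$spec, object$params, nsim)
}

#' @export
plot.stability_model <- function(x, ...) {
  curve <- roc_curve(x$fitted_scores, x$labels == "stable")
  graphics::plot(curve$fpr, curve$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = paste0("Training ROC (", x$variant, ")"), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(curve)
}

#' Persist a fitted stability model
#'
#' Writes the network document (structure + parameters) together with the
#' calibrated SVM and PWM components needed to score new sequences.
#'
#' @param object A `stability_model`.
#' @param path JSON file path.
#' @return Invisibly, `path`.
#' @export
write_stability_model <- function(object, path) {
  doc <- list(
    variant = object$variant,
    thresholds = object$thresholds,
    svm = if (!is.null(object$svm)) unclass(object$svm),
    meta = list(loglik = object$loglik,
                iterations = attr(object$params, "iterations"),
                seed = object$control$seed))
  tmp <- tempfile(fileext = ".json")
  write_bn_model(object$spec, object$params, tmp, meta = doc$meta)
  net <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  unlink(tmp)
  doc$network <- net
  if (!is.null(object$pwms)) {
    tmp <- tempfile(fileext = ".json")
    write_pwm_sets(object$pwms[!vapply(object$pwms, is.null, logical(1))], tmp)
    doc$pwms <- jsonlite::read_json(tmp, simplifyVector = FALSE)
    unlink(tmp)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted stability model from disk
#'
#' @param path JSON file written by [write_stability_model()].
#' @return A `stability_model` (without the training features).
#' @export
read_stability_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(doc$network, tmp, auto_unbox = TRUE, digits = NA)
  net <- read_bn_model(tmp)
  unlink(tmp)
  svm_model <- NULL
  if (!is.null(doc$svm)) {
    s <- doc$svm
    svm_model <- structure(list(
      weights = stats::setNames(as.numeric(unlist(s$weights)), AA20),
      offset = as.numeric(s$offset),
      gaussians = lapply(s$gaussians, function(g)
        list(mean = as.numeric(g$mean), var = as.numeric(g$var))),
      priors = stats::setNames(as.numeric(unlist(s$priors)),
                               names(s$priors)),
      normalize = isTRUE(s$normalize), cost = as.numeric(s$cost),
      seed = as.integer(s$seed), var_floor = as.numeric(s$var_floor)),
      class = "calibrated_svm")
  }
  pwms <- NULL
  if (!is.null(doc$pwms)) {
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(doc$pwms, tmp, auto_unbox = TRUE, digits = NA)
    pwms <- read_pwm_sets(tmp)
    unlink(tmp)
  }
  structure(list(spec = net$spec, params = net$params,
                 variant = doc$variant,
                 thresholds = as.numeric(unlist(doc$thresholds)),
                 svm = svm_model, pwms = pwms,
                 loglik = as.numeric(net$meta$loglik %||% NA)),
            class = "stability_model")
}
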