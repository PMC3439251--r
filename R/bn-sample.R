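# Ancestral sampling from the network and JSON serialization of the fitted
# model document.

#' Draw ancestral samples from a parameterized network
#'
#' Samples every discrete node in topological order from its conditional
#' given the sampled parents, then draws each continuous leaf from the
#' Gaussian selected by its parent's state. Uses the current RNG state.
#'
#' @param spec A `bn_spec`.
#' @param params A `bn_params`.
#' @param n Number of records.
#' @return Data.frame with one logical column per discrete node and one
#'   numeric column per continuous node.
#' @export
bn_sample <- function(spec, params, n) {
  stopifnot(n >= 1L)
  out <- data.frame(row.names = seq_len(n))
  for (nd in spec$order) {
    if (spec$kind[[nd]] == "gaussian") {
      g <- params$gdt[[nd]]
      idx <- as.integer(out[[spec$parents[[nd]]]]) + 1L
      out[[nd]] <- stats::rnorm(n, g$mean[idx], sqrt(g$var[idx]))
    } else {
      pa <- spec$parents[[nd]]
      pstates <- if (length(pa)) as.matrix(out[, pa, drop = FALSE]) else
        matrix(logical(0), nrow = n, ncol = 0)
      p <- node_prob_true(spec, params, nd, pstates)
      out[[nd]] <- stats::runif(n) < p
    }
  }
  out
}

#' Analytic marginal probability of a Boolean node
#'
#' `P(node = TRUE)` under the joint, computed by exact summation over all
#' discrete assignments (no evidence).
#'
#' @param spec A `bn_spec`.
#' @param params A `bn_params`.
#' @param node Name of a discrete node.
#' @return Scalar probability.
#' @export
bn_marginal <- function(spec, params, node) {
  stopifnot(node %in% spec$discrete)
  ev <- as.data.frame(stats::setNames(rep(list(NA), length(spec$discrete)),
                                      spec$discrete))
  res <- bn_enumerate(spec, params, ev, marginal_nodes = node)
  as.numeric(res$marginals[1, node])
}

#' Serialize / deserialize a network model document
#'
#' The JSON document carries the structure (node kinds, parents, variant),
#' all parameters (CPT rows, noisy-OR inhibition/leak vectors, Gaussian
#' tables) and any training metadata. Parameters round-trip within 1e-12.
#'
#' @param spec A `bn_spec`.
#' @param params A `bn_params`.
#' @param path JSON file path.
#' @param meta Optional named list of metadata (seed, iterations, final
#'   log-likelihood, ...).
#' @return `write_bn_model()` returns `path` invisibly; `read_bn_model()` a
#'   list with `spec`, `params`, `meta`.
#' @export
write_bn_model <- function(spec, params, path, meta = list()) {
  doc <- list(
    variant = spec$variant,
    nodes = lapply(stats::setNames(nm = names(spec$kind)), function(nd)
      list(kind = spec$kind[[nd]], parents = as.list(spec$parents[[nd]]))),
    cpt = params$cpt,
    noisy_or = params$noisy_or,
    gdt = params$gdt,
    meta = meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bn_model
#' @export
read_bn_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- names(doc$nodes)
  kind <- vapply(doc$nodes, function(x) x$kind, character(1))
  names(kind) <- nodes
  parents <- lapply(doc$nodes, function(x) as.character(unlist(x$parents)))
  names(parents) <- nodes
  spec <- bn_spec(kind, parents, variant = doc$variant)
  params <- structure(list(
    cpt = lapply(doc$cpt, function(x) as.numeric(unlist(x))),
    noisy_or = lapply(doc$noisy_or, function(x)
      list(q = as.numeric(unlist(x$q)), c0 = as.numeric(x$c0))),
    gdt = lapply(doc$gdt, function(x)
      list(mean = as.numeric(unlist(x$mean)), var = as.numeric(unlist(x$var))))),
    class = "bn_params")
  list(spec = spec, params = params, meta = doc$meta)
}

#' Threshold a score vector into the three stability classes
#'
#' Scores below `thresholds[1]` are `unstable`, above `thresholds[2]`
#' `stable`, all others `non-assigned`; the three classes partition
#' \[0, 1\] with no gaps or overlaps.
#'
#' @param ids Protein identifiers.
#' @param scores Posterior stability scores in \[0, 1\].
#' @param thresholds Numeric pair `(unstable_lt, stable_gt)` with
#'   `0 <= unstable_lt < stable_gt <= 1`.
#' @return Data.frame with columns `protein_id`, `score`, `class`.
#' @export
classify_scores <- function(ids, scores, thresholds = c(0.2, 0.75)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2],
            thresholds[1] >= 0, thresholds[2] <= 1)
  cls <- ifelse(scores < thresholds[1], "unstable",
                ifelse(scores > thresholds[2], "stable", "non-assigned"))
  data.frame(protein_id = ids, score = scores, class = cls,
             stringsAsFactors = FALSE)
}
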