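# Exact inference in the hybrid network. Queries are answered by summing
# the joint over the unobserved discrete nodes only (records are grouped
# by missingness pattern so the enumeration is vectorized across records);
# continuous evidence enters each term as a Gaussian density weight.

# Normalize a records data.frame against a spec: every discrete node gets a
# logical column (NA = unobserved), every continuous node a numeric column
# (NA = absent).
bn_prepare_data <- function(spec, data) {
  data <- as.data.frame(data)
  n <- max(1L, nrow(data))
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (nd in spec$discrete) {
    v <- if (nd %in% names(data)) data[[nd]] else rep(NA, nrow(data))
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1, NA))) stop("evidence for '", nd, "' outside {0,1,NA}")
      v <- as.logical(v)
    }
    if (!is.logical(v)) stop("evidence for Boolean node '", nd, "' must be logical")
    out[[nd]] <- v
  }
  for (nd in spec$continuous) {
    v <- if (nd %in% names(data)) data[[nd]] else rep(NA_real_, nrow(data))
    if (!is.numeric(v)) stop("evidence for continuous node '", nd, "' must be numeric")
    out[[nd]] <- as.numeric(v)
  }
  out
}

# log density of a Gaussian leaf given parent state (vectorized); absent
# values contribute 0
gdt_logdens <- function(params, node, value, parent_state) {
  g <- params$gdt[[node]]
  idx <- as.integer(parent_state) + 1L
  out <- stats::dnorm(value, g$mean[idx], sqrt(g$var[idx]), log = TRUE)
  out[is.na(value)] <- 0
  out
}

log_bernoulli <- function(p, state) {
  ifelse(state, log(p), log1p(-p))
}

accum_cell_counts <- function(counts, cellidx, w) {
  t <- rowsum(w, cellidx)
  i <- as.integer(rownames(t))
  counts[i] <- counts[i] + t[, 1]
  counts
}

# The shared enumeration engine. Returns per-record log-evidence, posterior
# marginals P(node = TRUE | evidence) for `marginal_nodes`, and (optionally)
# the expected sufficient statistics every parameter's M-step needs.
bn_enumerate <- function(spec, params, data, marginal_nodes = character(0),
                         want_stats = FALSE) {
  data <- bn_prepare_data(spec, data)
  n <- nrow(data)
  loglik <- numeric(n)
  marg <- matrix(NA_real_, n, length(marginal_nodes),
                 dimnames = list(NULL, marginal_nodes))
  stats_counts <- NULL
  stats_gdt <- NULL
  if (want_stats) {
    stats_counts <- lapply(spec$discrete, function(nd)
      numeric(2^(length(spec$parents[[nd]]) + 1L)))
    names(stats_counts) <- spec$discrete
    stats_gdt <- lapply(spec$continuous, function(nd)
      list(sw = c(0, 0), swx = c(0, 0), swx2 = c(0, 0)))
    names(stats_gdt) <- spec$continuous
  }

  na_disc <- is.na(as.matrix(data[, spec$discrete, drop = FALSE]))
  pattern <- apply(na_disc, 1L, function(r) paste(which(r), collapse = ","))
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    ng <- length(rows)
    U <- spec$discrete[na_disc[rows[1], ]]
    A <- pa_config_grid(length(U))        # assignments x |U|
    nA <- nrow(A)
    # flattened (record, assignment) layout, records varying fastest;
    # returns the state of `nd` as a length ng*nA logical vector
    state_flat <- function(nd) {
      if (nd %in% U) rep(A[, match(nd, U)], each = ng)
      else rep(data[[nd]][rows], times = nA)
    }
    dynamic <- vapply(spec$discrete, function(nd)
      nd %in% U || any(spec$parents[[nd]] %in% U), logical(1))
    dyn_cont <- vapply(spec$continuous, function(nd)
      spec$parents[[nd]] %in% U, logical(1))

    static_lp <- numeric(ng)
    for (nd in spec$discrete[!dynamic]) {
      pa <- spec$parents[[nd]]
      pstates <- if (length(pa))
        as.matrix(data[rows, pa, drop = FALSE]) else
        matrix(logical(0), nrow = ng, ncol = 0)
      p <- node_prob_true(spec, params, nd, pstates)
      static_lp <- static_lp + log_bernoulli(p, data[[nd]][rows])
    }
    for (nd in spec$continuous[!dyn_cont]) {
      static_lp <- static_lp +
        gdt_logdens(params, nd, data[[nd]][rows], data[[spec$parents[[nd]]]][rows])
    }

    lw_flat <- rep(static_lp, times = nA)
    for (nd in spec$discrete[dynamic]) {
      pa <- spec$parents[[nd]]
      pstates <- if (length(pa))
        matrix(unlist(lapply(pa, state_flat)), ncol = length(pa)) else
        matrix(logical(0), nrow = ng * nA, ncol = 0)
      p <- node_prob_true(spec, params, nd, pstates)
      lw_flat <- lw_flat + log_bernoulli(p, state_flat(nd))
    }
    for (nd in spec$continuous[dyn_cont]) {
      lw_flat <- lw_flat + gdt_logdens(params, nd,
                                       rep(data[[nd]][rows], times = nA),
                                       state_flat(spec$parents[[nd]]))
    }
    logW <- matrix(lw_flat, ng, nA)
    m <- apply(logW, 1L, max)
    ll <- m + log(rowSums(exp(logW - m)))
    loglik[rows] <- ll
    W <- exp(logW - ll)                  # posterior weight per assignment
    w_flat <- as.vector(W)

    for (nd in intersect(marginal_nodes, spec$discrete)) {
      if (nd %in% U) {
        marg[rows, nd] <- as.numeric(W %*% A[, match(nd, U)])
      } else {
        marg[rows, nd] <- as.numeric(data[[nd]][rows])
      }
    }

    if (want_stats) {
      for (nd in spec$discrete) {
        pa <- spec$parents[[nd]]
        np <- length(pa)
        if (!dynamic[[nd]]) {
          pstates <- if (np) as.matrix(data[rows, pa, drop = FALSE]) else
            matrix(logical(0), nrow = ng, ncol = 0)
          cell <- pa_config_index(pstates) + (2^np) * as.integer(data[[nd]][rows])
          stats_counts[[nd]] <- accum_cell_counts(stats_counts[[nd]], cell,
                                                  rep(1, ng))
        } else {
          pstates <- if (np)
            matrix(unlist(lapply(pa, state_flat)), ncol = np) else
            matrix(logical(0), nrow = ng * nA, ncol = 0)
          cell <- pa_config_index(pstates) + (2^np) * as.integer(state_flat(nd))
          stats_counts[[nd]] <- accum_cell_counts(stats_counts[[nd]], cell,
                                                  w_flat)
        }
      }
      for (nd in spec$continuous) {
        x <- data[[nd]][rows]
        present <- !is.na(x)
        if (!any(present)) next
        pa <- spec$parents[[nd]]
        ptrue <- if (pa %in% U)
          as.numeric(W %*% A[, match(pa, U)]) else as.numeric(data[[pa]][rows])
        for (s in 0:1) {
          wgt <- (if (s == 1) ptrue else 1 - ptrue)[present]
          xs <- x[present]
          stats_gdt[[nd]]$sw[s + 1]   <- stats_gdt[[nd]]$sw[s + 1] + sum(wgt)
          stats_gdt[[nd]]$swx[s + 1]  <- stats_gdt[[nd]]$swx[s + 1] + sum(wgt * xs)
          stats_gdt[[nd]]$swx2[s + 1] <- stats_gdt[[nd]]$swx2[s + 1] + sum(wgt * xs^2)
        }
      }
    }
  }
  list(loglik = loglik, marginals = marg,
       counts = stats_counts, gdt_stats = stats_gdt)
}

#' Joint log-probability of a full assignment
#'
#' Sum of the log conditional factors of every node. All discrete nodes
#' must be assigned; continuous leaves may be absent (`NA` or missing), in
#' which case their factor is omitted, so the exponentiated values summed
#' over all discrete assignments integrate to one.
#'
#' @param spec A `bn_spec`.
#' @param params A `bn_params`.
#' @param assignment Named list or one-row data.frame: logical values for
#'   discrete nodes, numeric for continuous.
#' @return Scalar log probability (log density when continuous evidence is
#'   included).
#' @export
joint_log_prob <- function(spec, params, assignment) {
  assignment <- as.list(assignment)
  missing <- setdiff(spec$discrete, names(assignment))
  if (length(missing) ||
      any(vapply(spec$discrete, function(nd) is.na(assignment[[nd]]), logical(1))))
    stop("assignment must cover every discrete node")
  lp <- 0
  for (nd in spec$discrete) {
    pa <- spec$parents[[nd]]
    pstates <- matrix(vapply(pa, function(p) isTRUE(assignment[[p]]), logical(1)),
                      nrow = 1)
    p <- node_prob_true(spec, params, nd, pstates)
    lp <- lp + log_bernoulli(p, isTRUE(assignment[[nd]]))
  }
  for (nd in spec$continuous) {
    v <- assignment[[nd]]
    if (is.null(v) || is.na(v)) next
    lp <- lp + gdt_logdens(params, nd, v, isTRUE(assignment[[spec$parents[[nd]]]]))
  }
  as.numeric(lp)
}

#' Posterior probability of stability given partial evidence
#'
#' Computes `P(stability = TRUE | evidence)` by exact summation over the
#' unobserved discrete nodes; continuous evidence values contribute their
#' Gaussian density under each parent state. Any subset of nodes may be
#' observed.
#'
#' @param spec A `bn_spec` containing a `stability` node.
#' @param params A `bn_params`.
#' @param evidence Data.frame (one row per query) or named list; logical
#'   columns for Boolean nodes (`NA` = unobserved), numeric for continuous
#'   (`NA` = absent). Columns not matching a node are ignored; the
#'   `stability` node must not be observed.
#' @return Numeric vector of posterior probabilities in (0, 1).
#' @export
infer_stability <- function(spec, params, evidence) {
  if (!"stability" %in% spec$discrete)
    stop("specification has no 'stability' node")
  if (!is.data.frame(evidence)) evidence <- as.data.frame(evidence)
  if ("stability" %in% names(evidence) && any(!is.na(evidence$stability)))
    stop("'stability' must not be observed in a stability query")
  evidence <- evidence[, intersect(names(evidence), spec$order), drop = FALSE]
  res <- bn_enumerate(spec, params, evidence, marginal_nodes = "stability")
  pmin(1, pmax(0, as.numeric(res$marginals[, "stability"])))  # roundoff guard
}

#' Observed-data log-likelihood of a set of records
#'
#' @param spec A `bn_spec`.
#' @param params A `bn_params`.
#' @param data Records data.frame (see [infer_stability()] for the column
#'   conventions; here any node, including `stability`, may be observed).
#' @return Total log-likelihood (sum over records).
#' @export
bn_loglik <- function(spec, params, data) {
  sum(bn_enumerate(spec, params, data)$loglik)
}
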