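# Expectation-maximization for the hybrid network. The E-step runs exact
# inference per record (latent PTM / Domain / Disorder nodes, plus any
# observable left unknown, are summed out); the M-step updates CPT rows
# from expected counts with a Laplace pseudocount, Gaussian tables from
# posterior-weighted moments under a variance floor, and noisy-OR
# parameters by bounded numerical maximization of the expected
# log-likelihood (started from the current values, so every iteration is a
# generalized-EM ascent step).

#' EM control options
#'
#' @param max_iter Maximum number of EM iterations.
#' @param tol Relative change of the observed-data log-likelihood below
#'   which iteration stops.
#' @param pseudocount Laplace pseudocount added to every CPT cell, keeping
#'   all entries strictly inside (0, 1) so no evidence pattern can receive
#'   a degenerate score.
#' @param var_floor Lower bound on every Gaussian-table variance.
#' @param seed Integer seed for the parameter initialization.
#' @param n_starts Number of seeded restarts; the fit with the best final
#'   log-likelihood is kept.
#' @param update_gaussians Update the Gaussian density tables during EM
#'   (`TRUE`), or keep their initial values fixed.
#' @return List of class `em_control`.
#' @export
em_control <- function(max_iter = 200L, tol = 1e-6, pseudocount = 1,
                       var_floor = 1e-6, seed = 1L, n_starts = 1L,
                       update_gaussians = TRUE) {
  stopifnot(max_iter >= 1L, tol > 0, pseudocount > 0, var_floor > 0,
            n_starts >= 1L)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 pseudocount = pseudocount, var_floor = var_floor,
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 update_gaussians = isTRUE(update_gaussians)),
            class = "em_control")
}

# Seeded initialization. Root priors and the Stability CPT are drawn from a
# mild Beta; rows of latent-child CPTs are biased so the child is more
# likely true the more parents are true (anchoring the latent orientation:
# a plain-CPT latent otherwise has an exact label-switching twin optimum).
# Gaussian tables start from observed moments, split by the parent when it
# is observed and by +/- half a standard deviation otherwise.
em_init_params <- function(spec, data, control) {
  data <- bn_prepare_data(spec, data)
  params <- list(cpt = list(), noisy_or = list(), gdt = list())
  for (nd in spec$discrete) {
    pa <- spec$parents[[nd]]
    p <- length(pa)
    if (spec$kind[[nd]] == "noisy_or") {
      params$noisy_or[[nd]] <- list(q = stats::runif(p, 0.15, 0.3), c0 = 0.05)
    } else if (p == 0L || nd == "stability") {
      params$cpt[[nd]] <- stats::rbeta(2^p, 5, 5)
    } else {
      grid <- pa_config_grid(p)
      base <- 0.08 + 0.84 * rowMeans(grid)
      params$cpt[[nd]] <- pmin(0.95, pmax(0.05, base + stats::runif(2^p, -0.03, 0.03)))
    }
  }
  for (nd in spec$continuous) {
    x <- data[[nd]]
    pa <- spec$parents[[nd]]
    pstate <- data[[pa]]
    present <- !is.na(x)
    if (!any(present)) {
      params$gdt[[nd]] <- list(mean = c(0, 0), var = c(1, 1))
      next
    }
    mu <- numeric(2); va <- numeric(2)
    pooled_m <- mean(x[present])
    pooled_s <- stats::sd(x[present])
    if (!is.finite(pooled_s) || pooled_s == 0) pooled_s <- 1
    for (s in 0:1) {
      sel <- present & !is.na(pstate) & (pstate == (s == 1))
      if (sum(sel) >= 2L) {
        mu[s + 1] <- mean(x[sel])
        va[s + 1] <- max(control$var_floor, stats::var(x[sel]))
      } else {
        mu[s + 1] <- pooled_m + (s - 0.5) * pooled_s
        va[s + 1] <- max(control$var_floor, pooled_s^2)
      }
    }
    params$gdt[[nd]] <- list(mean = mu, var = va)
  }
  structure(params, class = "bn_params")
}

# expected complete-data log-likelihood of one noisy-OR child given
# expected counts over parent configurations
noisy_or_expected_ll <- function(theta, grid, n_true, n_false) {
  p <- ncol(grid)
  q <- theta[seq_len(p)]; c0 <- theta[p + 1L]
  pr <- 1 - (1 - c0) * exp(grid %*% log(q))
  pr <- pmin(1 - 1e-12, pmax(1e-12, pr))
  sum(n_true * log(pr) + n_false * log(1 - pr))
}

em_mstep <- function(spec, params, est, control) {
  pc <- control$pseudocount
  for (nd in spec$discrete) {
    p <- length(spec$parents[[nd]])
    counts <- matrix(est$counts[[nd]], ncol = 2)  # configs x (FALSE, TRUE)
    if (spec$kind[[nd]] == "cpt") {
      params$cpt[[nd]] <- (counts[, 2] + pc) / (rowSums(counts) + 2 * pc)
    } else {
      grid <- pa_config_grid(p)
      cur <- c(params$noisy_or[[nd]]$q, params$noisy_or[[nd]]$c0)
      cur <- pmin(1 - 1e-6, pmax(1e-6, cur))
      opt <- stats::optim(cur, noisy_or_expected_ll, grid = grid,
                          n_true = counts[, 2], n_false = counts[, 1],
                          method = "L-BFGS-B",
                          lower = rep(1e-6, p + 1L),
                          upper = rep(1 - 1e-6, p + 1L),
                          control = list(fnscale = -1))
      best <- if (opt$value >= noisy_or_expected_ll(cur, grid, counts[, 2],
                                                    counts[, 1]))
        opt$par else cur
      params$noisy_or[[nd]] <- list(q = best[seq_len(p)], c0 = best[p + 1L])
    }
  }
  if (control$update_gaussians) {
    for (nd in spec$continuous) {
      st <- est$gdt_stats[[nd]]
      g <- params$gdt[[nd]]
      for (s in 1:2) {
        if (st$sw[s] > 1e-8) {
          m <- st$swx[s] / st$sw[s]
          v <- st$swx2[s] / st$sw[s] - m^2
          g$mean[s] <- m
          g$var[s] <- max(control$var_floor, v)
        }
      }
      params$gdt[[nd]] <- g
    }
  }
  params
}

# Dirichlet-smoothing prior term: the quantity EM ascends together with
# the observed-data log-likelihood when CPT rows are updated with a
# pseudocount (MAP EM). Noisy-OR and Gaussian parameters carry no prior.
em_prior_term <- function(spec, params, pc) {
  s <- 0
  for (nd in names(params$cpt)) {
    p <- params$cpt[[nd]]
    s <- s + pc * sum(log(p) + log1p(-p))
  }
  s
}

#' Fit network parameters by expectation-maximization
#'
#' Latent nodes (and any observable recorded as `NA`) are summed out
#' exactly in the E-step; the M-step updates are described in
#' [em_control()]. Because CPT rows are smoothed with a pseudocount, the
#' quantity EM ascends is the penalized (MAP) objective: observed-data
#' log-likelihood plus the Dirichlet smoothing term. That objective is
#' checked to be non-decreasing at every iteration (tolerance 1e-9); a
#' decrease raises an error, since it would indicate a defective M-step.
#' The raw observed-data log-likelihood is recorded alongside.
#'
#' @param spec A `bn_spec`.
#' @param data Records data.frame: logical columns per Boolean node (`NA` =
#'   unobserved; columns for latent nodes may be omitted entirely), numeric
#'   columns per continuous node (`NA` = absent). Supplying values for
#'   latent nodes clamps them, in which case EM collapses to smoothed
#'   counting.
#' @param control An [em_control()] list.
#' @param init Optional `bn_params` to start from (overrides the seeded
#'   initialization; used with `n_starts = 1`).
#' @return A `bn_params` with attributes `loglik` (final observed-data
#'   log-likelihood), `loglik_trace`, `objective_trace` (the penalized
#'   objective, non-decreasing), `iterations`, `seed`.
#' @export
em_train <- function(spec, data, control = em_control(), init = NULL) {
  if ("stability" %in% spec$discrete) {
    st <- if ("stability" %in% names(data)) data$stability else NULL
    if (!is.null(st) && length(unique(st[!is.na(st)])) < 2L)
      stop("training data must contain records of both classes")
  }
  run_one <- function(seed) {
    params <- if (!is.null(init)) init
    else {
      set.seed(seed)
      em_init_params(spec, data, control)
    }
    obj_prev <- -Inf
    trace <- numeric(0)
    obj_trace <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      est <- bn_enumerate(spec, params, data, want_stats = TRUE)
      ll <- sum(est$loglik)
      obj <- ll + em_prior_term(spec, params, control$pseudocount)
      if (obj < obj_prev - 1e-9)
        stop("EM objective decreased (", format(obj_prev), " -> ",
             format(obj), "); M-step is defective")
      trace <- c(trace, ll)
      obj_trace <- c(obj_trace, obj)
      converged <- is.finite(obj_prev) &&
        abs(obj - obj_prev) <= control$tol * (abs(obj_prev) + 1e-12)
      if (converged || iter >= control$max_iter) break
      params <- em_mstep(spec, params, est, control)
      obj_prev <- obj
    }
    attr(params, "loglik") <- trace[length(trace)]
    attr(params, "loglik_trace") <- trace
    attr(params, "objective_trace") <- obj_trace
    attr(params, "iterations") <- iter
    attr(params, "seed") <- seed
    params
  }
  fits <- lapply(control$seed + seq_len(control$n_starts) - 1L, run_one)
  best <- which.max(vapply(fits, attr, numeric(1), "loglik"))
  fits[[best]]
}
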