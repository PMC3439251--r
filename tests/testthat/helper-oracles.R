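# Independent brute-force oracles used to check the implementation paths.

# Exhaustive conditional: enumerate every assignment of the unobserved
# discrete nodes with scalar joint_log_prob calls and sum the consistent
# terms. `evidence` is a named list (logical for discrete, numeric for
# continuous; NA/missing = unobserved).
oracle_infer <- function(spec, params, evidence, query = "stability") {
  obs <- evidence[!vapply(evidence, function(v) is.null(v) || is.na(v),
                          logical(1))]
  free <- setdiff(spec$discrete, names(obs))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(free)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- free
  lw <- numeric(nrow(grid))
  qstate <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    asn <- c(obs, as.list(grid[i, , drop = FALSE]))
    lw[i] <- joint_log_prob(spec, params, asn)
    qstate[i] <- isTRUE(asn[[query]])
  }
  w <- exp(lw - max(lw))
  sum(w[qstate]) / sum(w)
}

# All-windows PWM scan by explicit loops over models, offsets and positions.
oracle_scan <- function(sequence, pwms) {
  if (inherits(pwms, "pwm_model")) pwms <- pwm_set("adhoc", list(pwms))
  chars <- strsplit(sequence, "")[[1]]
  best <- NA_real_
  for (m in pwms$models) {
    w <- m$width
    if (length(chars) < w) next
    for (s in seq_len(length(chars) - w + 1)) {
      win <- chars[s:(s + w - 1)]
      if (any(!win %in% rownames(m$cells))) next
      sc <- 0
      for (j in seq_len(w)) sc <- sc + unname(m$cells[win[j], j])
      if (is.na(best) || sc > best) best <- sc
    }
  }
  best
}

# 1-spectrum kernel by explicit enumeration over all k-mers (k = 1).
oracle_spectrum_kernel <- function(a, b) {
  ka <- strsplit(a, "")[[1]]
  kb <- strsplit(b, "")[[1]]
  alphabet <- stabnet:::AA20
  sum(vapply(alphabet, function(r) sum(ka == r) * sum(kb == r), numeric(1)))
}

# Two-sided Fisher exact p by exhaustive enumeration of all tables with the
# observed margins (hypergeometric sum of tables at most as probable).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)), numeric(1))
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by explicit enumeration of positive-negative pairs with half credit
# for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Max-F threshold by brute force over all observed scores.
oracle_max_f <- function(scores, labels) {
  cand <- sort(unique(scores))
  fs <- vapply(cand, function(t) {
    tp <- sum(labels & scores >= t); fp <- sum(!labels & scores >= t)
    fn <- sum(labels & scores < t)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  list(threshold = cand[which(fs >= max(fs) - 1e-12)[1]], F = max(fs))
}

random_aa_seq <- function(len) {
  paste(sample(stabnet:::AA20, len, replace = TRUE), collapse = "")
}

# tiny GPSP record table around three separated prototypes
tiny_gpsp <- function(n_per_group = 20, alpha = 200, seed = 1) {
  cfg <- fixture_config(n_stable = n_per_group, n_unstable = n_per_group,
                        n_nonassigned = n_per_group, alpha = alpha)
  simulate_gpsp(cfg, seed = seed)
}

# small random all-CPT network for joint/inference checks
random_chain_spec <- function(n_nodes = 6, seed = 1) {
  set.seed(seed)
  nodes <- paste0("x", seq_len(n_nodes))
  parents <- list()
  parents[[nodes[1]]] <- character(0)
  for (i in 2:n_nodes) {
    k <- sample(0:min(2, i - 1), 1)
    parents[[nodes[i]]] <- if (k > 0) sample(nodes[seq_len(i - 1)], k) else character(0)
  }
  kind <- stats::setNames(rep("cpt", n_nodes), nodes)
  bn_spec(kind, parents)
}
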