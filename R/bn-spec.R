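# Network structure and parameterization of the hybrid stability model:
# Boolean nodes with plain CPTs or noisy-OR conditionals, and continuous
# leaves with one Gaussian per state of their single Boolean parent.
#
# The full model (variant "bn_svm") is: Stability conditioned on N-terms,
# PTM, Domain and Disorder; PTM a noisy-OR child of the 4 specific PTM
# flags; Domain a noisy-OR child of the 9 domain flags; Disorder a plain
# CPT child of the 2 high-disorder indicators; the sequence-SVM score a
# Gaussian leaf under Stability and the two PWM scores Gaussian leaves
# under the two phosphorylation flags. Variant "bn" drops the SVM leaf;
# variant "svm" keeps only Stability and the SVM leaf.

#' Default observable schema of the stability network
#'
#' @return Named list: `nterm` (1 name), `ptm_obs` (4), `domain_obs` (9),
#'   `disorder_obs` (2).
#' @export
bn_node_schema <- function() {
  sc <- annotation_schema()
  list(nterm = "n_term_stab", ptm_obs = sc$ptm, domain_obs = sc$domain,
       disorder_obs = c("dis_coils_high", "dis_hot_loops_high"))
}

#' Construct a network specification
#'
#' Low-level constructor: declares each node's kind and parents and checks
#' acyclicity. Continuous (`gaussian`) nodes must be leaves with exactly
#' one Boolean parent.
#'
#' @param kind Named character vector; values `"cpt"`, `"noisy_or"` or
#'   `"gaussian"`.
#' @param parents Named list of parent-name vectors (in fixed order; the
#'   first parent is the least-significant bit of the parent-configuration
#'   index).
#' @param variant Label carried in the object.
#' @return Object of class `bn_spec` with elements `kind`, `parents`,
#'   `variant`, `discrete`, `continuous`, `order` (topological).
#' @export
bn_spec <- function(kind, parents, variant = "custom") {
  nodes <- names(kind)
  stopifnot(!is.null(nodes), setequal(nodes, names(parents)))
  stopifnot(all(kind %in% c("cpt", "noisy_or", "gaussian")))
  for (nd in nodes) {
    if (!all(parents[[nd]] %in% nodes))
      stop("node '", nd, "' has an undeclared parent")
    if (kind[[nd]] == "gaussian" && length(parents[[nd]]) != 1L)
      stop("continuous node '", nd, "' must have exactly one parent")
    if (kind[[nd]] == "noisy_or" && length(parents[[nd]]) < 1L)
      stop("noisy-OR node '", nd, "' needs at least one parent")
  }
  cont <- nodes[kind == "gaussian"]
  if (any(vapply(nodes, function(nd) any(parents[[nd]] %in% cont), logical(1))))
    stop("continuous nodes must be leaves")
  # Kahn's algorithm; cycle detection
  order <- character(0)
  indeg <- vapply(nodes, function(nd) length(parents[[nd]]), integer(1))
  remaining <- nodes
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(nd)
      all(parents[[nd]] %in% order), logical(1))]
    if (!length(free)) stop("network specification contains a cycle")
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  structure(list(kind = kind, parents = parents, variant = variant,
                 discrete = order[kind[order] != "gaussian"],
                 continuous = order[kind[order] == "gaussian"],
                 order = order),
            class = "bn_spec")
}

#' Build a stability-model network specification
#'
#' @param variant `"bn_svm"` (full hybrid model), `"bn"` (no sequence-SVM
#'   leaf) or `"svm"` (Stability plus the sequence-SVM leaf only).
#' @param schema Observable schema, see [bn_node_schema()].
#' @return A `bn_spec`.
#' @export
build_model <- function(variant = c("bn_svm", "bn", "svm"),
                        schema = bn_node_schema()) {
  variant <- match.arg(variant)
  stopifnot(length(schema$ptm_obs) == 4L, length(schema$domain_obs) == 9L,
            length(schema$disorder_obs) == 2L, length(schema$nterm) == 1L)
  if (variant == "svm") {
    kind <- c(stability = "cpt", svm_score = "gaussian")
    parents <- list(stability = character(0), svm_score = "stability")
    return(bn_spec(kind, parents, variant))
  }
  roots <- c(schema$nterm, schema$ptm_obs, schema$domain_obs,
             schema$disorder_obs)
  kind <- c(stats::setNames(rep("cpt", length(roots)), roots),
            ptm = "noisy_or", domain = "noisy_or", disorder = "cpt",
            stability = "cpt",
            pwm_tyr = "gaussian", pwm_ser_thr = "gaussian")
  parents <- c(stats::setNames(rep(list(character(0)), length(roots)), roots),
               list(ptm = schema$ptm_obs, domain = schema$domain_obs,
                    disorder = schema$disorder_obs,
                    stability = c(schema$nterm, "ptm", "domain", "disorder"),
                    pwm_tyr = schema$ptm_obs[1],
                    pwm_ser_thr = schema$ptm_obs[2]))
  if (variant == "bn_svm") {
    kind <- c(kind, svm_score = "gaussian")
    parents <- c(parents, list(svm_score = "stability"))
  }
  bn_spec(kind, parents, variant)
}

#' @export
print.bn_spec <- function(x, ...) {
  cat("Stability network specification (variant: ", x$variant, ")\n", sep = "")
  cat("  ", length(x$discrete), " Boolean nodes, ", length(x$continuous),
      " continuous leaves\n", sep = "")
  invisible(x)
}

# parent-configuration index: first parent = least significant bit,
# FALSE = 0, TRUE = 1; configurations are numbered 1 .. 2^p.
pa_config_index <- function(states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  p <- ncol(states)
  if (p == 0L) return(rep(1L, nrow(states)))
  as.integer(1L + states %*% 2^(seq_len(p) - 1L))
}

# enumerate all 2^p parent configurations as a logical matrix (row i is
# configuration index i)
pa_config_grid <- function(p) {
  if (p == 0L) return(matrix(logical(0), nrow = 1))
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

#' Noisy-OR activation probability
#'
#' `P(child = TRUE | parents) = 1 - (1 - c0) * prod(q_i over active
#' parents)`: each active parent independently fails to activate the child
#' with probability `q_i`; `c0` is the leak activation with all parents
#' inactive.
#'
#' @param params List with `q` (per-parent inhibition probabilities in
#'   (0, 1\]) and `c0` (leak in \[0, 1)).
#' @param parent_states Logical vector (or matrix, one row per case) of
#'   parent states.
#' @return Activation probability per case.
#' @export
noisy_or_prob <- function(params, parent_states) {
  if (is.null(dim(parent_states)))
    parent_states <- matrix(parent_states, nrow = 1)
  stopifnot(ncol(parent_states) == length(params$q))
  inhibit <- exp(parent_states %*% log(params$q))
  as.numeric(1 - (1 - params$c0) * inhibit)
}

# P(node = TRUE | parent states) for any discrete node, vectorized over a
# logical matrix of parent states (columns in spec$parents[[node]] order)
node_prob_true <- function(spec, params, node, parent_states) {
  kind <- spec$kind[[node]]
  if (kind == "cpt") {
    params$cpt[[node]][pa_config_index(parent_states)]
  } else if (kind == "noisy_or") {
    noisy_or_prob(params$noisy_or[[node]], parent_states)
  } else stop("node '", node, "' is not discrete")
}

#' Draw a random parameterization of a network
#'
#' Used for simulation studies and oracle checks: CPT true-probabilities
#' uniform in \[0.05, 0.95\], noisy-OR inhibitions in \[0.2, 0.9\] with leak
#' in \[0.01, 0.2\], Gaussian leaves with unit-scale means and moderate
#' variances. Uses the current RNG state.
#'
#' @param spec A `bn_spec`.
#' @return Object of class `bn_params` (lists `cpt`, `noisy_or`, `gdt`).
#' @export
random_bn_params <- function(spec) {
  params <- list(cpt = list(), noisy_or = list(), gdt = list())
  for (nd in spec$discrete) {
    p <- length(spec$parents[[nd]])
    if (spec$kind[[nd]] == "cpt") {
      params$cpt[[nd]] <- stats::runif(2^p, 0.05, 0.95)
    } else {
      params$noisy_or[[nd]] <- list(q = stats::runif(p, 0.2, 0.9),
                                    c0 = stats::runif(1, 0.01, 0.2))
    }
  }
  for (nd in spec$continuous) {
    params$gdt[[nd]] <- list(mean = c(stats::rnorm(1, -1, 0.5),
                                      stats::rnorm(1, 1, 0.5)),
                             var = stats::runif(2, 0.5, 2))
  }
  structure(params, class = "bn_params")
}
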