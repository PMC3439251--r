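# Derivation of stable / unstable / non-assigned classes from 7-bin
# stability distributions: the protein stability index (PSI), hierarchical
# clustering of bin vectors, and the centroid rule that labels the cut.

#' Protein stability index
#'
#' The bin-weighted mean PSI = sum over i of R_i * i, where R_i is the
#' proportion of cells in FACS bin i (bin 1 holds the least stable, bin 7
#' the most stable sub-population). A continuous stability surrogate in
#' \[1, 7\].
#'
#' @param bins Numeric vector of 7 non-negative proportions summing to 1,
#'   or a matrix/data.frame with 7 such columns (one protein per row).
#' @return A numeric PSI value per protein.
#' @examples
#' compute_psi(c(1, 0, 0, 0, 0, 0, 0))   # 1: all mass in the unstable bin
#' compute_psi(rep(1 / 7, 7))            # 4: uniform distribution
#' @export
compute_psi <- function(bins) {
  if (is.data.frame(bins)) bins <- as.matrix(bins[, gpsp_bin_cols()])
  if (is.null(dim(bins))) bins <- matrix(bins, nrow = 1)
  stopifnot(ncol(bins) == 7L)
  if (any(bins < 0) || any(abs(rowSums(bins) - 1) > 1e-6))
    stop("bins must be non-negative and sum to 1")
  as.numeric(bins %*% (1:7))
}

#' Hierarchically cluster 7-bin stability distributions
#'
#' Agglomerative clustering of the per-protein bin vectors under Euclidean
#' distance with complete linkage, as used to expose the stable and
#' unstable extremes of the distribution space.
#'
#' @param records Data.frame with columns `protein_id` and `R1`..`R7`
#'   (see [read_gpsp_table()]); at least two rows, unique identifiers.
#' @param method Agglomeration method passed to [stats::hclust()].
#' @return An object of class `hclust` whose labels are the protein
#'   identifiers.
#' @export
cluster_distributions <- function(records, method = "complete") {
  stopifnot(nrow(records) >= 2L)
  if (anyDuplicated(records$protein_id))
    stop("duplicate protein identifiers: ",
         records$protein_id[anyDuplicated(records$protein_id)])
  bins <- as.matrix(records[, gpsp_bin_cols()])
  rownames(bins) <- records$protein_id
  stats::hclust(stats::dist(bins, method = "euclidean"), method = method)
}

#' Assign stability class labels from a dendrogram cut
#'
#' Cuts the dendrogram into `k` groups. The group whose centroid carries
#' the largest mean mass in the unstable bins (R1 + R2) is labelled
#' `unstable`; the group with the largest mean mass in the stable bins
#' (R5 + R6 + R7) is labelled `stable`; every other group is
#' `non_assigned`. It is an error for the same group to win both rules.
#'
#' @param dendrogram An `hclust` object from [cluster_distributions()].
#' @param records The data.frame the dendrogram was built from.
#' @param k Number of groups to cut into (>= 3).
#' @return Data.frame with columns `protein_id`, `psi` and `label`
#'   (factor `stable` / `unstable` / `non_assigned`), in input row order.
#' @export
assign_classes <- function(dendrogram, records, k = 3L) {
  stopifnot(inherits(dendrogram, "hclust"), k >= 3L)
  grp <- stats::cutree(dendrogram, k = k)
  grp <- grp[records$protein_id]          # align with input order
  if (anyNA(grp)) stop("dendrogram labels do not match record identifiers")
  sizes <- tabulate(grp, nbins = k)
  if (any(sizes == 0)) stop("degenerate cut: a group is empty")
  bins <- as.matrix(records[, gpsp_bin_cols()])
  centroid <- function(g) colMeans(bins[grp == g, , drop = FALSE])
  cents <- t(vapply(seq_len(k), centroid, numeric(7)))
  g_unstable <- which.max(cents[, 1] + cents[, 2])
  g_stable <- which.max(cents[, 5] + cents[, 6] + cents[, 7])
  if (g_unstable == g_stable)
    stop("class assignment failed: the same group maximizes both the ",
         "unstable (R1+R2) and stable (R5-R7) centroid mass")
  label <- rep("non_assigned", nrow(records))
  label[grp == g_unstable] <- "unstable"
  label[grp == g_stable] <- "stable"
  data.frame(protein_id = records$protein_id,
             psi = compute_psi(bins),
             label = factor(label, levels = c("unstable", "non_assigned", "stable")),
             stringsAsFactors = FALSE)
}
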