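# Uniform-kernel nonparametric mode clustering.
#
# Density is estimated with a uniform (indicator) kernel on the Euclidean
# ball of radius R; each observation follows the strictly denser neighbour
# of maximal density within R, and the basins of the resulting strict-ascent
# chains are the clusters. Clusters smaller than CK are dissolved, smallest
# first, their members reassigned to the nearest remaining cluster.

#' Uniform-kernel density estimate
#'
#' \code{density(i) = m(i) / (n * V_R)} where \code{m(i)} counts the observations
#' (including i itself) within Euclidean distance `R` of row i, and `V_R` is
#' the volume of the d-ball of radius `R`. Self-inclusion keeps all
#' densities strictly positive.
#'
#' @param x Numeric matrix (rows = days, columns = standardized variables)
#'   or an [fw_features()] object.
#' @param r Kernel radius, in standardized units; \code{r > 0}.
#' @return Numeric vector of per-row densities.
#' @export
uniform_kernel_density <- function(x, r) {
  x <- as_values_matrix(x)
  stopifnot(r > 0, nrow(x) >= 1)
  if (!all(is.finite(x))) abort("non-finite rows in feature matrix")
  d <- ncol(x)
  m <- ukd_counts_cpp(x, r)
  vol <- pi^(d / 2) * r^d / gamma(d / 2 + 1)
  m / (nrow(x) * vol)
}

#' Assign observations to density modes
#'
#' Each observation points to the eligible neighbour within radius `r` of
#' maximal density, ties broken by lowest row index. A neighbour is
#' eligible when strictly denser, or equally dense with a lower row index
#' (so plateaus of tied density chain deterministically toward their
#' lowest-index member and the ascent stays acyclic). Observations with no
#' eligible neighbour are modes; every observation is labeled by the mode
#' its ascent chain reaches.
#'
#' @param x Matrix or [fw_features()] object.
#' @param densities Densities computed with the same `r`
#'   (see [uniform_kernel_density()]).
#' @param r Kernel radius.
#' @return A list: `labels` (integer cluster ids 1..k, numbered by ascending
#'   mode row index), `modes` (row indices of the modes, one per cluster).
#' @export
assign_modes <- function(x, densities, r) {
  x <- as_values_matrix(x)
  stopifnot(length(densities) == nrow(x), r > 0)
  res <- mode_assign_cpp(x, densities, r)
  modes <- sort(unique(res$root))
  labels <- match(res$root, modes)
  list(labels = labels, modes = modes)
}

#' Enforce a minimum cluster size
#'
#' Dissolves clusters with fewer than `ck` members, smallest first (ties by
#' lower mode row index). Each member of a dissolved cluster is reassigned
#' to the cluster of its nearest (Euclidean) neighbour among days still
#' belonging to a remaining cluster; when no cluster remains, members become
#' unassigned (label 0). Repeats until every remaining cluster has at least
#' `ck` members or none remain.
#'
#' @param labels Integer labels from [assign_modes()].
#' @param modes Mode row indices from [assign_modes()].
#' @param x Matrix or [fw_features()] object.
#' @param ck Minimum cluster size.
#' @return A list: `labels` (0 = unassigned; surviving clusters renumbered
#'   1..k by ascending mode index), `modes` (surviving mode row indices),
#'   `dissolved` (number of clusters dissolved).
#' @export
enforce_min_cluster_size <- function(labels, modes, x, ck) {
  x <- as_values_matrix(x)
  stopifnot(length(labels) == nrow(x), ck >= 1)
  lab <- labels
  max_id <- max(c(0L, labels))
  mode_vec <- rep(NA_integer_, max_id)
  mode_vec[sort(unique(labels[labels > 0]))] <- modes
  dissolved <- 0L
  repeat {
    counts <- tabulate(lab, nbins = max_id)
    live <- which(counts > 0)
    if (length(live) == 0) break
    small <- live[counts[live] < ck]
    if (length(small) == 0) break
    # smallest first; ties by lower mode row index
    ord <- order(counts[small], mode_vec[small])
    victim <- small[ord[1]]
    members <- which(lab == victim)
    lab[members] <- 0L
    dissolved <- dissolved + 1L
    remaining <- which(lab > 0)
    if (length(remaining) > 0) {
      nn <- nearest_candidate_cpp(x, as.integer(members),
                                  as.integer(remaining))
      lab[members] <- lab[remaining[nn]]
    }
  }
  live <- sort(unique(lab[lab > 0]))
  new_modes <- mode_vec[live]
  ord <- order(new_modes)
  relabel <- setNames(seq_along(live), live[ord])
  out <- integer(length(lab))
  keep <- lab > 0
  out[keep] <- relabel[as.character(lab[keep])]
  list(labels = out, modes = new_modes[ord], dissolved = dissolved)
}

#' Mode-cluster a feature matrix
#'
#' The full clustering engine: uniform-kernel density estimation, strict-
#' ascent mode assignment and minimum-cluster-size enforcement, at a single
#' kernel radius. Deterministic for fixed input.
#'
#' @param features An [fw_features()] object (or bare matrix).
#' @param r Kernel radius in standardized units.
#' @param ck Minimum cluster size (default 50).
#' @return An object of class `fw_cluster`: list with `labels` (0 =
#'   unassigned), `densities`, `modes` (row indices), `k`, `r`, `ck`,
#'   `dissolved`, `n`, and `date` (when `features` carries dates).
#' @export
#' @examples
#' x <- matrix(c(0, 1, 2, 10, 10.5, 11), ncol = 1)
#' mode_cluster(x, r = 1.5, ck = 1)$k
mode_cluster <- function(features, r, ck = 50) {
  x <- as_values_matrix(features)
  dens <- uniform_kernel_density(x, r)
  asg <- assign_modes(x, dens, r)
  enf <- enforce_min_cluster_size(asg$labels, asg$modes, x, ck)
  structure(list(labels = enf$labels, densities = dens, modes = enf$modes,
                 k = length(enf$modes), r = r, ck = ck,
                 dissolved = enf$dissolved, n = nrow(x),
                 date = if (inherits(features, "fw_features"))
                   feature_dates(features) else NULL),
            class = "fw_cluster")
}

#' @export
print.fw_cluster <- function(x, ...) {
  cat("<fw_cluster> k = ", x$k, ", R = ", format(x$r), ", CK = ", x$ck,
      ", n = ", x$n, " (", sum(x$labels == 0), " unassigned, ",
      x$dissolved, " clusters dissolved)\n", sep = "")
  invisible(x)
}

#' @describeIn mode_cluster Per-day tibble of cluster assignments:
#'   `date` (if known), `cluster` (0 = unassigned) and `density`.
#' @param x An `fw_cluster` object.
#' @param ... Unused.
#' @export
tidy.fw_cluster <- function(x, ...) {
  out <- tibble(cluster = x$labels, density = x$densities)
  if (!is.null(x$date)) out <- bind_cols(tibble(date = x$date), out)
  out
}

#' @describeIn mode_cluster One-row model summary.
#' @export
glance.fw_cluster <- function(x, ...) {
  tibble(k = x$k, r = x$r, ck = x$ck, n = x$n,
         n_unassigned = sum(x$labels == 0), dissolved = x$dissolved)
}

as_values_matrix <- function(x) {
  if (inherits(x, "fw_features")) return(feature_matrix(x))
  if (is.data.frame(x)) return(as.matrix(x))
  stopifnot(is.matrix(x), is.numeric(x))
  x
}
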