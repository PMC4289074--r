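# Stability validation: random day-level partitioning with re-analysis.

#' Partition-stability check of a cluster model
#'
#' Randomly partitions the days into `k_parts` disjoint parts, reruns the
#' clustering (and, where possible, the discriminant step) on each part at
#' the same radius, and scores agreement between each part's labels and the
#' full-data model restricted to that part's days, using the adjusted Rand
#' index (days unassigned in either labeling are excluded). The minimum
#' cluster size is scaled to the part fraction (`max(5, ck / k_parts)`) so
#' parts are judged by the same per-day standard as the full data.
#'
#' @param features An [fw_features()] object.
#' @param r Kernel radius of the model being validated.
#' @param ck Full-data minimum cluster size (default 50).
#' @param k_parts Number of parts (default 4).
#' @param seed RNG seed for the partition (required).
#' @param full_model Optional prefitted `fw_cluster` at (`r`, `ck`);
#'   refitted when omitted.
#' @return A list: `parts` (tibble: `part`, `n_days`, `k`, `ari`,
#'   `mean_r2`), `mean_ari`, `min_ari`, and `assignment` (per-day part
#'   index).
#' @export
partition_stability <- function(features, r, ck = 50, k_parts = 4, seed,
                                full_model = NULL) {
  if (missing(seed)) abort("partition_stability requires a seed")
  stopifnot(k_parts >= 1)
  n <- nrow(features)
  full_model <- full_model %||% mode_cluster(features, r, ck)
  part_ck <- max(5, ceiling(ck / k_parts))
  assignment <- with_seed(seed, sample(rep_len(seq_len(k_parts), n)))
  rows <- lapply(seq_len(k_parts), function(p) {
    idx <- which(assignment == p)
    if (length(idx) < 2 * part_ck) {
      warn(sprintf("part %d too small after CK scaling; skipped", p))
      return(tibble(part = p, n_days = length(idx), k = NA_integer_,
                    ari = NA_real_, mean_r2 = NA_real_))
    }
    sub <- subset_features(features, idx)
    m <- mode_cluster(sub, r, part_ck)
    mr2 <- tryCatch(mean(per_variable_r2(sub, m$labels)),
                    error = function(e) NA_real_)
    tibble(part = p, n_days = length(idx), k = m$k,
           ari = ari_labels(m$labels, full_model$labels[idx]),
           mean_r2 = mr2)
  })
  parts <- list_rbind(rows)
  list(parts = parts, mean_ari = mean(parts$ari, na.rm = TRUE),
       min_ari = suppressWarnings(min(parts$ari, na.rm = TRUE)),
       assignment = assignment)
}

# Row-subset an fw_features object, keeping its pipeline attributes (the
# subset stays on the full-data standardization so labels are comparable).
subset_features <- function(features, idx) {
  out <- as.data.frame(features)[idx, ]
  raw <- as.data.frame(attr(features, "raw"))[idx, ]
  structure(as_tibble(out),
            class = class(features),
            raw = as_tibble(raw),
            variables = feature_vars(features),
            log_vars = attr(features, "log_vars"),
            center = attr(features, "center"),
            scale = attr(features, "scale"),
            dropped = attr(features, "dropped"))
}
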