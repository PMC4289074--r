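# Brute-force oracles and small fixtures shared across tests. The oracles
# deliberately re-derive every quantity from first principles (distance
# matrices, explicit loops) independently of the package's C++ engine.

# Small weather tibble with three blocky seasons, for io/feature tests.
make_weather_tbl <- function(n = 90, seed = 1, start = "2000-01-01") {
  withr::with_seed(seed, {
    tibble::tibble(
      date = seq(as.Date(start), by = "day", length.out = n),
      rh = rnorm(n, rep(c(60, 80, 70), each = 30, length.out = n), 3),
      temp = rnorm(n, rep(c(15, 25, 20), each = 30, length.out = n), 2),
      solar = rnorm(n, rep(c(0.1, 0.3, 0.2), each = 30, length.out = n),
                    0.04),
      wind = rnorm(n, 8, 3),
      soil = exp(rnorm(n, rep(c(3, 2, 2.5), each = 30, length.out = n),
                       0.3)),
      rain = rgamma(n, 0.5, 2)
    )
  })
}

# fw_features from a plain matrix: wraps columns into a weather-shaped
# tibble with synthetic dates and no transform (columns already arbitrary).
features_from_matrix <- function(X, log_vars = character()) {
  colnames(X) <- colnames(X) %||% paste0("v", seq_len(ncol(X)))
  df <- tibble::as_tibble(X)
  df$date <- seq(as.Date("2000-01-01"), by = "day", length.out = nrow(X))
  fw_features(df, variables = colnames(X), log_vars = log_vars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) uniform-kernel density via a full distance matrix.
oracle_density <- function(X, R) {
  D <- as.matrix(dist(X))
  m <- unname(rowSums(D <= R))
  d <- ncol(X)
  m / (nrow(X) * pi^(d / 2) * R^d / gamma(d / 2 + 1))
}

# Independent full mode-clustering implementation: hill climbing to the
# eligible (strictly denser, or equally dense with lower index) neighbour
# of maximal density, then iterative dissolution of clusters below CK with
# nearest-labeled-neighbour reassignment.
oracle_mode_cluster <- function(X, R, CK) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  dens <- oracle_density(X, R)
  parent <- integer(n)
  for (i in seq_len(n)) {
    cand <- setdiff(which(D[i, ] <= R), i)
    cand <- cand[dens[cand] > dens[i] |
                   (dens[cand] == dens[i] & cand < i)]
    parent[i] <- if (length(cand) == 0) i else {
      top <- cand[dens[cand] == max(dens[cand])]
      min(top)
    }
  }
  root <- vapply(seq_len(n), function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    r
  }, integer(1))
  modes <- sort(unique(root))
  lab <- match(root, modes)
  mode_of <- modes
  repeat {
    counts <- tabulate(lab, nbins = length(modes))
    live <- which(counts > 0)
    small <- live[counts[live] < CK]
    if (length(small) == 0 || length(live) == 0) break
    ord <- order(counts[small], mode_of[small])
    victim <- small[ord[1]]
    members <- which(lab == victim)
    lab[members] <- 0L
    remaining <- which(lab > 0)
    if (length(remaining) > 0) {
      for (m in members) {
        lab[m] <- lab[remaining[which.min(D[m, remaining])]]
      }
    }
  }
  live <- sort(unique(lab[lab > 0]))
  relabel <- match(lab, live[order(mode_of[live])])
  relabel[is.na(relabel)] <- 0L
  list(labels = relabel, densities = dens)
}

# Are two labelings the same partition (up to renaming), treating 0/0 as
# matching unassigned?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == 0) == (b == 0))) return(FALSE)
  keep <- a > 0
  if (!any(keep)) return(TRUE)
  tab <- table(a[keep], b[keep])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Agreement of roles with generator truth after mapping labels to roles.
role_agreement <- function(labels, roles, truth) {
  mapped <- unname(roles[as.character(labels)])
  mean(mapped == truth, na.rm = TRUE)
}
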