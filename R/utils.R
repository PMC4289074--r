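# Shared small helpers.

#' Round half away from zero
#'
#' Integer rounding in which .5 always moves away from zero (the convention
#' used for the printed percentage shares in fire-regime summary tables),
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of whole numbers.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Percentage shares of a vector, integer-rounded
#'
#' Shares of `x` relative to its total, on the 0--100 scale, rounded
#' half-away-from-zero to whole percentages.
#'
#' @param x Non-negative numeric vector.
#' @return Numeric vector of whole-number percentages (may sum to
#'   100 +/- 1 due to rounding).
#' @export
#' @examples
#' percent_shares(c(13, 3, 43)) # 22 5 73
percent_shares <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0))
  tot <- sum(x)
  if (tot == 0) return(rep(0, length(x)))
  round_half_away(100 * x / tot)
}

# Day of year folded so Feb 29 maps onto day 59 and later days match
# non-leap years (used for circular day-of-year statistics).
doy_folded <- function(date) {
  d <- lubridate::yday(date)
  leap <- lubridate::leap_year(date)
  d[leap & d >= 60] <- d[leap & d >= 60] - 1L
  d
}

# Adjusted Rand index between two labelings, dropping positions unassigned
# (0 or NA) in either.
ari_labels <- function(a, b) {
  keep <- !is.na(a) & !is.na(b) & a != 0 & b != 0
  if (!any(keep)) return(NA_real_)
  mclust::adjustedRandIndex(a[keep], b[keep])
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) abort("a seed is required (reproducibility is mandatory)")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
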