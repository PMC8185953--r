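## Gene-expression-pattern similarity measures.
##
## The detector weights interactions with the Jackknife coexpression
## correlation (GEC): the minimum Pearson correlation over all
## leave-one-condition-out versions of the two profiles. Taking the minimum
## deprotects the score against a single shared outlier condition inflating
## an otherwise weak agreement. Euclidean distance and cosine similarity are
## provided as alternative measures but are not wired into edge weighting
## unless explicitly requested.

.check_pair <- function(u, v, min_n = 1L) {
  if (!is.numeric(u) || !is.numeric(v))
    stop("expression profiles must be numeric vectors", call. = FALSE)
  if (length(u) != length(v))
    stop(sprintf("profile lengths differ (%d vs %d)", length(u), length(v)),
         call. = FALSE)
  if (length(u) < min_n)
    stop(sprintf("profiles must have at least %d conditions, got %d",
                 min_n, length(u)), call. = FALSE)
  if (anyNA(u) || anyNA(v) || any(!is.finite(u)) || any(!is.finite(v)))
    stop("expression profiles must be finite and complete (no NA)",
         call. = FALSE)
  invisible(TRUE)
}

#' Euclidean distance between two expression profiles
#'
#' @param u,v Numeric vectors of equal length (expression values over the
#'   same ordered conditions).
#' @return Non-negative scalar; zero iff `u == v`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(u, v) {
  .check_pair(u, v, 1L)
  sqrt(sum((u - v)^2))
}

#' Standardize an expression profile to mean zero and unit variance
#'
#' Uses the population variance convention (divide by `n`); the choice is
#' immaterial for any correlation-based measure and only rescales the
#' Euclidean path.
#'
#' @param u Numeric vector, length >= 2, not constant.
#' @return Numeric vector with mean 0 and population variance 1.
#' @export
standardize_profile <- function(u) {
  if (!is.numeric(u) || length(u) < 2)
    stop("need a numeric profile of length >= 2", call. = FALSE)
  if (anyNA(u) || any(!is.finite(u)))
    stop("expression profiles must be finite and complete (no NA)",
         call. = FALSE)
  ctr <- u - mean(u)
  s2 <- mean(ctr^2)
  if (s2 <= 1e-24 * max(mean(u^2), 1))
    stop("cannot standardize a constant profile (zero variance)",
         call. = FALSE)
  ctr / sqrt(s2)
}

#' Cosine similarity between two expression profiles
#'
#' @inheritParams euclidean_distance
#' @return Scalar in \[-1, 1\]; 1 for parallel profiles.
#' @export
cosine_similarity <- function(u, v) {
  .check_pair(u, v, 1L)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for an all-zero profile", call. = FALSE)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Pearson correlation between two expression profiles
#'
#' Degenerate inputs (either profile constant) return 0 rather than failing:
#' the Jackknife sweep can legitimately hit flat leave-one-out vectors, and a
#' profile with no variation carries no coexpression signal.
#'
#' @inheritParams euclidean_distance
#' @return Scalar in \[-1, 1\]; 0 when either profile is constant.
#' @export
pearson_cor <- function(u, v) {
  .check_pair(u, v, 2L)
  if (.is_constant(u) || .is_constant(v)) return(0)
  min(1, max(-1, stats::cor(u, v)))
}

.is_constant <- function(x) {
  ctr <- x - mean(x)
  sum(ctr^2) <= 1e-24 * length(x) * max(mean(x^2), 1e-300)
}

#' Jackknife coexpression correlation (GEC)
#'
#' The minimum over `j = 1..n` of the Pearson correlation between the two
#' profiles with condition `j` deleted. Robust to single-outlier inflation:
#' if one shared extreme condition drives the agreement, the sweep that
#' removes it exposes the true (lower) correlation.
#'
#' Leave-one-out correlations are computed by down-dating the five running
#' sums of the full profiles, so the sweep costs O(n) rather than O(n^2).
#' Any leave-one-out pair with a constant member contributes 0 (no linear
#' signal), matching [pearson_cor()]'s degenerate convention.
#'
#' @inheritParams euclidean_distance
#' @return Scalar in \[-1, 1\], never exceeding any individual leave-one-out
#'   Pearson correlation.
#' @examples
#' # an outlier-inflated pair: full Pearson is high, GEC is not fooled
#' u <- c(1, 2, 3, 4, 100); v <- c(1, 2, 3, 4, 5)
#' cor(u, v)
#' jackknife_gec(u, v)
#' @export
jackknife_gec <- function(u, v) {
  .check_pair(u, v, 4L)
  min(leave_one_out_pearson(u, v))
}

#' All leave-one-out Pearson correlations of a profile pair
#'
#' @inheritParams euclidean_distance
#' @return Numeric vector of length `n`; element `j` is the Pearson
#'   correlation with condition `j` removed (0 where degenerate).
#' @export
leave_one_out_pearson <- function(u, v) {
  .check_pair(u, v, 4L)
  # centre first: the correlation is shift-invariant and centring keeps the
  # down-dated sums free of catastrophic cancellation for offset-heavy data
  u <- u - mean(u)
  v <- v - mean(v)
  n <- length(u)
  m <- n - 1
  su  <- sum(u)  - u
  sv  <- sum(v)  - v
  suu <- sum(u^2) - u^2
  svv <- sum(v^2) - v^2
  suv <- sum(u * v) - u * v
  num  <- m * suv - su * sv
  den2u <- m * suu - su^2
  den2v <- m * svv - sv^2
  # down-dated differences carry ~eps-relative rounding noise, so the
  # zero-variance test is relative at 1e-12, far below any usable signal
  degen <- den2u <= 1e-12 * m * pmax(suu, 1e-300) |
           den2v <= 1e-12 * m * pmax(svv, 1e-300)
  r <- numeric(n)
  ok <- !degen
  r[ok] <- num[ok] / sqrt(den2u[ok] * den2v[ok])
  pmin(1, pmax(-1, r))
}
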