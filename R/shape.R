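#' Default pool-size grid for shape analysis
#'
#' Log-ish spacing from the smallest possible pool (`n = 2`) up to `1e5`,
#' dense at small `n` where the dip of convex-down regimes lives and sparse
#' at large `n` where the curves are smooth.
#'
#' @return Increasing integer vector.
#' @export
default_n_grid <- function() {
  c(2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64, 100, 200, 500, 1000, 1e4, 1e5)
}

#' Normalized mean occupation time as a function of pool size
#'
#' The very-low-dose-rate approximation factorizes as
#' `T_abs = (1 / lambda) * f(n)` with `f(n) = 1 / (n * pi_1(n))`. `f` is the
#' dose-rate-free, dimensionless profile of `T_abs` against pool size,
#' normalized so that the neutral (all-costs-equal) case is identically 1:
#' values above 1 mean competition delays occupation, below 1 that it
#' accelerates it. `log_normalized_absorption_time()` returns `log f(n)`,
#' which stays finite for dominant regimes at `n = 1e5` where `f` itself
#' overflows double precision.
#'
#' @inheritParams fixation_probability
#' @return Numeric scalar (`f(n)`, or its log).
#' @export
normalized_absorption_time <- function(n, cm) {
  exp(log_normalized_absorption_time(n, cm))
}

#' @rdname normalized_absorption_time
#' @export
log_normalized_absorption_time <- function(n, cm) {
  -log(n) - log_fixation_probability(n, cm)
}

#' Classify the shape of T_abs against pool size
#'
#' Evaluates `log f(n)` ([log_normalized_absorption_time()]) over an
#' increasing grid of pool sizes and classifies the sign pattern of
#' successive differences:
#' * `constant` - all differences negligible (the neutral case).
#' * `monotone_decreasing` / `monotone_increasing` - all non-negligible
#'   differences share one sign.
#' * `convex_down` - a run of decreases followed by a run of increases
#'   (exactly one sign change).
#' * `other` - any other pattern, reported loudly rather than forced into a
#'   category.
#'
#' Differences with `|log f(n2) - log f(n1)| <= tol` count as zero;
#' `tol = 1e-9` on the log scale is a ~1e-9 relative tolerance on `f`, so
#' the neutral case classifies as `constant` rather than noise-monotone.
#'
#' @inheritParams fixation_probability
#' @param n_grid strictly increasing vector of pool sizes, length >= 3,
#'   minimum >= 2. Defaults to [default_n_grid()].
#' @param tol tolerance on log-scale differences treated as zero.
#' @return Character scalar shape label.
#' @examples
#' classify_shape(cost_matrix(1, 1, 0.8, 0.8))   # monotone_decreasing
#' classify_shape(cost_matrix(1, 1.5, 1.2, 0.5)) # convex_down
#' @export
classify_shape <- function(cm, n_grid = default_n_grid(), tol = 1e-9) {
  cm <- validate_cost_matrix(cm)
  if (length(n_grid) < 3) {
    stop("n_grid must contain at least 3 pool sizes", call. = FALSE)
  }
  if (any(diff(n_grid) <= 0) || min(n_grid) < 2) {
    stop("n_grid must be strictly increasing with minimum >= 2",
         call. = FALSE)
  }
  lf <- vapply(n_grid, log_normalized_absorption_time, numeric(1), cm = cm)
  d <- diff(lf)
  sgn <- sign(d)
  sgn[abs(d) <= tol] <- 0
  nz <- sgn[sgn != 0]
  if (length(nz) == 0) return("constant")
  if (all(nz < 0)) return("monotone_decreasing")
  if (all(nz > 0)) return("monotone_increasing")
  flips <- which(diff(nz) != 0)
  if (length(flips) == 1 && nz[1] < 0) return("convex_down")
  "other"
}

#' Does T_abs decrease between the two smallest pools?
#'
#' `TRUE` iff `f(3) < f(2)`, the operational definition of the small-pool
#' boundary in the shape diagram: inside it, enlarging the pool from 2 to 3
#' already shortens the (normalized) occupation time.
#'
#' @inheritParams fixation_probability
#' @return Logical scalar.
#' @export
small_n_decrease <- function(cm) {
  log_normalized_absorption_time(3, cm) <
    log_normalized_absorption_time(2, cm)
}

#' Does T_abs increase at very large pool sizes?
#'
#' `TRUE` iff `f(n_large) > f(n_large / 2)` evaluated in log space, the
#' operational definition of the large-pool boundary: inside it the curve
#' has turned upward by `n_large`. The default `n_large = 1e5` is reachable
#' without overflow thanks to the log-space evaluator.
#'
#' @inheritParams fixation_probability
#' @param n_large the large pool size probed.
#' @return Logical scalar.
#' @export
large_n_increase <- function(cm, n_large = 1e5) {
  check_pool_size(n_large)
  log_normalized_absorption_time(n_large, cm) >
    log_normalized_absorption_time(round(n_large / 2), cm)
}
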