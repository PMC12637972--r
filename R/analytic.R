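logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fixation probability of a single damaged cell (radiation off)
#'
#' Probability that, starting from one damaged cell in an otherwise intact
#' pool and with no further radiation hits, the damaged lineage occupies the
#' whole pool rather than going extinct. For the cost-driven birth-death
#' chain this is the classic ratio form
#' \deqn{\pi_1 = \left(1 + \sum_{j=1}^{n-1} \prod_{k=1}^{j} G_k / F_k\right)^{-1}}
#' with `F_k`, `G_k` the expected costs of intact and damaged cells
#' ([expected_cost_intact()], [expected_cost_damaged()]).
#'
#' The sum is evaluated in log space (cumulative sums of `log(G_k / F_k)`
#' aggregated by log-sum-exp), so pool sizes up to `1e5` and strongly
#' dominant regimes are handled without overflow. With all costs equal the
#' result is exactly `1/n`. `log_fixation_probability()` returns
#' `log(pi_1)`, which stays finite even when `pi_1` underflows.
#'
#' @param n pool size, `n >= 2`.
#' @param cm a [cost_matrix()].
#' @return `fixation_probability()`: numeric scalar in (0, 1].
#' @examples
#' fixation_probability(20, cost_matrix())          # 1/20
#' fixation_probability(10, cost_matrix(1, 1, 0.8, 0.8))
#' @export
fixation_probability <- function(n, cm) {
  exp(log_fixation_probability(n, cm))
}

#' @rdname fixation_probability
#' @export
log_fixation_probability <- function(n, cm) {
  cm <- validate_cost_matrix(cm)
  check_pool_size(n)
  k <- seq_len(n - 1)
  lr <- log(expected_cost_damaged(k, n, cm)) -
    log(expected_cost_intact(k, n, cm))
  -logsumexp(c(0, cumsum(lr)))
}

#' Fixation probability by dense linear solve (independent oracle)
#'
#' Solves the first-step equations for the probability of hitting `k = n`
#' before `k = 0` from `k = 1` in the radiation-free birth-death chain,
#' using the one-step probabilities from [transition_probabilities()] and a
#' tridiagonal (Thomas) solve carried out in extended precision with
#' iterative refinement - strongly selected matrices make the system badly
#' conditioned in double precision. Exists as an independent numerical route
#' to the same quantity as [fixation_probability()]; intended for `n <= 200`.
#'
#' @inheritParams fixation_probability
#' @return Numeric scalar in (0, 1].
#' @export
fixation_probability_bruteforce <- function(n, cm) {
  cm <- validate_cost_matrix(cm)
  check_pool_size(n)
  if (n > 200) stop("dense solve intended for n <= 200", call. = FALSE)
  tp <- transition_probabilities(seq_len(n - 1), n, cm)
  cpp_hitting_probability(tp$up, tp$down)
}

#' Very-low-dose-rate approximation of the mean occupation time
#'
#' When `lambda` is small enough that hits are rare compared with sweep
#' times, absorption is dominated by waiting for the first hit whose lineage
#' fixes: hits arrive at rate `n * lambda` per cell cycle and each fixes
#' with probability `pi_1`, giving
#' \deqn{T_{abs} \approx \frac{1}{n \lambda \pi_1}}
#' in cell cycles. Exactly proportional to `1 / lambda`; in the neutral case
#' `pi_1 = 1/n` and the approximation reduces to `1 / lambda` independent of
#' pool size.
#'
#' @inheritParams fixation_probability
#' @param lam dose-rate parameter, `lambda > 0`.
#' @return Approximate mean absorption time in cell cycles.
#' @examples
#' approx_absorption_time(20, 0.001, cost_matrix()) # 1000 cycles
#' @export
approx_absorption_time <- function(n, lam, cm) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be > 0", call. = FALSE)
  1 / (n * lam) * exp(-log_fixation_probability(n, cm))
}

#' Exact mean absorption time of the well-mixed chain
#'
#' Builds the exact one-elementary-step transition matrix of the composite
#' (radiation, then Moran division/elimination) process on the damaged-cell
#' count `k in 0..n`: the radiation substep is a binomial upward jump (each
#' intact cell flips with probability `1 - exp(-lambda / n)`) followed by
#' the birth-death step of [transition_probabilities()]. With `lambda > 0`
#' the all-damaged state is the unique absorbing state, so the fundamental
#' linear system `(I - Q) t = 1` over the transient states gives the exact
#' expected number of elementary steps to absorption from the all-intact
#' state; divided by `n`, the mean `T_abs` in cell cycles.
#'
#' Dense `(n+1)^2` construction and solve; intended for `n <= 100`.
#'
#' @inheritParams approx_absorption_time
#' @return Exact mean absorption time in cell cycles.
#' @examples
#' exact_expected_absorption_time(10, 0.1, cost_matrix())
#' @export
exact_expected_absorption_time <- function(n, lam, cm) {
  t <- wellmixed_mean_steps(n, lam, cm)
  t[1] / n
}

# Composite one-step transition matrix on k = 0..n (rows sum to 1).
wellmixed_step_matrix <- function(n, lam, cm) {
  cm <- validate_cost_matrix(cm)
  check_pool_size(n)
  if (!is.finite(lam) || lam < 0) stop("lam must be >= 0", call. = FALSE)
  p <- -expm1(-lam / n)
  rad <- matrix(0, n + 1, n + 1)
  for (k in 0:n) {
    rad[k + 1, (k:n) + 1] <- dbinom(0:(n - k), n - k, p)
  }
  tp <- transition_probabilities(0:n, n, cm)
  mor <- matrix(0, n + 1, n + 1)
  for (k in 0:n) {
    mor[k + 1, k + 1] <- tp$stay[k + 1]
    if (k < n) mor[k + 1, k + 2] <- tp$up[k + 1]
    if (k > 0) mor[k + 1, k] <- tp$down[k + 1]
  }
  rad %*% mor
}

# Expected elementary steps to absorption at k = n from each transient state.
wellmixed_mean_steps <- function(n, lam, cm) {
  if (!is.finite(lam) || lam <= 0) {
    stop("lam must be > 0 (with lam = 0 the all-intact state is absorbing ",
         "too and the mean occupation time from k = 0 is infinite)",
         call. = FALSE)
  }
  if (n > 100) stop("dense solve intended for n <= 100", call. = FALSE)
  pmat <- wellmixed_step_matrix(n, lam, cm)
  q <- pmat[1:n, 1:n, drop = FALSE]
  solve(diag(n) - q, rep(1, n))
}
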