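#' One-step Moran transition probabilities for the damaged-cell count
#'
#' Each elementary step one cell divides (chosen uniformly) and one cell is
#' eliminated (chosen with probability proportional to its expected cost).
#' The damaged-cell count `k` can change by at most one:
#' \deqn{P_{k,k+1} = \frac{k}{n} \cdot \frac{(n-k)F_k}{(n-k)F_k + kG_k},
#'       \quad
#'       P_{k,k-1} = \frac{n-k}{n} \cdot \frac{kG_k}{(n-k)F_k + kG_k},}
#' with the remainder staying put. The boundary states `k = 0` and `k = n`
#' cannot change by division/elimination alone (`up = down = 0`).
#'
#' @param k damaged-cell count(s), `0 <= k <= n` (vectorized).
#' @param n pool size, `n >= 2`.
#' @param cm a [cost_matrix()].
#' @return A data frame with columns `k`, `up`, `down`, `stay`.
#' @examples
#' transition_probabilities(10, 20, cost_matrix()) # up = down = 1/4
#' @export
transition_probabilities <- function(k, n, cm) {
  cm <- validate_cost_matrix(cm)
  check_pool_size(n)
  if (any(k < 0 | k > n)) stop("k must be in 0..n", call. = FALSE)
  up <- down <- numeric(length(k))
  mid <- which(k > 0 & k < n)
  if (length(mid)) {
    km <- k[mid]
    f <- expected_cost_intact(km, n, cm)
    g <- expected_cost_damaged(km, n, cm)
    w_int <- (n - km) * f
    w_dam <- km * g
    tot <- w_int + w_dam
    up[mid] <- (km / n) * w_int / tot
    down[mid] <- ((n - km) / n) * w_dam / tot
  }
  data.frame(k = k, up = up, down = down, stay = 1 - up - down)
}

#' Radiation substep of the well-mixed model
#'
#' Each intact cell is independently hit-and-converted with per-elementary-
#' step probability `1 - exp(-lambda / n)`. With all cells intact this gives
#' an expected `lambda` transitions per cell per cell cycle (`n` elementary
#' steps), i.e. `lambda` is the expected number of successful hits per cell
#' per cell-cycle length. Damage is irreversible; hits on damaged cells
#' change nothing. Uses R's global RNG stream.
#'
#' @inheritParams transition_probabilities
#' @param lam dose-rate parameter `lambda >= 0`.
#' @return Updated damaged-cell count (`>= k`).
#' @export
radiation_substep <- function(k, n, lam) {
  check_pool_size(n)
  stopifnot(length(k) == 1L, k >= 0, k <= n, lam >= 0)
  if (lam == 0 || k == n) return(k)
  k + rbinom(1L, n - k, -expm1(-lam / n))
}

#' Moran division/elimination substep of the well-mixed model
#'
#' Samples the composite (divider type, eliminated type) event directly from
#' [transition_probabilities()]. The population is exchangeable, so the
#' damaged-cell count is a sufficient statistic and individual cells need
#' not be tracked. Uses R's global RNG stream.
#'
#' @inheritParams radiation_substep
#' @param cm a [cost_matrix()].
#' @return Updated damaged-cell count (changed by at most one).
#' @export
moran_substep <- function(k, n, cm) {
  stopifnot(length(k) == 1L)
  tp <- transition_probabilities(k, n, cm)
  u <- runif(1)
  if (u < tp$up) k + 1L else if (u < tp$up + tp$down) k - 1L else k
}

default_max_cycles <- function(n) 1e7 / n

#' Simulate the time for damaged cells to occupy the well-mixed pool
#'
#' Starting from an all-intact pool, alternates the radiation substep and the
#' Moran division/elimination substep until all `n` cells are damaged. Each
#' elementary step is one division/elimination, so `n` steps are one cell
#' cycle; the absorption time `T_abs` is reported in cell cycles.
#'
#' Replicates are independent: replicate `i` runs on its own RNG stream
#' seeded deterministically from `(seed, i)`, so results are reproducible
#' and insensitive to replicate order. Replicates still unabsorbed after
#' `max_cycles` cycles are returned as censored (`t_abs_cycles = NA`) rather
#' than silently truncated; damaged-disadvantaged regimes at tiny `lambda`
#' can be astronomically slow.
#'
#' @param n pool size, `n >= 2`.
#' @param lam dose-rate parameter, `lambda > 0` (with `lambda = 0` the
#'   all-intact start can never be absorbed).
#' @param cm a [cost_matrix()].
#' @param reps number of independent replicates.
#' @param seed integer seed for the replicate RNG streams.
#' @param max_cycles censoring cap in cell cycles; defaults to `1e7 / n`
#'   (i.e. 1e7 elementary steps).
#' @return `simulate_absorption_times()` returns a data frame with one row
#'   per replicate: `n`, `lam`, the four cost entries, `replicate`,
#'   `t_abs_cycles` (NA if censored), `censored`, `seed`.
#'   `simulate_absorption_time()` runs a single replicate and returns
#'   `list(t_abs, censored)`.
#' @examples
#' sims <- simulate_absorption_times(10, 0.1, cost_matrix(), reps = 100, seed = 1)
#' mean(sims$t_abs_cycles)
#' @export
simulate_absorption_times <- function(n, lam, cm, reps = 1000, seed = 1,
                                      max_cycles = NULL) {
  cm <- validate_cost_matrix(cm)
  check_pool_size(n)
  if (!is.finite(lam) || lam <= 0) {
    stop("lam must be > 0: from an all-intact pool absorption is unreachable ",
         "without radiation", call. = FALSE)
  }
  stopifnot(reps >= 1)
  if (is.null(max_cycles)) max_cycles <- default_max_cycles(n)
  stopifnot(max_cycles > 0)
  t_cycles <- cpp_wellmixed_absorption(as.integer(n), lam, unclass(cm),
                                       max_cycles * n, as.numeric(seed),
                                       as.integer(reps))
  data.frame(
    n = n, lam = lam,
    cost_ii = cm[["c_ii"]], cost_id = cm[["c_id"]],
    cost_di = cm[["c_di"]], cost_dd = cm[["c_dd"]],
    replicate = seq_len(reps),
    t_abs_cycles = t_cycles,
    censored = is.na(t_cycles),
    seed = seed
  )
}

#' @rdname simulate_absorption_times
#' @export
simulate_absorption_time <- function(n, lam, cm, seed = 1, max_cycles = NULL) {
  rec <- simulate_absorption_times(n, lam, cm, reps = 1, seed = seed,
                                   max_cycles = max_cycles)
  list(t_abs = rec$t_abs_cycles[1], censored = rec$censored[1])
}
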