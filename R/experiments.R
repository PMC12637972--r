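#' Text-book cost matrices used throughout the package
#'
#' The four well-mixed reference parameter sets: `neutral` (all costs 1),
#' `damaged_advantage` (frequency-independent, damaged cells cheaper),
#' `intact_advantage` (frequency-independent, intact cells cheaper), and
#' `frequency_dependent` (a mixed case in which the advantaged type flips
#' with the damaged-cell frequency).
#'
#' @return Named list of [cost_matrix()] objects.
#' @export
default_cost_matrices <- function() {
  list(
    neutral = cost_matrix(1, 1, 1, 1),
    damaged_advantage = cost_matrix(1, 1, 0.8, 0.8),
    intact_advantage = cost_matrix(1, 1, 1.25, 1.25),
    frequency_dependent = cost_matrix(1, 1.5, 1.16, 0.8)
  )
}

# Scenario-level seed derivation: keeps replicate streams of different
# scenarios disjoint while staying a plain integer-valued double.
scenario_seed <- function(seed, index) {
  seed + 1000003 * index
}

summarize_sims <- function(sims) {
  ok <- !sims$censored
  t_ok <- sims$t_abs_cycles[ok]
  list(
    mean = if (length(t_ok)) mean(t_ok) else NA_real_,
    sd = if (length(t_ok) > 1) sd(t_ok) else NA_real_,
    se = if (length(t_ok) > 1) sd(t_ok) / sqrt(length(t_ok)) else NA_real_,
    n_ok = length(t_ok),
    censored = sum(!ok)
  )
}

#' Dose-rate sweep of the well-mixed model
#'
#' For each cost matrix and each dose rate, simulates mean `T_abs`, and
#' tabulates it next to the very-low-dose-rate approximation
#' ([approx_absorption_time()]), the exact chain solve
#' ([exact_expected_absorption_time()], for `n <= 100`), and the
#' simulation/approximation ratio (close to 1 where the approximation
#' holds). Censored replicates are counted and excluded from means, never
#' silently dropped.
#'
#' @param cost_matrices named list of [cost_matrix()] objects.
#' @param lam_grid positive dose rates; the default spans very low through
#'   high dose rates on a log grid.
#' @param n pool size (default 20).
#' @param reps replicates per condition (default 1000; 50 already give
#'   stable means).
#' @param seed integer seed.
#' @param max_cycles optional censoring cap in cycles.
#' @return Data frame, one row per (matrix, dose rate).
#' @export
run_dose_rate_sweep <- function(cost_matrices = default_cost_matrices(),
                                lam_grid = 10^seq(-4, 1, length.out = 11),
                                n = 20, reps = 1000, seed = 1,
                                max_cycles = NULL) {
  stopifnot(length(lam_grid) >= 1, all(lam_grid > 0))
  if (is.null(names(cost_matrices))) {
    names(cost_matrices) <- paste0("cm", seq_along(cost_matrices))
  }
  rows <- list()
  idx <- 0L
  for (nm in names(cost_matrices)) {
    cm <- validate_cost_matrix(cost_matrices[[nm]])
    for (lam in lam_grid) {
      idx <- idx + 1L
      s <- scenario_seed(seed, idx)
      sims <- simulate_absorption_times(n, lam, cm, reps = reps, seed = s,
                                        max_cycles = max_cycles)
      sm <- summarize_sims(sims)
      approx <- approx_absorption_time(n, lam, cm)
      exact <- if (n <= 100) exact_expected_absorption_time(n, lam, cm)
               else NA_real_
      rows[[idx]] <- data.frame(
        scenario = nm, model = "well_mixed", n = n, lam = lam,
        cost_ii = cm[["c_ii"]], cost_id = cm[["c_id"]],
        cost_di = cm[["c_di"]], cost_dd = cm[["c_dd"]],
        reps = reps, mean_t_abs = sm$mean, sd_t_abs = sm$sd,
        se_t_abs = sm$se, censored = sm$censored,
        t_abs_approx = approx, t_abs_exact = exact,
        ratio_sim_approx = sm$mean / approx, seed = s
      )
    }
  }
  do.call(rbind, rows)
}

#' Pool-size study of the normalized occupation time
#'
#' Evaluates the dose-rate-free normalized profile `f(n) = 1 / (n * pi_1)`
#' ([normalized_absorption_time()]) over a grid of pool sizes, classifies
#' its shape, and reports the two boundary indicators of the shape diagram.
#'
#' @param cm a [cost_matrix()].
#' @param n_grid strictly increasing pool sizes (default [default_n_grid()]).
#' @return A list of class `pool_size_study`: `records` (data frame with
#'   `n`, `log_t_abs_norm`, `t_abs_norm`), `shape`, `small_n_decrease`,
#'   `large_n_increase`, `cm`.
#' @export
run_pool_size_study <- function(cm, n_grid = default_n_grid()) {
  cm <- validate_cost_matrix(cm)
  if (length(n_grid) == 0) stop("n_grid must be non-empty", call. = FALSE)
  lf <- vapply(n_grid, log_normalized_absorption_time, numeric(1), cm = cm)
  structure(
    list(
      records = data.frame(
        n = n_grid,
        log_t_abs_norm = lf,
        t_abs_norm = exp(lf)
      ),
      shape = classify_shape(cm, n_grid = n_grid),
      small_n_decrease = small_n_decrease(cm),
      large_n_increase = large_n_increase(cm),
      cm = cm
    ),
    class = "pool_size_study"
  )
}

#' @export
print.pool_size_study <- function(x, ...) {
  cat("Pool-size study (", regime(x$cm), " cost matrix)\n", sep = "")
  cat("shape:", x$shape,
      "| decreases from n=2 to 3:", x$small_n_decrease,
      "| increasing at n=1e5:", x$large_n_increase, "\n")
  print(utils::head(x$records, 10), ...)
  if (nrow(x$records) > 10) cat("...", nrow(x$records), "pool sizes total\n")
  invisible(x)
}

#' Shape diagram over the damaged-cell cost entries
#'
#' Fixing the intact-cell costs (`c_ii`, `c_id`), sweeps a grid over the
#' damaged-cell entries (`c_di`, `c_dd`) and records the shape label and
#' boundary indicators at each point. The axes of the diagram are the tie
#' lines `c_di = c_ii` (vertical) and `c_dd = c_id` (horizontal), which
#' split it into the four game-theoretic regimes.
#'
#' @param c_di_grid,c_dd_grid positive grids for the damaged-cell entries
#'   (each length >= 2).
#' @param c_id,c_ii fixed intact-cell costs.
#' @param n_grid pool sizes used for classification.
#' @return Data frame with columns `cost_di`, `cost_dd`, `cost_id`,
#'   `shape_label`, `small_n_decrease`, `large_n_increase`.
#' @export
run_shape_diagram <- function(c_di_grid = seq(0.05, 2, length.out = 20),
                              c_dd_grid = seq(0.05, 2, length.out = 20),
                              c_id = 1, c_ii = 1,
                              n_grid = default_n_grid()) {
  stopifnot(length(c_di_grid) >= 2, length(c_dd_grid) >= 2)
  pts <- expand.grid(cost_di = c_di_grid, cost_dd = c_dd_grid,
                     KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    cm <- cost_matrix(c_ii, c_id, pts$cost_di[i], pts$cost_dd[i])
    data.frame(
      cost_di = pts$cost_di[i], cost_dd = pts$cost_dd[i], cost_id = c_id,
      shape_label = classify_shape(cm, n_grid = n_grid),
      small_n_decrease = small_n_decrease(cm),
      large_n_increase = large_n_increase(cm)
    )
  })
  do.call(rbind, res)
}

#' Compare the well-mixed and lattice models at matched pool sizes
#'
#' For each cost matrix and each pool size (which must be a perfect square
#' so the lattice side is an integer), simulates mean `T_abs` under both
#' models and tabulates the analytic well-mixed approximation alongside.
#' Long format: one row per (scenario, n, model).
#'
#' @param cost_matrices named list of [cost_matrix()] objects.
#' @param n_list pool sizes, each a perfect square `>= 16`.
#' @param lam dose-rate parameter (small, so the low-dose-rate approximation
#'   is meaningful on the analytic rows).
#' @param reps replicates per condition.
#' @param seed integer seed.
#' @param max_cycles optional censoring cap in cycles.
#' @return Data frame with columns `scenario`, `model`
#'   (`well_mixed` / `lattice` / `analytic`), `n`, `side`, `lam`, cost
#'   entries, `reps`, `mean_t_abs`, `sd_t_abs`, `se_t_abs`, `censored`,
#'   `seed`.
#' @export
run_lattice_comparison <- function(cost_matrices = default_cost_matrices(),
                                   n_list = c(16, 36, 64, 100),
                                   lam = 0.01, reps = 50, seed = 1,
                                   max_cycles = NULL) {
  sides <- sqrt(n_list)
  if (any(sides != round(sides)) || any(n_list < 16)) {
    stop("each pool size in n_list must be a perfect square >= 16 ",
         "(the lattice side must be an integer)", call. = FALSE)
  }
  if (is.null(names(cost_matrices))) {
    names(cost_matrices) <- paste0("cm", seq_along(cost_matrices))
  }
  rows <- list()
  idx <- 0L
  for (nm in names(cost_matrices)) {
    cm <- validate_cost_matrix(cost_matrices[[nm]])
    for (i in seq_along(n_list)) {
      n <- n_list[i]
      side <- as.integer(sides[i])
      idx <- idx + 1L
      s_wm <- scenario_seed(seed, 2L * idx)
      s_lat <- scenario_seed(seed, 2L * idx + 1L)
      wm <- summarize_sims(simulate_absorption_times(
        n, lam, cm, reps = reps, seed = s_wm, max_cycles = max_cycles))
      lat <- summarize_sims(simulate_lattice_absorption_times(
        side, lam, cm, reps = reps, seed = s_lat, max_cycles = max_cycles))
      base <- data.frame(
        scenario = nm, n = n, side = side, lam = lam,
        cost_ii = cm[["c_ii"]], cost_id = cm[["c_id"]],
        cost_di = cm[["c_di"]], cost_dd = cm[["c_dd"]]
      )
      rows[[length(rows) + 1L]] <- cbind(
        base, model = "well_mixed", reps = reps, mean_t_abs = wm$mean,
        sd_t_abs = wm$sd, se_t_abs = wm$se, censored = wm$censored,
        seed = s_wm)
      rows[[length(rows) + 1L]] <- cbind(
        base, model = "lattice", reps = reps, mean_t_abs = lat$mean,
        sd_t_abs = lat$sd, se_t_abs = lat$se, censored = lat$censored,
        seed = s_lat)
      rows[[length(rows) + 1L]] <- cbind(
        base, model = "analytic", reps = NA_integer_,
        mean_t_abs = approx_absorption_time(n, lam, cm),
        sd_t_abs = NA_real_, se_t_abs = NA_real_, censored = NA_integer_,
        seed = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  cols <- c("scenario", "model", "n", "side", "lam", "cost_ii", "cost_id",
            "cost_di", "cost_dd", "reps", "mean_t_abs", "sd_t_abs",
            "se_t_abs", "censored", "seed")
  out[, cols]
}
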