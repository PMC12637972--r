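#' Create a lattice state
#'
#' Cells live on an `side x side` square lattice with periodic boundaries
#' (a torus): every site has exactly 8 Moore neighbors (orthogonal and
#' diagonal) and there are no edges. Sites hold 0 (intact) or 1 (damaged).
#' `side = 3` is allowed but degenerate - every site then neighbors every
#' other site, so the dynamics collapse toward the well-mixed model.
#'
#' @param side lattice side length `L >= 3`; pool size is `L^2`.
#' @param damaged optional integer vector of site indices (1-based,
#'   column-major as in an R matrix) to start damaged.
#' @return An integer matrix of 0/1 values.
#' @export
lattice_state <- function(side, damaged = integer(0)) {
  check_side(side)
  grid <- matrix(0L, side, side)
  if (length(damaged)) {
    stopifnot(all(damaged >= 1), all(damaged <= side^2))
    grid[damaged] <- 1L
  }
  grid
}

check_side <- function(side) {
  if (length(side) != 1L || !is.finite(side) || side < 3 ||
      side != round(side)) {
    stop("lattice side must be a single integer >= 3 (the 8-site Moore ",
         "neighborhood needs distinct neighbors under periodic wrap)",
         call. = FALSE)
  }
  invisible(side)
}

check_grid <- function(grid) {
  if (!is.matrix(grid) || nrow(grid) != ncol(grid) ||
      !all(grid %in% c(0L, 1L))) {
    stop("grid must be a square 0/1 matrix", call. = FALSE)
  }
  check_side(nrow(grid))
  invisible(grid)
}

# Cyclic shift of a square matrix by (dr, dc).
shift_grid <- function(grid, dr, dc) {
  l <- nrow(grid)
  grid[(seq_len(l) - 1 - dr) %% l + 1, (seq_len(l) - 1 - dc) %% l + 1,
       drop = FALSE]
}

# Number of damaged cells among the 8 Moore neighbors of every site.
damaged_neighbor_counts <- function(grid) {
  l <- nrow(grid)
  counts <- matrix(0, l, l)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      counts <- counts + shift_grid(grid, dr, dc)
    }
  }
  counts
}

#' Interaction cost of every lattice site
#'
#' A site interacting with its 8 Moore neighbors, `l` of them damaged,
#' costs `(c_ii * (8 - l) + c_id * l) / 8` if intact and
#' `(c_di * (8 - l) + c_dd * l) / 8` if damaged. This is the full
#' recompute over the whole grid; the simulation engine maintains the same
#' quantities incrementally and the two routes are required to agree.
#'
#' @param grid a 0/1 lattice matrix (see [lattice_state()]).
#' @param cm a [cost_matrix()].
#' @return Numeric matrix of per-site costs, same shape as `grid`.
#' @export
site_costs <- function(grid, cm) {
  check_grid(grid)
  cm <- validate_cost_matrix(cm)
  l <- damaged_neighbor_counts(grid)
  intact <- (cm[["c_ii"]] * (8 - l) + cm[["c_id"]] * l) / 8
  damaged <- (cm[["c_di"]] * (8 - l) + cm[["c_dd"]] * l) / 8
  ifelse(grid == 1L, damaged, intact)
}

#' @rdname site_costs
#' @param row,col site coordinates (1-based).
#' @export
cell_cost <- function(grid, row, col, cm) {
  site_costs(grid, cm)[row, col]
}

#' Per-site elimination probabilities
#'
#' A cell is eliminated with probability proportional to its interaction
#' cost: `P(site i) = Phi_i / sum_j Phi_j`. Sums to 1 by construction.
#'
#' @inheritParams site_costs
#' @return Numeric matrix of probabilities summing to 1.
#' @export
elimination_distribution <- function(grid, cm) {
  phi <- site_costs(grid, cm)
  phi / sum(phi)
}

#' One competition substep on the lattice
#'
#' Samples the eliminated site from [elimination_distribution()], then
#' chooses the cell that divides into the vacated site uniformly from the
#' 9-member candidate set: the removed cell's own former occupant plus its
#' 8 Moore neighbors (so a clone of the removed cell itself can refill the
#' space). Uses R's global RNG stream; the compiled engine implements the
#' identical rule.
#'
#' @inheritParams site_costs
#' @return Updated grid.
#' @export
lattice_substep <- function(grid, cm) {
  check_grid(grid)
  l <- nrow(grid)
  prob <- elimination_distribution(grid, cm)
  site <- sample.int(l * l, 1L, prob = as.vector(prob))
  row <- (site - 1) %% l + 1
  col <- (site - 1) %/% l + 1
  cand <- sample.int(9L, 1L)
  if (cand < 9L) {
    offsets <- cbind(
      dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
      dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
    )
    nr <- (row - 1 + offsets[cand, "dr"]) %% l + 1
    nc <- (col - 1 + offsets[cand, "dc"]) %% l + 1
    grid[row, col] <- grid[nr, nc]
  }
  grid
}

#' Radiation substep on the lattice
#'
#' Identical scheme to the well-mixed model with `n = L^2`: each intact site
#' independently flips to damaged with per-elementary-step probability
#' `1 - exp(-lambda / L^2)`. Uses R's global RNG stream.
#'
#' @inheritParams site_costs
#' @param lam dose-rate parameter `lambda >= 0`.
#' @return Updated grid (damaged count non-decreasing).
#' @export
lattice_radiation_substep <- function(grid, lam) {
  check_grid(grid)
  stopifnot(lam >= 0)
  if (lam == 0) return(grid)
  p <- -expm1(-lam / length(grid))
  intact <- which(grid == 0L)
  if (length(intact)) {
    flips <- intact[runif(length(intact)) < p]
    grid[flips] <- 1L
  }
  grid
}

#' Simulate lattice occupation times
#'
#' Starting from an all-intact lattice, alternates the radiation substep and
#' the competition substep until every site is damaged. One elementary step
#' is one division/elimination, so `L^2` steps are one cell cycle and
#' `T_abs` is reported in cell cycles. Censoring and per-replicate seeding
#' behave as in [simulate_absorption_times()].
#'
#' @param side lattice side `L >= 3`.
#' @param lam dose-rate parameter, `> 0`.
#' @param cm a [cost_matrix()].
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param max_cycles censoring cap in cell cycles (default `1e7 / L^2`).
#' @return Data frame with one row per replicate: `side`, `n`, `lam`, cost
#'   entries, `replicate`, `t_abs_cycles`, `censored`, `seed`.
#' @export
simulate_lattice_absorption_times <- function(side, lam, cm, reps = 50,
                                              seed = 1, max_cycles = NULL) {
  check_side(side)
  cm <- validate_cost_matrix(cm)
  if (!is.finite(lam) || lam <= 0) {
    stop("lam must be > 0: an all-intact lattice cannot be absorbed ",
         "without radiation", call. = FALSE)
  }
  stopifnot(reps >= 1)
  n <- side^2
  if (is.null(max_cycles)) max_cycles <- default_max_cycles(n)
  if (side == 3) {
    message("side = 3 is degenerate: every site neighbors every other, ",
            "so the lattice behaves like the well-mixed model")
  }
  t_cycles <- cpp_lattice_absorption(as.integer(side), lam, unclass(cm),
                                     max_cycles * n, as.numeric(seed),
                                     as.integer(reps))
  data.frame(
    side = side, n = n, lam = lam,
    cost_ii = cm[["c_ii"]], cost_id = cm[["c_id"]],
    cost_di = cm[["c_di"]], cost_dd = cm[["c_dd"]],
    replicate = seq_len(reps),
    t_abs_cycles = t_cycles,
    censored = is.na(t_cycles),
    seed = seed
  )
}

#' Estimate the lattice fixation probability by simulation
#'
#' Radiation is switched off; each replicate places a single damaged cell at
#' a uniformly random site (translation invariance of the torus makes the
#' placement irrelevant) and runs competition substeps until the lattice is
#' uniform. The fixation probability `pi_1` is estimated as the fraction of
#' replicates in which the damaged lineage took over, with its binomial
#' standard error.
#'
#' @inheritParams simulate_lattice_absorption_times
#' @param n_reps number of replicates, `>= 1`.
#' @param max_steps guard cap on elementary steps per replicate.
#' @return A list: `estimate`, `se`, `n_reps`, `n_fixed`, `n_censored`.
#' @examples
#' estimate_fixation_probability_lattice(4, cost_matrix(), n_reps = 200, seed = 1)
#' @export
estimate_fixation_probability_lattice <- function(side, cm, n_reps = 5000,
                                                  seed = 1,
                                                  max_steps = 1e8) {
  check_side(side)
  cm <- validate_cost_matrix(cm)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  out <- cpp_lattice_fixation(as.integer(side), unclass(cm),
                              as.numeric(seed), as.integer(n_reps),
                              max_steps)
  ok <- !is.na(out)
  n_ok <- sum(ok)
  est <- mean(out[ok])
  list(
    estimate = est,
    se = sqrt(est * (1 - est) / n_ok),
    n_reps = n_reps,
    n_fixed = sum(out[ok] == 1L),
    n_censored = n_reps - n_ok
  )
}
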