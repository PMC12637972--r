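test_that("lattice construction and side validation", {
  g <- lattice_state(4)
  expect_identical(dim(g), c(4L, 4L))
  expect_true(all(g == 0L))
  g1 <- lattice_state(5, damaged = 13)
  expect_identical(sum(g1), 1L)
  expect_error(lattice_state(2), "side")
  expect_error(simulate_lattice_absorption_times(2, 0.1, cm_neutral), "side")
})

test_that("site costs match hand-computed Moore-neighborhood values", {
  g <- lattice_state(5)
  expect_equal(site_costs(g, cm_neutral), matrix(1, 5, 5))
  # intact site surrounded by damaged cells only is forced to c_id
  g_all_dam <- lattice_state(5, damaged = setdiff(1:25, 13))
  expect_equal(cell_cost(g_all_dam, 3, 3, cm_green), 1.5)
  # intact with 3 damaged neighbors, c_ii = 1, c_id = 0.25
  g3 <- lattice_state(5, damaged = c(7, 8, 9))
  expect_equal(cell_cost(g3, 3, 3, cost_matrix(1, 0.25, 1, 1)),
               (1 * 5 + 0.25 * 3) / 8)
})

test_that("elimination distribution is the cost-weighted ratio and sums to 1", {
  # neutral: uniform over all sites
  expect_equal(elimination_distribution(lattice_state(4), cm_neutral),
               matrix(1 / 16, 4, 4))
  # 3x3 torus with damaged center: every site neighbors every other
  g <- lattice_state(3, damaged = 5)
  d <- elimination_distribution(g, cm_green)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(d[2, 2], 1.16 / (1.16 + 8 * 1.0625), tolerance = 1e-12)
  expect_equal(d[1, 1], 1.0625 / (1.16 + 8 * 1.0625), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:10) {
    gi <- random_grid(sample(3:8, 1))
    di <- elimination_distribution(gi, random_cost_matrix())
    expect_equal(sum(di), 1, tolerance = 1e-12)
    expect_true(all(di > 0))
  }
})

test_that("raising a site's cost raises its elimination probability", {
  g <- lattice_state(5, damaged = 13)
  before <- elimination_distribution(g, cost_matrix(1, 1, 0.9, 1))[13]
  after <- elimination_distribution(g, cost_matrix(1, 1, 1.8, 1))[13]
  expect_gt(after, before)
})

test_that("periodic wrap has no edges: exactly 8 neighbors, translation invariant", {
  for (side in c(4, 5)) {
    # a single damaged cell elevates the cost of exactly its 8 neighbors
    g <- lattice_state(side, damaged = 1)
    phi <- site_costs(g, cost_matrix(1, 2, 1, 1))
    expect_identical(sum(phi > 1), 8L)
  }
  # cyclically shifting the grid shifts the distribution identically
  set.seed(42)
  g <- random_grid(6)
  cm <- random_cost_matrix()
  d0 <- elimination_distribution(g, cm)
  gs <- g[c(3:6, 1:2), c(5:6, 1:4)]
  ds <- elimination_distribution(gs, cm)
  expect_equal(ds, d0[c(3:6, 1:2), c(5:6, 1:4)], tolerance = 1e-12)
})

test_that("competition substep: uniform grids are fixed points, neutral drift is zero", {
  set.seed(43)
  g_int <- lattice_state(4)
  expect_identical(lattice_substep(g_int, cm_green), g_int)
  g_dam <- lattice_state(4, damaged = 1:16)
  expect_identical(lattice_substep(g_dam, cm_green), g_dam)
  # neutral damaged-count is a martingale: mean one-step change ~ 0
  g <- lattice_state(5, damaged = sample(25, 10))
  deltas <- vapply(1:2000, function(i) {
    sum(lattice_substep(g, cm_neutral)) - sum(g)
  }, numeric(1))
  expect_true(all(abs(deltas) <= 1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("lattice radiation substep mirrors the well-mixed scheme", {
  g <- lattice_state(5)
  expect_identical(lattice_radiation_substep(g, 0), g)
  g_dam <- lattice_state(5, damaged = 1:25)
  expect_identical(lattice_radiation_substep(g_dam, 3), g_dam)
  set.seed(44)
  lam <- 0.5
  flips <- vapply(1:2e4, function(i) {
    sum(lattice_radiation_substep(g, lam))
  }, numeric(1))
  expected <- 25 * (1 - exp(-lam / 25))
  se <- sd(flips) / sqrt(length(flips))
  expect_lt(abs(mean(flips) - expected), 3 * se)
})

test_that("incremental engine costs equal a full recompute of the final grid", {
  set.seed(45)
  for (i in 1:5) {
    side <- sample(4:7, 1)
    g <- random_grid(side)
    cm <- random_cost_matrix()
    out <- cellcompete:::cpp_lattice_run(g, unclass(cm), lam = 0.5,
                                         nsteps = 400, seed = i)
    expect_equal(out$phi, site_costs(out$grid, cm), tolerance = 1e-12)
    expect_identical(utils::tail(out$nd_trace, 1), sum(out$grid))
    # radiation never repairs: damaged count non-decreasing apart from
    # competition steps which change it by at most one
    expect_true(all(diff(out$nd_trace) >= -1))
  }
})

test_that("neutral lattice fixation equals the initial frequency", {
  est <- estimate_fixation_probability_lattice(4, cm_neutral, n_reps = 5000,
                                               seed = 46)
  expect_equal(est$n_censored, 0)
  expect_lt(abs(est$estimate - 1 / 16), 3 * est$se)
  expect_error(
    estimate_fixation_probability_lattice(4, cm_neutral, n_reps = 0),
    "n_reps")
})

test_that("strong damaged-cell advantage lifts fixation above neutrality", {
  est <- estimate_fixation_probability_lattice(
    5, cost_matrix(1, 1, 0.1, 0.1), n_reps = 2000, seed = 47)
  expect_gt(est$estimate - 1 / 25, 3 * est$se)
})

test_that("neutral lattice and well-mixed occupation times agree in law", {
  lat <- simulate_lattice_absorption_times(4, 0.05, cm_neutral, reps = 200,
                                           seed = 48)
  wm <- simulate_absorption_times(16, 0.05, cm_neutral, reps = 200, seed = 49)
  se <- sqrt(sd(lat$t_abs_cycles)^2 / 200 + sd(wm$t_abs_cycles)^2 / 200)
  expect_lt(abs(mean(lat$t_abs_cycles) - mean(wm$t_abs_cycles)), 3 * se)
  # reproducibility of the lattice stream
  expect_identical(lat,
                   simulate_lattice_absorption_times(4, 0.05, cm_neutral,
                                                     reps = 200, seed = 48))
})
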