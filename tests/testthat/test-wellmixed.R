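test_that("transition probabilities match hand arithmetic", {
  # absorbing ends: no division/elimination can change k
  for (cm in list(cm_neutral, cm_green)) {
    ends <- transition_probabilities(c(0, 20), 20, cm)
    expect_equal(ends$up, c(0, 0))
    expect_equal(ends$down, c(0, 0))
    expect_equal(ends$stay, c(1, 1))
  }
  mid <- transition_probabilities(10, 20, cm_neutral)
  expect_equal(mid$up, 0.25)
  expect_equal(mid$down, 0.25)
  expect_equal(mid$stay, 0.5)
  # n = 2 with the mixed matrix: F_1 = 1.5, G_1 = 1.16
  tp <- transition_probabilities(1, 2, cm_green)
  expect_equal(tp$up, 0.5 * 1.5 / (1.5 + 1.16))
  expect_equal(tp$down, 0.5 * 1.16 / (1.5 + 1.16))
})

test_that("transition probabilities are a distribution for random matrices", {
  set.seed(7)
  for (i in 1:20) {
    cm <- random_cost_matrix()
    n <- sample(c(2:10, 50, 200), 1)
    tp <- transition_probabilities(0:n, n, cm)
    expect_true(all(tp$up >= 0 & tp$up <= 1))
    expect_true(all(tp$down >= 0 & tp$down <= 1))
    expect_true(all(tp$stay >= 0 & tp$stay <= 1))
    expect_equal(tp$up + tp$down + tp$stay, rep(1, n + 1), tolerance = 1e-12)
  }
})

test_that("scaling all costs by a common factor leaves the process law unchanged", {
  set.seed(8)
  for (scale in c(0.01, 3, 250)) {
    cm <- random_cost_matrix()
    cm2 <- as.numeric(unclass(cm)) * scale
    tp1 <- transition_probabilities(0:12, 12, cm)
    tp2 <- transition_probabilities(0:12, 12, cm2)
    expect_equal(tp1$up, tp2$up, tolerance = 1e-12)
    expect_equal(tp1$down, tp2$down, tolerance = 1e-12)
    expect_equal(exact_expected_absorption_time(8, 0.1, cm),
                 exact_expected_absorption_time(8, 0.1, cm2),
                 tolerance = 1e-10)
  }
})

test_that("radiation substep only damages intact cells at the advertised rate", {
  set.seed(11)
  expect_identical(radiation_substep(3, 20, 0), 3)
  expect_identical(radiation_substep(20, 20, 5), 20)
  k1 <- vapply(1:1e5, function(i) radiation_substep(0, 20, 0.08), numeric(1))
  expect_true(all(k1 >= 0))
  # expected transitions per elementary step ~= lambda for an intact pool
  expected <- 20 * (1 - exp(-0.08 / 20))
  se <- sd(k1) / sqrt(length(k1))
  expect_lt(abs(mean(k1) - expected), 3 * se)
  expect_lt(abs(expected - 0.08), 2e-4)
})

test_that("moran substep frequencies follow the transition probabilities", {
  set.seed(12)
  expect_identical(moran_substep(0, 10, cm_green), 0)
  expect_identical(moran_substep(10, 10, cm_green), 10)
  k <- 6; n <- 15
  draws <- vapply(1:2e4, function(i) moran_substep(k, n, cm_green),
                  numeric(1))
  expect_true(all(abs(draws - k) <= 1))
  tp <- transition_probabilities(k, n, cm_green)
  for (delta in c(1, -1, 0)) {
    p <- switch(as.character(delta), "1" = tp$up, "-1" = tp$down, tp$stay)
    phat <- mean(draws == k + delta)
    se <- sqrt(p * (1 - p) / length(draws))
    expect_lt(abs(phat - p), 3 * se)
  }
})

test_that("simulation refuses an unreachable absorption", {
  expect_error(simulate_absorption_times(10, 0, cm_neutral), "lam must be > 0")
})

test_that("simulated mean absorption times match the exact chain", {
  for (n in c(2, 5)) {
    sims <- simulate_absorption_times(n, 0.1, cm_green, reps = 2000, seed = 3)
    expect_false(any(sims$censored))
    exact <- exact_expected_absorption_time(n, 0.1, cm_green)
    se <- sd(sims$t_abs_cycles) / sqrt(nrow(sims))
    expect_lt(abs(mean(sims$t_abs_cycles) - exact), 3 * se)
  }
})

test_that("neutral absorption at very low dose rate takes ~1/lambda cycles", {
  sims <- simulate_absorption_times(10, 0.001, cm_neutral, reps = 2000,
                                    seed = 4)
  se <- sd(sims$t_abs_cycles) / sqrt(nrow(sims))
  expect_lt(abs(mean(sims$t_abs_cycles) - 1000), 3 * se)
})

test_that("a damaged-cell cost advantage shortens occupation times", {
  neutral <- simulate_absorption_times(20, 0.001, cm_neutral, reps = 500,
                                       seed = 5)
  adv <- simulate_absorption_times(20, 0.001, cm_damaged_adv, reps = 500,
                                   seed = 6)
  se <- sqrt(sd(neutral$t_abs_cycles)^2 / 500 + sd(adv$t_abs_cycles)^2 / 500)
  expect_gt(mean(neutral$t_abs_cycles) - mean(adv$t_abs_cycles), 3 * se)
})

test_that("replicate streams are reproducible and censoring is explicit", {
  a <- simulate_absorption_times(5, 0.05, cm_green, reps = 50, seed = 99)
  b <- simulate_absorption_times(5, 0.05, cm_green, reps = 50, seed = 99)
  expect_identical(a, b)
  c2 <- simulate_absorption_times(5, 0.05, cm_green, reps = 50, seed = 100)
  expect_false(identical(a$t_abs_cycles, c2$t_abs_cycles))
  # a tiny step cap forces visible censoring rather than silent truncation
  cen <- simulate_absorption_times(10, 1e-4, cm_intact_adv, reps = 10,
                                   seed = 1, max_cycles = 1)
  expect_true(all(cen$censored))
  expect_true(all(is.na(cen$t_abs_cycles)))
  single <- simulate_absorption_time(5, 0.05, cm_green, seed = 99)
  expect_identical(single$t_abs, a$t_abs_cycles[1])
})
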