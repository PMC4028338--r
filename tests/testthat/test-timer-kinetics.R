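test_that("maturation converts green to red with the expected half-time", {
  p <- timer_params(k_mat = log(2) / 24)
  tr <- simulate_pools(p, c(0, 24, 48), init = c(1, 0))
  expect_equal(tr$green[2], 0.5, tolerance = 1e-8)
  expect_equal(tr$red[2], 0.5, tolerance = 1e-8)
  # total conserved without synthesis or degradation
  expect_equal(tr$green + tr$red, rep(1, 3), tolerance = 1e-12)
})

test_that("synthesis without maturation accumulates green linearly", {
  p <- timer_params(k_mat = 0, k_deg = 0, s = 1)
  tr <- simulate_pools(p, 0:10)
  expect_equal(tr$green, 0:10, tolerance = 1e-10)
  expect_equal(tr$red, rep(0, 11))
})

test_that("red/green converges to k_mat/k_deg under continuous induction", {
  p <- timer_params(k_mat = 0.03, k_deg = 0.03, s = 1)
  tr <- simulate_pools(p, c(0, 20 / 0.03))
  expect_equal(tr$red_green_ratio[2], 1, tolerance = 0.01)
  expect_equal(steady_state_ratio(p), 1)
  expect_equal(steady_state_ratio(timer_params(k_mat = 0.06, k_deg = 0.03, s = 1)), 2)
  expect_error(steady_state_ratio(timer_params(k_mat = 0.03, k_deg = 0, s = 1)),
               "no steady state")
})

test_that("integration matches the matrix-exponential solution on random schedules", {
  set.seed(42)
  for (i in 1:10) {
    w <- if (i %% 2 == 0) {
      t1 <- runif(1, 1, 10); t2 <- t1 + runif(1, 1, 10)
      cbind(c(0, t2 + runif(1, 1, 5)), c(t1, t2 + runif(1, 6, 10)))
    } else {
      NULL
    }
    p <- timer_params(k_mat = runif(1, 0.005, 0.1), k_deg = runif(1, 0, 0.05),
                      s = runif(1, 0, 2), import_windows = w)
    grid <- sort(c(0, runif(6, 0.5, 40)))
    init <- runif(2, 0, 2)
    got <- simulate_pools(p, grid, init = init)
    want <- oracle_pools(p, grid, init = init)
    scale <- pmax(abs(want$green), abs(want$red), 1e-8)
    expect_lt(max(abs(got$green - want$green) / scale), 1e-6)
    expect_lt(max(abs(got$red - want$red) / scale), 1e-6)
  }
})

test_that("ratio trajectory is invariant to the synthesis rate", {
  grid <- seq(0, 48, by = 4)
  p1 <- timer_params(k_mat = 0.03, k_deg = 0.02, s = 1)
  p3 <- timer_params(k_mat = 0.03, k_deg = 0.02, s = 3)
  tr1 <- simulate_pools(p1, grid)
  tr3 <- simulate_pools(p3, grid)
  expect_equal(tr3$green, 3 * tr1$green, tolerance = 1e-10)
  expect_equal(tr3$red_green_ratio[-1], tr1$red_green_ratio[-1], tolerance = 1e-10)
  # ratio under continuous induction is non-decreasing toward k_mat/k_deg
  expect_true(all(diff(tr1$red_green_ratio[-1]) >= -1e-12))
  expect_lt(tr1$red_green_ratio[length(grid)], steady_state_ratio(p1) + 1e-9)
})

test_that("input validation rejects malformed parameters and grids", {
  expect_error(timer_params(k_mat = -1), "k_mat")
  expect_error(timer_params(import_windows = cbind(c(0, 3), c(5, 8))),
               "non-overlapping")
  expect_error(timer_params(import_windows = cbind(0, Inf)), "finite")
  p <- timer_params()
  expect_error(simulate_pools(p, numeric(0)), "non-empty")
  expect_error(simulate_pools(p, c(0, 2, 2)), "strictly increasing")
  expect_error(simulate_pools(p, 0:2, init = c(-1, 0)), "non-negative")
})

test_that("noiseless parameter fits recover the generating constants", {
  truth <- timer_params(k_mat = 0.03, k_deg = 0.02, s = 1)
  traj <- simulate_pools(truth, seq(0, 48, by = 2.4))
  fit <- fit_kinetics(traj, timer_params(k_mat = 0.08, k_deg = 0.02, s = 1),
                      free = "k_mat")
  expect_lt(abs(fit$estimates[["k_mat"]] - 0.03), 1e-4)
  fit2 <- fit_kinetics(traj, timer_params(k_mat = 0.1, k_deg = 0.05, s = 1),
                       free = c("k_mat", "k_deg"))
  expect_lt(abs(fit2$estimates[["k_mat"]] - 0.03), 1e-3)
  expect_lt(abs(fit2$estimates[["k_deg"]] - 0.02), 1e-3)
})

test_that("degenerate trajectories are rejected as unidentifiable", {
  zero <- data.frame(t_hours = 0:5, green = 0, red = 0)
  expect_error(fit_kinetics(zero, timer_params(), free = "k_mat"),
               "unidentifiable")
  expect_error(fit_kinetics(data.frame(t_hours = 0:2, green = 1:3, red = 0:2),
                            timer_params(), free = "k_mat"),
               "at least 4")
})

test_that("pulse induction ages the pool relative to continuous induction", {
  p <- timer_params(k_mat = log(2) / 24, k_deg = 0, s = 1)
  r_pulse <- scenario_ratio("pulse", 24, p, pulse_hours = 4)
  r_cont <- scenario_ratio("continuous", 24, p)
  expect_gt(r_pulse, r_cont)
  expect_error(scenario_ratio("continuous", 0, p), "undefined ratio")
})

test_that("an import block lowers green only while synthesis is ongoing", {
  p <- timer_params(k_mat = log(2) / 24, k_deg = 0.01, s = 1)
  grid <- seq(0, 24, by = 1)
  base_on <- scenario_trajectory("continuous", p, grid)
  block_on <- scenario_trajectory("import_block", p, grid,
                                  block_window = c(21, 24), synthesis_on = TRUE)
  expect_lt(block_on$green[25], base_on$green[25])
  # synthesis withdrawn before the block: the block changes nothing
  pre <- timer_params(k_mat = p$k_mat, k_deg = p$k_deg, s = p$s,
                      import_windows = cbind(0, 21))
  base_off <- simulate_pools(pre, grid)
  block_off <- scenario_trajectory("import_block", p, grid,
                                   block_window = c(21, 24), synthesis_on = FALSE)
  expect_lt(abs(block_off$green[25] - base_off$green[25]) / base_off$green[25],
            0.01)
})

test_that("disabling turnover increases the aged (red) pool", {
  grid <- seq(0, 48, by = 2)
  with_deg <- scenario_trajectory("continuous",
                                  timer_params(k_mat = log(2) / 24,
                                               k_deg = 0.02, s = 1), grid)
  no_deg <- scenario_trajectory("autophagy_off",
                                timer_params(k_mat = log(2) / 24,
                                             k_deg = 0.02, s = 1), grid)
  expect_gt(no_deg$red[25], with_deg$red[25])
})

test_that("trajectories survive a CSV round trip", {
  tr <- simulate_pools(timer_params(k_mat = 0.05, s = 1), 0:5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$green, tr$green, tolerance = 1e-12)
  expect_equal(back$red, tr$red, tolerance = 1e-12)
})
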