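well_mixed_geo <- function(extent = 40) cell_geometry("well_mixed", extent = extent)

quiet_cfg <- function(...) {
  args <- list(k_mat = 0, k_deg = 0, s = 0, import_mode = "continuous",
               fusion_rate = 0, fission_rate = 0, mitophagy_rate = 0,
               biogenesis_rate = 0)
  do.call(network_config, utils::modifyList(args, list(...)))
}

test_that("fusion and fission conserve size and both pools exactly", {
  geo <- well_mixed_geo()
  # fusion-only run
  cfg <- quiet_cfg(n_init = 40, fusion_rate = 0.02, motility_D = 0.5,
                   init_pools = "preloaded", init_green = 2, init_red = 1,
                   dt = 0.05, t_end = 10, seed = 3)
  sim <- run_simulation(cfg, geo, snapshot_times = c(0, 10))
  t0 <- sim$snapshots[[1]]; t1 <- sim$snapshots[[2]]
  expect_gt(sim$counts[["fusions"]], 0)
  expect_equal(sum(t1$green), sum(t0$green), tolerance = 1e-12)
  expect_equal(sum(t1$red), sum(t0$red), tolerance = 1e-12)
  expect_equal(sum(t1$size), sum(t0$size), tolerance = 1e-12)
  # fission-only run from a uniform ratio: every fragment keeps the ratio
  cfg2 <- quiet_cfg(n_init = 30, fission_rate = 0.5, motility_D = 0,
                    init_pools = "preloaded", init_green = 2, init_red = 1,
                    dt = 0.05, t_end = 10, seed = 4)
  sim2 <- run_simulation(cfg2, geo, snapshot_times = c(0, 10))
  expect_gt(sim2$counts[["fissions"]], 0)
  expect_equal(sum(sim2$snapshots[[2]]$green), sum(sim2$snapshots[[1]]$green),
               tolerance = 1e-12)
  expect_equal(unique(round(sim2$snapshots[[2]]$ratio, 12)), 0.5)
})

test_that("a quiescent population conserves total fluorescence over many steps", {
  cfg <- quiet_cfg(n_init = 20, motility_D = 0.5, init_pools = "preloaded",
                   init_green = 1, init_red = 1, dt = 0.01, t_end = 10, seed = 1)
  sim <- run_simulation(cfg, well_mixed_geo(), snapshot_times = c(0, 10))
  expect_equal(sum(sim$snapshots[[2]]$green + sim$snapshots[[2]]$red),
               sum(sim$snapshots[[1]]$green + sim$snapshots[[1]]$red),
               tolerance = 1e-9)
})

test_that("identical configs and seeds give bit-identical output", {
  sc <- scenario_network("fusion_on", seed = 9)
  a <- run_simulation(sc$config, sc$geometry)
  b <- run_simulation(sc$config, sc$geometry)
  expect_identical(a$snapshots, b$snapshots)
  c2 <- run_simulation(scenario_network("fusion_on", seed = 10)$config, sc$geometry)
  expect_false(identical(a$snapshots, c2$snapshots))
})

test_that("with spatial events off, population totals follow the two-pool model", {
  cfg <- network_config(n_init = 25, k_mat = 0.04, k_deg = 0.015, s = 12,
                        import_mode = "continuous", fusion_rate = 0,
                        fission_rate = 0, mitophagy_rate = 0, motility_D = 0,
                        dt = 0.1, t_end = 24, seed = 5)
  sim <- run_simulation(cfg, well_mixed_geo(), snapshot_times = c(0, 12, 24))
  ref <- simulate_pools(timer_params(k_mat = 0.04, k_deg = 0.015, s = 12),
                        c(0, 12, 24))
  got_g <- vapply(sim$snapshots, function(t) sum(t$green), numeric(1))
  got_r <- vapply(sim$snapshots, function(t) sum(t$red), numeric(1))
  expect_equal(unname(got_g), ref$green, tolerance = 1e-6)
  expect_equal(unname(got_r), ref$red, tolerance = 1e-6)
})

test_that("event probabilities above the step guard are rejected by name", {
  expect_error(network_config(fission_rate = 2, dt = 0.1), "fission_rate")
  expect_error(network_config(shuttle_rate = 1.5, dt = 0.1), "shuttle_rate")
  expect_error(network_config(t_end = 0.05, dt = 0.1), "at least one step")
})

test_that("heterogeneity SD is invariant to relabeling and joint scaling", {
  sc <- scenario_network("fusion_off", seed = 2)
  tab <- run_simulation(sc$config, sc$geometry)$snapshots[[1]]
  sd0 <- as.numeric(heterogeneity_sd(tab))
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(as.numeric(heterogeneity_sd(perm)), sd0)
  scaled <- tab
  scaled$green <- tab$green * 7.5
  scaled$red <- tab$red * 7.5
  scaled$ratio <- scaled$red / scaled$green
  expect_equal(as.numeric(heterogeneity_sd(scaled)), sd0, tolerance = 1e-12)
})

test_that("size-binned heterogeneity handles hand-built and degenerate tables", {
  tab <- data.frame(size = c(rep(1, 6), rep(10, 6)),
                    ratio = c(0.5, 1.5, 0.5, 1.5, 0.5, 1.5, rep(1, 6)))
  out <- small_mito_heterogeneity(tab, n_bins = 2)
  expect_equal(out$sd_ratio[1], sd(c(0.5, 1.5, 0.5, 1.5, 0.5, 1.5)))
  expect_equal(out$sd_ratio[2], 0)
  same <- data.frame(size = rep(c(1, 10), each = 6), ratio = 1)
  expect_true(all(small_mito_heterogeneity(same, n_bins = 2)$sd_ratio == 0))
  expect_error(small_mito_heterogeneity(tab[1:4, ]), "at least")
})

test_that("neuron-mode positions stay on the cell and import decays with distance", {
  sc <- scenario_network("neuron_control", seed = 6)
  tab <- run_simulation(sc$config, sc$geometry)$snapshots[[1]]
  lens <- neurite_lengths(sc$geometry)
  nt <- tab[tab$compartment == "neurite", ]
  expect_true(all(nt$dist_um >= 0))
  expect_true(all(nt$dist_um <= lens[nt$neurite] + 1e-9))
  expect_true(all(tab$dist_um[tab$compartment == "soma"] == 0))
  # distal organelles accumulate relatively more aged (red) protein
  prox <- nt$ratio[nt$dist_um < 30]
  dist <- nt$ratio[nt$dist_um > 70]
  expect_gt(mean(dist, na.rm = TRUE), mean(prox, na.rm = TRUE))
})
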