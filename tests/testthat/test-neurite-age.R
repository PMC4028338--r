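straight_geo <- function() {
  # soma below the origin so the neurite roots at (0, 0)
  cell_geometry("neuron", soma_center = c(0, -5), soma_radius = 5,
                neurites = list(rbind(c(0, 0), c(0, 100))))
}

test_that("path distance is arc length from the soma boundary", {
  geo <- straight_geo()
  expect_equal(path_distance(rbind(c(0, -5)), geo), 0)       # soma center
  expect_equal(path_distance(rbind(c(0, 40)), geo), 40)
  # L-shaped neurite
  geoL <- cell_geometry("neuron", soma_center = c(0, -5), soma_radius = 5,
                        neurites = list(rbind(c(0, 0), c(0, 30), c(40, 30))))
  expect_equal(path_distance(rbind(c(10, 30)), geoL), 40)
  expect_error(path_distance(rbind(c(25, 5)), geo), "from the nearest")
})

test_that("path distance is invariant to polyline re-vertexing", {
  geo <- straight_geo()
  fine <- cell_geometry("neuron", soma_center = c(0, -5), soma_radius = 5,
                        neurites = list(cbind(0, seq(0, 100, by = 2.5))))
  pts <- cbind(runif(20, -0.5, 0.5), runif(20, 1, 99))
  expect_equal(path_distance(pts, geo), path_distance(pts, fine),
               tolerance = 1e-6)
})

test_that("geometry constructors validate their inputs", {
  expect_error(cell_geometry("neuron", neurites = list()), "at least one")
  expect_error(cell_geometry("neuron", soma_radius = 5,
                             neurites = list(rbind(c(10, 10), c(20, 20)))),
               "soma boundary")
  geo <- neuron_geometry(3, lengths = c(50, 60, 70), soma_radius = 8)
  expect_equal(neurite_lengths(geo), c(50, 60, 70))
})

test_that("slope fits reproduce exact lines and reject degenerate traces", {
  f <- fit_slope(c(0, 50, 100), c(2, 1.5, 1))
  expect_equal(f$slope, -0.01)
  expect_equal(f$intercept, 2)
  expect_equal(fit_slope(c(0, 10, 30), c(1, 1, 1))$slope, 0)
  expect_error(fit_slope(c(5, 5, 5), c(1, 2, 3)), "identical")
  expect_error(fit_slope(c(0, 1), c(1, 2)), "at least 3")
})

test_that("slope fits are equivariant under scaling and translation", {
  set.seed(13)
  d <- runif(15, 0, 120)
  r <- 2 - 0.008 * d + rnorm(15, 0, 0.05)
  base <- fit_slope(d, r)$slope
  expect_equal(fit_slope(d, 3 * r)$slope, 3 * base, tolerance = 1e-12)
  expect_equal(fit_slope(d + 40, r)$slope, base, tolerance = 1e-10)
})

test_that("noisy linear traces are recovered without slope bias", {
  set.seed(99)
  est <- replicate(200, {
    d <- runif(30, 0, 100)
    fit_slope(d, 1.5 - 0.005 * d + rnorm(30, 0, 0.05))$slope
  })
  expect_lt(abs(mean(est) - (-0.005)) / 0.005, 0.10)
})

test_that("slope distributions summarize conditions and report empty groups", {
  out <- slope_distribution(c(-0.01), "control")
  expect_equal(out$summary$fraction_negative, 1)
  mixed <- slope_distribution(c(-0.02, -0.01, 0.005, NA),
                              c("a", "a", "a", "b"))
  a <- mixed$summary[mixed$summary$condition == "a", ]
  expect_equal(a$fraction_negative, 2 / 3, tolerance = 1e-12)
  b <- mixed$summary[mixed$summary$condition == "b", ]
  expect_equal(b$n, 0)
  expect_true(is.na(b$mean))
})

test_that("traces are built per neurite with one point per organelle", {
  tab <- data.frame(
    compartment = c("neurite", "neurite", "neurite", "soma", "neurite"),
    neurite = c(1, 1, 1, NA, 2),
    dist_um = c(10, 50, 90, NA, 20),
    green = c(2, 1.5, 1, 5, 3), red = c(1, 1, 1, 2, 1)
  )
  tr <- neurite_traces(tab)
  expect_equal(nrow(tr$points), 4)               # soma excluded
  s1 <- tr$slopes[tr$slopes$neurite == 1, ]
  expect_equal(s1$slope, -0.0125)                # exact line 2, 1.5, 1 over 10..90
  expect_true(is.na(tr$slopes$slope[tr$slopes$neurite == 2]))  # too few points
})

test_that("compartment kinetics flags empty compartments and equal inputs agree", {
  soma_only <- lapply(1:3, function(i) {
    data.frame(compartment = "soma", green = c(4, 5), red = c(1, 1))
  })
  ck <- compartment_kinetics(soma_only, 1:3)
  expect_true(all(is.na(ck$series$mean_green[ck$series$compartment == "neurite"])))
  # identical pools in both compartments: identical series
  both <- lapply(c(5, 4, 3), function(g) {
    data.frame(compartment = rep(c("soma", "neurite"), each = 3),
               green = g, red = 1)
  })
  ck2 <- compartment_kinetics(both, 1:3)
  s <- ck2$series
  expect_equal(s$mean_green[s$compartment == "soma"],
               s$mean_green[s$compartment == "neurite"])
  expect_equal(ck2$summary$peak_time, c(1, 1))
  expect_error(compartment_kinetics(both[1:2], 1:2), "at least 3")
})
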