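#' Kinetic parameters of the two-pool timer model
#'
#' The fluorescent timer is synthesized and imported as a green species that
#' matures irreversibly into a red species; autophagic turnover removes both
#' colors at the same rate. At whole-cell resolution the pools obey
#' \deqn{dG/dt = s \cdot 1[\mathrm{import\ on}](t) - (k_{mat} + k_{deg}) G}
#' \deqn{dR/dt = k_{mat} G - k_{deg} R}
#' where `G` and `R` are green and red amounts in arbitrary intensity units.
#'
#' @param k_mat Maturation rate (per hour) of the green-to-red transition.
#'   Defaults to `log(2)/24`, i.e. a 24 h half-transition matching the
#'   probe's reported day-scale color shift.
#' @param k_deg First-order turnover rate (per hour) acting equally on both
#'   pools (autophagic degradation of whole organelle content).
#' @param s Synthesis/import rate in intensity units per hour while import is
#'   switched on.
#' @param import_windows `NULL` for import always on, or a two-column
#'   numeric matrix/data frame of `(start, end)` hours during which import is
#'   on. Windows must be finite, ordered and non-overlapping. Induction
#'   schedules (continuous vs. pulse) and import blocks (depolarization) are
#'   expressed through these windows.
#' @param lag Delay (hours) added to every window start and end, modelling
#'   the transcription/translation/import lag between induction and visible
#'   green signal. Default 0.
#'
#' @return An object of class `timer_params`.
#' @examples
#' p <- timer_params(k_mat = log(2) / 24, k_deg = 0.02, s = 1)
#' steady_state_ratio(p)
#' @export
timer_params <- function(k_mat = log(2) / 24, k_deg = 0, s = 0,
                         import_windows = NULL, lag = 0) {
  check_number(k_mat, "k_mat", lower = 0)
  check_number(k_deg, "k_deg", lower = 0)
  check_number(s, "s", lower = 0)
  check_number(lag, "lag", lower = 0)
  if (!is.null(import_windows)) {
    import_windows <- as.matrix(import_windows)
    if (ncol(import_windows) != 2L || !is.numeric(import_windows)) {
      stopf("'import_windows' must be a two-column numeric matrix (start, end)")
    }
    if (any(!is.finite(import_windows))) {
      stopf("'import_windows' must be finite")
    }
    if (any(import_windows[, 2] <= import_windows[, 1])) {
      stopf("each import window must have end > start")
    }
    if (nrow(import_windows) > 1L) {
      o <- order(import_windows[, 1])
      import_windows <- import_windows[o, , drop = FALSE]
      if (any(import_windows[-1L, 1] < import_windows[-nrow(import_windows), 2])) {
        stopf("'import_windows' must be non-overlapping")
      }
    }
    colnames(import_windows) <- c("start", "end")
  }
  structure(
    list(k_mat = k_mat, k_deg = k_deg, s = s,
         import_windows = import_windows, lag = lag),
    class = "timer_params"
  )
}

#' @export
print.timer_params <- function(x, ...) {
  cat("Timer kinetic parameters\n")
  cat(sprintf("  k_mat: %.5g /h   k_deg: %.5g /h   s: %.5g units/h\n",
              x$k_mat, x$k_deg, x$s))
  if (is.null(x$import_windows)) {
    cat("  import: always on")
  } else {
    cat("  import windows (h):",
        paste(sprintf("[%g, %g]", x$import_windows[, 1] + x$lag,
                      x$import_windows[, 2] + x$lag), collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# TRUE iff import is on at time t (right-continuous at window edges).
import_on_at <- function(params, t) {
  w <- params$import_windows
  if (is.null(w)) return(rep(TRUE, length(t)))
  tt <- t - params$lag
  on <- rep(FALSE, length(t))
  for (i in seq_len(nrow(w))) on <- on | (tt >= w[i, 1] & tt < w[i, 2])
  on
}

# Breakpoints of the import schedule inside (t0, t1).
schedule_breaks <- function(params, t0, t1) {
  w <- params$import_windows
  if (is.null(w)) return(numeric(0))
  b <- sort(unique(c(w[, 1], w[, 2]))) + params$lag
  b[b > t0 + 1e-12 & b < t1 - 1e-12]
}

## Fixed-step classical 4th-order Runge-Kutta for the linear system
## y' = M y + c with piecewise-constant coefficients. For a linear system a
## single RK4 step of size h is the exact affine map y -> A(h) y + b(h);
## composing maps (with binary powering across uniform segments) reproduces
## the stepper's trajectory without looping over every step.

rk4_affine_step <- function(M, cvec, h) {
  I2 <- diag(2)
  M2 <- M %*% M
  M3 <- M2 %*% M
  A <- I2 + h * M + (h^2 / 2) * M2 + (h^3 / 6) * M3 + (h^4 / 24) * (M3 %*% M)
  b <- (h * I2 + (h^2 / 2) * M + (h^3 / 6) * M2 + (h^4 / 24) * M3) %*% cvec
  list(A = A, b = as.numeric(b))
}

affine_identity <- function() list(A = diag(2), b = c(0, 0))

# f2 after f1
affine_compose <- function(f2, f1) {
  list(A = f2$A %*% f1$A, b = as.numeric(f2$A %*% f1$b) + f2$b)
}

affine_power <- function(f, m) {
  out <- affine_identity()
  base <- f
  while (m > 0) {
    if (m %% 2 == 1) out <- affine_compose(base, out)
    base <- affine_compose(base, base)
    m <- m %/% 2
  }
  out
}

# Affine map advancing the state across a segment of length L with constant
# import state, using RK4 steps of size h (plus one short remainder step).
segment_map <- function(M, cvec, L, h) {
  m <- floor((L + 1e-12) / h)
  r <- L - m * h
  f <- affine_power(rk4_affine_step(M, cvec, h), m)
  if (r > 1e-10) f <- affine_compose(rk4_affine_step(M, cvec, r), f)
  f
}

#' Simulate the two-pool timer trajectory
#'
#' Integrates the green/red pool system on a time grid with a fixed-step
#' classical 4th-order Runge-Kutta scheme (step 0.01 h by default), splitting
#' steps exactly at import-schedule boundaries.
#'
#' @param params A [timer_params()] object.
#' @param t_grid Strictly increasing vector of output times (hours).
#' @param init Length-2 numeric `c(green, red)` initial amounts at
#'   `t_grid[1]`; both non-negative. Default `c(0, 0)`.
#' @param step Internal integrator step in hours (default 0.01).
#'
#' @return A `timer_trajectory` data frame with columns `t_hours`, `green`,
#'   `red` and `red_green_ratio` (`NA` where green is zero), and the
#'   generating parameters stored in the `"params"` attribute.
#' @examples
#' p <- timer_params(k_mat = log(2) / 24)
#' tr <- simulate_pools(p, seq(0, 48, by = 1), init = c(1, 0))
#' tr[tr$t_hours == 24, ]  # half of the initial green has matured
#' @export
simulate_pools <- function(params, t_grid, init = c(0, 0), step = 0.01) {
  stopifnot(inherits(params, "timer_params"))
  if (length(t_grid) == 0L) stopf("'t_grid' must be non-empty")
  if (!is.numeric(t_grid) || any(!is.finite(t_grid))) {
    stopf("'t_grid' must be finite numeric")
  }
  if (length(t_grid) > 1L && any(diff(t_grid) <= 0)) {
    stopf("'t_grid' must be strictly increasing")
  }
  if (length(init) != 2L || any(init < 0) || any(!is.finite(init))) {
    stopf("'init' must be two non-negative finite numbers (green, red)")
  }
  check_number(step, "step", lower = 1e-6)

  a <- params$k_mat + params$k_deg
  M <- matrix(c(-a, params$k_mat, 0, -params$k_deg), 2, 2)
  c_on <- c(params$s, 0)
  c_off <- c(0, 0)

  n <- length(t_grid)
  out <- matrix(0, n, 2)
  y <- as.numeric(init)
  out[1, ] <- y
  if (n > 1L) {
    for (i in 2:n) {
      t0 <- t_grid[i - 1L]
      t1 <- t_grid[i]
      edges <- c(t0, schedule_breaks(params, t0, t1), t1)
      for (k in seq_len(length(edges) - 1L)) {
        on <- import_on_at(params, edges[k])
        f <- segment_map(M, if (on) c_on else c_off, edges[k + 1L] - edges[k], step)
        y <- as.numeric(f$A %*% y) + f$b
      }
      out[i, ] <- y
    }
  }
  out[out < 0 & out > -1e-9] <- 0
  traj <- data.frame(
    t_hours = t_grid,
    green = out[, 1],
    red = out[, 2],
    red_green_ratio = ifelse(out[, 1] > 0, out[, 2] / out[, 1], NA_real_)
  )
  attr(traj, "params") <- params
  class(traj) <- c("timer_trajectory", "data.frame")
  traj
}

#' Steady-state red/green ratio under continuous induction
#'
#' With import continuously on and `k_deg > 0` the pools settle to
#' `G* = s / (k_mat + k_deg)` and `R* = k_mat G* / k_deg`, so the limiting
#' red/green ratio is `k_mat / k_deg` independent of the expression level
#' `s` (the ratio, not the intensities, is the age readout).
#'
#' @param params A [timer_params()] object with `k_deg > 0`.
#' @return The limiting red/green ratio `k_mat / k_deg`.
#' @export
steady_state_ratio <- function(params) {
  stopifnot(inherits(params, "timer_params"))
  if (params$k_deg <= 0) {
    stopf("no steady state: k_deg must be > 0 for the ratio to converge")
  }
  params$k_mat / params$k_deg
}

#' Fit timer kinetic parameters to a trajectory
#'
#' Least-squares fit of the free parameters of the two-pool model to observed
#' green and red time series, by Levenberg-Marquardt on the stacked residuals
#' of both channels against [simulate_pools()] run from the trajectory's
#' first observation.
#'
#' @param traj A `timer_trajectory` (or data frame with `t_hours`, `green`,
#'   `red`) with at least 4 time points.
#' @param params A [timer_params()] holding the known parameter values and
#'   the import schedule; entries named in `free` are treated as unknowns.
#' @param free Character vector naming the parameters to estimate, a subset
#'   of `c("k_mat", "k_deg", "s")`.
#' @param start Optional named numeric of starting values for the free
#'   parameters; defaults to the values in `params` (or 0.05 where those are
#'   zero).
#' @return A `timer_fit` list with elements `params` (fitted
#'   [timer_params()]), `estimates`, `residual_ss`, `converged` and
#'   `message`.
#' @export
fit_kinetics <- function(traj, params, free = "k_mat", start = NULL) {
  stopifnot(is.data.frame(traj))
  need <- c("t_hours", "green", "red")
  if (!all(need %in% names(traj))) {
    stopf("'traj' must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(traj) < 4L) stopf("need at least 4 time points to fit")
  if (all(traj$green == 0) && all(traj$red == 0)) {
    stopf("unidentifiable: trajectory is all zeros")
  }
  if (stats::sd(traj$green) == 0 && stats::sd(traj$red) == 0) {
    stopf("unidentifiable: both channels are constant")
  }
  free <- match.arg(free, c("k_mat", "k_deg", "s"), several.ok = TRUE)
  stopifnot(inherits(params, "timer_params"))

  p0 <- vapply(free, function(nm) {
    v <- if (!is.null(start) && nm %in% names(start)) start[[nm]] else params[[nm]]
    if (v <= 0) 0.05 else v
  }, numeric(1))
  init <- c(traj$green[1], traj$red[1])
  obs <- c(traj$green, traj$red)

  make_params <- function(theta) {
    p <- params
    for (nm in free) p[[nm]] <- max(theta[[nm]], 0)
    p
  }
  resid_fn <- function(theta) {
    names(theta) <- free
    sim <- simulate_pools(make_params(as.list(theta)), traj$t_hours, init = init)
    c(sim$green, sim$red) - obs
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = rep(0, length(p0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- as.list(stats::coef(fit))
  names(est) <- free
  converged <- fit$info %in% 1:4
  if (!converged) {
    warnf("fit did not converge: %s", fit$message)
  }
  out <- list(
    params = make_params(est),
    estimates = unlist(est),
    residual_ss = fit$deviance,
    converged = converged,
    message = fit$message
  )
  class(out) <- "timer_fit"
  out
}

#' @export
print.timer_fit <- function(x, ...) {
  cat("Timer kinetics fit\n")
  cat("  estimates:",
      paste(sprintf("%s = %.6g", names(x$estimates), x$estimates),
            collapse = ", "), "\n")
  cat(sprintf("  residual SS: %.6g  converged: %s\n", x$residual_ss, x$converged))
  invisible(x)
}

# Remove `block` (start, end) from a set of on-windows.
subtract_window <- function(windows, block) {
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(windows))) {
    s <- windows[i, 1]; e <- windows[i, 2]
    if (block[2] <= s || block[1] >= e) {
      out <- rbind(out, c(s, e))
    } else {
      if (block[1] > s) out <- rbind(out, c(s, block[1]))
      if (block[2] < e) out <- rbind(out, c(block[2], e))
    }
  }
  out
}

#' Named induction/turnover scenarios
#'
#' Builds the import schedule for a named experimental scenario and runs the
#' two-pool model from empty pools at time 0:
#' \describe{
#'   \item{`continuous`}{doxycycline-style induction on for the whole run.}
#'   \item{`pulse`}{induction only during `[0, pulse_hours]`.}
#'   \item{`import_block`}{induction on, but protein import blocked
#'     (depolarization analog) during `block_window`; when `synthesis_on` is
#'     `FALSE` the inducer is withdrawn at `block_window[1]` so the block has
#'     nothing to block.}
#'   \item{`autophagy_off`}{continuous induction with `k_deg` forced to 0
#'     (autophagy inhibition analog).}
#' }
#'
#' @param scenario One of `"continuous"`, `"pulse"`, `"import_block"`,
#'   `"autophagy_off"`.
#' @param params Baseline [timer_params()]; its `import_windows` are replaced
#'   by the scenario schedule.
#' @param t_grid Output time grid (hours) starting at 0.
#' @param pulse_hours Pulse length for `"pulse"` (default 4 h).
#' @param block_window Import-block interval for `"import_block"`
#'   (default `c(21, 24)` h).
#' @param synthesis_on For `"import_block"`: whether synthesis is ongoing
#'   during the block (default `TRUE`).
#' @return A `timer_trajectory` (see [simulate_pools()]).
#' @export
scenario_trajectory <- function(scenario = c("continuous", "pulse",
                                             "import_block", "autophagy_off"),
                                params = timer_params(s = 1, k_deg = 0.02),
                                t_grid = seq(0, 24, by = 0.5),
                                pulse_hours = 4,
                                block_window = c(21, 24),
                                synthesis_on = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "timer_params"))
  if (t_grid[1] != 0) stopf("'t_grid' must start at 0 (induction start)")
  t_end <- max(t_grid)
  p <- params
  p$import_windows <- switch(
    scenario,
    continuous = NULL,
    pulse = cbind(start = 0, end = pulse_hours),
    import_block = {
      base <- if (synthesis_on) cbind(0, t_end) else cbind(0, block_window[1])
      w <- subtract_window(base, block_window)
      if (nrow(w) == 0) NULL else w
    },
    autophagy_off = NULL
  )
  if (scenario == "autophagy_off") p$k_deg <- 0
  p <- timer_params(k_mat = p$k_mat, k_deg = p$k_deg, s = p$s,
                    import_windows = p$import_windows, lag = p$lag)
  simulate_pools(p, t_grid)
}

#' Red/green ratio of a named scenario at a given time
#'
#' @inheritParams scenario_trajectory
#' @param eval_t Evaluation time in hours (> 0).
#' @return The red/green ratio at `eval_t`.
#' @export
scenario_ratio <- function(scenario, eval_t, params = timer_params(s = 1, k_deg = 0.02),
                           ...) {
  check_number(eval_t, "eval_t", lower = 0)
  if (eval_t <= 0) {
    stopf("undefined ratio: eval_t must be after induction start (G = R = 0 at t = 0)")
  }
  tr <- scenario_trajectory(scenario, params = params, t_grid = c(0, eval_t), ...)
  g <- tr$green[nrow(tr)]
  if (g <= 0) stopf("undefined ratio: green pool is zero at eval_t")
  tr$red[nrow(tr)] / g
}

#' Write / read a trajectory as CSV
#'
#' Columns: `t_hours`, `green`, `red`, `red_green_ratio`.
#' @param traj A `timer_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a `timer_trajectory` (without params).
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  traj <- utils::read.csv(path)
  class(traj) <- c("timer_trajectory", "data.frame")
  traj
}
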