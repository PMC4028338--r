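#' Configuration of the mitochondrial network simulator
#'
#' Parameters of the seeded agent-based model: a population of mitochondria,
#' each carrying green and red timer pools, evolving by (1) timer kinetics
#' with size- and position-weighted import, (2) fusion with complete content
#' mixing, (3) fission with proportional content split, (4) mitophagy,
#' (5) optional biogenesis of new green-only organelles and (6) motility.
#' Events are drawn per fixed time step as Bernoulli trials; every event
#' probability `rate * dt` must stay at or below 0.1 (accuracy guard for the
#' discrete-time approximation of the underlying Poisson processes).
#'
#' @param n_init Initial number of mitochondria.
#' @param k_mat,k_deg Maturation and protein-turnover rates (per hour), as in
#'   [timer_params()]. `k_deg` here is continuous protein loss; discrete
#'   whole-organelle removal is `mitophagy_rate`.
#' @param s Total cellular synthesis/import rate (intensity units per hour),
#'   shared across mitochondria proportionally to `size` and, in neuron
#'   mode, to `exp(-dist / import_lambda)`.
#' @param import_mode `"packet"` (default): import arrives as discrete
#'   protein packets of size `import_packet`, Poisson-distributed per
#'   organelle per step — the stochastic source of age heterogeneity.
#'   `"continuous"`: deterministic mean-field import (used for closed-form
#'   cross-checks).
#' @param import_packet Packet size (intensity units) in packet mode.
#' @param import_lambda Length scale (um) of the distance decay of import
#'   access in neuron mode.
#' @param import_windows Import on-windows as in [timer_params()]
#'   (`NULL` = always on).
#' @param fusion_rate Fusion events per candidate pair per hour. In
#'   well-mixed mode every pair is a candidate; in neuron mode only pairs of
#'   soma residents or same-neurite neighbours within `capture_dist`.
#' @param fission_rate Fission events per mitochondrion per hour; the split
#'   fraction is uniform on [0.3, 0.7] and both fragments inherit the parent
#'   red/green ratio exactly. Organelles smaller than `min_size / 0.3` do
#'   not divide.
#' @param min_size Lower size bound enforced through the fission rule.
#' @param mitophagy_rate Whole-organelle removal events per mitochondrion per
#'   hour.
#' @param mitophagy_bias_red If `TRUE`, removal probability is weighted by
#'   the organelle's red/green ratio (age-selective mitophagy). Default
#'   `FALSE`: removal is uniform.
#' @param biogenesis_rate New-organelle events per cell per hour (Poisson);
#'   newborns have size `newborn_size` and green-only content
#'   `newborn_green`.
#' @param newborn_size,newborn_green Size and green content of newborns.
#' @param motility_D Along-path (or free 2D) diffusivity, um^2 per hour.
#' @param shuttle_rate Transport-run events per neurite mitochondrion per
#'   hour; an event relocates the organelle uniformly along its neurite,
#'   modelling fast bidirectional microtubule transport.
#' @param capture_dist Fusion capture distance (um) in neuron mode.
#' @param soma_fraction Fraction of the initial population placed in the
#'   soma (neuron mode).
#' @param init_pools `"empty"`, or `"preloaded"` to start every organelle
#'   with `init_green * size` green and `init_red * size` red (a population
#'   that already expressed the probe before time 0).
#' @param init_green,init_red Per-unit-size initial pool densities for
#'   `"preloaded"`.
#' @param size_meanlog,size_sdlog Log-normal initial size distribution.
#' @param dt Time step (hours).
#' @param t_end End time (hours); must be a multiple of `dt`.
#' @param seed Master RNG seed; one generator drives all draws in a fixed
#'   order, so runs are bit-reproducible.
#' @return A `network_config` object.
#' @export
network_config <- function(n_init = 120,
                           k_mat = log(2) / 24, k_deg = 0.01, s = 60,
                           import_mode = c("packet", "continuous"),
                           import_packet = 0.5, import_lambda = 25,
                           import_windows = NULL,
                           fusion_rate = 0, fission_rate = 0.3, min_size = 0.25,
                           mitophagy_rate = 0.02, mitophagy_bias_red = FALSE,
                           biogenesis_rate = 0, newborn_size = 0.3,
                           newborn_green = 0.5,
                           motility_D = 0.5, shuttle_rate = 0,
                           capture_dist = 1, soma_fraction = 0.4,
                           init_pools = c("empty", "preloaded"),
                           init_green = 0, init_red = 0,
                           size_meanlog = 0, size_sdlog = 0.4,
                           dt = 0.1, t_end = 24, seed = 1) {
  import_mode <- match.arg(import_mode)
  init_pools <- match.arg(init_pools)
  for (nm in c("n_init", "k_mat", "k_deg", "s", "import_packet",
               "import_lambda", "fusion_rate", "fission_rate", "min_size",
               "mitophagy_rate", "biogenesis_rate", "newborn_size",
               "newborn_green", "motility_D", "shuttle_rate", "capture_dist",
               "init_green", "init_red")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(dt, "dt", lower = 1e-6)
  check_number(t_end, "t_end", lower = 0)
  if (t_end < dt) stopf("'t_end' must be at least one step 'dt'")
  if (abs(t_end / dt - round(t_end / dt)) > 1e-6) {
    stopf("'t_end' must be a multiple of 'dt'")
  }
  for (nm in c("fusion_rate", "fission_rate", "mitophagy_rate", "shuttle_rate")) {
    if (get(nm) * dt > 0.1 + 1e-12) {
      stopf("event probability per step for '%s' is %g * %g = %g > 0.1; reduce dt",
            nm, get(nm), dt, get(nm) * dt)
    }
  }
  # validate windows through the kinetics constructor
  kp <- timer_params(k_mat = k_mat, k_deg = k_deg, s = s,
                     import_windows = import_windows)
  structure(
    list(n_init = as.integer(n_init), k_mat = k_mat, k_deg = k_deg, s = s,
         import_mode = import_mode, import_packet = import_packet,
         import_lambda = import_lambda, import_windows = kp$import_windows,
         fusion_rate = fusion_rate, fission_rate = fission_rate,
         min_size = min_size, mitophagy_rate = mitophagy_rate,
         mitophagy_bias_red = mitophagy_bias_red,
         biogenesis_rate = biogenesis_rate, newborn_size = newborn_size,
         newborn_green = newborn_green, motility_D = motility_D,
         shuttle_rate = shuttle_rate, capture_dist = capture_dist,
         soma_fraction = soma_fraction, init_pools = init_pools,
         init_green = init_green, init_red = init_red,
         size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         dt = dt, t_end = t_end, seed = as.integer(seed)),
    class = "network_config"
  )
}

# Exact update of (green, red) pools over one step of length dt with
# per-organelle constant import s (vectorized closed form of the linear
# two-pool system).
propagate_pools_vec <- function(green, red, s, k_mat, k_deg, dt) {
  a <- k_mat + k_deg
  if (a == 0) {
    return(list(green = green + s * dt, red = red))
  }
  gs <- s / a
  ea <- exp(-a * dt)
  ed <- exp(-k_deg * dt)
  g_new <- gs + (green - gs) * ea
  r_new <- red * ed +
    k_mat * (gs * phi_exp(k_deg, dt) + (green - gs) * ed * phi_exp(k_mat, dt))
  list(green = pmax(g_new, 0), red = pmax(r_new, 0))
}

# Initial population. State is a plain list of parallel vectors for speed;
# `nid` is NA for soma (neuron mode) or free (well-mixed) residents.
init_network <- function(config, geometry) {
  n <- config$n_init
  size <- pmax(stats::rlnorm(n, config$size_meanlog, config$size_sdlog),
               config$min_size)
  if (config$init_pools == "preloaded") {
    green <- config$init_green * size
    red <- config$init_red * size
  } else {
    green <- red <- rep(0, n)
  }
  if (geometry$mode == "well_mixed") {
    nid <- rep(NA_integer_, n)
    d <- rep(NA_real_, n)
    x <- stats::runif(n, 0, geometry$extent)
    y <- stats::runif(n, 0, geometry$extent)
  } else {
    n_soma <- round(config$soma_fraction * n)
    lens <- neurite_lengths(geometry)
    nid <- c(rep(NA_integer_, n_soma),
             sample.int(length(lens), n - n_soma, replace = TRUE,
                        prob = lens / sum(lens)))
    d <- rep(NA_real_, n)
    x <- y <- rep(NA_real_, n)
    rr <- geometry$soma_radius * sqrt(stats::runif(n_soma))
    th <- stats::runif(n_soma, 0, 2 * pi)
    x[seq_len(n_soma)] <- geometry$soma_center[1] + rr * cos(th)
    y[seq_len(n_soma)] <- geometry$soma_center[2] + rr * sin(th)
    idx <- which(!is.na(nid))
    d[idx] <- stats::runif(length(idx)) * lens[nid[idx]]
  }
  list(time = 0, id = seq_len(n), size = size, green = green, red = red,
       nid = nid, d = d, x = x, y = y, next_id = n + 1L,
       counts = c(fusions = 0, fissions = 0, mitophagy = 0, biogenesis = 0))
}

# Decode pair index m (1-based, pairs (i, j) with i < j enumerated by i) of
# an n-element set.
decode_pair <- function(m, n) {
  i <- 1L
  while (m > n - i) {
    m <- m - (n - i)
    i <- i + 1L
  }
  c(i, i + m)
}

schedule_on <- function(windows, t) {
  if (is.null(windows)) return(TRUE)
  any(t >= windows[, 1] & t < windows[, 2])
}

#' Advance the network by one time step
#'
#' Applies, in order: pool kinetics with weighted import, fusion, fission,
#' mitophagy, biogenesis, and position updates. Fusion sums size and both
#' pools exactly; fission splits them by one uniform fraction so both
#' fragments inherit the parent's red/green ratio exactly.
#'
#' @param state A network state as produced by [run_simulation()]
#'   (`$final_state`) or internally by the stepper.
#' @param config A [network_config()].
#' @param geometry A [cell_geometry()].
#' @return The updated state.
#' @export
step_network <- function(state, config, geometry) {
  dt <- config$dt
  n <- length(state$id)
  neuron <- geometry$mode == "neuron"

  ## (1) pools: import weighted by size and, in neuron mode, distance decay
  if (n > 0L) {
    w <- state$size
    if (neuron) {
      acc <- ifelse(is.na(state$nid), 1, exp(-state$d / config$import_lambda))
      w <- w * acc
    }
    on <- schedule_on(config$import_windows, state$time + dt / 2)
    s_i <- if (on && sum(w) > 0) config$s * w / sum(w) else rep(0, n)
    if (config$import_mode == "continuous") {
      pools <- propagate_pools_vec(state$green, state$red, s_i,
                                   config$k_mat, config$k_deg, dt)
      state$green <- pools$green
      state$red <- pools$red
    } else {
      pools <- propagate_pools_vec(state$green, state$red, 0,
                                   config$k_mat, config$k_deg, dt)
      npack <- stats::rpois(n, s_i * dt / config$import_packet)
      state$green <- pools$green + npack * config$import_packet
      state$red <- pools$red
    }
  }

  ## (2) fusion with complete content mixing
  if (config$fusion_rate > 0 && n >= 2L) {
    p <- config$fusion_rate * dt
    pairs <- NULL
    if (!neuron) {
      npair <- n * (n - 1) / 2
      k <- stats::rbinom(1L, npair, p)
      if (k > 0L) {
        sel <- sample.int(npair, min(k, npair))
        pairs <- t(vapply(sel, decode_pair, integer(2), n = n))
      }
    } else {
      cand_i <- integer(0); cand_j <- integer(0); cand_p <- numeric(0)
      soma_idx <- which(is.na(state$nid))
      if (length(soma_idx) >= 2L) {
        # soma pairs meet only when nearby: scale the per-pair probability
        # by the encounter factor (capture area over soma area)
        p_soma <- p * min(1, (config$capture_dist / geometry$soma_radius)^2)
        cp <- utils::combn(soma_idx, 2L)
        cand_i <- c(cand_i, cp[1, ]); cand_j <- c(cand_j, cp[2, ])
        cand_p <- c(cand_p, rep(p_soma, ncol(cp)))
      }
      for (ni in seq_along(geometry$neurites)) {
        mem <- which(!is.na(state$nid) & state$nid == ni)
        if (length(mem) >= 2L) {
          mem <- mem[order(state$d[mem])]
          gaps <- diff(state$d[mem])
          ok <- which(gaps <= config$capture_dist)
          cand_i <- c(cand_i, mem[ok]); cand_j <- c(cand_j, mem[ok + 1L])
          cand_p <- c(cand_p, rep(p, length(ok)))
        }
      }
      if (length(cand_i) > 0L) {
        hit <- which(stats::runif(length(cand_i)) < cand_p)
        if (length(hit) > 0L) pairs <- cbind(cand_i[hit], cand_j[hit])
      }
    }
    if (!is.null(pairs)) {
      used <- rep(FALSE, n)
      drop <- rep(FALSE, n)
      nfus <- 0
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (used[i] || used[j]) next
        wsum <- state$size[i] + state$size[j]
        wi <- state$size[i] / wsum
        if (is.na(state$nid[i])) {
          state$x[i] <- wi * state$x[i] + (1 - wi) * state$x[j]
          state$y[i] <- wi * state$y[i] + (1 - wi) * state$y[j]
        } else {
          state$d[i] <- wi * state$d[i] + (1 - wi) * state$d[j]
        }
        state$size[i] <- wsum
        state$green[i] <- state$green[i] + state$green[j]
        state$red[i] <- state$red[i] + state$red[j]
        used[i] <- used[j] <- TRUE
        drop[j] <- TRUE
        nfus <- nfus + 1
      }
      if (any(drop)) {
        keep <- !drop
        for (f in c("id", "size", "green", "red", "nid", "d", "x", "y")) {
          state[[f]] <- state[[f]][keep]
        }
        n <- length(state$id)
      }
      state$counts["fusions"] <- state$counts["fusions"] + nfus
    }
  }

  ## (3) fission with proportional content split
  if (config$fission_rate > 0 && n > 0L) {
    eligible <- state$size >= config$min_size / 0.3
    sel <- which(stats::runif(n) < config$fission_rate * dt & eligible)
    if (length(sel) > 0L) {
      f <- stats::runif(length(sel), 0.3, 0.7)
      child <- list(
        id = state$next_id + seq_along(sel) - 1L,
        size = state$size[sel] * (1 - f),
        green = state$green[sel] * (1 - f),
        red = state$red[sel] * (1 - f),
        nid = state$nid[sel], d = state$d[sel],
        x = state$x[sel], y = state$y[sel]
      )
      state$size[sel] <- state$size[sel] * f
      state$green[sel] <- state$green[sel] * f
      state$red[sel] <- state$red[sel] * f
      for (fld in c("id", "size", "green", "red", "nid", "d", "x", "y")) {
        state[[fld]] <- c(state[[fld]], child[[fld]])
      }
      state$next_id <- state$next_id + length(sel)
      state$counts["fissions"] <- state$counts["fissions"] + length(sel)
      n <- length(state$id)
    }
  }

  ## (4) mitophagy
  if (config$mitophagy_rate > 0 && n > 0L) {
    p_i <- rep(config$mitophagy_rate * dt, n)
    if (config$mitophagy_bias_red) {
      ratio <- ifelse(state$green > 0, state$red / state$green, 1)
      mr <- mean(ratio)
      if (mr > 0) p_i <- pmin(p_i * ratio / mr, 0.5)
    }
    kill <- stats::runif(n) < p_i
    if (any(kill)) {
      keep <- !kill
      for (f in c("id", "size", "green", "red", "nid", "d", "x", "y")) {
        state[[f]] <- state[[f]][keep]
      }
      state$counts["mitophagy"] <- state$counts["mitophagy"] + sum(kill)
      n <- length(state$id)
    }
  }

  ## (5) biogenesis: new green-only organelles
  if (config$biogenesis_rate > 0) {
    kb <- stats::rpois(1L, config$biogenesis_rate * dt)
    if (kb > 0L) {
      if (neuron) {
        rr <- geometry$soma_radius * sqrt(stats::runif(kb))
        th <- stats::runif(kb, 0, 2 * pi)
        nx <- geometry$soma_center[1] + rr * cos(th)
        ny <- geometry$soma_center[2] + rr * sin(th)
        nnid <- rep(NA_integer_, kb); nd <- rep(NA_real_, kb)
      } else {
        nx <- stats::runif(kb, 0, geometry$extent)
        ny <- stats::runif(kb, 0, geometry$extent)
        nnid <- rep(NA_integer_, kb); nd <- rep(NA_real_, kb)
      }
      add <- list(id = state$next_id + seq_len(kb) - 1L,
                  size = rep(config$newborn_size, kb),
                  green = rep(config$newborn_green, kb),
                  red = rep(0, kb), nid = nnid, d = nd, x = nx, y = ny)
      for (f in c("id", "size", "green", "red", "nid", "d", "x", "y")) {
        state[[f]] <- c(state[[f]], add[[f]])
      }
      state$next_id <- state$next_id + kb
      state$counts["biogenesis"] <- state$counts["biogenesis"] + kb
      n <- length(state$id)
    }
  }

  ## (6) motility: along-path / free diffusion, reflecting boundaries,
  ##     plus transport-run relocation events
  if (n > 0L && (config$motility_D > 0 || config$shuttle_rate > 0)) {
    sdstep <- sqrt(2 * config$motility_D * dt)
    if (!neuron) {
      if (config$motility_D > 0) {
        state$x <- reflect_interval(state$x + stats::rnorm(n, 0, sdstep),
                                    0, geometry$extent)
        state$y <- reflect_interval(state$y + stats::rnorm(n, 0, sdstep),
                                    0, geometry$extent)
      }
    } else {
      on_neurite <- which(!is.na(state$nid))
      lens <- neurite_lengths(geometry)
      if (config$motility_D > 0 && length(on_neurite) > 0L) {
        dn <- state$d[on_neurite] + stats::rnorm(length(on_neurite), 0, sdstep)
        state$d[on_neurite] <- reflect_interval(dn, 0, lens[state$nid[on_neurite]])
      }
      if (config$shuttle_rate > 0 && length(on_neurite) > 0L) {
        hop <- stats::runif(length(on_neurite)) < config$shuttle_rate * dt
        if (any(hop)) {
          tgt <- on_neurite[hop]
          state$d[tgt] <- stats::runif(length(tgt)) * lens[state$nid[tgt]]
        }
      }
    }
  }

  state$time <- state$time + dt
  state
}

# Reflect values into [lo, hi] (elementwise hi allowed).
reflect_interval <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}

# Measurement table of a state (simulator ground truth).
network_table <- function(state, geometry) {
  n <- length(state$id)
  neuron <- geometry$mode == "neuron"
  comp <- if (neuron) ifelse(is.na(state$nid), "soma", "neurite") else rep("free", n)
  x <- state$x
  y <- state$y
  if (neuron && n > 0L) {
    for (ni in seq_along(geometry$neurites)) {
      mem <- which(!is.na(state$nid) & state$nid == ni)
      if (length(mem) > 0L) {
        pts <- point_at_distance(geometry, ni, state$d[mem])
        x[mem] <- pts[, 1]
        y[mem] <- pts[, 2]
      }
    }
  }
  data.frame(
    time = rep(state$time, n), id = state$id, size = state$size,
    green = state$green, red = state$red,
    ratio = ifelse(state$green > 0, state$red / state$green, NA_real_),
    compartment = comp, neurite = state$nid,
    dist_um = ifelse(is.na(state$nid), ifelse(rep(neuron, n), 0, NA_real_),
                     state$d),
    x_um = x, y_um = y
  )
}

#' Run the network simulation
#'
#' Runs the stepper from time 0 to `t_end` under the master seed and emits
#' per-mitochondrion ground-truth tables at the requested snapshot times.
#' Identical configs and seeds give bit-identical output.
#'
#' @param config A [network_config()].
#' @param geometry A [cell_geometry()].
#' @param snapshot_times Times (hours, multiples of `dt`) at which to record
#'   a measurement table. Default: `t_end` only.
#' @return A `mito_simulation` list with `snapshots` (named list of data
#'   frames with columns `time`, `id`, `size`, `green`, `red`, `ratio`,
#'   `compartment`, `neurite`, `dist_um`, `x_um`, `y_um`), `times`,
#'   `final_state`, `counts`, `config` and `geometry`.
#' @examples
#' geo <- cell_geometry("well_mixed", extent = 40)
#' cfg <- network_config(n_init = 50, t_end = 2, seed = 7)
#' sim <- run_simulation(cfg, geo)
#' head(sim$snapshots[[1]])
#' @export
run_simulation <- function(config, geometry, snapshot_times = config$t_end) {
  stopifnot(inherits(config, "network_config"), inherits(geometry, "cell_geometry"))
  if (any(snapshot_times < 0 | snapshot_times > config$t_end)) {
    stopf("snapshot times must lie in [0, t_end]")
  }
  snap_steps <- round(snapshot_times / config$dt)
  if (any(abs(snap_steps * config$dt - snapshot_times) > 1e-6)) {
    stopf("snapshot times must be multiples of dt")
  }
  n_steps <- round(config$t_end / config$dt)
  snapshots <- vector("list", length(snapshot_times))
  names(snapshots) <- sprintf("t=%g", snapshot_times)
  state <- with_seed(config$seed, {
    st <- init_network(config, geometry)
    hit <- which(snap_steps == 0L)
    for (h in hit) snapshots[[h]] <- network_table(st, geometry)
    for (step_i in seq_len(n_steps)) {
      st <- step_network(st, config, geometry)
      hit <- which(snap_steps == step_i)
      for (h in hit) snapshots[[h]] <- network_table(st, geometry)
    }
    st
  })
  structure(
    list(snapshots = snapshots, times = snapshot_times, final_state = state,
         counts = state$counts, config = config, geometry = geometry),
    class = "mito_simulation"
  )
}

#' @export
print.mito_simulation <- function(x, ...) {
  cat(sprintf("Mitochondrial network simulation: %d snapshot(s), t_end = %g h\n",
              length(x$snapshots), x$config$t_end))
  cat(sprintf("  final population: %d organelles\n", length(x$final_state$id)))
  cat("  events:", paste(sprintf("%s = %d", names(x$counts), x$counts),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Size-binned heterogeneity of the red/green ratio
#'
#' Sample standard deviation of per-organelle red/green ratios within size
#' bins (quantile bins of `size`). In fragmented (fusion-deficient)
#' populations the smallest organelles show the greatest age heterogeneity.
#'
#' @param table A measurement table with `size` and `ratio` columns.
#' @param n_bins Number of size-quantile bins (default 4).
#' @param min_per_bin Bins with fewer usable organelles are dropped with a
#'   warning (default 5).
#' @return Data frame with `bin`, `size_min`, `size_max`, `n`, `sd_ratio`.
#' @export
small_mito_heterogeneity <- function(table, n_bins = 4, min_per_bin = 5) {
  stopifnot(is.data.frame(table), all(c("size", "ratio") %in% names(table)))
  tab <- table[is.finite(table$ratio), , drop = FALSE]
  if (nrow(tab) < 2 * min_per_bin) {
    stopf("need at least %d organelles with defined ratios", 2 * min_per_bin)
  }
  br <- unique(stats::quantile(tab$size, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3L) stopf("size distribution too degenerate to bin")
  bin <- cut(tab$size, br, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    v <- tab$ratio[bin == b]
    data.frame(bin = b, size_min = br[b], size_max = br[b + 1L],
               n = length(v),
               sd_ratio = if (length(v) >= 2L) stats::sd(v) else NA_real_)
  }))
  small <- out$n < min_per_bin
  if (any(small)) {
    warnf("dropping %d size bin(s) with fewer than %d organelles",
          sum(small), min_per_bin)
    out <- out[!small, , drop = FALSE]
  }
  if (nrow(out) < 2L) stopf("need at least 2 usable size bins")
  out
}
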