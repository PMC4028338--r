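#' Ordinary least-squares age-versus-distance slope
#'
#' Fits `ratio ~ distance` by OLS. For green/red traces a negative slope
#' means older (redder) protein distally; the slope sign is the age-gradient
#' readout.
#'
#' @param dist Path distances (um), at least 3 points with at least 2
#'   distinct values.
#' @param ratio Green/red (or red/green) ratios, same length.
#' @return List with `slope` (per um), `intercept` and `n`.
#' @export
fit_slope <- function(dist, ratio) {
  ok <- is.finite(dist) & is.finite(ratio)
  dist <- dist[ok]; ratio <- ratio[ok]
  if (length(dist) < 3L) stopf("need at least 3 points to fit a slope")
  if (length(unique(dist)) < 2L) stopf("all distances identical; slope undefined")
  fit <- stats::lm.fit(cbind(1, dist), ratio)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = length(dist))
}

#' Per-neurite age-versus-distance traces
#'
#' Builds one trace per neurite from a per-organelle measurement table:
#' ordered (distance, ratio) points and the OLS best-fit slope. By default
#' the green/red ratio is used (young-to-old readout; negative slope = older
#' protein distally); red/green is available via `direction`.
#'
#' @param table Measurement table with `compartment`, `neurite`, `dist_um`
#'   and either `green`/`red` or `mean_green`/`mean_red` columns. One point
#'   per organelle.
#' @param direction `"green_over_red"` (default) or `"red_over_green"`.
#' @param min_points Traces with fewer points get `NA` slopes (default 3).
#' @return List with `points` (data frame `neurite`, `dist_um`, `ratio`) and
#'   `slopes` (data frame `neurite`, `n`, `slope`, `intercept`).
#' @export
neurite_traces <- function(table, direction = c("green_over_red", "red_over_green"),
                           min_points = 3) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(table))
  g <- if ("mean_green" %in% names(table)) table$mean_green else table$green
  r <- if ("mean_red" %in% names(table)) table$mean_red else table$red
  ratio <- if (direction == "green_over_red") {
    ifelse(r > 0, g / r, NA_real_)
  } else {
    ifelse(g > 0, r / g, NA_real_)
  }
  sel <- table$compartment == "neurite" & is.finite(ratio) &
    is.finite(table$dist_um)
  pts <- data.frame(neurite = table$neurite[sel], dist_um = table$dist_um[sel],
                    ratio = ratio[sel])
  pts <- pts[order(pts$neurite, pts$dist_um), , drop = FALSE]
  slopes <- do.call(rbind, lapply(sort(unique(pts$neurite)), function(ni) {
    sub <- pts[pts$neurite == ni, ]
    fit <- if (nrow(sub) >= min_points && length(unique(sub$dist_um)) >= 2L) {
      fit_slope(sub$dist_um, sub$ratio)
    } else {
      list(slope = NA_real_, intercept = NA_real_, n = nrow(sub))
    }
    data.frame(neurite = ni, n = fit$n, slope = fit$slope,
               intercept = fit$intercept)
  }))
  if (is.null(slopes)) {
    slopes <- data.frame(neurite = integer(0), n = integer(0),
                         slope = numeric(0), intercept = numeric(0))
  }
  list(points = pts, slopes = slopes)
}

#' Distribution of age-versus-distance slopes across conditions
#'
#' Collects per-neurite slopes by condition and reports mean, median and the
#' fraction of negative slopes — the summary used to contrast baseline
#' transport with motility-enhanced conditions.
#'
#' @param slopes Numeric vector of slopes (per um).
#' @param condition Condition label per slope.
#' @return List with `slopes` (data frame `condition`, `slope`) and
#'   `summary` (data frame `condition`, `n`, `mean`, `median`,
#'   `fraction_negative`). Conditions with no valid slopes are reported with
#'   `n = 0`.
#' @export
slope_distribution <- function(slopes, condition) {
  stopifnot(length(slopes) == length(condition))
  df <- data.frame(condition = as.character(condition), slope = slopes)
  summ <- do.call(rbind, lapply(unique(df$condition), function(cc) {
    v <- df$slope[df$condition == cc]
    v <- v[is.finite(v)]
    data.frame(
      condition = cc, n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      median = if (length(v)) stats::median(v) else NA_real_,
      fraction_negative = if (length(v)) mean(v < 0) else NA_real_
    )
  }))
  list(slopes = df, summary = summ)
}

#' Soma versus neurite compartment kinetics
#'
#' From a time-lapse series of measurement tables, computes the mean green
#' and red intensity over organelles in each compartment at every time
#' point, each compartment's green peak time, and the mean post-peak decline
#' rate of green (OLS slope of mean green on time from the peak onward; 0
#' when the peak is at the last time point). A compartment empty at some
#' time gets `NA` there.
#'
#' @param tables List of measurement tables (one per time point) with
#'   `compartment`, `green`, `red` columns.
#' @param times Numeric vector of acquisition times (hours), same length.
#' @return List with `series` (data frame `time`, `compartment`,
#'   `mean_green`, `mean_red`, `n`) and `summary` (data frame `compartment`,
#'   `peak_time`, `post_peak_decline` in intensity units per hour and
#'   `post_peak_decline_frac` as a fraction of the peak per hour; negative =
#'   declining). The fractional rate is the right quantity for comparing
#'   compartments whose absolute intensities differ.
#' @export
compartment_kinetics <- function(tables, times) {
  stopifnot(is.list(tables), length(tables) == length(times))
  if (length(times) < 3L) stopf("need at least 3 time points")
  comps <- c("soma", "neurite")
  series <- do.call(rbind, lapply(seq_along(times), function(i) {
    tab <- tables[[i]]
    do.call(rbind, lapply(comps, function(cc) {
      sub <- tab[tab$compartment == cc, , drop = FALSE]
      g <- if ("mean_green" %in% names(sub)) sub$mean_green else sub$green
      r <- if ("mean_red" %in% names(sub)) sub$mean_red else sub$red
      data.frame(time = times[i], compartment = cc, n = nrow(sub),
                 mean_green = if (nrow(sub)) mean(g) else NA_real_,
                 mean_red = if (nrow(sub)) mean(r) else NA_real_)
    }))
  }))
  summary <- do.call(rbind, lapply(comps, function(cc) {
    sub <- series[series$compartment == cc & is.finite(series$mean_green), ]
    if (nrow(sub) < 3L) {
      return(data.frame(compartment = cc, peak_time = NA_real_,
                        post_peak_decline = NA_real_,
                        post_peak_decline_frac = NA_real_))
    }
    ipk <- which.max(sub$mean_green)
    decline <- if (ipk == nrow(sub)) {
      0
    } else if (ipk == nrow(sub) - 1L) {
      diff(sub$mean_green[ipk + 0:1]) / diff(sub$time[ipk + 0:1])
    } else {
      fit_slope(sub$time[ipk:nrow(sub)], sub$mean_green[ipk:nrow(sub)])$slope
    }
    pk <- sub$mean_green[ipk]
    data.frame(compartment = cc, peak_time = sub$time[ipk],
               post_peak_decline = decline,
               post_peak_decline_frac = if (pk > 0) decline / pk else NA_real_)
  }))
  list(series = series, summary = summary)
}
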