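#' Normalize per-organelle intensities to the cell average
#'
#' Divides each object's mean green (resp. red) by the unweighted average of
#' object means for the cell, so that normalized values average exactly to 1
#' per channel. This is the scatter-plot normalization used to compare age
#' profiles across cells with different expression levels.
#'
#' @param table Measurement table with `mean_green` and `mean_red` columns
#'   (or simulator columns `green`/`red`, used as means per object).
#' @return The table with added columns `norm_green` and `norm_red`.
#' @export
normalize_to_cell <- function(table) {
  stopifnot(is.data.frame(table))
  g <- if ("mean_green" %in% names(table)) table$mean_green else table$green
  r <- if ("mean_red" %in% names(table)) table$mean_red else table$red
  if (is.null(g) || is.null(r)) stopf("table lacks green/red intensity columns")
  if (nrow(table) < 1L) stopf("need at least one object")
  mg <- mean(g); mr <- mean(r)
  if (mg == 0 || mr == 0) stopf("zero cell-average intensity in a channel")
  table$norm_green <- g / mg
  table$norm_red <- r / mr
  table
}

#' Subcellular heterogeneity of the red/green ratio
#'
#' Sample standard deviation (n - 1 denominator) of per-organelle red/green
#' ratios across all mitochondria of one cell: low when fusion keeps matrix
#' content well mixed, high in fusion-deficient or compartmentalized
#' populations. Objects with undefined ratio (zero green) are excluded and
#' counted.
#'
#' @param table Measurement table with a `ratio` column.
#' @return The SD, with attribute `n_excluded` (objects without a defined
#'   ratio) and `n_used`.
#' @export
heterogeneity_sd <- function(table) {
  stopifnot(is.data.frame(table), "ratio" %in% names(table))
  ok <- is.finite(table$ratio)
  if (sum(ok) < 2L) stopf("need at least 2 objects with defined ratios")
  out <- stats::sd(table$ratio[ok])
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Red/green ratio versus organelle area
#'
#' Pairs each object's area with its ratio and summarizes the absolute
#' deviation from the cell-mean ratio by area quartile: in fragmented
#' populations the smallest objects deviate the most.
#'
#' @param table Measurement table with `ratio` and an area column
#'   (`area_um2`, `area_px` or `size`).
#' @return List with `pairs` (data frame `area`, `ratio`, `abs_deviation`)
#'   and `by_quartile` (data frame `quartile`, `n`, `mean_abs_deviation`).
#' @export
ratio_vs_area <- function(table) {
  stopifnot(is.data.frame(table))
  area <- table$area_um2
  if (is.null(area)) area <- table$area_px
  if (is.null(area)) area <- table$size
  if (is.null(area)) stopf("table lacks an area/size column")
  ok <- is.finite(table$ratio) & is.finite(area)
  if (sum(ok) < 4L) stopf("need at least 4 objects with defined ratio and area")
  area <- area[ok]
  ratio <- table$ratio[ok]
  dev <- abs(ratio - mean(ratio))
  br <- unique(stats::quantile(area, probs = seq(0, 1, 0.25)))
  q <- if (length(br) >= 3L) {
    cut(area, br, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(area))
  }
  by_q <- do.call(rbind, lapply(sort(unique(q)), function(b) {
    data.frame(quartile = b, n = sum(q == b),
               mean_abs_deviation = mean(dev[q == b]))
  }))
  list(pairs = data.frame(area = area, ratio = ratio, abs_deviation = dev),
       by_quartile = by_q)
}

#' Cell-level age profile
#'
#' Collapses a per-organelle measurement table into one cell profile:
#' object count, cell-mean green and red, their ratio, and the heterogeneity
#' SD (when at least two objects have defined ratios).
#'
#' @param table Measurement table.
#' @param cell_id Identifier stored in the profile.
#' @return A one-row data frame with columns `cell_id`, `n_mito`,
#'   `mean_green`, `mean_red`, `red_green`, `heterogeneity_sd`,
#'   `n_ratio_excluded`.
#' @export
cell_profile <- function(table, cell_id = 1L) {
  stopifnot(is.data.frame(table))
  g <- if ("mean_green" %in% names(table)) table$mean_green else table$green
  r <- if ("mean_red" %in% names(table)) table$mean_red else table$red
  mg <- mean(g); mr <- mean(r)
  hsd <- tryCatch(heterogeneity_sd(table), error = function(e) NA_real_)
  data.frame(
    cell_id = cell_id, n_mito = nrow(table),
    mean_green = mg, mean_red = mr,
    red_green = if (mg > 0) mr / mg else NA_real_,
    heterogeneity_sd = as.numeric(hsd),
    n_ratio_excluded = if (is.na(hsd)) NA_integer_ else attr(hsd, "n_excluded")
  )
}

#' Descriptive summary of cell profiles by condition
#'
#' Mean and sample SD of the cell-level quantities per condition group. No
#' hypothesis testing is performed; with a single cell per group the SD is
#' `NA` (flagged, not an error).
#'
#' @param profiles Data frame of [cell_profile()] rows.
#' @param grouping Factor/character vector (length `nrow(profiles)`) of
#'   condition labels, or the name of a column in `profiles`.
#' @return Data frame with one row per condition and mean/sd columns for
#'   `mean_green`, `mean_red`, `red_green` and `heterogeneity_sd`.
#' @export
condition_summary <- function(profiles, grouping) {
  stopifnot(is.data.frame(profiles))
  if (length(grouping) == 1L && is.character(grouping)) {
    if (!grouping %in% names(profiles)) {
      stopf("unknown grouping column '%s'", grouping)
    }
    grouping <- profiles[[grouping]]
  }
  if (length(grouping) != nrow(profiles)) {
    stopf("'grouping' must have one label per profile row")
  }
  vars <- c("mean_green", "mean_red", "red_green", "heterogeneity_sd")
  do.call(rbind, lapply(unique(grouping), function(gr) {
    sub <- profiles[grouping == gr, , drop = FALSE]
    row <- data.frame(condition = gr, n_cells = nrow(sub))
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(sub[[v]], na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- if (nrow(sub) >= 2L) {
        stats::sd(sub[[v]], na.rm = TRUE)
      } else {
        NA_real_
      }
    }
    row
  }))
}
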