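#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum over the z dimension, used before segmentation so that
#' the whole mitochondrial volume contributes to the 2D analysis image.
#'
#' @param stack Either a 3D numeric array `[y, x, z]` (one channel) or a
#'   list of such arrays (e.g. `list(green = ..., red = ...)`).
#' @return A matrix (or list of matrices) of the same y/x shape.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) return(lapply(stack, max_project))
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stopf("'stack' must be a [y, x, z] array or a list of them")
  }
  if (dim(stack)[3] < 1L) stopf("'stack' has no z-slices")
  apply(stack, c(1, 2), max)
}

#' Fractional threshold on the red channel
#'
#' Builds the mitochondrial mask as all pixels whose red intensity is at
#' least `fraction` of the image's maximum red intensity (boundary
#' inclusive). No upper threshold is applied; saturation is checked
#' separately with [saturation_check()]. An all-zero image yields an empty
#' mask with attribute `all_zero = TRUE`.
#'
#' @param red 2D numeric matrix (red channel, usually a max projection).
#' @param fraction Threshold as a fraction of the maximum pixel intensity
#'   (default 0.15).
#' @return Logical matrix mask.
#' @export
threshold_red <- function(red, fraction = 0.15) {
  stopifnot(is.matrix(red), length(red) >= 1L)
  if (fraction <= 0 || fraction >= 1) stopf("'fraction' must be in (0, 1)")
  mx <- max(red)
  if (mx <= 0) {
    mask <- matrix(FALSE, nrow(red), ncol(red))
    attr(mask, "all_zero") <- TRUE
    return(mask)
  }
  mask <- red >= fraction * mx
  attr(mask, "all_zero") <- FALSE
  mask
}

# 8-connected component labeling by iterated minimum-label propagation,
# then relabeling 1..N in raster order (row-major order of each component's
# first pixel). Vectorized over shifted copies of the label grid.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  lab[fg] <- seq_along(fg)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  pad <- function(m, dy, dx) {
    # neighbor value at offset (dy, dx), Inf outside
    out <- matrix(Inf, ny, nx)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  work <- matrix(Inf, ny, nx)
  work[fg] <- lab[fg]
  repeat {
    new <- work
    for (sh in shifts) {
      nb <- pad(work, sh[1], sh[2])
      new <- pmin(new, nb)
    }
    new[!mask] <- Inf
    if (all(new[fg] == work[fg])) break
    work <- new
  }
  comp <- work[fg]
  # raster order (row-major) of each component's first pixel
  rows <- ((fg - 1L) %% ny) + 1L
  cols <- ((fg - 1L) %/% ny) + 1L
  raster <- (rows - 1L) * nx + cols
  first <- tapply(raster, comp, min)
  newlab <- integer(length(first))
  newlab[order(first)] <- seq_along(first)
  names(newlab) <- names(first)
  lab[fg] <- unname(newlab[as.character(comp)])
  lab
}

#' Remove single-pixel objects from a binary mask
#'
#' Deletes every 8-connected component consisting of exactly one pixel;
#' larger components are untouched. Idempotent.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with isolated pixels removed.
#' @export
remove_single_pixels <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE  # coerce to logical
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(lab[lab > 0L])
  singles <- which(sizes == 1L)
  if (length(singles) > 0L) mask[lab %in% singles] <- FALSE
  mask
}

#' Label objects in a cleaned binary mask
#'
#' 8-connected components are labeled 1..N in raster-scan order (row-major)
#' of each component's first pixel; background is 0.
#'
#' @param mask Logical matrix (after thresholding and cleanup).
#' @param connectivity 4 or 8 (default 8, matching the cleanup step).
#' @return Integer label matrix.
#' @export
label_objects <- function(mask, connectivity = 8) {
  label_components(mask, connectivity = connectivity)
}

#' Per-object intensity and geometry measurements
#'
#' For every labeled object: pixel and physical area, mean green and red
#' intensity over the object's pixels, the red/green ratio of those means,
#' and the intensity-unweighted centroid. Objects whose mean green is zero
#' keep their row with `ratio = NA` and `ratio_defined = FALSE` rather than
#' being dropped.
#'
#' The per-object ratio is the ratio of mean intensities, not the mean of
#' pixelwise ratios; pixelwise ratios are only used for display images
#' ([ratio_image()]).
#'
#' @param labels Integer label matrix from [label_objects()].
#' @param green,red 2D intensity matrices, same shape as `labels`.
#' @param pixel_size Pixel edge length in micrometres (default 0.2).
#' @param subtract_background Constant background level subtracted from both
#'   channels before measuring (default 0; clamped at zero from below).
#' @return Data frame with columns `label`, `area_px`, `area_um2`,
#'   `mean_green`, `mean_red`, `ratio`, `ratio_defined`, `centroid_x_um`,
#'   `centroid_y_um` (pixel-center convention, 0-based pixel indices).
#' @export
measure_objects <- function(labels, green, red, pixel_size = 0.2,
                            subtract_background = 0) {
  stopifnot(is.matrix(labels), is.matrix(green), is.matrix(red))
  if (!all(dim(labels) == dim(green)) || !all(dim(labels) == dim(red))) {
    stopf("'labels', 'green' and 'red' must have identical dimensions")
  }
  check_number(pixel_size, "pixel_size", lower = 1e-9)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), mean_green = numeric(0),
                      mean_red = numeric(0), ratio = numeric(0),
                      ratio_defined = logical(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0)))
  }
  lv <- labels[idx]
  g <- pmax(green[idx] - subtract_background, 0)
  r <- pmax(red[idx] - subtract_background, 0)
  ny <- nrow(labels)
  rows0 <- ((idx - 1L) %% ny)        # 0-based y
  cols0 <- ((idx - 1L) %/% ny)       # 0-based x
  area <- as.integer(tabulate(lv))
  labs <- which(area > 0L)
  area <- area[labs]
  sums_g <- as.numeric(rowsum(g, lv)[, 1])
  sums_r <- as.numeric(rowsum(r, lv)[, 1])
  cx <- as.numeric(rowsum(as.numeric(cols0), lv)[, 1]) / area
  cy <- as.numeric(rowsum(as.numeric(rows0), lv)[, 1]) / area
  mean_g <- sums_g / area
  mean_r <- sums_r / area
  data.frame(
    label = labs, area_px = area, area_um2 = area * pixel_size^2,
    mean_green = mean_g, mean_red = mean_r,
    ratio = ifelse(mean_g > 0, mean_r / mean_g, NA_real_),
    ratio_defined = mean_g > 0,
    centroid_x_um = cx * pixel_size, centroid_y_um = cy * pixel_size
  )
}

#' Pixelwise ratio image
#'
#' Divides one channel by the other inside the mask; pixels outside the mask
#' or with a zero denominator are `NA` (undefined). Used for pseudocolored
#' display of age variation; quantitative per-object ratios come from
#' [measure_objects()].
#'
#' @param red,green 2D intensity matrices.
#' @param mask Logical matrix restricting the ratio to mitochondrial areas.
#' @param direction `"red_over_green"` (default) or `"green_over_red"`.
#' @return Numeric matrix of ratios with `NA` for undefined pixels.
#' @export
ratio_image <- function(red, green, mask = NULL,
                        direction = c("red_over_green", "green_over_red")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(red), is.matrix(green), all(dim(red) == dim(green)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(red), ncol(red))
  stopifnot(all(dim(mask) == dim(red)))
  num <- if (direction == "red_over_green") red else green
  den <- if (direction == "red_over_green") green else red
  out <- matrix(NA_real_, nrow(red), ncol(red))
  ok <- mask & den != 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Pseudocolor rendering of a ratio image
#'
#' Maps defined ratio pixels onto a color scale and writes a PNG; undefined
#' pixels are transparent black.
#'
#' @param ratio Numeric matrix from [ratio_image()].
#' @param path Output PNG path.
#' @param limits Ratio range mapped to the colormap ends; defaults to the
#'   finite data range.
#' @param palette Colormap name passed to [grDevices::hcl.colors()]
#'   (default "Viridis").
#' @return `path`, invisibly.
#' @export
write_pseudocolor_png <- function(ratio, path, limits = NULL,
                                  palette = "Viridis") {
  stopifnot(is.matrix(ratio))
  vals <- ratio[is.finite(ratio)]
  if (is.null(limits)) {
    limits <- if (length(vals)) range(vals) else c(0, 1)
  }
  if (diff(limits) <= 0) limits <- limits + c(-0.5, 0.5)
  cols <- grDevices::hcl.colors(256, palette)
  rgbm <- grDevices::col2rgb(cols) / 255
  scaled <- (ratio - limits[1]) / diff(limits)
  scaled <- pmin(pmax(scaled, 0), 1)
  ci <- matrix(1L + as.integer(round(scaled * 255)), nrow(ratio), ncol(ratio))
  img <- array(0, dim = c(nrow(ratio), ncol(ratio), 4))
  def <- is.finite(ratio)
  for (k in 1:3) {
    plane <- matrix(0, nrow(ratio), ncol(ratio))
    plane[def] <- rgbm[k, ci[def]]
    img[, , k] <- plane
  }
  img[, , 4] <- def * 1
  png::writePNG(img, path)
  invisible(path)
}

#' Saturation check
#'
#' Flags images containing pixels at the detector's maximum representable
#' value (`2^bit_depth - 1`); quantitative measurements require unsaturated
#' data.
#'
#' @param image Numeric array or matrix of intensities (counts).
#' @param bit_depth Detector bit depth (default 16).
#' @return List with `saturated` (logical) and `n_saturated` (pixel count).
#' @export
saturation_check <- function(image, bit_depth = 16) {
  mx <- 2^bit_depth - 1
  n <- sum(image >= mx)
  list(saturated = n > 0, n_saturated = n)
}

#' Average integrated intensity over a cell mask
#'
#' Integrated (summed) intensity over the cell mask divided by the mask
#' area: the per-cell mean that excludes background pixels outside the cell
#' region.
#'
#' @param image 2D intensity matrix (one channel).
#' @param cell_mask Logical matrix of the cell region; must be non-empty.
#' @return Mean intensity over the mask (scalar).
#' @export
cell_average_intensity <- function(image, cell_mask) {
  stopifnot(is.matrix(image), is.matrix(cell_mask),
            all(dim(image) == dim(cell_mask)))
  n <- sum(cell_mask)
  if (n == 0L) stopf("'cell_mask' is empty")
  sum(image[cell_mask]) / n
}

#' Full segmentation and measurement pipeline
#'
#' Convenience wrapper chaining [max_project()], [threshold_red()],
#' [remove_single_pixels()], [label_objects()] and [measure_objects()].
#'
#' @param stack List with `green` and `red` z-stack arrays `[y, x, z]` (or
#'   2D matrices).
#' @param pixel_size Pixel size in um (default 0.2).
#' @param threshold_fraction Red-channel threshold fraction (default 0.15).
#' @param subtract_background Constant background subtracted before
#'   measurement (default 0).
#' @return List with `projection` (list of matrices), `mask`, `labels` and
#'   `measurements` (see [measure_objects()]).
#' @export
segment_stack <- function(stack, pixel_size = 0.2, threshold_fraction = 0.15,
                          subtract_background = 0) {
  stopifnot(is.list(stack), all(c("green", "red") %in% names(stack)))
  proj <- list(green = max_project(stack$green), red = max_project(stack$red))
  mask <- threshold_red(proj$red, fraction = threshold_fraction)
  mask <- remove_single_pixels(mask)
  labels <- label_objects(mask)
  meas <- measure_objects(labels, proj$green, proj$red,
                          pixel_size = pixel_size,
                          subtract_background = subtract_background)
  list(projection = proj, mask = mask, labels = labels, measurements = meas)
}
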