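#' Optical/acquisition configuration for the synthetic renderer
#'
#' Plausible confocal defaults: 0.2 um pixels, six z-slices of 0.7 um, a
#' modest lateral/axial Gaussian PSF, constant background and 16-bit
#' quantization. None of these are measured values; they are free parameters
#' of the synthetic-data model.
#'
#' @param pixel_size Pixel edge (um/px).
#' @param field_px Square field size in pixels.
#' @param n_z Number of z-slices.
#' @param z_step Slice spacing (um).
#' @param psf_sigma_xy Lateral PSF sigma (um).
#' @param psf_sigma_z Axial PSF sigma (um).
#' @param background Constant background level (counts).
#' @param gain Counts per intensity unit of pool density.
#' @param read_noise Gaussian read-noise sigma (counts).
#' @param bit_depth Quantization depth (default 16).
#' @param area_per_size Footprint area (um^2) per unit of organelle size;
#'   converts the simulator's volume proxy to a drawn 2D extent.
#' @return An `optics_config` object.
#' @export
optics_config <- function(pixel_size = 0.2, field_px = 256, n_z = 6,
                          z_step = 0.7, psf_sigma_xy = 0.25, psf_sigma_z = 0.7,
                          background = 20, gain = 2000, read_noise = 3,
                          bit_depth = 16, area_per_size = 0.5) {
  for (nm in c("pixel_size", "field_px", "n_z", "z_step", "psf_sigma_xy",
               "psf_sigma_z", "gain", "bit_depth", "area_per_size")) {
    check_number(get(nm), nm, lower = 1e-9)
  }
  check_number(background, "background", lower = 0)
  check_number(read_noise, "read_noise", lower = 0)
  structure(
    list(pixel_size = pixel_size, field_px = as.integer(field_px),
         n_z = as.integer(n_z), z_step = z_step,
         psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
         background = background, gain = gain, read_noise = read_noise,
         bit_depth = as.integer(bit_depth), area_per_size = area_per_size),
    class = "optics_config"
  )
}

# Gaussian footprint sigma (um) for an organelle of given size.
footprint_sigma <- function(size, optics) {
  # draw radius r with pi r^2 = area_per_size * size; sigma = r / 2 keeps
  # most of the mass inside the nominal footprint
  sqrt(optics$area_per_size * size / pi) / 2
}

#' Render a simulated population into a two-channel z-stack
#'
#' Each mitochondrion is drawn as an isotropic 2D Gaussian footprint whose
#' area is proportional to its size and whose per-channel amplitude is
#' proportional to pool density (`pool / size`), distributed across z-slices
#' with Gaussian axial weights, blurred with a lateral Gaussian PSF, then
#' (optionally) degraded with Poisson shot noise, Gaussian read noise, a
#' constant background, and quantized to the detector bit depth. Blur and
#' noise are channel-independent, so noise-free rendering preserves each
#' object's green/red ratio exactly.
#'
#' Ground truth uses the "merge-truth" convention: organelles whose
#' footprints touch are merged into a single truth object (summed pools),
#' since no intensity-based pipeline can separate them.
#'
#' @param table Measurement table (one snapshot) from [run_simulation()],
#'   with columns `id`, `size`, `green`, `red`, `x_um`, `y_um`.
#' @param optics An [optics_config()].
#' @param seed RNG seed for noise and axial placement.
#' @param noise If `FALSE`, returns the noiseless, unquantized signal
#'   (floating point, zero background); used for exact-ratio validation.
#' @param origin_um xy offset (um) subtracted from coordinates before
#'   rendering, to place the population in the field.
#' @return A `mito_scene` list: `stack` (list of `green`/`red` arrays
#'   `[y, x, z]`), `labels` (truth label matrix), `truth` (data frame:
#'   `truth_id`, `n_merged`, `ids`, `size`, `green`, `red`, `ratio`,
#'   `centroid_x_um`, `centroid_y_um`, `peak_red_signal`), `optics`,
#'   `saturated` flag.
#' @export
render_scene <- function(table, optics, seed = 1, noise = TRUE,
                         origin_um = c(0, 0)) {
  stopifnot(inherits(optics, "optics_config"), is.data.frame(table))
  need <- c("id", "size", "green", "red", "x_um", "y_um")
  if (!all(need %in% names(table))) {
    stopf("'table' must have columns %s", paste(need, collapse = ", "))
  }
  npx <- optics$field_px
  ps <- optics$pixel_size
  n <- nrow(table)
  xs <- (table$x_um - origin_um[1]) / ps   # 0-based pixel coordinates
  ys <- (table$y_um - origin_um[2]) / ps
  sig_px <- footprint_sigma(table$size, optics) / ps
  margin <- 3 * sig_px
  bad <- which(xs < margin | xs > npx - 1 - margin |
                 ys < margin | ys > npx - 1 - margin)
  if (length(bad) > 0L) {
    stopf("mitochondrion id %s lies outside the rendering field",
          paste(table$id[bad], collapse = ", "))
  }

  with_seed(seed, {
    ## axial positions and per-slice weights (normalized: projection of the
    ## weighted slices preserves channel totals)
    z_um <- (seq_len(optics$n_z) - (optics$n_z + 1) / 2) * optics$z_step
    zpos <- if (n > 0) stats::runif(n, min(z_um), max(z_um)) else numeric(0)

    signal <- list(
      green = array(0, dim = c(npx, npx, optics$n_z)),
      red = array(0, dim = c(npx, npx, optics$n_z))
    )
    sup <- matrix(FALSE, npx, npx)   # union of footprint supports
    centers_px <- cbind(xs, ys)
    peak_red <- numeric(n)

    for (i in seq_len(n)) {
      s <- sig_px[i]
      half <- max(3L, ceiling(3 * s))
      cx <- xs[i]; cy <- ys[i]
      x_idx <- max(1L, floor(cx + 1 - half)):min(npx, ceiling(cx + 1 + half))
      y_idx <- max(1L, floor(cy + 1 - half)):min(npx, ceiling(cy + 1 + half))
      gx <- exp(-((x_idx - 1 - cx)^2) / (2 * s^2))
      gy <- exp(-((y_idx - 1 - cy)^2) / (2 * s^2))
      foot <- outer(gy, gx)          # [y, x]
      wz <- exp(-(z_um - zpos[i])^2 / (2 * optics$psf_sigma_z^2))
      wz <- wz / sum(wz)
      amp_g <- optics$gain * table$green[i] / table$size[i]
      amp_r <- optics$gain * table$red[i] / table$size[i]
      for (k in seq_len(optics$n_z)) {
        signal$green[y_idx, x_idx, k] <-
          signal$green[y_idx, x_idx, k] + amp_g * wz[k] * foot
        signal$red[y_idx, x_idx, k] <-
          signal$red[y_idx, x_idx, k] + amp_r * wz[k] * foot
      }
      peak_red[i] <- max(amp_r * max(wz))
      ## truth support: footprint disk plus PSF reach
      r_sup <- (2 * s + 2 * optics$psf_sigma_xy / ps)
      xi <- x_idx[abs(x_idx - 1 - cx) <= r_sup]
      yi <- y_idx[abs(y_idx - 1 - cy) <= r_sup]
      if (length(xi) && length(yi)) {
        dd <- outer((yi - 1 - cy)^2, (xi - 1 - cx)^2, "+")
        sup[yi, xi] <- sup[yi, xi] | (dd <= r_sup^2)
      }
    }

    ## lateral PSF blur, channel-independent
    blur_px <- optics$psf_sigma_xy / ps
    if (blur_px > 0.05 && npx >= 9) {
      for (ch in c("green", "red")) {
        for (k in seq_len(optics$n_z)) {
          signal[[ch]][, , k] <- EBImage::gblur(signal[[ch]][, , k],
                                                sigma = blur_px)
        }
      }
    }

    maxval <- 2^optics$bit_depth - 1
    if (noise) {
      for (ch in c("green", "red")) {
        lam <- signal[[ch]] + optics$background
        counts <- stats::rpois(length(lam), pmax(lam, 0)) +
          stats::rnorm(length(lam), 0, optics$read_noise)
        counts <- pmin(pmax(floor(counts), 0), maxval)
        signal[[ch]] <- array(counts, dim = dim(lam))
      }
    }
    frac_sat <- (sum(signal$green >= maxval) + sum(signal$red >= maxval)) /
      (2 * length(signal$green))
    saturated <- frac_sat > 0.01
    if (saturated) {
      warnf("%.2f%% of pixels are saturated; measurements will be biased",
            100 * frac_sat)
    }

    ## merge-truth labels
    labels <- label_components(sup, connectivity = 8)
    tr <- merge_truth(table, labels, centers_px, peak_red, optics)

    structure(
      list(stack = signal, labels = labels, truth = tr$truth,
           objects = tr$objects, optics = optics,
           saturated = saturated, seed = seed, origin_um = origin_um),
      class = "mito_scene"
    )
  })
}

# Aggregate simulated organelles per truth label component.
merge_truth <- function(table, labels, centers_px, peak_red, optics) {
  n <- nrow(table)
  empty_truth <- data.frame(truth_id = integer(0), n_merged = integer(0),
                            ids = character(0), size = numeric(0),
                            green = numeric(0), red = numeric(0),
                            ratio = numeric(0),
                            centroid_x_um = numeric(0),
                            centroid_y_um = numeric(0),
                            peak_red_signal = numeric(0))
  empty_objects <- data.frame(id = integer(0), truth_id = integer(0),
                              size = numeric(0), green = numeric(0),
                              red = numeric(0), x_px = numeric(0),
                              y_px = numeric(0), peak_red_signal = numeric(0))
  if (n == 0L) {
    return(list(truth = empty_truth, objects = empty_objects))
  }
  ci <- pmin(pmax(round(centers_px[, 1]) + 1L, 1L), ncol(labels))
  ri <- pmin(pmax(round(centers_px[, 2]) + 1L, 1L), nrow(labels))
  comp <- labels[cbind(ri, ci)]
  # a center pixel can only miss its own support through rounding; snap to 1px neighborhood
  for (i in which(comp == 0L)) {
    win_r <- pmin(pmax(ri[i] + (-1:1), 1L), nrow(labels))
    win_c <- pmin(pmax(ci[i] + (-1:1), 1L), ncol(labels))
    vals <- labels[win_r, win_c]
    vals <- vals[vals > 0L]
    comp[i] <- if (length(vals)) vals[1] else 0L
  }
  keep <- comp > 0L
  truth <- do.call(rbind, lapply(sort(unique(comp[keep])), function(cc) {
    idx <- which(comp == cc)
    g <- sum(table$green[idx]); r <- sum(table$red[idx])
    w <- table$size[idx] / sum(table$size[idx])
    data.frame(
      truth_id = cc, n_merged = length(idx),
      ids = paste(table$id[idx], collapse = ";"),
      size = sum(table$size[idx]), green = g, red = r,
      ratio = if (g > 0) r / g else NA_real_,
      centroid_x_um = sum(w * centers_px[idx, 1]) * optics$pixel_size,
      centroid_y_um = sum(w * centers_px[idx, 2]) * optics$pixel_size,
      peak_red_signal = max(peak_red[idx])
    )
  }))
  if (is.null(truth)) truth <- empty_truth
  objects <- data.frame(id = table$id, truth_id = comp, size = table$size,
                        green = table$green, red = table$red,
                        x_px = centers_px[, 1], y_px = centers_px[, 2],
                        peak_red_signal = peak_red)
  list(truth = truth, objects = objects)
}

#' Score a segmentation against a rendered scene's ground truth
#'
#' Assigns each simulated organelle to the measured object (labeled mask
#' component) containing its center pixel, then compares every measured
#' object's red/green ratio with the pool ratio of the organelles assigned
#' to it. Ground-truth objects that the imaging itself cannot separate
#' (touching footprints) are already merged in `scene$truth`; a truth object
#' counts as recovered when at least one of its organelles lands in a
#' measured component.
#'
#' @param scene A `mito_scene` from [render_scene()].
#' @param segmentation Output of [segment_stack()] on `scene$stack`.
#' @param red_fraction Threshold fraction used to decide which truth objects
#'   are bright enough to be detectable (their peak red signal at or above
#'   this fraction of the scene's maximum peak; default 0.15, matching the
#'   segmentation threshold).
#' @return List with `matches` (data frame `label`, `measured_ratio`,
#'   `expected_ratio`, `rel_error`, `n_organelles`), `n_truth_above`,
#'   `n_recovered` and `recovery_rate`.
#' @export
evaluate_recovery <- function(scene, segmentation, red_fraction = 0.15) {
  stopifnot(inherits(scene, "mito_scene"))
  labs <- segmentation$labels
  meas <- segmentation$measurements
  obj <- scene$objects
  ci <- pmin(pmax(round(obj$x_px) + 1L, 1L), ncol(labs))
  ri <- pmin(pmax(round(obj$y_px) + 1L, 1L), nrow(labs))
  comp <- labs[cbind(ri, ci)]
  matches <- do.call(rbind, lapply(sort(unique(comp[comp > 0L])), function(cc) {
    idx <- which(comp == cc)
    g <- sum(obj$green[idx]); r <- sum(obj$red[idx])
    expected <- if (g > 0) r / g else NA_real_
    measured <- meas$ratio[meas$label == cc]
    data.frame(label = cc, measured_ratio = measured,
               expected_ratio = expected,
               rel_error = abs(measured - expected) / expected,
               n_organelles = length(idx))
  }))
  if (is.null(matches)) {
    matches <- data.frame(label = integer(0), measured_ratio = numeric(0),
                          expected_ratio = numeric(0), rel_error = numeric(0),
                          n_organelles = integer(0))
  }
  thr <- red_fraction * max(scene$truth$peak_red_signal)
  above <- scene$truth[scene$truth$peak_red_signal >= thr, , drop = FALSE]
  recovered <- vapply(seq_len(nrow(above)), function(i) {
    ids <- as.integer(strsplit(above$ids[i], ";")[[1]])
    any(comp[match(ids, obj$id)] > 0L)
  }, logical(1))
  list(matches = matches, n_truth_above = nrow(above),
       n_recovered = sum(recovered),
       recovery_rate = if (nrow(above)) mean(recovered) else NA_real_)
}

#' @export
print.mito_scene <- function(x, ...) {
  d <- dim(x$stack$green)
  cat(sprintf("Synthetic two-channel scene: %d x %d px, %d z-slices, %d truth objects\n",
              d[1], d[2], d[3], nrow(x$truth)))
  if (x$saturated) cat("  WARNING: saturation flag set\n")
  invisible(x)
}

#' Write / read a two-channel z-stack as multi-page TIFF
#'
#' Pages are ordered channel-major: all green slices (z = 1..n) followed by
#' all red slices. Intensities are stored as `bit_depth`-bit samples; pixel
#' size, z-step and channel order are recorded in a JSON sidecar file
#' (`<path>.json`) next to the image.
#'
#' @param stack List with `green` and `red` arrays `[y, x, z]` (counts).
#' @param path Output TIFF path.
#' @param optics The [optics_config()] used (for metadata and bit depth).
#' @return `path` invisibly (`write`); a list with `green`, `red` arrays and
#'   `metadata` (`read`).
#' @export
write_stack_tiff <- function(stack, path, optics) {
  maxval <- 2^optics$bit_depth - 1
  pages <- list()
  for (ch in c("green", "red")) {
    a <- stack[[ch]]
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    for (k in seq_len(dim(a)[3])) {
      pages[[length(pages) + 1L]] <- pmin(pmax(a[, , k], 0), maxval) / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(
    channel_order = c("green", "red"), n_z = optics$n_z,
    pixel_size_um = optics$pixel_size, z_step_um = optics$z_step,
    bit_depth = optics$bit_depth
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    NULL
  }
  n_z <- if (!is.null(meta)) meta$n_z else length(pages) / 2L
  bit_depth <- if (!is.null(meta)) meta$bit_depth else 16L
  maxval <- 2^bit_depth - 1
  to_array <- function(ps) {
    a <- array(0, dim = c(dim(ps[[1]]), length(ps)))
    for (k in seq_along(ps)) a[, , k] <- ps[[k]] * maxval
    a
  }
  list(green = to_array(pages[seq_len(n_z)]),
       red = to_array(pages[n_z + seq_len(n_z)]),
       metadata = meta)
}

#' Write a label map as 16-bit TIFF
#'
#' @param labels Integer label matrix (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535) stopf("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}
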