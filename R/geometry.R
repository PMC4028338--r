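#' Cell geometry for the network simulator
#'
#' Two geometry modes are supported. `well_mixed` is a square cytoplasm of
#' side `extent` micrometres in which mitochondria move freely and any pair
#' may fuse. `neuron` consists of a circular soma plus one or more neurite
#' polylines rooted on the soma boundary; mitochondria on a neurite are
#' addressed by arc-length distance from the root.
#'
#' @param mode `"well_mixed"` or `"neuron"`.
#' @param extent Side (um) of the well-mixed field. Ignored in neuron mode.
#' @param soma_center,soma_radius Soma disk (um). Used in neuron mode.
#' @param neurites List of n-by-2 numeric matrices of polyline vertices (um).
#'   Each polyline must be simple and start on the soma boundary (within
#'   1e-6 um).
#' @return A `cell_geometry` object with precomputed neurite segment lengths.
#' @seealso [neuron_geometry()] for a convenience constructor.
#' @export
cell_geometry <- function(mode = c("well_mixed", "neuron"),
                          extent = 40,
                          soma_center = c(0, 0), soma_radius = 10,
                          neurites = list()) {
  mode <- match.arg(mode)
  check_number(extent, "extent", lower = 1e-6)
  check_number(soma_radius, "soma_radius", lower = 1e-6)
  stopifnot(length(soma_center) == 2L, is.numeric(soma_center))
  neurites <- lapply(neurites, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 2L || nrow(m) < 2L) {
      stopf("each neurite must be an n-by-2 matrix with n >= 2")
    }
    m
  })
  if (mode == "neuron") {
    if (length(neurites) == 0L) stopf("neuron mode requires at least one neurite")
    for (i in seq_along(neurites)) {
      r0 <- sqrt(sum((neurites[[i]][1, ] - soma_center)^2))
      if (abs(r0 - soma_radius) > 1e-6) {
        stopf("neurite %d does not start on the soma boundary", i)
      }
    }
  }
  lens <- lapply(neurites, function(m) {
    seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
    if (any(seg <= 0)) stopf("neurite has duplicated consecutive vertices")
    c(0, cumsum(seg))
  })
  structure(
    list(mode = mode, extent = extent, soma_center = soma_center,
         soma_radius = soma_radius, neurites = neurites, cumlen = lens),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Cell geometry (%s)\n", x$mode))
  if (x$mode == "well_mixed") {
    cat(sprintf("  field: %g x %g um\n", x$extent, x$extent))
  } else {
    cat(sprintf("  soma: center (%g, %g), radius %g um\n",
                x$soma_center[1], x$soma_center[2], x$soma_radius))
    cat(sprintf("  neurites: %d (lengths %s um)\n", length(x$neurites),
                paste(sprintf("%.1f", vapply(x$cumlen, max, 1)), collapse = ", ")))
  }
  invisible(x)
}

#' Radial neuron geometry
#'
#' Convenience constructor: a soma at the origin with `n_neurites` straight
#' neurites of the given lengths radiating at equal angles.
#'
#' @param n_neurites Number of neurites.
#' @param lengths Neurite lengths (um), recycled to `n_neurites`.
#' @param soma_radius Soma radius (um).
#' @return A `cell_geometry` in neuron mode.
#' @export
neuron_geometry <- function(n_neurites = 3, lengths = 100, soma_radius = 10) {
  lengths <- rep_len(lengths, n_neurites)
  ang <- 2 * pi * (seq_len(n_neurites) - 1) / n_neurites
  neurites <- lapply(seq_len(n_neurites), function(i) {
    u <- c(cos(ang[i]), sin(ang[i]))
    rbind(soma_radius * u, (soma_radius + lengths[i]) * u)
  })
  cell_geometry("neuron", soma_radius = soma_radius, neurites = neurites)
}

#' Neurite lengths of a geometry
#' @param geometry A `cell_geometry`.
#' @return Numeric vector of arc lengths (um), one per neurite.
#' @export
neurite_lengths <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  vapply(geometry$cumlen, max, numeric(1))
}

# xy coordinates of the point at arc-length d along neurite i.
point_at_distance <- function(geometry, i, d) {
  m <- geometry$neurites[[i]]
  cl <- geometry$cumlen[[i]]
  d <- pmin(pmax(d, 0), max(cl))
  seg <- pmin(findInterval(d, cl, rightmost.closed = TRUE), nrow(m) - 1L)
  frac <- (d - cl[seg]) / (cl[seg + 1L] - cl[seg])
  m[seg, , drop = FALSE] +
    frac * (m[seg + 1L, , drop = FALSE] - m[seg, , drop = FALSE])
}

# Project one xy point onto neurite i: arc length and perpendicular distance.
project_on_neurite <- function(geometry, i, xy) {
  m <- geometry$neurites[[i]]
  cl <- geometry$cumlen[[i]]
  best <- c(dist = Inf, arc = NA_real_)
  for (k in seq_len(nrow(m) - 1L)) {
    a <- m[k, ]; b <- m[k + 1L, ]
    ab <- b - a
    tpar <- sum((xy - a) * ab) / sum(ab * ab)
    tpar <- min(max(tpar, 0), 1)
    pt <- a + tpar * ab
    dd <- sqrt(sum((xy - pt)^2))
    if (dd < best["dist"]) {
      best <- c(dist = dd, arc = cl[k] + tpar * sqrt(sum(ab * ab)))
    }
  }
  best
}

#' Assign points to cell compartments
#'
#' Classifies xy points (um) as soma or neurite and computes the arc-length
#' path distance from the soma boundary. Soma points get distance 0. In
#' well-mixed mode all points are compartment `"free"` with distance `NA`.
#'
#' @param xy n-by-2 matrix of coordinates (um).
#' @param geometry A `cell_geometry`.
#' @param snap_tol Maximum perpendicular distance (um) at which a point is
#'   snapped to a neurite (default 1).
#' @return Data frame with columns `compartment` (`"soma"`, `"neurite"`,
#'   `"free"`), `neurite` (index or `NA`) and `dist_um`.
#' @export
assign_compartment <- function(xy, geometry, snap_tol = 1) {
  stopifnot(inherits(geometry, "cell_geometry"))
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- nrow(xy)
  if (geometry$mode == "well_mixed") {
    return(data.frame(compartment = rep("free", n), neurite = NA_integer_,
                      dist_um = NA_real_))
  }
  comp <- character(n); nid <- rep(NA_integer_, n); d <- rep(NA_real_, n)
  r <- sqrt(colSums((t(xy) - geometry$soma_center)^2))
  for (j in seq_len(n)) {
    if (r[j] <= geometry$soma_radius + 1e-9) {
      comp[j] <- "soma"; d[j] <- 0
      next
    }
    projs <- vapply(seq_along(geometry$neurites),
                    function(i) project_on_neurite(geometry, i, xy[j, ]),
                    numeric(2))
    i_best <- which.min(projs["dist", ])
    if (projs["dist", i_best] > snap_tol) {
      stopf("point %d (%.2f, %.2f) is %.2f um from the nearest structure (tol %.2f)",
            j, xy[j, 1], xy[j, 2], projs["dist", i_best], snap_tol)
    }
    comp[j] <- "neurite"; nid[j] <- i_best; d[j] <- projs["arc", i_best]
  }
  data.frame(compartment = comp, neurite = nid, dist_um = d)
}

#' Path distance from the soma
#'
#' Arc-length distance (um) along the neurite from its soma-boundary root to
#' each point; points inside the soma have distance 0. Points farther than
#' `snap_tol` from any structure are rejected.
#'
#' @inheritParams assign_compartment
#' @return Numeric vector of distances (um).
#' @export
path_distance <- function(xy, geometry, snap_tol = 1) {
  assign_compartment(xy, geometry, snap_tol)$dist_um
}

#' Write / read geometry as JSON
#'
#' Stores mode, field extent, soma disk and neurite vertex lists (um).
#' @param geometry A `cell_geometry`.
#' @param path File path.
#' @return `write_geometry_json()` returns `path` invisibly;
#'   `read_geometry_json()` returns a `cell_geometry`.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "cell_geometry"))
  obj <- list(
    mode = geometry$mode, extent = geometry$extent,
    soma_center = geometry$soma_center, soma_radius = geometry$soma_radius,
    neurites = lapply(geometry$neurites, unname)  # matrices -> nested arrays
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  cell_geometry(
    mode = obj$mode, extent = obj$extent,
    soma_center = as.numeric(obj$soma_center), soma_radius = obj$soma_radius,
    neurites = lapply(obj$neurites, function(nl) do.call(rbind, nl))
  )
}
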