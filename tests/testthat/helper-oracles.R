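# Independent oracles used to validate the implementation.

# Piecewise solution of the two-pool system via the matrix exponential of the
# augmented (G, R, 1) system, computed with Matrix::expm. Independent of the
# package's fixed-step Runge-Kutta path.
oracle_pools <- function(params, t_grid, init = c(0, 0)) {
  k_mat <- params$k_mat; k_deg <- params$k_deg; s <- params$s
  a <- k_mat + k_deg
  on_at <- function(t) {
    w <- params$import_windows
    if (is.null(w)) return(TRUE)
    tt <- t - params$lag
    any(tt >= w[, 1] & tt < w[, 2])
  }
  breaks_in <- function(t0, t1) {
    w <- params$import_windows
    if (is.null(w)) return(numeric(0))
    b <- sort(unique(c(w[, 1], w[, 2]))) + params$lag
    b[b > t0 + 1e-12 & b < t1 - 1e-12]
  }
  y <- c(init, 1)
  out <- matrix(0, length(t_grid), 2)
  out[1, ] <- init
  for (i in seq_along(t_grid)[-1]) {
    edges <- c(t_grid[i - 1], breaks_in(t_grid[i - 1], t_grid[i]), t_grid[i])
    for (k in seq_len(length(edges) - 1)) {
      s_on <- if (on_at(edges[k])) s else 0
      A <- matrix(c(-a, k_mat, 0,
                    0, -k_deg, 0,
                    s_on, 0, 0), 3, 3)
      E <- as.matrix(Matrix::expm(Matrix::Matrix(A * (edges[k + 1] - edges[k]))))
      y <- as.numeric(E %*% y)
    }
    out[i, ] <- y[1:2]
  }
  data.frame(t_hours = t_grid, green = out[, 1], red = out[, 2])
}

# Brute-force flood-fill connected-component labeling (8-connectivity),
# labels assigned in row-major raster order of first encounter.
oracle_label <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nxt <- 0L
  for (r in seq_len(ny)) {
    for (c in seq_len(nx)) {
      if (mask[r, c] && lab[r, c] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(r, c))
        lab[r, c] <- nxt
        while (length(queue) > 0) {
          p <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (dr in -1:1) for (dc in -1:1) {
            rr <- p[1] + dr; cc <- p[2] + dc
            if (rr >= 1 && rr <= ny && cc >= 1 && cc <= nx &&
                mask[rr, cc] && lab[rr, cc] == 0L) {
              lab[rr, cc] <- nxt
              queue[[length(queue) + 1]] <- c(rr, cc)
            }
          }
        }
      }
    }
  }
  lab
}

# Loop-based per-label measurement oracle.
oracle_measure <- function(lab, green, red) {
  labs <- sort(unique(lab[lab > 0L]))
  area <- integer(length(labs))
  mg <- numeric(length(labs))
  mr <- numeric(length(labs))
  for (j in seq_along(labs)) {
    px <- which(lab == labs[j])
    area[j] <- length(px)
    mg[j] <- mean(green[px])
    mr[j] <- mean(red[px])
  }
  list(label = labs, area_px = area, mean_green = mg, mean_red = mr)
}

# Small random binary mask.
random_mask <- function(ny, nx, p = 0.4) {
  matrix(stats::runif(ny * nx) < p, ny, nx)
}

# Integer -> 4x4 binary mask (bit pattern), for exhaustive enumeration.
int_to_mask4 <- function(i) {
  matrix(bitwAnd(bitwShiftR(i, 0:15), 1L) == 1L, 4, 4)
}
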