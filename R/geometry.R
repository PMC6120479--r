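#' Interphase cell geometry prior and optical parameters of the simulator
#'
#' Rod ("capsule") geometry uses standard fission-yeast interphase
#' dimensions: length 7-14 um, width 3.5 um, with the two poles defined as
#' the extreme points of the rounded caps, exactly `length` apart along the
#' cell axis. Fluorophore amplitudes are areal photon densities (photons per
#' square micron of the projected cell) so that rendered intensities are
#' independent of the pixel size chosen.
#'
#' @param length_range Interphase cell length range in um.
#' @param width Cell width (= optical thickness) in um.
#' @param margin Minimum clearance between a cell mask and the field border,
#'   in um.
#' @param gap Minimum clearance between two cell masks, in um.
#' @param tip_sigma Lateral s.d. of the Gaussian tip spot, um.
#' @param tip_density Peak areal density of the brighter tip spot,
#'   photons/um^2.
#' @param cyto_density Areal density of the cytosolic plateau, photons/um^2.
#' @param brightness_sdlog Cell-to-cell log-normal s.d. of overall
#'   brightness (expression variability).
#' @param compartment_sdlog Extra per-compartment log-normal s.d.
#' @param bipolarity Baseline bipolarity parameter: the mean ratio of
#'   new-end to old-end tip amplitude across the interphase population
#'   (0 = fully monopolar, 1 = fully bipolar).
#' @param bipolarity_kappa Beta-distribution precision of the per-cell
#'   bipolarity draw.
#' @param spb_density Peak areal density of the red spindle-pole-body spot
#'   carried by wild-type (control) cells, photons/um^2.
#' @param spb_sigma_xy,spb_sigma_z Lateral and axial s.d. of the red spot,
#'   um.
#' @return A list of class `poldep_cell_prior`.
#' @export
cell_prior <- function(length_range = c(7, 14), width = 3.5,
                       margin = 1.5, gap = 2,
                       tip_sigma = 0.45, tip_density = 5e5,
                       cyto_density = 1.5e4,
                       brightness_sdlog = 0.2, compartment_sdlog = 0.1,
                       bipolarity = 0.5, bipolarity_kappa = 8,
                       spb_density = 6e5, spb_sigma_xy = 0.25,
                       spb_sigma_z = 0.3) {
  stopifnot(length_range[1] > width, length_range[2] >= length_range[1])
  structure(as.list(environment()), class = "poldep_cell_prior")
}

# minimum distance between 2-D segments p1-q1 and p2-q2
segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2)
  b <- sum(d1 * d2); c1 <- sum(d1 * r); f <- sum(d2 * r)
  den <- a * e - b * b
  s <- if (den > 1e-12) clamp((b * f - c1 * e) / den, 0, 1) else 0
  t <- if (e > 1e-12) clamp((b * s + f) / e, 0, 1) else 0
  s <- if (a > 1e-12) clamp((b * t - c1) / a, 0, 1) else 0
  u <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(u * u))
}

#' Sample non-overlapping rod-cell geometries within a field
#'
#' Cells are placed by rejection sampling (up to `max_attempts` draws per
#' cell), mimicking sparsely mounted cells; placements keep the whole mask
#' at least `margin` um from the field border and `gap` um from every other
#' cell.
#'
#' @param n Number of cells to place.
#' @param field_um Field side length in um.
#' @param prior A [cell_prior()].
#' @param max_attempts Placement attempts per cell before giving up.
#' @return Tibble with columns `cell_id`, `x`, `y` (centre, um), `theta`
#'   (orientation, radians), `length`, `width`, `pole1_x`, `pole1_y`,
#'   `pole2_x`, `pole2_y`.
#' @export
sample_cell_geometry <- function(n, field_um, prior = cell_prior(),
                                 max_attempts = 500L) {
  xs <- ys <- ths <- lens <- numeric(n)
  segs <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      len <- runif(1, prior$length_range[1], prior$length_range[2])
      th <- runif(1, 0, pi)
      half <- len / 2 + prior$margin
      if (2 * half >= field_um) break
      cx <- runif(1, half, field_um - half)
      cy <- runif(1, half, field_um - half)
      hl <- (len - prior$width) / 2   # axis half-length of the capsule core
      u <- c(cos(th), sin(th))
      p <- c(cx, cy) - hl * u
      q <- c(cx, cy) + hl * u
      clash <- FALSE
      for (s in segs) {
        if (segment_distance(p, q, s$p, s$q) < prior$width + prior$gap) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        xs[i] <- cx; ys[i] <- cy; ths[i] <- th; lens[i] <- len
        segs[[length(segs) + 1L]] <- list(p = p, q = q)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      poldep_abort(
        paste0("could not place cell ", i, " of ", n,
               " in a ", round(field_um, 1), " um field"),
        "poldep_capacity_error"
      )
    }
  }
  tibble(
    cell_id = seq_len(n), x = xs, y = ys, theta = ths,
    length = lens, width = prior$width,
    pole1_x = xs + lens / 2 * cos(ths), pole1_y = ys + lens / 2 * sin(ths),
    pole2_x = xs - lens / 2 * cos(ths), pole2_y = ys - lens / 2 * sin(ths)
  )
}

# Anti-aliased capsule mask over the cell's bounding box.
# Returns integer pixel indices (rows = y, cols = x, 1-based) into a
# (ny, nx) image plus per-pixel coverage in [0, 1]; linear ramp across one
# pixel approximates exact area coverage of the capsule boundary.
capsule_patch <- function(geom, pixel_size, ny, nx) {
  hl <- (geom$length - geom$width) / 2
  u <- c(cos(geom$theta), sin(geom$theta))
  p <- c(geom$x, geom$y) - hl * u
  q <- c(geom$x, geom$y) + hl * u
  r <- geom$width / 2
  pad <- r + pixel_size
  x0 <- max(1L, floor((min(p[1], q[1]) - pad) / pixel_size) + 1L)
  x1 <- min(nx, ceiling((max(p[1], q[1]) + pad) / pixel_size) + 1L)
  y0 <- max(1L, floor((min(p[2], q[2]) - pad) / pixel_size) + 1L)
  y1 <- min(ny, ceiling((max(p[2], q[2]) + pad) / pixel_size) + 1L)
  xs <- (seq(x0, x1) - 0.5) * pixel_size
  ys <- (seq(y0, y1) - 0.5) * pixel_size
  gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
  # distance from pixel centre to the capsule axis segment
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  l2 <- dx * dx + dy * dy
  t <- if (l2 > 1e-12) clamp(((gx - p[1]) * dx + (gy - p[2]) * dy) / l2, 0, 1)
       else 0
  ddx <- gx - (p[1] + t * dx)
  ddy <- gy - (p[2] + t * dy)
  d <- sqrt(ddx * ddx + ddy * ddy) - r   # signed distance to boundary
  cov <- clamp(0.5 - d / pixel_size, 0, 1)
  list(rows = seq(y0, y1), cols = seq(x0, x1), coverage = cov)
}

# Analytic area of the capsule footprint, um^2
capsule_area <- function(length, width) {
  (length - width) * width + pi * (width / 2)^2
}
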