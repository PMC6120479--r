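#' Widefield camera and optics model
#'
#' The forward model applied to every z-slice of the noise-free photon
#' image: lateral Gaussian PSF blur, Poisson shot noise, additive Gaussian
#' read noise, then a constant camera offset. Each term can be switched off
#' independently (`poisson_scale = 0`, `read_sigma = 0`, ...) which gives
#' exact noise-free images for oracle tests.
#'
#' @param psf_sigma Lateral PSF s.d. in um (Gaussian approximation of a
#'   high-NA widefield PSF).
#' @param poisson_scale Photon-to-count gain used for shot noise; counts are
#'   drawn as `Poisson(lambda * scale) / scale`. `0` disables shot noise.
#' @param read_sigma Gaussian read noise s.d. in counts; `0` disables.
#' @param background_offset Constant camera offset added to every pixel.
#' @return A list of class `poldep_noise`.
#' @export
noise_model <- function(psf_sigma = 0.15, poisson_scale = 1,
                        read_sigma = 2, background_offset = 10) {
  stopifnot(psf_sigma >= 0, poisson_scale >= 0, read_sigma >= 0,
            background_offset >= 0)
  structure(as.list(environment()), class = "poldep_noise")
}

#' Imaging geometry profile
#'
#' Field dimensions and sampling of the simulated microscope. The default
#' profile mirrors typical 100x/1.45NA camera sampling (0.1 um/px) with
#' 31 z-slices spaced 0.2 um. The `"scaled"` profile trades lateral
#' sampling for speed (0.2 um/px, smaller fields) and is used for
#' study-scale simulations.
#'
#' @param pixel_size_xy Lateral pixel size, um/px.
#' @param field_px Field side length in pixels (square fields).
#' @param n_z Number of z-slices.
#' @param z_step Axial slice spacing, um.
#' @param cells_per_field Default number of cells placed per field; `NULL`
#'   derives it from the field capacity.
#' @param name Optional profile label.
#' @return A list of class `poldep_sim_profile`.
#' @export
sim_profile <- function(pixel_size_xy = 0.1, field_px = 512L,
                        n_z = 31L, z_step = 0.2,
                        cells_per_field = NULL, name = "default") {
  stopifnot(pixel_size_xy > 0, field_px >= 32L, n_z >= 1L, z_step > 0)
  field_um <- field_px * pixel_size_xy
  if (is.null(cells_per_field)) {
    # ~140 um^2 of field area per cell keeps rejection sampling reliable
    cells_per_field <- max(2L, as.integer(field_um^2 / 140))
  }
  structure(list(pixel_size_xy = pixel_size_xy, field_px = as.integer(field_px),
                 n_z = as.integer(n_z), z_step = z_step,
                 cells_per_field = as.integer(cells_per_field),
                 field_um = field_um, name = name),
            class = "poldep_sim_profile")
}

#' @rdname sim_profile
#' @export
sim_profile_scaled <- function() {
  sim_profile(pixel_size_xy = 0.2, field_px = 256L, cells_per_field = 13L,
              name = "scaled")
}

#' Create an empty two-channel field canvas
#'
#' A `field_stack` holds one field of view: the noise-free per-pixel photon
#' images of both channels while cells are being painted in, and - after
#' [finalize_field()] - the noisy 31-slice stacks and/or their maximum
#' projections, plus the per-cell ground-truth annotations.
#'
#' @param profile A [sim_profile()].
#' @param field_id Field identifier string.
#' @param marker,deletion Labels of the study arm imaged in this field.
#' @return An object of class `field_stack`.
#' @export
field_stack <- function(profile = sim_profile(), field_id = "field_001",
                        marker = NA_character_, deletion = NA_character_) {
  n <- profile$field_px
  structure(
    list(
      gfp_base = matrix(0, n, n), red_base = matrix(0, n, n),
      gfp = NULL, red = NULL, gfp_proj = NULL, red_proj = NULL,
      pixel_size_xy = profile$pixel_size_xy, z_step = profile$z_step,
      n_z = profile$n_z, field_um = profile$field_um,
      field_id = field_id, marker = marker, deletion = deletion,
      cells = tibble(), cell_rows = list(), finalized = FALSE
    ),
    class = "field_stack"
  )
}

#' @export
print.field_stack <- function(x, ...) {
  cat("<field_stack> ", x$field_id, ": ", nrow(x$gfp_base), "x",
      ncol(x$gfp_base), " px x ", x$n_z, " z (",
      x$pixel_size_xy, " um/px), ", nrow(x$cells), " cells, ",
      if (x$finalized) "finalized" else "noise-free canvas", "\n", sep = "")
  invisible(x)
}

# chord-thickness z-weight profile of a rod lying on the coverslip:
# w_k proportional to the cell thickness sampled at slice k, centred
# mid-stack; normalised to sum 1 so z-distribution conserves photons.
z_profile_chord <- function(n_z, z_step, radius_um) {
  z <- (seq_len(n_z) - (n_z + 1) / 2) * z_step
  w <- sqrt(pmax(0, 1 - (z / radius_um)^2))
  if (sum(w) == 0) w[ceiling(n_z / 2)] <- 1
  w / sum(w)
}

# Gaussian axial profile (point-like red spindle-pole-body spot)
z_profile_gauss <- function(n_z, z_step, sigma_um) {
  z <- (seq_len(n_z) - (n_z + 1) / 2) * z_step
  w <- exp(-z^2 / (2 * sigma_um^2))
  w / sum(w)
}

# add an isotropic 2-D Gaussian spot (peak areal density `density`,
# photons/um^2) at (cx, cy) um to a per-pixel photon image
add_gaussian_spot <- function(img, cx, cy, sigma, density, pixel_size) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- 4 * sigma
  x0 <- max(1L, floor((cx - pad) / pixel_size) + 1L)
  x1 <- min(nx, ceiling((cx + pad) / pixel_size) + 1L)
  y0 <- max(1L, floor((cy - pad) / pixel_size) + 1L)
  y1 <- min(ny, ceiling((cy + pad) / pixel_size) + 1L)
  if (x0 > x1 || y0 > y1) return(img)
  xs <- (seq(x0, x1) - 0.5) * pixel_size - cx
  ys <- (seq(y0, y1) - 0.5) * pixel_size - cy
  g <- exp(-outer(ys^2, xs^2, `+`) / (2 * sigma^2))
  img[y0:y1, x0:x1] <- img[y0:y1, x0:x1] + density * pixel_size^2 * g
  img
}

#' Paint one cell into a field canvas
#'
#' Adds the noise-free GFP signal of a rod cell - a uniform cytosolic
#' plateau over the capsule footprint plus Gaussian tip spots centred on
#' the two poles - to the canvas, and for `genotype = "control"` one or two
#' red punctate spindle-pole-body spots placed inside the cell. Deletion
#' cells contribute no red signal. Blur, axial distribution and noise are
#' applied later by [finalize_field()].
#'
#' @param canvas A [field_stack()] (not yet finalized).
#' @param geom One-row geometry tibble from [sample_cell_geometry()].
#' @param genotype `"control"` or `"deletion"`.
#' @param tip1_amp,tip2_amp Peak areal densities of the pole-1 / pole-2 tip
#'   spots, photons/um^2.
#' @param cyto_amp Areal density of the cytosolic plateau, photons/um^2.
#' @param prior A [cell_prior()] (spot widths, red-spot parameters).
#' @param n_spb Number of red spots for control cells (1 or 2); `NULL`
#'   draws 1 or 2 with equal probability from the current RNG stream.
#' @param seed Optional seed set before the red-spot draws.
#' @return The updated canvas.
#' @export
render_cell <- function(canvas, geom, genotype = c("control", "deletion"),
                        tip1_amp, tip2_amp, cyto_amp,
                        prior = cell_prior(), n_spb = NULL, seed = NULL) {
  stopifnot(inherits(canvas, "field_stack"), !canvas$finalized,
            tip1_amp >= 0, tip2_amp >= 0, cyto_amp >= 0)
  genotype <- match.arg(genotype)
  if (!is.null(seed)) set.seed(seed)
  ps <- canvas$pixel_size_xy
  half <- geom$length / 2 + 1e-9
  if (geom$x - half < 0 || geom$y - half < 0 ||
      geom$x + half > canvas$field_um || geom$y + half > canvas$field_um) {
    poldep_abort("cell geometry does not fit inside the canvas",
                 "poldep_placement_error")
  }

  patch <- capsule_patch(geom, ps, nrow(canvas$gfp_base),
                         ncol(canvas$gfp_base))
  canvas$gfp_base[patch$rows, patch$cols] <-
    canvas$gfp_base[patch$rows, patch$cols] +
    cyto_amp * ps^2 * patch$coverage
  canvas$gfp_base <- add_gaussian_spot(canvas$gfp_base, geom$pole1_x,
                                       geom$pole1_y, prior$tip_sigma,
                                       tip1_amp, ps)
  canvas$gfp_base <- add_gaussian_spot(canvas$gfp_base, geom$pole2_x,
                                       geom$pole2_y, prior$tip_sigma,
                                       tip2_amp, ps)

  n_spb_drawn <- 0L
  if (genotype == "control") {
    n_spb_drawn <- if (is.null(n_spb)) sample(1:2, 1) else as.integer(n_spb)
    # SPB sits near the nucleus: along the axis within the central half
    u <- c(cos(geom$theta), sin(geom$theta))
    v <- c(-u[2], u[1])
    for (k in seq_len(n_spb_drawn)) {
      a <- runif(1, -geom$length / 5, geom$length / 5)
      b <- runif(1, -geom$width / 5, geom$width / 5)
      canvas$red_base <- add_gaussian_spot(
        canvas$red_base,
        geom$x + a * u[1] + b * v[1], geom$y + a * u[2] + b * v[2],
        prior$spb_sigma_xy, prior$spb_density, ps
      )
    }
  }

  ann <- list(
    field_id = canvas$field_id, cell_id = geom$cell_id,
    genotype = genotype, marker = canvas$marker, deletion = canvas$deletion,
    pole1_x = geom$pole1_x, pole1_y = geom$pole1_y,
    pole2_x = geom$pole2_x, pole2_y = geom$pole2_y,
    true_end1 = max(tip1_amp, tip2_amp), true_end2 = min(tip1_amp, tip2_amp),
    true_cyto = cyto_amp,
    x = geom$x, y = geom$y, theta = geom$theta,
    length = geom$length, width = geom$width,
    tip1_amp = tip1_amp, tip2_amp = tip2_amp, n_spb = n_spb_drawn,
    true_gfp_photons = 2 * pi * prior$tip_sigma^2 * (tip1_amp + tip2_amp) +
      capsule_area(geom$length, geom$width) * cyto_amp,
    true_red_photons = n_spb_drawn * 2 * pi * prior$spb_sigma_xy^2 *
      prior$spb_density
  )
  canvas$cell_rows <- c(canvas$cell_rows, list(ann))
  canvas
}

# separable Gaussian blur via banded kernel matrices (BLAS); photons at the
# border are truncated, not re-normalised, so blur is strictly linear
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px < 0.05) return(img)
  r <- ceiling(4 * sigma_px)
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  n <- nrow(img)
  K <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    idx <- seq_len(n - abs(j))
    if (j >= 0) K[cbind(idx + j, idx)] <- k[j + r + 1]
    else K[cbind(idx, idx - j)] <- k[j + r + 1]
  }
  K %*% img %*% t(K)
}

#' Apply optics and camera model to a painted field
#'
#' Blurs each channel with the lateral PSF, distributes the photon image
#' across the 31 z-slices (chord-thickness profile for the GFP channel,
#' narrow Gaussian for the red spindle-pole-body spots), then applies
#' Poisson shot noise, Gaussian read noise and the constant camera offset
#' per voxel. The maximum projection is always computed; the full stacks
#' are kept only if `keep_stack = TRUE`.
#'
#' @param canvas A painted [field_stack()].
#' @param noise A [noise_model()].
#' @param prior A [cell_prior()] (axial extents).
#' @param seed Integer seed for the noise streams.
#' @param keep_stack Keep the full 3-D arrays (needed to write TIFFs or to
#'   test projection code) or only the projections.
#' @return The finalized `field_stack`.
#' @export
finalize_field <- function(canvas, noise = noise_model(), prior = cell_prior(),
                           seed = 1L, keep_stack = FALSE) {
  stopifnot(inherits(canvas, "field_stack"), !canvas$finalized)
  ps <- canvas$pixel_size_xy
  sigma_px <- noise$psf_sigma / ps
  gfp_b <- gaussian_blur(canvas$gfp_base, sigma_px)
  red_b <- gaussian_blur(canvas$red_base, sigma_px)
  zw_gfp <- z_profile_chord(canvas$n_z, canvas$z_step, prior$width / 2)
  zw_red <- z_profile_gauss(canvas$n_z, canvas$z_step, prior$spb_sigma_z)
  g <- simulate_stack_cpp(gfp_b, zw_gfp, noise$poisson_scale,
                          noise$read_sigma, noise$background_offset,
                          subseed(seed, "noise-gfp"), keep_stack)
  r <- simulate_stack_cpp(red_b, zw_red, noise$poisson_scale,
                          noise$read_sigma, noise$background_offset,
                          subseed(seed, "noise-red"), keep_stack)
  canvas$gfp_proj <- g$proj
  canvas$red_proj <- r$proj
  canvas$gfp <- g$stack
  canvas$red <- r$stack
  canvas$finalized <- TRUE
  canvas$noise <- noise
  canvas$cells <- bind_rows(canvas$cell_rows)
  canvas$cell_rows <- NULL
  canvas
}

#' Simulate one mixed wild-type / deletion field of view
#'
#' Places `n_control + n_deletion` cells at random non-overlapping
#' positions, draws per-cell brightness and bipolarity from the prior,
#' applies the ground-truth effect multipliers to the deletion cells, and
#' runs the full optics and camera model. The internal-control design of
#' the assay - both genotypes in the same field, distinguished only by the
#' red spindle-pole-body tag - is reproduced exactly.
#'
#' @param marker,deletion Arm labels.
#' @param n_control,n_deletion Cells of each genotype (>= 1).
#' @param truth One-row data frame with `mult_end1`, `mult_end2`,
#'   `mult_cyto`, `bipolarity_shift` (see [truth_table()]); `NULL` means no
#'   effect.
#' @param noise A [noise_model()].
#' @param prior A [cell_prior()].
#' @param profile A [sim_profile()].
#' @param field_id Field identifier.
#' @param seed Integer seed; geometry, amplitudes and noise all derive from
#'   it.
#' @param keep_stack Keep full 3-D stacks (see [finalize_field()]).
#' @return A finalized [field_stack()] with ground-truth annotations in
#'   `$cells`.
#' @examples
#' fs <- render_field("Tea1", "tea2", 2, 2,
#'                    profile = sim_profile(field_px = 256), seed = 1)
#' fs$cells$genotype
#' @export
render_field <- function(marker, deletion, n_control, n_deletion,
                         truth = NULL, noise = noise_model(),
                         prior = cell_prior(), profile = sim_profile(),
                         field_id = "field_001", seed = 1L,
                         keep_stack = FALSE) {
  stopifnot(n_control >= 1, n_deletion >= 1)
  set.seed(subseed(seed, "geometry"))
  n <- n_control + n_deletion
  geoms <- sample_cell_geometry(n, profile$field_um, prior)
  genotypes <- sample(c(rep("control", n_control),
                        rep("deletion", n_deletion)))
  mult <- c(end1 = 1, end2 = 1, cyto = 1)
  shift <- 0
  if (!is.null(truth)) {
    mult <- c(end1 = truth$mult_end1, end2 = truth$mult_end2,
              cyto = truth$mult_cyto)
    shift <- truth$bipolarity_shift
  }
  canvas <- field_stack(profile, field_id, marker, deletion)
  for (i in seq_len(n)) {
    del <- genotypes[i] == "deletion"
    bright <- rlnorm(1, 0, prior$brightness_sdlog)
    b <- clamp(prior$bipolarity + if (del) shift else 0, 0.02, 0.98)
    beta <- rbeta(1, b * prior$bipolarity_kappa,
                  (1 - b) * prior$bipolarity_kappa)
    t1 <- prior$tip_density * bright * rlnorm(1, 0, prior$compartment_sdlog)
    t2 <- beta * prior$tip_density * bright *
      rlnorm(1, 0, prior$compartment_sdlog)
    cy <- prior$cyto_density * bright * rlnorm(1, 0, prior$compartment_sdlog)
    if (del) {
      t1 <- t1 * mult[["end1"]]
      t2 <- t2 * mult[["end2"]]
      cy <- cy * mult[["cyto"]]
    }
    canvas <- render_cell(canvas, geoms[i, ], genotypes[i],
                          tip1_amp = t1, tip2_amp = t2, cyto_amp = cy,
                          prior = prior)
  }
  finalize_field(canvas, noise, prior, seed = subseed(seed, "noise"),
                 keep_stack = keep_stack)
}
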