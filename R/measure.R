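#' Estimate the field background from a cell-free circular region
#'
#' Scans a grid of candidate positions for a 3-um-diameter disc lying
#' entirely inside the image and at least `background_clearance` um away
#' from every cell mask, and returns the mean intensity of the candidate
#' disc with the smallest intensity variance (the "cleanest" cell-free
#' region, a deterministic surrogate for the experimenter's choice of a
#' background ROI). Ties break to the first candidate in row-major order.
#'
#' @param gfp_projection 2-D matrix.
#' @param labels Integer cell label matrix (0 = background), e.g. from
#'   [segment_cells()].
#' @param pixel_size um per pixel.
#' @param params A [quantify_params()].
#' @return The background mean (scalar) with the chosen disc centre (px)
#'   attached as attribute `"center"`.
#' @export
estimate_background <- function(gfp_projection, labels, pixel_size,
                                params = quantify_params()) {
  ny <- nrow(gfp_projection); nx <- ncol(gfp_projection)
  r_px <- max(1L, round(params$roi_diameter / 2 / pixel_size))
  clear_px <- r_px + params$background_clearance / pixel_size
  dist <- EBImage::distmap(matrix(as.numeric(labels == 0L), ny, nx))
  dist <- matrix(as.numeric(EBImage::imageData(dist)), ny, nx)
  if (!any(labels != 0L)) dist[] <- Inf
  stride <- max(1L, r_px)
  cy <- seq(r_px + 1L, ny - r_px, by = stride)
  cx <- seq(r_px + 1L, nx - r_px, by = stride)
  off <- disc_offsets(r_px)
  best <- NULL
  for (x in cx) {
    for (y in cy) {
      if (dist[y, x] < clear_px) next
      vals <- gfp_projection[cbind(y + off[, "dy"], x + off[, "dx"])]
      v <- var(vals)
      if (is.null(best) || v < best$v) best <- list(v = v, y = y, x = x,
                                                    m = mean(vals))
    }
  }
  if (is.null(best)) {
    poldep_abort("no cell-free background ROI available; field rejected",
                 "poldep_no_background")
  }
  structure(best$m, center = c(y = best$y, x = best$x))
}

# re-centre a tip ROI on the local maximum of the 3x3-smoothed image within
# `r_px` of the initial pole estimate (the mask extreme sits at the tip of
# the blur halo, not on the tip spot itself; an experimenter would centre
# the ROI on the visible tip signal)
refine_center <- function(img, cx_px, cy_px, r_px) {
  ny <- nrow(img); nx <- ncol(img)
  cx <- round(cx_px); cy <- round(cy_px)
  x0 <- max(2L, cx - r_px); x1 <- min(nx - 1L, cx + r_px)
  y0 <- max(2L, cy - r_px); y1 <- min(ny - 1L, cy + r_px)
  if (x0 > x1 || y0 > y1) return(c(x = cx_px, y = cy_px))
  w <- img[(y0 - 1L):(y1 + 1L), (x0 - 1L):(x1 + 1L)]
  nr <- nrow(w)
  sm <- w[1:(nr - 2), ] + w[2:(nr - 1), ] + w[3:nr, ]
  nc <- ncol(sm)
  sm <- sm[, 1:(nc - 2)] + sm[, 2:(nc - 1)] + sm[, 3:nc]
  yy <- rep(y0:y1, times = ncol(sm))
  xx <- rep(x0:x1, each = nrow(sm))
  ok <- (yy - cy)^2 + (xx - cx)^2 <= r_px^2
  sm[!ok] <- -Inf
  i <- which.max(sm)
  c(x = xx[i], y = yy[i])
}

# mean/max of one ROI disc; returns NULL if too little of it is in-image
roi_statistics <- function(img, cx_px, cy_px, r_px, min_fraction,
                           foci_quantile = NULL) {
  off <- disc_offsets(r_px)
  yy <- round(cy_px) + off[, "dy"]
  xx <- round(cx_px) + off[, "dx"]
  inside <- yy >= 1 & yy <= nrow(img) & xx >= 1 & xx <= ncol(img)
  if (mean(inside) < min_fraction) return(NULL)
  vals <- img[cbind(yy[inside], xx[inside])]
  if (!is.null(foci_quantile)) {
    vals <- vals[vals <= quantile(vals, foci_quantile)]
  }
  list(mean = mean(vals), max = max(vals))
}

#' Measure tip and cytosol ROIs of segmented cells
#'
#' Implements the per-cell measurement scheme: mean and maximum intensity
#' within 3-um-diameter circular regions centred on each pole and on a
#' non-foci cytosolic region (the centroid disc with its brightest decile
#' dropped), each recorded raw and background-corrected. `End1` is the
#' cell end with the brighter background-corrected mean; the bipolarity
#' index is the corrected End2/End1 mean ratio clamped to \[0, 1\].
#'
#' @param cells Segmentation tibble (with `genotype` if available).
#' @param gfp_projection 2-D matrix.
#' @param background_mean Field background level from
#'   [estimate_background()].
#' @param pixel_size um per pixel.
#' @param params A [quantify_params()].
#' @return `cells` with measurement columns and an `analysed` flag; cells
#'   failing QC (segmentation flags, ambiguous genotype, clipped ROI) keep
#'   `analysed = FALSE` and NA measurements.
#' @export
measure_cells <- function(cells, gfp_projection, background_mean, pixel_size,
                          params = quantify_params()) {
  r_px <- max(1L, round(params$roi_diameter / 2 / pixel_size))
  n <- nrow(cells)
  cols <- c("end1_mean_raw", "end1_max_raw", "end1_mean", "end1_max",
            "end2_mean_raw", "end2_max_raw", "end2_mean", "end2_max",
            "cyto_mean_raw", "cyto_max_raw", "cyto_mean", "cyto_max")
  out <- cells
  for (cl in cols) out[[cl]] <- NA_real_
  out$background_mean <- as.numeric(background_mean)
  out$end1_x <- out$end1_y <- out$end2_x <- out$end2_y <- NA_real_
  out$bipolarity_index <- NA_real_
  out$analysed <- FALSE
  qc <- out$qc_flags
  geno_ok <- if ("genotype" %in% names(out)) out$genotype != "ambiguous"
             else rep(TRUE, n)
  if (!all(geno_ok)) {
    qc[!geno_ok] <- ifelse(qc[!geno_ok] == "", "ambiguous_genotype",
                           paste0(qc[!geno_ok], ",ambiguous_genotype"))
  }
  for (i in seq_len(n)) {
    if (qc[i] != "") next
    x1 <- cells$pole1_x[i] / pixel_size + 0.5
    y1 <- cells$pole1_y[i] / pixel_size + 0.5
    x2 <- cells$pole2_x[i] / pixel_size + 0.5
    y2 <- cells$pole2_y[i] / pixel_size + 0.5
    p1 <- roi_statistics(gfp_projection, x1, y1, r_px,
                         params$min_roi_fraction)
    p2 <- roi_statistics(gfp_projection, x2, y2, r_px,
                         params$min_roi_fraction)
    cy <- roi_statistics(gfp_projection,
                         cells$centroid_x[i] / pixel_size + 0.5,
                         cells$centroid_y[i] / pixel_size + 0.5, r_px,
                         params$min_roi_fraction,
                         foci_quantile = params$foci_quantile)
    if (is.null(p1) || is.null(p2) || is.null(cy)) {
      qc[i] <- "roi_clipped"
      next
    }
    # End1 = brighter end by background-corrected mean
    swap <- (p2$mean - background_mean) > (p1$mean - background_mean)
    if (swap) {
      tmp <- p1; p1 <- p2; p2 <- tmp
    }
    out$end1_x[i] <- if (swap) cells$pole2_x[i] else cells$pole1_x[i]
    out$end1_y[i] <- if (swap) cells$pole2_y[i] else cells$pole1_y[i]
    out$end2_x[i] <- if (swap) cells$pole1_x[i] else cells$pole2_x[i]
    out$end2_y[i] <- if (swap) cells$pole1_y[i] else cells$pole2_y[i]
    e1 <- p1$mean - background_mean
    e2 <- p2$mean - background_mean
    out$end1_mean_raw[i] <- p1$mean; out$end1_max_raw[i] <- p1$max
    out$end1_mean[i] <- e1; out$end1_max[i] <- p1$max - background_mean
    out$end2_mean_raw[i] <- p2$mean; out$end2_max_raw[i] <- p2$max
    out$end2_mean[i] <- e2; out$end2_max[i] <- p2$max - background_mean
    out$cyto_mean_raw[i] <- cy$mean; out$cyto_max_raw[i] <- cy$max
    out$cyto_mean[i] <- cy$mean - background_mean
    out$cyto_max[i] <- cy$max - background_mean
    out$bipolarity_index[i] <- if (e1 <= 0) 0 else clamp(e2 / e1, 0, 1)
    out$analysed[i] <- TRUE
  }
  out$qc_flags <- qc
  out
}

#' Quantify one field of view
#'
#' Runs the full measurement chain on a field: maximum projection of both
#' channels, segmentation, genotype calling from the red channel,
#' background estimation and ROI measurement. Fields without a valid
#' cell-free background region are rejected with a warning and return no
#' rows.
#'
#' @param fs A finalized [field_stack()].
#' @param params A [quantify_params()].
#' @return Tibble with one row per segmented cell (analysed and excluded),
#'   carrying `field_id`, `marker`, `deletion`, genotype, geometry, QC
#'   flags and the measurement columns of [measure_cells()].
#' @export
quantify_field <- function(fs, params = quantify_params()) {
  stopifnot(inherits(fs, "field_stack"), fs$finalized)
  gproj <- max_project(fs, "gfp")
  rproj <- max_project(fs, "red")
  seg <- segment_cells(gproj, fs$pixel_size_xy, params)
  if (nrow(seg) == 0L) return(empty_measurement(fs))
  seg <- call_genotype(seg, rproj, params = params)
  bg <- tryCatch(estimate_background(gproj, attr(seg, "labels"),
                                     fs$pixel_size_xy, params),
                 poldep_no_background = function(e) NULL)
  if (is.null(bg)) {
    warn(paste0("field ", fs$field_id,
                ": no background ROI available; field dropped"))
    return(empty_measurement(fs))
  }
  meas <- measure_cells(seg, gproj, bg, fs$pixel_size_xy, params)
  mutate(meas, field_id = fs$field_id, marker = fs$marker,
         deletion = fs$deletion, .before = 1L)
}

empty_measurement <- function(fs) {
  m <- measure_cells(empty_segmentation(), matrix(0, 2, 2), 0, 1)
  mutate(m, field_id = character(), marker = character(),
         deletion = character(), genotype = character(), .before = 1L)
}

#' Quantify a set of fields
#'
#' @param fields A list of finalized [field_stack()] objects, or a
#'   [generate_study()] manifest tibble (fields are then read from disk).
#' @param params A [quantify_params()].
#' @return Combined per-cell measurement tibble.
#' @export
quantify_study <- function(fields, params = quantify_params()) {
  if (is.data.frame(fields)) {
    fields <- map(seq_len(nrow(fields)),
                  function(i) read_field_stack(fields[i, ]))
  }
  bind_rows(map(fields, quantify_field, params = params))
}

#' Attach ground-truth annotations to measured cells
#'
#' Matches each measured cell to the nearest annotated ground-truth cell of
#' the same field (by centroid distance) so recovery of planted effects can
#' be checked.
#'
#' @param cells Measurement tibble from [quantify_field()].
#' @param annotations Ground-truth annotation tibble (e.g. `fs$cells`).
#' @param max_dist Maximum centre-to-centre match distance, um.
#' @return `cells` with `true_end1`, `true_end2`, `true_cyto`,
#'   `true_genotype` columns (NA where unmatched).
#' @export
join_truth <- function(cells, annotations, max_dist = 2) {
  ann <- annotations
  idx <- map(seq_len(nrow(cells)), function(i) {
    cand <- which(ann$field_id == cells$field_id[i])
    if (!length(cand)) return(NA_integer_)
    d <- sqrt((ann$x[cand] - cells$centroid_x[i])^2 +
              (ann$y[cand] - cells$centroid_y[i])^2)
    j <- which.min(d)
    if (d[j] <= max_dist) cand[j] else NA_integer_
  })
  idx <- unlist(idx)
  mutate(cells,
         true_end1 = ann$true_end1[idx], true_end2 = ann$true_end2[idx],
         true_cyto = ann$true_cyto[idx],
         true_genotype = ann$genotype[idx])
}
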