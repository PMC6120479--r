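#' Parameters of the quantification stage
#'
#' @param length_range Accepted interphase mask length range, um; cells
#'   outside are flagged `length_range` and excluded.
#' @param min_aspect Minimum length/width aspect ratio of a rod.
#' @param max_width Maximum mask width in um; wider components are merged
#'   neighbours that escaped the watershed split and are flagged
#'   `non_rod`.
#' @param min_area_um2 Connected components smaller than this are treated
#'   as debris and never become cell candidates.
#' @param roi_diameter Diameter of the circular measurement regions, um.
#' @param refine_radius Search radius (um) for re-centring a tip ROI on
#'   the local intensity maximum near the mask pole.
#' @param foci_quantile Cytosol-disc pixels above this quantile are dropped
#'   before averaging (the "non-foci" rule).
#' @param min_roi_fraction Minimum fraction of an ROI disc that must lie
#'   inside the image; otherwise the cell is excluded (`roi_clipped`).
#' @param genotype_k_hi,genotype_k_lo Hysteresis thresholds for genotype
#'   calling: control if the brightest in-mask red pixel is at least
#'   `k_hi` times the robust red background, deletion if below `k_lo`
#'   times, ambiguous (excluded) in between.
#' @param septum_ratio A transverse intensity ridge at mid-cell exceeding
#'   this multiple of the central axial profile flags a septating cell.
#' @param threshold_factor Segmentation threshold as a multiple of the
#'   image median (robust background).
#' @param background_clearance Minimum distance between the background ROI
#'   and any cell mask, um.
#' @return A list of class `poldep_quantify_params`.
#' @export
quantify_params <- function(length_range = c(5.5, 18), min_aspect = 1.5,
                            max_width = 5,
                            min_area_um2 = 6, roi_diameter = 3,
                            refine_radius = 1.2,
                            foci_quantile = 0.9, min_roi_fraction = 0.8,
                            genotype_k_hi = 5, genotype_k_lo = 3,
                            septum_ratio = 1.3, threshold_factor = 1.8,
                            background_clearance = 1) {
  structure(as.list(environment()), class = "poldep_quantify_params")
}

# axial intensity profile septum check: a bright transverse ridge in the
# central third of the cell marks septation
has_septum <- function(int, pos, len, septum_ratio) {
  if (len <= 0) return(FALSE)
  nb <- max(8L, ceiling(len / 0.3))
  bins <- cut(pos, breaks = seq(min(pos), max(pos), length.out = nb + 1),
              include.lowest = TRUE)
  prof <- tapply(int, bins, mean)
  prof <- prof[!is.na(prof)]
  n <- length(prof)
  if (n < 6) return(FALSE)
  central <- prof[ceiling(n * 0.35):floor(n * 0.65)]
  body <- prof[ceiling(n * 0.2):floor(n * 0.8)]
  max(central) > septum_ratio * stats::median(body)
}

#' Segment rod-shaped cells from a maximum projection
#'
#' Global intensity threshold at a fixed multiple of the image median (the
#' robust background level of a sparsely mounted field), hole filling and
#' small-object removal; connected components too large to be one cell are
#' split with a distance-map watershed (touching rods neck at the contact
#' point). Then per-component rod quality control: length
#' gate, aspect-ratio gate, border exclusion and a septum heuristic (a
#' transverse intensity ridge at mid-cell). The
#' poles of each accepted cell are found from the two extremal mask pixels
#' along the principal axis and then re-centred on the local maximum of the
#' lightly smoothed projection within `refine_radius` (the mask extreme
#' sits at the tip of the blur halo, whereas the tip signal itself is the
#' natural ROI anchor, as in manual measurement). All intensity criteria
#' are ratios, so segmentation is invariant to a global intensity
#' rescaling of the image.
#'
#' @param gfp_projection 2-D non-negative matrix (maximum projection).
#' @param pixel_size um per pixel.
#' @param params A [quantify_params()].
#' @return Tibble of segmented cells (one row each) with centroid,
#'   orientation, mask length/width in um, pole coordinates (um) and
#'   `qc_flags` (comma-joined; empty = passes QC). The integer label
#'   matrix is attached as attribute `"labels"`.
#' @export
segment_cells <- function(gfp_projection, pixel_size,
                          params = quantify_params()) {
  stopifnot(is.matrix(gfp_projection), all(gfp_projection >= 0))
  img <- gfp_projection
  top <- max(img)
  if (top <= 0) {
    out <- empty_segmentation()
    attr(out, "labels") <- matrix(0L, nrow(img), ncol(img))
    return(out)
  }
  # threshold relative to the robust background level (the image median:
  # background pixels dominate a sparsely mounted field). A background-
  # anchored threshold keeps working when different genotypes in one field
  # have very different cytosolic brightness, where a two-class split can
  # land between the two cytosol levels; being a pure intensity ratio it
  # is also invariant to global rescaling.
  thr <- max(params$threshold_factor * stats::median(img), 1e-3 * top)
  mask <- img > thr
  # closing heals speckle holes in dim cytosol before the opening removes
  # isolated noise pixels
  mask <- EBImage::closing(mask, EBImage::makeBrush(3, "disc"))
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, "disc"))
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(img), ncol(img))
  ny <- nrow(img); nx <- ncol(img)

  # rods whose blur halos touch merge into one component. Only components
  # too large to be a single cell are split (distance-map watershed at the
  # neck between cell spines); splitting every component would fragment
  # dim rods whose bright tip bulbs create shallow necks of their own.
  max_len <- params$length_range[2] + 1
  comp_ids <- setdiff(unique(as.vector(labels)), 0L)
  for (lb in comp_ids) {
    idx <- which(labels == lb)
    yy <- ((idx - 1L) %% ny) + 1L
    xx <- ((idx - 1L) %/% ny) + 1L
    ext_um <- max(diff(range(yy)), diff(range(xx))) * pixel_size
    area_um <- length(idx) * pixel_size^2
    if (ext_um <= max_len &&
        area_um <= max_len * params$max_width) {
      next
    }
    sub <- matrix(0, max(yy) - min(yy) + 1L, max(xx) - min(xx) + 1L)
    sub[cbind(yy - min(yy) + 1L, xx - min(xx) + 1L)] <- 1
    w <- EBImage::watershed(EBImage::distmap(sub), tolerance = 2)
    w <- matrix(as.integer(EBImage::imageData(w)), nrow(sub), ncol(sub))
    pieces <- w[cbind(yy - min(yy) + 1L, xx - min(xx) + 1L)]
    top_id <- max(labels)
    labels[idx] <- ifelse(pieces > 1L, top_id + pieces - 1L, lb)
  }
  min_px <- params$min_area_um2 / pixel_size^2
  ids <- setdiff(unique(as.vector(labels)), 0L)
  keep_labels <- matrix(0L, ny, nx)
  rows <- list()
  next_id <- 0L
  for (lb in ids) {
    idx <- which(labels == lb)
    if (length(idx) < min_px) next
    next_id <- next_id + 1L
    yy <- ((idx - 1L) %% ny) + 1L
    xx <- ((idx - 1L) %/% ny) + 1L
    keep_labels[idx] <- next_id
    # principal axis from the pixel-coordinate covariance
    pxy <- cbind((xx - 0.5) * pixel_size, (yy - 0.5) * pixel_size)
    ctr <- colMeans(pxy)
    cv <- stats::cov(pxy)
    ev <- eigen(cv, symmetric = TRUE)
    axis <- ev$vectors[, 1]
    proj_major <- (pxy[, 1] - ctr[1]) * axis[1] + (pxy[, 2] - ctr[2]) * axis[2]
    proj_minor <- -(pxy[, 1] - ctr[1]) * axis[2] +
      (pxy[, 2] - ctr[2]) * axis[1]
    len <- diff(range(proj_major)) + pixel_size
    wid <- diff(range(proj_minor)) + pixel_size
    i1 <- which.max(proj_major); i2 <- which.min(proj_major)
    r_ref <- max(1L, round(params$refine_radius / pixel_size))
    p1 <- refine_center(img, pxy[i1, 1] / pixel_size + 0.5,
                        pxy[i1, 2] / pixel_size + 0.5, r_ref)
    p2 <- refine_center(img, pxy[i2, 1] / pixel_size + 0.5,
                        pxy[i2, 2] / pixel_size + 0.5, r_ref)
    flags <- character()
    if (any(yy <= 1L) || any(xx <= 1L) || any(yy >= ny) || any(xx >= nx)) {
      flags <- c(flags, "border")
    }
    if (len < params$length_range[1] || len > params$length_range[2]) {
      flags <- c(flags, "length_range")
    }
    if (wid <= 0 || len / wid < params$min_aspect ||
        wid > params$max_width) {
      flags <- c(flags, "non_rod")
    }
    spine <- abs(proj_minor) <= 0.35 * wid   # exclude lateral halo pixels
    if (has_septum(img[idx][spine], proj_major[spine], len,
                   params$septum_ratio)) {
      flags <- c(flags, "septated")
    }
    rows[[next_id]] <- list(
      cell_id = next_id,
      centroid_x = ctr[1], centroid_y = ctr[2],
      theta = atan2(axis[2], axis[1]),
      length_um = len, width_um = wid,
      aspect = if (wid > 0) len / wid else Inf,
      pole1_x = (p1[["x"]] - 0.5) * pixel_size,
      pole1_y = (p1[["y"]] - 0.5) * pixel_size,
      pole2_x = (p2[["x"]] - 0.5) * pixel_size,
      pole2_y = (p2[["y"]] - 0.5) * pixel_size,
      area_um2 = length(idx) * pixel_size^2,
      n_px = length(idx),
      qc_flags = paste(flags, collapse = ",")
    )
  }
  out <- if (length(rows)) bind_rows(rows) else empty_segmentation()
  attr(out, "labels") <- keep_labels
  attr(out, "pixel_size") <- pixel_size
  out
}

empty_segmentation <- function() {
  tibble(cell_id = integer(), centroid_x = double(), centroid_y = double(),
         theta = double(), length_um = double(), width_um = double(),
         aspect = double(), pole1_x = double(), pole1_y = double(),
         pole2_x = double(), pole2_y = double(), area_um2 = double(),
         n_px = integer(), qc_flags = character())
}

#' Call cell genotype from the red spindle-pole-body channel
#'
#' Wild-type (control) cells carry a bright red punctum; deletion cells do
#' not. A cell is called `control` if its brightest in-mask red pixel
#' reaches `k_hi` times the robust (median) red background, `deletion` if
#' it stays below `k_lo` times, and `ambiguous` between the two hysteresis
#' thresholds; ambiguous cells are excluded from all statistics.
#'
#' @param cells Segmentation tibble from [segment_cells()] (its `"labels"`
#'   attribute is used; pass `labels` explicitly otherwise).
#' @param red_projection 2-D red-channel maximum projection.
#' @param labels Optional integer label matrix matching `cells$cell_id`.
#' @param params A [quantify_params()].
#' @return `cells` with a `genotype` column added.
#' @export
call_genotype <- function(cells, red_projection, labels = NULL,
                          params = quantify_params()) {
  labels <- labels %||% attr(cells, "labels")
  stopifnot(is.matrix(labels), all(dim(labels) == dim(red_projection)))
  bg <- stats::median(red_projection[labels == 0L])
  bg <- max(bg, .Machine$double.eps)
  geno <- map_chr(cells$cell_id, function(id) {
    m <- max(red_projection[labels == id])
    if (m >= params$genotype_k_hi * bg) "control"
    else if (m <= params$genotype_k_lo * bg) "deletion"
    else "ambiguous"
  })
  out <- mutate(cells, genotype = geno)
  attr(out, "labels") <- labels
  attr(out, "pixel_size") <- attr(cells, "pixel_size")
  out
}
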