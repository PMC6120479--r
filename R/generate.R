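# plan of fields for a design: how many fields per combination and how the
# two genotype arms are split across them
field_plan <- function(design, profile) {
  cpf <- profile$cells_per_field
  n_fields <- design$fields_per_combination %||%
    max(1L, ceiling(2 * design$cells_per_arm / cpf))
  split_arm <- function(total, k) {
    base <- rep(total %/% k, k)
    extra <- total %% k
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  per_field_ctrl <- split_arm(design$cells_per_arm, n_fields)
  per_field_del <- split_arm(design$cells_per_arm, n_fields)
  combos <- design$combinations
  plans <- pmap(list(combos$marker, combos$deletion,
                     seq_len(nrow(combos))), function(m, d, ci) {
    tibble(
      marker = m, deletion = d, combo_index = ci,
      field_index = seq_len(n_fields),
      n_control = per_field_ctrl, n_deletion = per_field_del,
      field_id = sprintf("%s_%s_f%02d", m, d, seq_len(n_fields))
    )
  })
  plan <- bind_rows(plans)
  filter(plan, .data$n_control + .data$n_deletion > 0)
}

# render one planned field; on a capacity failure (rejection sampling could
# not place all cells) retry deterministically with fresh sub-seeds
render_planned_field <- function(row, truth_row, noise, prior, profile,
                                 seed, keep_stack = FALSE, retries = 3L) {
  for (r in 0:retries) {
    fseed <- subseed(seed, "simulate",
                     row$combo_index * 100000 + row$field_index * 10 + r)
    fs <- tryCatch(
      render_field(row$marker, row$deletion, row$n_control, row$n_deletion,
                   truth = truth_row, noise = noise, prior = prior,
                   profile = profile, field_id = row$field_id, seed = fseed,
                   keep_stack = keep_stack),
      poldep_capacity_error = function(e) NULL
    )
    if (!is.null(fs)) return(fs)
  }
  poldep_abort(paste0("field ", row$field_id, " could not be placed after ",
                      retries + 1, " attempts; reduce cells_per_field"),
               "poldep_capacity_error")
}

#' Generate a synthetic imaging study on disk
#'
#' Renders every planned field of the design and writes, per field, a
#' multi-page 32-bit float TIFF (page order: all GFP z-slices, then all red
#' z-slices) and a per-cell ground-truth annotation CSV, plus one manifest
#' CSV indexing the whole study. TIFF float pages can only hold values in
#' \[0, 1\], so each stack is stored divided by its `intensity_scale`
#' (recorded in the manifest) and multiplied back on read.
#'
#' @param design A [study_design()].
#' @param truth A [truth_table()] for the design.
#' @param noise A [noise_model()].
#' @param prior A [cell_prior()].
#' @param profile A [sim_profile()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed; the study is fully reproducible from
#'   (design, truth, seed).
#' @return The manifest tibble (also written to `out_dir/manifest.csv`).
#' @export
generate_study <- function(design, truth = truth_table(design, "null"),
                           noise = noise_model(), prior = cell_prior(),
                           profile = sim_profile(), out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    poldep_abort(paste0("cannot create output directory ", out_dir),
                 "poldep_io_error")
  }
  plan <- field_plan(design, profile)
  if (anyDuplicated(plan$field_id)) {
    poldep_abort("duplicate field_id in study plan", "poldep_integrity_error")
  }
  truth_key <- paste(truth$marker, truth$deletion)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    tr <- truth[match(paste(row$marker, row$deletion), truth_key), ]
    fs <- render_planned_field(row, tr, noise, prior, profile, seed,
                               keep_stack = TRUE)
    # float TIFF pages must lie in [0, 1]: store (x - offset) / scale and
    # record both constants in the manifest (read noise makes a few counts
    # slightly negative)
    shift <- min(min(fs$gfp), min(fs$red), 0)
    scale <- (max(max(fs$gfp), max(fs$red)) - shift + 1) * (1 + 1e-6)
    pages <- c(lapply(seq_len(fs$n_z),
                      function(k) (fs$gfp[, , k] - shift) / scale),
               lapply(seq_len(fs$n_z),
                      function(k) (fs$red[, , k] - shift) / scale))
    img_path <- file.path(out_dir, paste0(row$field_id, ".tif"))
    ann_path <- file.path(out_dir, paste0(row$field_id, "_cells.csv"))
    tiff::writeTIFF(pages, img_path, bits.per.sample = 32L,
                    compression = "deflate")
    readr::write_csv(fs$cells, ann_path)
    rows[[i]] <- mutate(row,
                        path = img_path, annotation_path = ann_path,
                        n_z = fs$n_z, pixel_size_xy = fs$pixel_size_xy,
                        z_step = fs$z_step, intensity_scale = scale,
                        intensity_offset = shift, seed = seed)
  }
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read a simulated field back from disk
#'
#' @param manifest_row One row of a [generate_study()] manifest.
#' @return A finalized [field_stack()] with full 3-D arrays and, when the
#'   annotation CSV is present, the ground-truth cell table.
#' @export
read_field_stack <- function(manifest_row) {
  stopifnot(nrow(manifest_row) == 1L)
  pages <- tiff::readTIFF(manifest_row$path, all = TRUE)
  n_z <- manifest_row$n_z
  if (length(pages) != 2L * n_z) {
    poldep_abort("TIFF page count does not match 2 channels x n_z",
                 "poldep_io_error")
  }
  sc <- manifest_row$intensity_scale
  sh <- manifest_row$intensity_offset %||% 0
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  to_array <- function(idx) {
    a <- array(0, c(ny, nx, n_z))
    for (k in seq_len(n_z)) a[, , k] <- pages[[idx[k]]] * sc + sh
    a
  }
  profile <- sim_profile(pixel_size_xy = manifest_row$pixel_size_xy,
                         field_px = nx, n_z = n_z,
                         z_step = manifest_row$z_step)
  fs <- field_stack(profile, manifest_row$field_id,
                    manifest_row$marker, manifest_row$deletion)
  fs$gfp <- to_array(seq_len(n_z))
  fs$red <- to_array(n_z + seq_len(n_z))
  fs$finalized <- TRUE
  if (!is.na(manifest_row$annotation_path) &&
      file.exists(manifest_row$annotation_path)) {
    fs$cells <- readr::read_csv(manifest_row$annotation_path,
                                show_col_types = FALSE)
  }
  fs
}
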