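test_that("max projection matches the brute-force z-loop exactly", {
  set.seed(1)
  arr <- array(rnorm(20 * 18 * 31), c(20, 18, 31))
  expect_identical(max_project(arr), brute_force_max_project(arr))

  one <- array(runif(12 * 12), c(12, 12, 1))
  expect_identical(max_project(one), one[, , 1])
  expect_identical(max_project(array(0, c(5, 5, 31))), matrix(0, 5, 5))
  expect_error(max_project(array(1, c(3, 3, 0))),
               class = "poldep_empty_stack")

  fs <- test_field(seed = 2, keep_stack = TRUE)
  expect_equal(max_project(fs, "gfp"), brute_force_max_project(fs$gfp))
  # kept stack and streaming projection come from identical draws
  expect_equal(max_project(fs, "gfp"), fs$gfp_proj)
})

test_that("segmentation recovers well-separated cells and their poles", {
  prof <- sim_profile(pixel_size_xy = 0.2, field_px = 256L,
                      cells_per_field = 5L)
  fs <- render_field("Tea1", "tea2", 3, 2, profile = prof, seed = 21)
  seg <- segment_cells(max_project(fs, "gfp"), fs$pixel_size_xy)
  ok <- seg[seg$qc_flags == "", ]
  expect_equal(nrow(ok), 5L)
  ann <- fs$cells
  for (i in seq_len(nrow(ok))) {
    j <- which.min((ann$x - ok$centroid_x[i])^2 + (ann$y - ok$centroid_y[i])^2)
    d1 <- sqrt((ann$pole1_x[j] - ok$pole1_x[i])^2 +
               (ann$pole1_y[j] - ok$pole1_y[i])^2)
    d1b <- sqrt((ann$pole2_x[j] - ok$pole1_x[i])^2 +
                (ann$pole2_y[j] - ok$pole1_y[i])^2)
    expect_lt(min(d1, d1b), 0.5)   # um
    expect_gte(ok$aspect[i], 1.5)
  }
})

test_that("empty and degenerate projections yield no cells", {
  expect_equal(nrow(segment_cells(matrix(0, 64, 64), 0.2)), 0L)
  expect_equal(nrow(segment_cells(matrix(7, 64, 64), 0.2)), 0L)
  set.seed(2)
  flat <- matrix(10 + rnorm(64 * 64, sd = 2), 64, 64)
  flat[flat < 0] <- 0
  expect_equal(nrow(segment_cells(flat, 0.2)), 0L)
})

test_that("cells touching the field border are excluded with a qc flag", {
  prof <- test_profile()
  prior <- cell_prior(margin = 0)
  geom <- tibble::tibble(cell_id = 1L, x = 4.2, y = prof$field_um / 2,
                         theta = 0, length = 8, width = 3.5,
                         pole1_x = 8.2, pole1_y = prof$field_um / 2,
                         pole2_x = 0.2, pole2_y = prof$field_um / 2)
  canvas <- render_cell(field_stack(prof), geom, "deletion",
                        1e5, 1e5, 1e4, prior = prior)
  fs <- finalize_field(canvas, noise_model(), seed = 1)
  seg <- segment_cells(max_project(fs, "gfp"), prof$pixel_size_xy)
  expect_equal(nrow(seg), 1L)
  expect_match(seg$qc_flags, "border")
})

test_that("a transverse mid-cell ridge flags septation", {
  prof <- test_profile()
  set.seed(8)
  geom <- sample_cell_geometry(1, prof$field_um, cell_prior())
  canvas <- render_cell(field_stack(prof), geom, "deletion", 1e5, 5e4, 1e4)
  # paint a bright septum stripe across the mid-cell
  u <- c(cos(geom$theta), sin(geom$theta))
  v <- c(-u[2], u[1])
  for (t in seq(-1.6, 1.6, by = 0.1)) {
    canvas$gfp_base <- poldep:::add_gaussian_spot(
      canvas$gfp_base, geom$x + t * v[1], geom$y + t * v[2],
      sigma = 0.15, density = 3e5, pixel_size = prof$pixel_size_xy
    )
  }
  fs <- finalize_field(canvas, noise_model(), seed = 2)
  seg <- segment_cells(max_project(fs, "gfp"), prof$pixel_size_xy)
  expect_equal(nrow(seg), 1L)
  expect_match(seg$qc_flags, "septated")
})

test_that("genotype calling is driven by the red channel hysteresis", {
  fs <- test_field(seed = 31)
  seg <- segment_cells(max_project(fs, "gfp"), fs$pixel_size_xy)
  seg <- call_genotype(seg, max_project(fs, "red"))
  q <- quantify_field(fs)
  qt <- join_truth(q, fs$cells)
  a <- qt[qt$analysed & !is.na(qt$true_genotype), ]
  expect_true(all(a$genotype == a$true_genotype))

  # engineered ambiguous cell: in-mask red maximum between the thresholds
  labels <- matrix(0L, 40, 40)
  labels[10:20, 10:20] <- 1L
  red <- matrix(10, 40, 40)
  red[15, 15] <- 40    # 4x the median background: between k_lo=3 and k_hi=5
  cells <- tibble::tibble(cell_id = 1L)
  out <- call_genotype(cells, red, labels = labels)
  expect_equal(out$genotype, "ambiguous")
  red[15, 15] <- 80
  expect_equal(call_genotype(cells, red, labels = labels)$genotype,
               "control")
  red[15, 15] <- 12
  expect_equal(call_genotype(cells, red, labels = labels)$genotype,
               "deletion")
})

test_that("ROI measurement is background-exact, symmetric and ordered", {
  # uniform image measured against its own background: all corrected 0
  img <- matrix(17.3, 80, 80)
  cells <- tibble::tibble(
    cell_id = 1L, centroid_x = 8, centroid_y = 8, theta = 0,
    length_um = 10, width_um = 3.5, aspect = 2.9,
    pole1_x = 12, pole1_y = 8, pole2_x = 4, pole2_y = 8,
    area_um2 = 35, n_px = 875L, qc_flags = ""
  )
  m <- measure_cells(cells, img, background_mean = 17.3, pixel_size = 0.2)
  expect_equal(m$end1_mean, 0)
  expect_equal(m$end2_mean, 0)
  expect_equal(m$cyto_mean, 0)
  expect_equal(m$bipolarity_index, 0)   # defined as 0 when End1 <= 0

  # swapping the stored pole order leaves the measurement unchanged
  fs <- test_field(seed = 33)
  proj <- max_project(fs, "gfp")
  seg <- segment_cells(proj, fs$pixel_size_xy)
  seg <- seg[seg$qc_flags == "", ]
  bg <- estimate_background(proj, attr(seg, "labels"), fs$pixel_size_xy)
  swapped <- dplyr::rename(seg,
    pole1_x = "pole2_x", pole1_y = "pole2_y",
    pole2_x = "pole1_x", pole2_y = "pole1_y")
  m1 <- measure_cells(seg, proj, bg, fs$pixel_size_xy)
  m2 <- measure_cells(swapped, proj, bg, fs$pixel_size_xy)
  for (col in c("end1_mean", "end2_mean", "cyto_mean", "bipolarity_index")) {
    expect_equal(m1[[col]], m2[[col]])
  }
  expect_true(all(m1$end1_mean[m1$analysed] >= m1$end2_mean[m1$analysed]))
})

test_that("End1 lands on the brighter rendered pole", {
  prof <- test_profile()
  hits <- 0L
  n_try <- 30L
  for (s in seq_len(n_try)) {
    set.seed(1000 + s)
    geom <- sample_cell_geometry(1, prof$field_um, cell_prior())
    a <- 1.2e5
    canvas <- render_cell(field_stack(prof), geom, "deletion",
                          tip1_amp = 2 * a, tip2_amp = a, cyto_amp = 1.5e4)
    fs <- finalize_field(canvas, noise_model(), seed = 2000 + s)
    q <- quantify_field(fs)
    q <- q[q$analysed, ]
    if (nrow(q) == 1L) {
      d_bright <- sqrt((q$end1_x - geom$pole1_x)^2 +
                       (q$end1_y - geom$pole1_y)^2)
      d_dim <- sqrt((q$end1_x - geom$pole2_x)^2 +
                    (q$end1_y - geom$pole2_y)^2)
      if (d_bright < d_dim) hits <- hits + 1L
    } else {
      n_try <- n_try - 1L
    }
  }
  expect_gte(hits / n_try, 0.95)
})

test_that("background ROI selection is clean, deterministic and guarded", {
  img <- matrix(12, 120, 120)
  labels <- matrix(0L, 120, 120)
  expect_equal(as.numeric(estimate_background(img, labels, 0.2)), 12)

  # a bright debris spot makes that candidate region high-variance; the
  # clean region must win
  img2 <- img
  img2[20:24, 20:24] <- 500
  b2 <- estimate_background(img2, labels, 0.2)
  expect_equal(as.numeric(b2), 12)
  ctr <- attr(b2, "center")
  expect_gt(sqrt((ctr["y"] - 22)^2 + (ctr["x"] - 22)^2), 8)

  expect_identical(estimate_background(img2, labels, 0.2),
                   estimate_background(img2, labels, 0.2))

  # no cell-free disc -> classed error (field rejected upstream)
  all_cells <- matrix(1L, 40, 40)
  expect_error(estimate_background(matrix(1, 40, 40), all_cells, 0.2),
               class = "poldep_no_background")
})

test_that("per-field bookkeeping splits segmented into analysed + excluded", {
  for (s in c(41, 42)) {
    q <- quantify_field(test_field(seed = s))
    expect_equal(nrow(q), sum(q$analysed) + sum(!q$analysed))
    excl <- q[!q$analysed, ]
    expect_true(all(excl$qc_flags != ""))
  }
})

test_that("corrected End1 means track the ground-truth tip amplitudes", {
  cells <- list()
  for (s in 1:36) {
    fs <- test_field(seed = 500 + s)
    cells[[s]] <- join_truth(quantify_field(fs), fs$cells)
  }
  cells <- dplyr::bind_rows(cells)
  a <- cells[cells$analysed & !is.na(cells$true_end1), ]
  expect_gte(nrow(a), 200)
  expect_gte(cor(a$end1_mean, a$true_end1), 0.9)
})
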