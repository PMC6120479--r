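test_that("truth tables cover the design and encode presets correctly", {
  d <- study_design()
  expect_equal(nrow(d$combinations), 81L)   # 9 markers x 10 deletions, no self
  expect_equal(planned_cells(study_design(cells_per_arm = 100L)), 16200L)

  tt0 <- truth_table(d, "null")
  expect_equal(nrow(tt0), 81L)
  expect_true(all(tt0$mult_end1 == 1 & tt0$mult_end2 == 1 &
                  tt0$mult_cyto == 1 & tt0$bipolarity_shift == 0))

  tt <- truth_table(d, "literature")
  tip1_myo52 <- tt[tt$marker == "Tip1" & tt$deletion == "myo52", ]
  expect_gt(tip1_myo52$mult_end1, 1)   # more polar Tip1 without Myo52
  tea1_tea2 <- tt[tt$marker == "Tea1" & tt$deletion == "tea2", ]
  expect_lt(tea1_tea2$mult_end1, 1)    # Tea1 needs the Tea2 kinesin
  expect_lt(tea1_tea2$mult_end2, 1)

  expect_error(truth_table(d, "no_such_preset"), class = "poldep_name_error")
  expect_error(
    truth_table(d, tibble::tibble(marker = "Xyz9", deletion = "tea2",
                                  mult_end1 = 2)),
    class = "poldep_name_error"
  )
  expect_error(
    truth_table(d, tibble::tibble(marker = "Tea1", deletion = "tea2",
                                  mult_end1 = -1)),
    class = "poldep_design_error"
  )

  planted <- planted_entries(truth_table(d, "planted"))
  expect_equal(nrow(planted), 20L)
})

test_that("rendered cells have the constructed geometry and channels", {
  prof <- test_profile()
  set.seed(1)
  geom <- sample_cell_geometry(1, prof$field_um, cell_prior())
  # poles exactly `length` apart along the axis
  expect_equal(
    sqrt((geom$pole1_x - geom$pole2_x)^2 + (geom$pole1_y - geom$pole2_y)^2),
    geom$length
  )

  # cytosol-only cell: interior plateau is exactly uniform before noise
  canvas <- field_stack(prof)
  canvas <- render_cell(canvas, geom, "deletion", tip1_amp = 0, tip2_amp = 0,
                        cyto_amp = 1000)
  inside <- canvas$gfp_base[canvas$gfp_base > 0]
  plateau <- max(canvas$gfp_base)
  expect_gt(mean(abs(inside / plateau - 1) < 1e-9), 0.8)  # all but edge ramp
  expect_equal(plateau, 1000 * prof$pixel_size_xy^2)

  # control cells carry red puncta, deletion cells none
  ctrl <- render_cell(field_stack(prof), geom, "control", 100, 100, 10,
                      seed = 3)
  expect_gt(max(ctrl$red_base), 0)
  del <- render_cell(field_stack(prof), geom, "deletion", 100, 100, 10)
  expect_equal(max(del$red_base), 0)

  # genotype has no effect on the GFP forward model
  expect_equal(ctrl$gfp_base, del$gfp_base)

  # geometry that does not fit errors
  bad <- geom
  bad$x <- prof$field_um - 0.1
  expect_error(render_cell(field_stack(prof), bad, "control", 1, 1, 1),
               class = "poldep_placement_error")
})

test_that("asymmetric tips give asymmetric noise-free pole-disc sums", {
  prof <- test_profile()
  set.seed(5)
  geom <- sample_cell_geometry(1, prof$field_um, cell_prior())
  canvas <- render_cell(field_stack(prof), geom, "deletion",
                        tip1_amp = 2e5, tip2_amp = 1e5, cyto_amp = 1e4)
  fs <- finalize_field(canvas, noise_free(), seed = 1, keep_stack = TRUE)
  ps <- prof$pixel_size_xy
  disc_sum <- function(arr, cx, cy) {
    off <- poldep:::disc_offsets(round(1.5 / ps))
    tot <- 0
    for (k in seq_len(dim(arr)[3])) {
      tot <- tot + sum(arr[cbind(round(cy / ps) + off[, "dy"],
                                 round(cx / ps) + off[, "dx"], k)])
    }
    tot
  }
  s1 <- disc_sum(fs$gfp, geom$pole1_x, geom$pole1_y)
  s2 <- disc_sum(fs$gfp, geom$pole2_x, geom$pole2_y)
  expect_gt(s1, s2)
})

test_that("fields conserve photons and are reproducible from the seed", {
  fs1 <- test_field(seed = 3, noise = noise_free(), keep_stack = TRUE)
  # blur + z-distribution redistribute but do not create or destroy photons
  expect_equal(sum(fs1$gfp), sum(fs1$cells$true_gfp_photons),
               tolerance = 0.01)
  expect_equal(sum(fs1$red), sum(fs1$cells$true_red_photons),
               tolerance = 0.01)

  fs2 <- test_field(seed = 3, noise = noise_free(), keep_stack = TRUE)
  expect_identical(fs1$gfp, fs2$gfp)
  expect_identical(fs1$cells, fs2$cells)

  fs3 <- test_field(seed = 4, noise = noise_free())
  expect_false(identical(fs1$cells, fs3$cells))

  # default noise: same seed, same stack; red channel marks exactly the
  # control cells
  fa <- test_field(seed = 9)
  fb <- test_field(seed = 9)
  expect_identical(fa$gfp_proj, fb$gfp_proj)
  expect_equal(sum(fa$cells$n_spb > 0),
               sum(fa$cells$genotype == "control"))
})

test_that("cytosol effect multipliers propagate to measured intensities", {
  tr <- tibble::tibble(marker = "Tea1", deletion = "tea2",
                       mult_end1 = 1, mult_end2 = 1, mult_cyto = 0.5,
                       bipolarity_shift = 0)
  cells <- list()
  for (s in 1:12) {
    fs <- test_field(seed = 100 + s, truth = tr)
    cells[[s]] <- quantify_field(fs)
  }
  cells <- dplyr::bind_rows(cells)
  a <- cells[cells$analysed, ]
  del <- a$cyto_mean[a$genotype == "deletion"]
  ctl <- a$cyto_mean[a$genotype == "control"]
  expect_gte(length(del), 25L)
  ratio <- mean(del) / mean(ctl)
  se <- ratio * sqrt(var(del) / (mean(del)^2 * length(del)) +
                     var(ctl) / (mean(ctl)^2 * length(ctl)))
  expect_lt(abs(ratio - 0.5), 3 * se + 0.02)
})

test_that("expected End1 signal increases monotonically with the truth multiplier", {
  level_mean <- function(mult, seeds) {
    tr <- tibble::tibble(marker = "Tea1", deletion = "tea2",
                         mult_end1 = mult, mult_end2 = mult, mult_cyto = 1,
                         bipolarity_shift = 0)
    vals <- c()
    for (s in seeds) {
      q <- quantify_field(test_field(seed = 300 + s, truth = tr))
      vals <- c(vals, q$end1_mean[q$analysed & q$genotype == "deletion"])
    }
    mean(vals)
  }
  m <- vapply(c(0.6, 1.0, 1.6), level_mean, numeric(1), seeds = 1:4)
  expect_true(all(diff(m) > 0))
})

test_that("generate_study writes a reproducible TIFF study to disk", {
  d <- study_design(markers = c("Tea1", "Tea2"),
                    deletions = c("tip1", "mal3"),
                    cells_per_arm = 2L, fields_per_combination = 1L)
  out1 <- withr::local_tempdir()
  man <- generate_study(d, truth_table(d, "null"),
                        profile = test_profile(160L), out_dir = out1,
                        seed = 5)
  expect_equal(nrow(man), 4L)   # one stack per combination
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(man$annotation_path)))
  expect_true(file.exists(file.path(out1, "manifest.csv")))

  # byte-identical annotations on re-generation with the same seed
  out2 <- withr::local_tempdir()
  man2 <- generate_study(d, truth_table(d, "null"),
                         profile = test_profile(160L), out_dir = out2,
                         seed = 5)
  for (i in seq_len(nrow(man))) {
    expect_identical(readBin(man$annotation_path[i], "raw", 1e6),
                     readBin(man2$annotation_path[i], "raw", 1e6))
  }

  # disk round trip preserves the stack to float32 precision
  fs <- read_field_stack(man[1, ])
  expect_equal(dim(fs$gfp), c(160L, 160L, 31L))
  expect_equal(dim(fs$red), c(160L, 160L, 31L))
  expect_equal(nrow(fs$cells), 4L)
  q <- quantify_field(fs)
  expect_gt(nrow(q), 0L)
})
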