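# record-level fabrication helper: normalized-measurement tables without
# rendering, for statistics-only checks
fake_cells <- function(marker, deletion, field_id, genotype, end1,
                       end2 = end1 / 2, cyto = end1 / 5) {
  n <- length(end1)
  tibble::tibble(
    field_id = field_id, cell_id = seq_len(n), marker = marker,
    deletion = deletion, genotype = genotype,
    end1_mean = end1, end2_mean = end2, cyto_mean = cyto,
    end1_max = end1, end2_max = end2, cyto_max = cyto,
    bipolarity_index = pmin(pmax(end2 / end1, 0), 1),
    analysed = TRUE
  )
}

test_that("normalisation divides by the same-field control mean", {
  cells <- dplyr::bind_rows(
    fake_cells("Tea1", "tea2", "f1", rep(c("control", "deletion"), c(2, 1)),
               end1 = c(8, 12, 10)),
    fake_cells("Tea1", "tea2", "f2", rep(c("control", "deletion"), c(2, 1)),
               end1 = c(16, 24, 10))
  )
  norm <- normalize_to_controls(cells)
  del <- norm[norm$genotype == "deletion", ]
  # field control means are 10 and 20: a deletion cell equal to the control
  # mean normalises to 1; the f2 cell at 10 normalises to 0.5
  expect_equal(del$norm_end1, c(1.0, 0.5))
  # control normalized values average exactly 1 in every field
  ctl <- norm[norm$genotype == "control", ]
  means <- tapply(ctl$norm_end1, ctl$field_id, mean)
  expect_equal(as.numeric(means), c(1, 1))

  # a field without controls is dropped with a warning
  cells2 <- dplyr::bind_rows(
    cells, fake_cells("Tea1", "tea2", "f3", "deletion", end1 = 5)
  )
  expect_warning(norm2 <- normalize_to_controls(cells2), "f3")
  expect_false("f3" %in% norm2$field_id)

  # internal control removes multiplicative field effects entirely
  cells3 <- cells
  cells3[cells3$field_id == "f2", c("end1_mean", "end2_mean", "cyto_mean")] <-
    cells3[cells3$field_id == "f2", c("end1_mean", "end2_mean", "cyto_mean")] * 37
  expect_equal(normalize_to_controls(cells3)$norm_end1, norm$norm_end1)
})

test_that("combination summaries recover effects and calibrate under the null", {
  set.seed(101)
  # planted halving of end1 at n = 100/arm
  mk <- function(mult) {
    dplyr::bind_rows(lapply(1:4, function(f) {
      nc <- 25
      fake_cells("Tea1", "tea2", paste0("f", f),
                 rep(c("control", "deletion"), each = nc),
                 end1 = c(rlnorm(nc, log(100), 0.25),
                          rlnorm(nc, log(100 * mult), 0.25)))
    }))
  }
  s <- summarize_combination(normalize_to_controls(mk(0.5)), "end1")
  expect_lt(s$rel_diff, -0.4)
  expect_gt(s$rel_diff, -0.6)
  expect_lt(s$p_value, 0.001)
  expect_false(s$underpowered)
  expect_equal(s$n_del, 100L)

  # identical arm distributions: mostly non-significant over 10 replicates
  null_p <- replicate(10, {
    summarize_combination(normalize_to_controls(mk(1)), "end1")$p_value
  })
  expect_gte(sum(null_p > 0.05), 9L)

  # long-run type-I rate of the location test at alpha = 0.05
  hits <- replicate(400, {
    a <- rlnorm(100, 0, 0.25)
    b <- rlnorm(100, 0, 0.25)
    stats::t.test(log(a), log(b))$p.value < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.02)

  # a combination with no deletion cells is a missing arm
  ctrl_only <- normalize_to_controls(
    fake_cells("Tea1", "tea2", "f1", rep("control", 4), end1 = c(5, 6, 7, 8))
  )
  expect_error(summarize_combination(ctrl_only, "end1"),
               class = "poldep_missing_arm")
})

test_that("matrix building adjusts jointly, calls by sign and guards integrity", {
  set.seed(7)
  d <- study_design(cells_per_arm = 100L)
  entries <- tidyr::expand_grid(d$combinations,
                                compartment = c("end1", "end2", "cyto"))
  entries <- dplyr::mutate(entries,
    n_del = 100L, n_ctrl = 100L, n_dropped = 0L,
    rel_diff = 0.01, p_value = runif(dplyr::n(), 0.2, 1),
    underpowered = FALSE)
  # a handful of strong planted entries
  entries$rel_diff[1:5] <- c(0.5, -0.5, 0.4, -0.3, 0.25)
  entries$p_value[1:5] <- 1e-8

  mx <- build_matrix(entries, alpha = 0.05, min_effect = 0.10)
  e <- tidy(mx)
  expect_equal(nrow(e), 81L * 3L)
  expect_equal(e$call[1:5],
               c("increase", "decrease", "increase", "decrease", "increase"))
  expect_true(all(e$call[-(1:5)] == "ns"))
  # BH: q is p * m / rank for the best entries
  expect_true(all(e$q_value >= e$p_value))

  wide <- matrix_wide(mx, "end1")
  expect_equal(dim(wide), c(9L, 11L))   # marker column + 10 deletions
  expect_equal(sum(is.na(wide[, -1])), 9L)  # the self diagonal

  g <- glance(mx)
  expect_equal(g$n_increase + g$n_decrease + g$n_ns, g$n_entries)

  expect_error(build_matrix(dplyr::bind_rows(entries, entries[1, ])),
               class = "poldep_integrity_error")

  # every p-value at 1: nothing is ever called
  entries$p_value <- 1
  expect_true(all(tidy(build_matrix(entries))$call == "ns"))

  # underpowered arms are flagged, not dropped
  s <- summarize_combination(
    normalize_to_controls(fake_cells("Tea1", "tea2", "f1",
                                     rep(c("control", "deletion"), each = 20),
                                     end1 = rlnorm(40, log(50), 0.2))),
    "end1", min_cells = 100L)
  expect_true(s$underpowered)
})

test_that("bipolarity shift testing responds to shifts and not to identity", {
  set.seed(11)
  # identical perfectly monopolar arms: delta 0, never shifted
  mono <- fake_cells("For3", "tea1", "f1",
                     rep(c("control", "deletion"), each = 30),
                     end1 = rlnorm(60, log(80), 0.2), end2 = 0)
  nt <- neto_shift_test(mono)
  expect_equal(nt$delta_bipolarity, 0)
  expect_false(nt$shifted)

  # a genuine downward shift in the deletion arm is detected
  ctl_idx <- rbeta(120, 2, 2)
  del_idx <- rbeta(120, 0.6, 3.4)
  shifted_cells <- fake_cells("For3", "tea1", "f1",
                              rep(c("control", "deletion"), each = 120),
                              end1 = rep(100, 240),
                              end2 = 100 * c(ctl_idx, del_idx))
  nt2 <- neto_shift_test(shifted_cells)
  expect_true(nt2$shifted)
  expect_lt(nt2$delta_bipolarity, 0)

  # null calibration: rarely shifted after adjustment
  set.seed(12)
  calls <- replicate(50, {
    idx <- rbeta(120, 2, 2)
    cells <- fake_cells("For3", "tea1", "f1",
                        rep(c("control", "deletion"), each = 60),
                        end1 = rep(100, 120), end2 = 100 * idx)
    neto_shift_test(cells)$shifted
  })
  expect_gte(mean(!calls), 0.9)
})

test_that("a rendered null study normalises to unity within tolerance", {
  run <- study_scale_run()
  truth <- run$config$truth
  untouched <- truth[truth$mult_end1 == 1 & truth$mult_end2 == 1 &
                     truth$mult_cyto == 1 & truth$bipolarity_shift == 0, ]
  norm <- run$normalized
  del <- norm[norm$genotype == "deletion" &
              paste(norm$marker, norm$deletion) %in%
                paste(untouched$marker, untouched$deletion), ]
  expect_gte(nrow(del), 5000)
  expect_lt(abs(mean(del$norm_end1) - 1), 0.02)
  expect_lt(abs(mean(del$norm_cyto) - 1), 0.02)
})
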