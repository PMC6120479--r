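# shared simulation fixtures; the expensive study-scale runs are built once
# per test session and reused by several test files

.fixture_env <- new.env(parent = emptyenv())

# small but fully featured field profile for unit tests
test_profile <- function(field_px = 192L) {
  sim_profile(pixel_size_xy = 0.2, field_px = field_px, cells_per_field = 6L)
}

test_field <- function(seed = 1, marker = "Tea1", deletion = "tea2",
                       n_control = 3, n_deletion = 3, truth = NULL,
                       noise = noise_model(), keep_stack = FALSE,
                       profile = test_profile()) {
  render_field(marker, deletion, n_control, n_deletion, truth = truth,
               noise = noise, profile = profile,
               field_id = sprintf("%s_%s_s%d", marker, deletion, seed),
               seed = seed, keep_stack = keep_stack)
}

noise_free <- function() {
  noise_model(psf_sigma = 0.15, poisson_scale = 0, read_sigma = 0,
              background_offset = 0)
}

# study-scale run shared by the bookkeeping and recovery checks: the full
# marker x deletion grid with the planted-effect truth table at >= 100
# analysed cells per arm
study_scale_run <- function() {
  if (is.null(.fixture_env$paper_run)) {
    cfg <- run_config(
      design = study_design(cells_per_arm = 116L),
      truth = "planted", profile = "scaled",
      min_cells = 100L, seed = 42L
    )
    .fixture_env$paper_run <- run_study(cfg)
  }
  .fixture_env$paper_run
}

# small all-null study reused by the calibration checks
null_run <- function() {
  if (is.null(.fixture_env$null_run)) {
    cfg <- run_config(
      design = study_design(markers = c("Tea1", "Tip1"),
                            deletions = c("tea2", "myo52"),
                            cells_per_arm = 60L),
      truth = "null", profile = "scaled", min_cells = 30L, seed = 7L
    )
    .fixture_env$null_run <- run_study(cfg)
  }
  .fixture_env$null_run
}
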