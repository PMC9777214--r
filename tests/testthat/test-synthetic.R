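test_that("motion spec validation", {
  expect_s3_class(motion_profile_spec(), "motion_profile_spec")
  expect_error(motion_profile_spec(n_reps = 0), class = "armkin_invalid_input")
  expect_error(motion_profile_spec(marker_noise_sd = -1), class = "armkin_invalid_input")
  expect_error(motion_profile_spec(amplitude_deg = 1:3), class = "armkin_invalid_input")
})

test_that("profiles are deterministic under a fixed seed", {
  spec <- motion_profile_spec("abduction_adduction", n_reps = 3, sample_rate = 20,
                              amplitude_jitter_sd = 3, marker_noise_sd = 1, seed = 9)
  a <- simulate_motion(spec)
  b <- simulate_motion(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(a$markers, b$markers)
  spec2 <- motion_profile_spec("abduction_adduction", n_reps = 3, sample_rate = 20,
                               amplitude_jitter_sd = 3, marker_noise_sd = 1, seed = 10)
  expect_false(identical(simulate_motion(spec2)$markers, a$markers))
})

test_that("noiseless per-cycle ROM equals the configured amplitudes", {
  spec <- motion_profile_spec("abduction_adduction", n_reps = 5, sample_rate = 40)
  truth <- generate_joint_profiles(spec, geometry = default_geom)
  rom <- compute_rom(truth, mode = "per_cycle")
  expect_equal(rom$rom_deg, abs(spec$amplitude_deg), tolerance = 1e-9)
})

test_that("profiles violating the anatomical branch conditions refuse to generate", {
  bad <- motion_profile_spec("abduction_adduction",
                             offset_deg = c(5, 10, 0, 16, 20, 12))  # clavicle downward
  err <- tryCatch(generate_joint_profiles(bad, geometry = default_geom),
                  error = function(e) e)
  expect_s3_class(err, "armkin_anatomical_violation")
  expect_match(conditionMessage(err), "sample 1")
})

test_that("symmetric marker offsets keep the centroids on the joint centres", {
  g <- default_geom
  spec <- motion_profile_spec("external_internal", n_reps = 1, sample_rate = 15)
  truth <- generate_joint_profiles(spec, geometry = g)
  markers <- synthesize_markers(truth, g, spec)
  cen <- estimate_joint_centers(markers, normalize = FALSE)
  for (i in c(1, 8, 15)) {
    fk <- oracle_fk(as.numeric(truth[i, paste0("theta", 1:6)]), g)
    expect_lt(max(abs(c(cen$S_x[i], cen$S_y[i], cen$S_z[i]) - fk[[2]][1:3, 4])), 1e-9)
    expect_lt(max(abs(c(cen$EE_x[i], cen$EE_y[i], cen$EE_z[i]) - fk[[6]][1:3, 4])), 1e-9)
  }
  # the shoulder markers really are spread out, not stacked on the centre
  spread <- sqrt((markers$SH1_x - markers$SH2_x)^2 +
                 (markers$SH1_y - markers$SH2_y)^2 +
                 (markers$SH1_z - markers$SH2_z)^2)
  expect_true(all(spread > 10))
})

test_that("marker noise propagates to centres as the cluster-average SD", {
  g <- default_geom
  n <- 2000
  truth <- tibble::tibble(time = (seq_len(n) - 1) / 50, cycle = 1L)
  th0 <- deg2rad_test(c(5, -12, 0, 16, 20, 12))
  for (k in 1:6) truth[[paste0("theta", k)]] <- rep(th0[k], n)
  spec <- motion_profile_spec("abduction_adduction", marker_noise_sd = 1, seed = 3)
  markers <- synthesize_markers(truth, g, spec)
  fk <- oracle_fk(th0, g)
  # raw cluster centroids carry the 1/sqrt(k) cluster-size factor
  s_cent <- cbind((markers$SH1_x + markers$SH2_x + markers$SH3_x) / 3,
                  (markers$SH1_y + markers$SH2_y + markers$SH3_y) / 3,
                  (markers$SH1_z + markers$SH2_z + markers$SH3_z) / 3) -
    matrix(fk[[2]][1:3, 4], n, 3, byrow = TRUE)
  e_cent <- cbind((markers$EL1_x + markers$EL2_x) / 2,
                  (markers$EL1_y + markers$EL2_y) / 2,
                  (markers$EL1_z + markers$EL2_z) / 2) -
    matrix(fk[[5]][1:3, 4], n, 3, byrow = TRUE)
  # independent Monte-Carlo oracle for the centroid-of-k-markers noise SD
  set.seed(99)
  mc3 <- sd(rowMeans(matrix(rnorm(3 * 1e5), ncol = 3)))
  mc2 <- sd(rowMeans(matrix(rnorm(2 * 1e5), ncol = 2)))
  expect_lt(max(abs(colMeans(s_cent))), 0.1)
  expect_equal(mean(apply(s_cent, 2, sd)), mc3, tolerance = 0.05)
  expect_equal(mean(apply(e_cent, 2, sd)), mc2, tolerance = 0.05)
  expect_equal(mc3, 1 / sqrt(3), tolerance = 0.02)
  # base-referenced centres additionally carry the base marker's noise
  cen <- estimate_joint_centers(markers, normalize = FALSE)
  s_err <- cbind(cen$S_x, cen$S_y, cen$S_z) -
    matrix(fk[[2]][1:3, 4], n, 3, byrow = TRUE)
  mc3_base <- sd(rowMeans(matrix(rnorm(3 * 1e5), ncol = 3)) - rnorm(1e5))
  expect_equal(mean(apply(s_err, 2, sd)), mc3_base, tolerance = 0.05)
})

test_that("noiseless end-to-end recovery is exact to hundredths of a degree", {
  g <- default_geom
  for (mo in c("abduction_adduction", "external_internal")) {
    spec <- motion_profile_spec(mo, n_reps = 3, sample_rate = 40, seed = 4)
    sim <- simulate_motion(spec, g)
    res <- analyze_markers(sim$markers, g)
    truth_rom <- vapply(paste0("theta", 1:6),
                        function(k) diff(range(sim$truth[[k]])) * 180 / pi, numeric(1))
    expect_lt(max(abs(res$rom$rom_deg - truth_rom)), 0.01)
    expect_lt(abs(composite_rom(res$rom, mo) -
                  composite_rom(setNames(truth_rom, paste0("theta", 1:6)), mo)), 0.02)
  }
})

test_that("the default abduction spec recovers the configured composite ROM", {
  g <- default_geom
  spec <- motion_profile_spec("abduction_adduction", n_reps = 3, sample_rate = 40)
  sim <- simulate_motion(spec, g)
  res <- analyze_markers(sim$markers, g)
  expect_lt(abs(composite_rom(res$rom, "abduction_adduction") - (15 + 129)), 0.5)
})
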