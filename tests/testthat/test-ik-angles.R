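test_that("clavicle angles from the shoulder position", {
  g <- default_geom
  expect_equal(unname(theta_1_2(c(g$l2, 0, 0), g$l2)), c(0, 0))
  expect_equal(unname(theta_1_2(c(0, g$l2, 0), g$l2)), c(pi / 2, 0))
  set.seed(61)
  for (i in 1:50) {
    th12 <- c(runif(1, -pi, pi), runif(1, -pi / 2 + 0.01, pi / 2 - 0.01))
    S <- oracle_fk(c(th12, 0, 0, 0, 0), g)[[2]][1:3, 4]
    rec <- theta_1_2(S, g$l2)
    expect_lt(max(abs(rec - th12)), 1e-9)
  }
  expect_error(theta_1_2(c(0, 0, 1), g$l2), class = "armkin_singular")
})

test_that("shoulder roll extraction and its half-space ambiguity", {
  g <- default_geom
  set.seed(63)
  for (i in 1:40) {
    th <- as.numeric(sample_valid(1, g)[1, ])
    pose <- oracle_fk(th, g)[[6]]
    raw <- theta_3(pose, th[1], th[2], g)
    err_direct <- abs(wrap_angle(raw - th[3]))
    err_flip <- abs(wrap_angle(raw + pi - th[3]))
    if (sin(th[4]) > 0) {
      expect_lt(err_direct, 1e-9)
    } else {
      expect_lt(err_flip, 1e-9)
    }
  }
  # rest roll: theta3 = 0 recovered at zero
  th0 <- c(0.2, -0.3, 0, 0.8, 0.5, 0.4)
  pose0 <- oracle_fk(th0, g)[[6]]
  expect_lt(abs(theta_3(pose0, th0[1], th0[2], g)), 1e-9)
})

test_that("wrist pitch extraction and its half-space ambiguity", {
  g <- default_geom
  set.seed(67)
  got_pos <- got_neg <- 0L
  while (got_pos < 15L || got_neg < 15L) {
    th <- as.numeric(sample_valid(1, g)[1, ])
    if (sin(th[4]) <= 0) next   # keep the roll stage on its direct branch
    pose <- oracle_fk(th, g)[[6]]
    raw <- theta_4(pose, th[1], th[2], th[3], g)
    if (sin(th[5]) < 0) {
      expect_lt(abs(wrap_angle(raw - th[4])), 1e-9)
      got_neg <- got_neg + 1L
    } else {
      expect_lt(abs(wrap_angle(raw + pi - th[4])), 1e-9)
      got_pos <- got_pos + 1L
    }
  }
  # exact wrist singularity: sin(theta5) = 0
  th_s <- c(0.2, -0.3, 0.4, 0.9, 0, 0.5)
  pose_s <- oracle_fk(th_s, g)[[6]]
  expect_error(theta_4(pose_s, th_s[1], th_s[2], th_s[3], g),
               class = "armkin_singular")
})

test_that("axial and flexion extraction, with trig identities", {
  g <- default_geom
  set.seed(71)
  for (i in 1:40) {
    th <- as.numeric(sample_valid(1, g)[1, ])
    if (sin(th[4]) <= 0 || cos(th[6]) <= 0) next
    pose <- oracle_fk(th, g)[[6]]
    raw5 <- theta_5(pose, th[1], th[2], th[3], th[4], g)
    expect_lt(abs(wrap_angle(raw5 - th[5])), 1e-9)
    raw6 <- theta_6(pose, th[1], th[2], th[3], th[4], th[5], g)
    expect_lt(abs(wrap_angle(raw6 - th[6])), 1e-9)
  }
  # theta6 pair is an exact sine/cosine pair: S^2 + C^2 = 1
  th <- c(0.5, -0.7, 0.9, 1.3, 0.8, 0)
  T05 <- Reduce(`%*%`, lapply(1:5, function(j) oracle_dh(j, th[j], g)))
  pose <- T05 %*% oracle_dh(6, th[6], g)
  M <- solve(T05) %*% pose
  expect_equal(M[1, 1]^2 + M[2, 1]^2, 1, tolerance = 1e-9)
  expect_equal(M[1, 1], 1, tolerance = 1e-9)  # theta6 = 0 -> cos = 1
  expect_equal(M[2, 1], 0, tolerance = 1e-9)  # theta6 = 0 -> sin = 0
})

test_that("solve_all round-trips poses and honours every intermediate identity", {
  g <- default_geom
  set.seed(73)
  js <- sample_valid(150, g)
  for (i in seq_len(nrow(js))) {
    th <- as.numeric(js[i, ])
    pose <- oracle_fk(th, g)[[6]]
    sol <- solve_all(pose, g)
    expect_lt(sol$fk_residual, 1e-6)
    expect_lt(pose_distance(oracle_fk(as.numeric(sol$joints), g)[[6]], pose), 1e-6)
    expect_lt(sqrt(sum((sol$shoulder$shoulder - oracle_fk(th, g)[[2]][1:3, 4])^2)), 1e-6)
    expect_lt(max(abs(ik_identity_residuals(sol))), 1e-9)
  }
})

test_that("solve_all rejects unreachable and inconsistent input", {
  g <- default_geom
  far <- new_pose(diag(3), c(g$l2 + g$d5 + g$l6 + 50, 0, 0))
  expect_error(solve_all(far, g), class = "armkin_unreachable")
  th <- find_violating_joints(g)
  pose <- oracle_fk(th, g)[[6]]
  expect_error(solve_all(pose, g, mode = "strict"),
               class = "armkin_anatomical_violation")
  streamed <- solve_all(pose, g, mode = "streaming")
  expect_true(all(is.nan(streamed$joints)))
  expect_true(glance(streamed)$violation)
})

test_that("tidy and glance summarise a solution", {
  g <- default_geom
  th <- c(0.3, -0.4, 0.5, 1.1, 0.6, 0.3)
  sol <- solve_all(oracle_fk(th, g)[[6]], g)
  td <- tidy(sol)
  expect_equal(td$joint, paste0("theta", 1:6))
  expect_equal(td$angle_deg, td$angle_rad * 180 / pi)
  gl <- glance(sol)
  expect_lt(gl$fk_residual, 1e-6)
  expect_false(gl$violation)
})

test_that("joint-angle recovery is robust to 1 mm marker noise at mid-range", {
  g <- default_geom
  # mid-range abduction configuration, solved from noisy marker clusters
  th_mid <- deg2rad_test(c(17, -19.5, 19.5, 80.5, 48.5, 23.5))
  spec <- motion_profile_spec("abduction_adduction", n_reps = 1, sample_rate = 10,
                              marker_noise_sd = 1, seed = 5)
  errs <- matrix(NA_real_, 200, 3)
  set.seed(5)
  fk <- oracle_fk(th_mid, g)
  S <- fk[[2]][1:3, 4]; E <- fk[[5]][1:3, 4]; EE <- fk[[6]][1:3, 4]
  for (t in 1:200) {
    S_m <- S + colMeans(matrix(rnorm(9), 3, 3))      # 3-marker centroid noise
    E_m <- E + colMeans(matrix(rnorm(6), 2, 3))      # 2-marker midpoint noise
    EE_m <- EE + colMeans(matrix(rnorm(6), 2, 3))
    x <- (EE_m - E_m) / sqrt(sum((EE_m - E_m)^2))
    zr <- c(x[2] * (S_m - E_m)[3] - x[3] * (S_m - E_m)[2],
            x[3] * (S_m - E_m)[1] - x[1] * (S_m - E_m)[3],
            x[1] * (S_m - E_m)[2] - x[2] * (S_m - E_m)[1])
    z <- zr / sqrt(sum(zr^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
    pose <- rbind(cbind(x, y, z, EE_m), c(0, 0, 0, 1))
    sol <- solve_all(pose, g, previous = th_mid, mode = "streaming")
    errs[t, ] <- abs(wrap_angle(sol$joints[c(2, 4, 5)] - th_mid[c(2, 4, 5)])) * 180 / pi
  }
  med <- apply(errs, 2, median, na.rm = TRUE)
  expect_true(all(med < 2))
})
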