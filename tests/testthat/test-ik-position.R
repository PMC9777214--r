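test_that("elbow reconstruction from the end-effector pose", {
  P <- c(10, 0, 0)
  pose <- new_pose(diag(3), P)
  expect_equal(elbow_from_end_effector(pose, 2), c(8, 0, 0))
  expect_equal(elbow_from_end_effector(pose, 0), P)
  g <- default_geom
  set.seed(41)
  th <- as.numeric(sample_valid(1, g)[1, ])
  fk <- oracle_fk(th, g)
  E <- elbow_from_end_effector(fk[[6]], g$l6)
  expect_lt(max(abs(E - fk[[5]][1:3, 4])), 1e-9)
  bad <- diag(3); bad[1, 1] <- 1.1
  expect_error(elbow_from_end_effector(rbind(cbind(bad, P), c(0, 0, 0, 1)), 2),
               class = "armkin_invalid_pose")
})

test_that("cos_theta0 is the law of cosines in the O-S-E triangle", {
  g <- default_geom
  # collinear limit: fully extended
  ext <- cos_theta0(c(g$l2 + g$d5, 0, 0), g)
  expect_equal(ext$cos_theta0, 1, tolerance = 1e-12)
  # right-triangle identity |OE|^2 = l2^2 + d5^2 -> cos = d5/|OE|
  d_oe <- sqrt(g$l2^2 + g$d5^2)
  rt <- cos_theta0(c(0, d_oe, 0), g)
  expect_equal(rt$cos_theta0, g$d5 / d_oe, tolerance = 1e-12)
  # explicit triangle coordinates as an independent geometric oracle
  l2 <- 180; d5 <- 300; d_oe <- 250
  gg <- arm_geometry(l2, d5, l2 + d5)  # l6 irrelevant here
  Sx <- (d_oe^2 + l2^2 - d5^2) / (2 * d_oe)
  S <- c(Sx, sqrt(l2^2 - Sx^2), 0)
  E <- c(d_oe, 0, 0)
  cos_at_E <- sum((S - E) * (c(0, 0, 0) - E)) / (d5 * d_oe)
  res <- cos_theta0(E, gg)
  expect_equal(res$cos_theta0, cos_at_E, tolerance = 1e-12)
  # beta reduces to (|OE|^2 - d5^2 + l2^2) / 2
  expect_equal(res$beta, (d_oe^2 - d5^2 + l2^2) / 2, tolerance = 1e-9)
  # unreachable target
  expect_error(cos_theta0(c(2 * (l2 + d5), 0, 0), gg), class = "armkin_unreachable")
})

test_that("derived plane coefficients are consistent with the raw planes", {
  g <- default_geom
  set.seed(43)
  js <- sample_valid(25, g)
  for (i in seq_len(nrow(js))) {
    th <- as.numeric(js[i, ])
    fk <- oracle_fk(th, g)
    pose <- fk[[6]]
    E <- pose[1:3, 4] - g$l6 * pose[1:3, 1]
    ct <- cos_theta0(E, g)
    n <- pose[1:3, 3]
    alpha <- sum(n * E)
    pl <- shoulder_plane_coefficients(pose, E, alpha, ct$beta)
    S <- fk[[2]][1:3, 4]
    a <- pl$axes[1]; b <- pl$axes[2]; k <- pl$axes[3]
    # the FK-true shoulder satisfies both derived planes
    expect_lt(abs(pl$plane1[["p"]] * S[b] + pl$plane1[["q"]] * S[k] - pl$plane1[["r"]]),
              1e-9 * g$l2)
    expect_lt(abs(pl$plane2[["p"]] * S[a] + pl$plane2[["q"]] * S[k] - pl$plane2[["r"]]),
              1e-9 * g$l2)
    # linear-algebra oracle: given the true Zc, solving the two raw planes
    # as a 2x2 system in (Xc, Yc) agrees with the derived-plane
    # back-substitution
    A2 <- rbind(n[1:2], E[1:2])
    rhs <- c(alpha - n[3] * S[3], ct$beta - E[3] * S[3])
    xy <- solve(A2, rhs)
    expect_lt(max(abs(xy - S[1:2])), 1e-6)
  }
})

test_that("the shoulder quadratic recovers the FK shoulder on the valid branch", {
  g <- default_geom
  set.seed(47)
  js <- sample_valid(60, g)
  for (i in seq_len(nrow(js))) {
    th <- as.numeric(js[i, ])
    fk <- oracle_fk(th, g)
    pose <- fk[[6]]
    E <- elbow_from_end_effector(pose, g$l6)
    sol <- solve_shoulder_position(pose, E, g)
    S_true <- fk[[2]][1:3, 4]
    expect_lt(sqrt(sum((sol$shoulder - S_true)^2)), 1e-6)
    # sphere residual of the selected root
    expect_lt(abs(sum(sol$shoulder^2) - g$l2^2), 1e-6 * g$l2^2)
    # both roots, back-substituted, satisfy the sphere equation exactly
    for (cand in sol$candidates) {
      expect_lt(abs(sum(cand^2) - g$l2^2), 1e-6 * g$l2^2)
    }
    # orthogonality of E->S to the end-effector z-axis
    expect_lt(abs(sum((sol$shoulder - E) * pose[1:3, 3])), 1e-9 * g$l2)
  }
})

test_that("anatomical violations are errors in strict mode, flags in streaming", {
  g <- default_geom
  th <- find_violating_joints(g)
  pose <- oracle_fk(th, g)[[6]]
  E <- elbow_from_end_effector(pose, g$l6)
  expect_error(solve_shoulder_position(pose, E, g, mode = "strict"),
               class = "armkin_anatomical_violation")
  sol <- solve_shoulder_position(pose, E, g, mode = "streaming")
  expect_true(sol$diagnostics$violation)
  expect_true(all(is.nan(sol$shoulder)))
})

test_that("selected shoulder is continuous along a smooth pose trajectory", {
  g <- default_geom
  spec <- motion_profile_spec("abduction_adduction", n_reps = 2, sample_rate = 40)
  truth <- generate_joint_profiles(spec, geometry = g)
  prev <- NULL
  S_prev <- NULL
  max_step <- 0
  for (i in seq_len(nrow(truth))) {
    th <- as.numeric(truth[i, paste0("theta", 1:6)])
    pose <- oracle_fk(th, g)[[6]]
    E <- elbow_from_end_effector(pose, g$l6)
    sol <- solve_shoulder_position(pose, E, g, previous_shoulder = S_prev)
    if (!is.null(S_prev)) max_step <- max(max_step, sqrt(sum((sol$shoulder - S_prev)^2)))
    S_prev <- sol$shoulder
  }
  # bound: the true shoulder moves by < 6 mm between frames at this rate
  expect_lt(max_step, 6)
})

test_that("quadratic solution matches the brute-force sphere search", {
  g <- default_geom
  set.seed(53)
  js <- sample_valid(40, g)
  for (i in seq_len(nrow(js))) {
    th <- as.numeric(js[i, ])
    pose <- oracle_fk(th, g)[[6]]
    E <- elbow_from_end_effector(pose, g$l6)
    sol <- solve_shoulder_position(pose, E, g)
    pts <- oracle_shoulder_candidates(pose, E, g)
    expect_gte(length(pts), 1)
    d <- min(vapply(pts, function(p) sqrt(sum((p - sol$shoulder)^2)), numeric(1)))
    expect_lt(d, 1e-4)
  }
})
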