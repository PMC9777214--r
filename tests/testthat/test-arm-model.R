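test_that("link_length matches the distance formula", {
  expect_equal(link_length(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(link_length(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(11)
  for (i in 1:20) {
    a <- runif(3, -500, 500); b <- runif(3, -500, 500)
    expect_equal(link_length(a, b), sqrt(sum((a - b)^2)), tolerance = 1e-12)
    expect_identical(link_length(a, b), link_length(b, a))
  }
  expect_error(link_length(c(0, 0, NA), c(1, 1, 1)), class = "armkin_invalid_input")
})

test_that("the DH table has the chain's structure", {
  g <- arm_geometry(181, 307, 263)
  tab <- dh_table(g)
  expect_equal(tab$d_mm, c(0, 0, 0, 0, 307, 0))
  expect_equal(tab$l_mm, c(0, 181, 0, 0, 0, 263))
  expect_equal(tab$alpha_rad, c(-pi / 2, pi / 2, -pi / 2, pi / 2, -pi / 2, 0))
})

test_that("dh_transform reproduces the printed single-joint matrices", {
  g <- default_geom
  # zero-angle spot checks
  T6 <- dh_transform(6, 0, g)
  expect_equal(T6[1:3, 1:3], diag(3))
  expect_equal(T6[1:3, 4], c(g$l6, 0, 0))
  T1 <- dh_transform(1, 0, g)
  expect_equal(T1[1:3, 1:3], rbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)))
  expect_equal(T1[1:3, 4], c(0, 0, 0))
  T2 <- dh_transform(2, pi / 2, g)
  expect_equal(T2[1:3, 4], c(0, g$l2, 0))
  # element-wise symbolic agreement over random draws, all six joints
  set.seed(21)
  for (i in 1:200) {
    th <- runif(1, -pi, pi)
    for (j in 1:6) {
      expect_lt(max(abs(dh_transform(j, th, g) - oracle_dh(j, th, g))), 1e-12)
    }
  }
  expect_error(dh_transform(7, 0, g), class = "armkin_invalid_input")
})

test_that("forward kinematics places the joint centres correctly", {
  g <- default_geom
  fk0 <- forward_kinematics(g, rep(0, 6))
  pts <- fk_points(fk0)
  expect_equal(unlist(pts[pts$point == "S", c("x", "y", "z")], use.names = FALSE),
               c(g$l2, 0, 0))
  # forearm direction equals the end-effector x-axis
  E <- pose_position(fk0$T05); EE <- pose_position(fk0$T06)
  expect_equal(sqrt(sum((EE - E)^2)), g$l6, tolerance = 1e-12)
  expect_equal((EE - E) / g$l6, fk0$T06[1:3, 1], tolerance = 1e-12)

  set.seed(31)
  for (i in 1:100) {
    th <- runif(6, -pi, pi)
    fk <- forward_kinematics(g, th)
    S <- pose_position(fk$T02); E <- pose_position(fk$T05); EE <- pose_position(fk$T06)
    expect_lt(abs(sqrt(sum(S^2)) - g$l2), 1e-9)
    expect_lt(abs(sqrt(sum((E - S)^2)) - g$d5), 1e-9)
    expect_lt(abs(sqrt(sum((EE - E)^2)) - g$l6), 1e-9)
    # chain consistency and rotation orthonormality of cumulative products
    expect_lt(max(abs(fk$T06 - fk$T05 %*% dh_transform(6, th[6], g))), 1e-12)
    expect_lt(max(abs(fk$T05 - fk$T04 %*% dh_transform(5, th[5], g))), 1e-12)
    for (k in 1:6) {
      R <- pose_rotation(fk[[k]])
      expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
      expect_lt(abs(det(R) - 1), 1e-9)
    }
  }
})

test_that("geometry validation and config loading work", {
  expect_error(arm_geometry(-1, 300, 260), class = "armkin_invalid_input")
  expect_error(arm_geometry(180, 0, 260), class = "armkin_invalid_input")
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(l2_mm = 170, d5_mm = 290, l6_mm = 250), path,
                       auto_unbox = TRUE)
  g <- read_arm_geometry(path)
  expect_s3_class(g, "arm_geometry")
  expect_equal(g$d5, 290)
  yml <- tempfile(fileext = ".yaml")
  writeLines("l2_mm: 171\nd5_mm: 291\nl6_mm: 251", yml)
  expect_equal(read_arm_geometry(yml)$l6, 251)
  # reachability envelope: triangle inequality on |OE|
  expect_true(is_reachable_elbow(400, default_geom))
  expect_false(is_reachable_elbow(default_geom$l2 + default_geom$d5 + 1, default_geom))
  expect_false(is_reachable_elbow(default_geom$d5 - default_geom$l2 - 1, default_geom))
})
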