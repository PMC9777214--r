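# Independent oracles used across the suite.  These deliberately avoid the
# package's own kinematics helpers: the DH matrices are written out
# literally in their printed single-joint forms, and the shoulder search
# is a grid-plus-refinement optimisation on the sphere.

# the six single-joint transforms, written element by element
oracle_dh <- function(joint, th, g) {
  C <- cos(th); S <- sin(th)
  switch(joint,
    rbind(c(C, 0, -S, 0), c(S, 0, C, 0), c(0, -1, 0, 0), c(0, 0, 0, 1)),
    rbind(c(C, 0, S, g$l2 * C), c(S, 0, -C, g$l2 * S), c(0, 1, 0, 0), c(0, 0, 0, 1)),
    rbind(c(C, 0, -S, 0), c(S, 0, C, 0), c(0, -1, 0, 0), c(0, 0, 0, 1)),
    rbind(c(C, 0, S, 0), c(S, 0, -C, 0), c(0, 1, 0, 0), c(0, 0, 0, 1)),
    rbind(c(C, 0, -S, 0), c(S, 0, C, 0), c(0, -1, 0, g$d5), c(0, 0, 0, 1)),
    rbind(c(C, -S, 0, g$l6 * C), c(S, C, 0, g$l6 * S), c(0, 0, 1, 0), c(0, 0, 0, 1))
  )
}

oracle_fk <- function(th, g) {
  acc <- diag(4)
  out <- vector("list", 6)
  for (j in 1:6) {
    acc <- acc %*% oracle_dh(j, th[j], g)
    out[[j]] <- acc
  }
  out
}

# brute-force shoulder search: grid over the sphere, refined by BFGS with
# an analytic gradient, on the sum of squared residuals of the
# orthogonality plane, the law-of-cosines plane and (implicitly, via the
# parameterisation) the sphere
oracle_shoulder_candidates <- function(pose, elbow, g, n_az = 72, n_el = 36) {
  n <- pose[1:3, 3]
  alpha <- sum(n * elbow)
  d_oe <- sqrt(sum(elbow^2))
  c0 <- (g$d5^2 + d_oe^2 - g$l2^2) / (2 * g$d5 * d_oe)
  beta <- d_oe^2 - g$d5 * d_oe * c0
  e_sc <- sqrt(sum(elbow^2))   # keep both residuals on the mm scale
  sph <- function(p) g$l2 * c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
  f <- function(p) {
    S <- sph(p)
    (sum(n * S) - alpha)^2 + ((sum(elbow * S) - beta) / e_sc)^2
  }
  gr <- function(p) {
    S <- sph(p)
    dS_daz <- g$l2 * c(-cos(p[2]) * sin(p[1]), cos(p[2]) * cos(p[1]), 0)
    dS_del <- g$l2 * c(-sin(p[2]) * cos(p[1]), -sin(p[2]) * sin(p[1]), cos(p[2]))
    r1 <- sum(n * S) - alpha
    r2 <- (sum(elbow * S) - beta) / e_sc
    c(2 * r1 * sum(n * dS_daz) + 2 * r2 * sum(elbow * dS_daz) / e_sc,
      2 * r1 * sum(n * dS_del) + 2 * r2 * sum(elbow * dS_del) / e_sc)
  }
  az <- seq(-pi, pi, length.out = n_az)
  el <- seq(-pi / 2, pi / 2, length.out = n_el)
  grid <- expand.grid(az = az, el = el)
  vals <- apply(grid, 1, f)
  # refinement starts spread out in 3-D (az/el distance degenerates at the
  # poles), so both intersection points are found even when one dominates
  # the low-residual region of the grid
  ord <- order(vals)
  pt3 <- function(p) c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
  starts <- grid[ord[1], , drop = FALSE]
  start_pts <- list(pt3(as.numeric(starts[1, ])))
  for (i in ord[-1]) {
    p3 <- pt3(as.numeric(grid[i, ]))
    d <- min(vapply(start_pts, function(q) sqrt(sum((q - p3)^2)), numeric(1)))
    if (d > 0.25) {
      starts <- rbind(starts, grid[i, ])
      start_pts[[length(start_pts) + 1]] <- p3
    }
    if (nrow(starts) >= 10) break
  }
  pts <- list()
  for (i in seq_len(nrow(starts))) {
    op <- stats::optim(as.numeric(starts[i, ]), f, gr, method = "BFGS",
                       control = list(reltol = 1e-16, maxit = 500))
    op <- stats::optim(op$par, f, gr, method = "BFGS",
                       control = list(reltol = 1e-16, maxit = 500))
    if (op$value < 1e-8) {
      S <- sph(op$par)
      dup <- any(vapply(pts, function(p) sqrt(sum((p - S)^2)) < 1e-2, logical(1)))
      if (!dup) pts[[length(pts) + 1]] <- S
    }
  }
  pts
}

# joint vectors on the branch-valid domain, checked geometrically
sample_valid <- function(n, g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_reachable_joints(n, g)
}

# a joint vector whose pose puts both shoulder roots outside the
# anatomical sign rules (used to exercise violation handling)
find_violating_joints <- function(g, seed = 42) {
  set.seed(seed)
  repeat {
    th <- c(runif(1, -1.4, 1.4), runif(1, 0.3, 1.2), runif(1, -pi, pi),
            runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    fk <- oracle_fk(th, g)
    S <- fk[[2]][1:3, 4]
    if (S[3] >= 0) next       # want the true root below the horizontal
    R <- fk[[6]][1:3, 1:3]
    E <- fk[[5]][1:3, 4]
    u <- c(R[2, 3] * E[3] - R[3, 3] * E[2],
           R[3, 3] * E[1] - R[1, 3] * E[3],
           R[1, 3] * E[2] - R[2, 3] * E[1])
    if (sum(u^2) < 1) next
    S2 <- S - 2 * (sum(S * u) / sum(u^2)) * u
    if (S2[3] <= 0 || S2[1] <= 0) return(th)   # both roots inadmissible
  }
}

default_geom <- arm_geometry()

deg2rad_test <- function(x) x * pi / 180
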