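test_that("blakelet vanishes identically on the wall", {
  set.seed(1)
  for (i in 1:20) {
    x <- c(runif(2, -2, 2), 0)
    X <- c(runif(2, -1, 1), runif(1, 0.05, 1.5))
    B <- blakelet(x, X, 0.01)
    expect_lt(max(abs(B)), 1e-12)
  }
})

test_that("blakelet converges to the classical singular image solution", {
  set.seed(2)
  for (i in 1:10) {
    x <- c(runif(2, -1, 1), runif(1, 0.3, 1.5))
    X <- c(runif(2, -1, 1), runif(1, 0.3, 1))
    if (sqrt(sum((x - X)^2)) < 0.3) next
    ref <- blake_singular(x, X)
    d3 <- max(abs(blakelet(x, X, 1e-3) - ref))
    d4 <- max(abs(blakelet(x, X, 1e-4) - ref))
    expect_lt(d3, 1e-4)
    expect_lt(d4, 1e-5)        # and the error shrinks with epsilon
    expect_lt(d4, d3)
  }
})

test_that("blakelet velocity fields are incompressible (finite differences)", {
  X <- c(0.2, -0.3, 0.6)
  g <- c(0.7, -0.4, 0.5)
  eps <- 0.05
  h <- 1e-4
  set.seed(3)
  for (i in 1:10) {
    x <- c(runif(2, -1, 1), runif(1, 0.2, 1.2))
    div <- 0
    for (j in 1:3) {
      ej <- numeric(3); ej[j] <- h
      up <- blakelet(x + ej, X, eps) %*% g
      dn <- blakelet(x - ej, X, eps) %*% g
      div <- div + (up[j] - dn[j]) / (2 * h)
    }
    expect_lt(abs(div), 1e-5)
  }
})

test_that("blakelet rejects sources on or below the wall", {
  expect_error(blakelet(c(0, 0, 1), c(0, 0, 0), 0.01), "above the wall")
  expect_error(blakelet(c(0, 0, 1), c(0, 0, -0.2), 0.01), "above the wall")
  expect_error(blakelet(c(0, 0, 1), c(0, 0, 0.5), -1), "positive")
})

test_that("rod meshes respect the stated geometry", {
  geom <- rod_geometry()
  # vertical rod: nodes on the x3 axis, extremes near 0 and L
  m0 <- build_rod_mesh(geom, orientation_angles(0, 0), 8, 32)
  expect_lt(max(abs(m0$quad_nodes[, 1:2])), 1e-12)
  expect_lt(min(m0$quad_nodes[, 3]), 0.05)
  expect_gt(max(m0$quad_nodes[, 3]), 0.95)
  # wall-grazing rod along e1: heights clamp at the rod radius
  m90 <- build_rod_mesh(geom, orientation_angles(90, 0), 8, 32)
  expect_equal(max(m90$quad_nodes[, 3]), geom$radius)
  expect_gt(max(m90$quad_nodes[, 1]), 0.9)
  # surface mesh at 90 degrees: max height about one radius above wall
  ms <- build_rod_mesh(geom, orientation_angles(90, 0), 12, 48,
                       type = "surface")
  expect_lt(max(ms$quad_nodes[, 3]), 2.5 * geom$radius)
  expect_error(orientation_angles(95, 0), "90")
})

test_that("nearest-neighbour map stays total under quadrature refinement", {
  geom <- rod_geometry()
  ang <- orientation_angles(50, 120)
  for (nq in c(16, 32, 64)) {
    m <- build_rod_mesh(geom, ang, 16, nq)
    expect_length(m$nn_map, nrow(m$quad_nodes))
    expect_true(all(m$nn_map %in% seq_len(nrow(m$force_nodes))))
    # pigeonhole: every force node owns at least one quadrature node
    expect_true(all(tabulate(m$nn_map, nrow(m$force_nodes)) >= 1))
  }
})

test_that("resistance solves are homogeneous and linear", {
  mesh <- build_rod_mesh(rod_geometry(), orientation_angles(40, 70), 12, 48)
  z <- solve_resistance(mesh, c(0, 0, 0))
  expect_equal(max(abs(z$torque)), 0)
  expect_equal(max(abs(z$force_density)), 0)
  ang <- mesh$orientation
  one <- solve_resistance(mesh, ang$e_theta)
  two <- solve_resistance(mesh, 2 * ang$e_theta)
  expect_equal(two$torque, 2 * one$torque, tolerance = 1e-12)
})

test_that("nearest-neighbour and dense Nystrom torques agree on small meshes", {
  geom <- rod_geometry()
  ang <- orientation_angles(55, 0)
  # both discretizations must resolve the regularization length; the dense
  # single-grid Nystrom needs node spacing ~ epsilon to be a valid oracle
  nn <- build_rod_mesh(geom, ang, 24, 96)
  dense <- build_rod_mesh(geom, ang, 96, 96)   # n_quad = n_force: plain Nystrom
  for (om in list(ang$e_theta, ang$e_phi)) {
    t_nn <- solve_resistance(nn, om)$torque
    t_d <- solve_resistance(dense, om)$torque
    expect_lt(sqrt(sum((t_nn - t_d)^2)) / sqrt(sum(t_nn^2)), 0.03)
  }
})

test_that("torques are grid-converged at the default discretization", {
  geom <- rod_geometry()
  ang <- orientation_angles(45, 0)
  t1 <- solve_resistance(build_rod_mesh(geom, ang, 24, 96), ang$e_theta)$torque
  t2 <- solve_resistance(build_rod_mesh(geom, ang, 48, 192), ang$e_theta)$torque
  expect_lt(sqrt(sum((t1 - t2)^2)) / sqrt(sum(t2^2)), 0.01)
})

test_that("mobility solve is quiescent without forcing and dual to resistance", {
  geom <- rod_geometry()
  mesh <- build_rod_mesh(geom, orientation_angles(60, 20), 12, 48)
  still <- solve_mobility(mesh, shear = 0)
  expect_lt(max(abs(still$angular_velocity)), 1e-12)
  # duality: R2 w = projected torque of the held rod under shear
  ang <- mesh$orientation
  mob <- solve_mobility(mesh)
  A <- phageflow:::.assemble(mesh, geom$epsilon)
  M <- nrow(mesh$force_nodes)
  fm <- matrix(solve(A, -c(mesh$force_nodes[, 3], numeric(2 * M))), M, 3)
  Theld <- colSums(t(vapply(seq_len(M), function(m)
    phageflow:::.cross(mesh$force_nodes[m, ], fm[m, ]) * mesh$areas[m],
    numeric(3))))
  basis <- cbind(ang$e_theta, ang$e_phi)
  R2 <- t(basis) %*% cbind(solve_resistance(mesh, ang$e_theta)$torque,
                           solve_resistance(mesh, ang$e_phi)$torque)
  w <- as.numeric(t(basis) %*% mob$angular_velocity)
  expect_lt(max(abs(R2 %*% w + t(basis) %*% Theld)), 1e-10)
})

test_that("advection components have the mirror symmetry of shear flow", {
  geom <- rod_geometry()
  for (th in c(30, 75)) for (ph in c(25, 110)) {
    a1 <- solve_mobility(build_rod_mesh(geom, orientation_angles(th, ph),
                                        12, 48))$alpha
    a2 <- solve_mobility(build_rod_mesh(geom, orientation_angles(th, -ph),
                                        12, 48))$alpha
    expect_equal(a1[["theta"]], a2[["theta"]], tolerance = 1e-10)
    expect_equal(a1[["phi"]], -a2[["phi"]], tolerance = 1e-10)
  }
})

test_that("coefficient table splines are periodic and the rotational
           resistance is symmetric positive definite", {
  co <- pf_coeffs()
  a0 <- coef_alpha(co, c(15, 50, 85), 0)
  a360 <- coef_alpha(co, c(15, 50, 85), 360)
  expect_equal(a0$alpha_theta, a360$alpha_theta, tolerance = 1e-12)
  expect_equal(a0$alpha_phi, a360$alpha_phi, tolerance = 1e-12)
  # splines reproduce tabulated values at the nodes
  at <- coef_alpha(co, co$theta_grid, co$phi_grid)
  expect_equal(at$alpha_theta, co$alpha_theta, tolerance = 1e-9)
  dd <- coef_D(co, co$theta_grid)
  expect_equal(dd$Dtt, co$Dtt, tolerance = 1e-12)
  # diffusion matrix positive definite everywhere tabulated
  expect_true(all(co$Dtt > 0))
  expect_true(all(co$Dpp > 0))
  expect_true(all(co$Dtt * co$Dpp - co$Dtp^2 > 0))
})

test_that("the rotational resistance does not depend on phi", {
  geom <- rod_geometry()
  r2_at <- function(ph) {
    ang <- orientation_angles(50, ph)
    mesh <- build_rod_mesh(geom, ang, 12, 48)
    basis <- cbind(ang$e_theta, ang$e_phi)
    t(basis) %*% cbind(solve_resistance(mesh, ang$e_theta)$torque,
                       solve_resistance(mesh, ang$e_phi)$torque)
  }
  expect_equal(r2_at(0), r2_at(140), tolerance = 1e-8)
})
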