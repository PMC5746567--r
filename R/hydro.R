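#' Rod geometry
#'
#' Dimensionless geometry of the tethered rod.  Lengths are scaled so the
#' rod has unit length; the default radius ratio reflects a 7 nm wide,
#' roughly 900 nm long M13 filament, and the regularization length epsilon
#' is 1\% of the rod length.
#'
#' @param length rod length (scale; default 1).
#' @param radius_ratio rod radius / rod length.
#' @param epsilon regularization length of the stokeslet blobs.
#' @return a `rod_geometry` list.
#' @export
rod_geometry <- function(length = 1, radius_ratio = 7 / 900,
                         epsilon = 0.01 * length) {
  stopifnot(length > 0, epsilon > 0, epsilon < length, radius_ratio > 0)
  structure(list(length = length, radius = radius_ratio * length,
                 epsilon = epsilon, tether = c(0, 0, 0)),
            class = "rod_geometry")
}

#' Orientation angles of the rod
#'
#' Spherical polar orientation: `theta` is the polar angle from the wall
#' normal (0 = vertical rod, 90 = rod in the wall plane) and `phi` the
#' azimuth from the flow direction.
#'
#' @param theta polar angle, degrees in `[0, 90]`.
#' @param phi azimuthal angle, degrees in `[0, 360)`.
#' @return an `orientation_angles` list with the direction vector `d` and
#'   the local basis vectors `e_theta`, `e_phi`.
#' @export
orientation_angles <- function(theta, phi) {
  if (theta < 0 || theta > 90) stop("theta must lie in [0, 90] degrees")
  phi <- phi %% 360
  th <- theta * pi / 180; ph <- phi * pi / 180
  structure(list(
    theta = theta, phi = phi,
    d = c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
    e_theta = c(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th)),
    e_phi = c(-sin(ph), cos(ph), 0)), class = "orientation_angles")
}

#' Regularized wall Green's function (blakelet)
#'
#' The regularized image-system Green's tensor for a stokeslet blob above
#' a plane no-slip wall: the velocity at `x` due to a smoothed point force
#' at `X` (with `X[3] > 0`) is `B %*% g / (8 * pi * mu)`.  The tensor
#' vanishes identically on the wall, is exactly divergence-free, stays
#' finite as `x -> X`, and converges to the classical singular image
#' solution as `epsilon -> 0`.
#'
#' @param x field point (length 3, `x[3] >= 0`).
#' @param X source point (length 3, `X[3] > 0`).
#' @param epsilon regularization length, `> 0`.
#' @return 3x3 numeric tensor `B[j, k]`.
#' @export
blakelet <- function(x, X, epsilon) {
  if (X[3] <= 0) stop("source point must lie strictly above the wall")
  if (epsilon <= 0) stop("epsilon must be positive")
  cmp <- .blakelet_components(x[1] - X[1], x[2] - X[2], x[3], X[3], epsilon)
  matrix(unlist(cmp), 3, 3)  # components are scalars here; fills by (j,k)
}

# vectorized kernel over all field/source pairs: returns list b[[j]][[k]]
# of M x Q matrices
.blakelet_pairs <- function(field, src, epsilon) {
  M <- nrow(field); Q <- nrow(src)
  a1 <- outer(field[, 1], src[, 1], "-")
  a2 <- outer(field[, 2], src[, 2], "-")
  z  <- matrix(field[, 3], M, Q)
  h  <- matrix(src[, 3], M, Q, byrow = TRUE)
  .blakelet_components(a1, a2, z, h, epsilon)
}

#' Discretize the rod into force and quadrature nodes
#'
#' Nearest-neighbour discretization of the regularized stokeslet boundary
#' integral: a coarse set of force stations and a finer set of quadrature
#' nodes, each quadrature node mapped to its nearest force station.  The
#' default `"line"` type places nodes on the rod centreline (the blob
#' radius plays the role of the physical radius, which it matches in
#' scale); `"surface"` samples rings on the slender cylinder surface.
#'
#' @param geom a [rod_geometry()].
#' @param angles an [orientation_angles()]; `theta > 90` is a domain error.
#' @param n_force number of force stations (>= 2).
#' @param n_quad number of quadrature stations (>= n_force).
#' @param type `"line"` or `"surface"`.
#' @param n_ring surface ring points per station (surface type only).
#' @param clamp minimum node height above the wall; defaults to the rod
#'   radius so wall-touching configurations stay admissible.
#' @return a `rod_mesh` list: `force_nodes` (N x 3), `quad_nodes` (Q x 3),
#'   `weights` (per quadrature node), `nn_map`, `areas` (per force node),
#'   `orientation`, `geom`.
#' @export
build_rod_mesh <- function(geom, angles, n_force = 24L, n_quad = 96L,
                           type = c("line", "surface"), n_ring = 6L,
                           clamp = NULL) {
  type <- match.arg(type)
  stopifnot(n_quad >= n_force, n_force >= 2)
  if (is.null(clamp)) clamp <- geom$radius
  L <- geom$length; d <- angles$d
  stations <- function(n) (seq_len(n) - 0.5) * L / n
  if (type == "line") {
    Xf <- outer(stations(n_force), d)
    Xq <- outer(stations(n_quad), d)
    w <- rep(L / n_quad, n_quad)
  } else {
    # orthonormal frame transverse to the rod axis
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    n1 <- ref - sum(ref * d) * d; n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(d[2] * n1[3] - d[3] * n1[2],
            d[3] * n1[1] - d[1] * n1[3],
            d[1] * n1[2] - d[2] * n1[1])
    ring <- function(svec, nr, offset = 0) {
      beta <- 2 * pi * (seq_len(nr) - 1) / nr + offset
      circ <- geom$radius * (outer(cos(beta), n1) + outer(sin(beta), n2))
      do.call(rbind, lapply(svec, function(s)
        sweep(circ, 2, s * d, "+")))
    }
    ns_f <- max(2L, as.integer(round(n_force / n_ring)))
    ns_q <- max(ns_f, as.integer(round(n_quad / (2L * n_ring))))
    Xf <- ring(stations(ns_f), n_ring)
    Xq <- ring(stations(ns_q), 2L * n_ring, offset = pi / (2L * n_ring))
    w <- rep(2 * pi * geom$radius * L / nrow(Xq), nrow(Xq))
  }
  Xf[, 3] <- pmax(Xf[, 3], clamp)
  Xq[, 3] <- pmax(Xq[, 3], clamp)
  d2 <- function(P, Q) {
    outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  }
  nn <- max.col(-d2(Xq, Xf), ties.method = "first")
  areas <- vapply(seq_len(nrow(Xf)),
                  function(n) sum(w[nn == n]), numeric(1))
  structure(list(force_nodes = Xf, quad_nodes = Xq, weights = w,
                 nn_map = nn, areas = areas, orientation = angles,
                 geom = geom, type = type), class = "rod_mesh")
}

# assemble the nearest-neighbour collocation matrix: u_j(X_m) =
# sum_{n,k} A[(j,m),(k,n)] f_k(X_n), A = (1/8pi) sum_{q in nn^-1(n)} w_q B
.assemble <- function(mesh, epsilon, field = mesh$force_nodes) {
  M <- nrow(field); N <- nrow(mesh$force_nodes); Q <- nrow(mesh$quad_nodes)
  b <- .blakelet_pairs(field, mesh$quad_nodes, epsilon)
  # quadrature-to-force aggregation (Q x N indicator weighted matrix)
  W <- matrix(0, Q, N)
  W[cbind(seq_len(Q), mesh$nn_map)] <- mesh$weights
  A <- matrix(0, 3 * M, 3 * N)
  for (j in 1:3) for (k in 1:3)
    A[(j - 1) * M + seq_len(M), (k - 1) * N + seq_len(N)] <-
      (b[[(k - 1) * 3 + j]] %*% W) / (8 * pi)
  A
}
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Solve the rotational resistance problem
#'
#' Prescribes a rigid rotation `omega` about the tether with zero far-field
#' flow, solves the discretized boundary-integral equation for the force
#' density, and integrates the torque the rod exerts on the fluid.
#'
#' @param mesh a [build_rod_mesh()] result.
#' @param omega angular velocity vector (length 3).
#' @param epsilon regularization length; defaults to the mesh geometry's.
#' @return a `stokes_solution` list: `force_density` (N x 3), `omega`,
#'   `torque`, `farfield = "quiescent"`.
#' @export
solve_resistance <- function(mesh, omega, epsilon = mesh$geom$epsilon) {
  Xf <- mesh$force_nodes
  M <- nrow(Xf)
  A <- .assemble(mesh, epsilon)
  u <- t(vapply(seq_len(M), function(m) .cross(omega, Xf[m, ]),
                numeric(3)))
  f <- tryCatch(solve(A, as.numeric(u)),
                error = function(e)
                  stop("resistance system is singular or ill-conditioned: ",
                       conditionMessage(e)))
  fmat <- matrix(f, M, 3)
  torque <- colSums(t(vapply(seq_len(M), function(m)
    .cross(Xf[m, ], fmat[m, ]) * mesh$areas[m], numeric(3))))
  structure(list(force_density = fmat, angular_velocity = omega,
                 torque = torque, farfield = "quiescent"),
            class = "stokes_solution")
}

#' Solve the rotational mobility problem
#'
#' Prescribes zero hydrodynamic torque about the tether and a far-field
#' flow (default: unit shear `u = x3 e1`), and solves for the force
#' density and the free angular velocity of the pivoting rod.
#'
#' @param mesh a [build_rod_mesh()] result.
#' @param epsilon regularization length.
#' @param shear far-field shear rate multiplying `x3 e1`.
#' @return a `stokes_solution` list with `angular_velocity` the solved
#'   rotation rate and `alpha` its `(theta, phi)` components
#'   `(dtheta/dt, sin(theta) dphi/dt)`.
#' @export
solve_mobility <- function(mesh, epsilon = mesh$geom$epsilon, shear = 1) {
  Xf <- mesh$force_nodes
  M <- nrow(Xf)
  A <- .assemble(mesh, epsilon)
  ang <- mesh$orientation
  # The angular velocity is expanded in the transverse basis (e_theta,
  # e_phi): spin about the rod axis neither moves the director nor (for a
  # slender line distribution) generates resistance, so it is excluded.
  basis <- cbind(ang$e_theta, ang$e_phi)
  C <- matrix(0, 3 * M, 2)   # maps (w_theta, w_phi) -> omega x X_m
  for (b in 1:2) {
    om <- basis[, b]
    cx <- t(vapply(seq_len(M), function(m) .cross(om, Xf[m, ]), numeric(3)))
    C[, b] <- as.numeric(cx)
  }
  Tq <- matrix(0, 3, 3 * M)  # maps stacked f -> total torque
  for (m in seq_len(M)) {
    X <- Xf[m, ] * mesh$areas[m]
    Tq[1, M + m]     <- -X[3]; Tq[1, 2 * M + m] <-  X[2]
    Tq[2, m]         <-  X[3]; Tq[2, 2 * M + m] <- -X[1]
    Tq[3, m]         <- -X[2]; Tq[3, M + m]     <-  X[1]
  }
  Tq2 <- t(basis) %*% Tq     # torque balance projected on the basis
  uinf <- c(shear * Xf[, 3], numeric(M), numeric(M))
  lhs <- rbind(cbind(A, -C), cbind(Tq2, matrix(0, 2, 2)))
  rhs <- c(-uinf, numeric(2))
  sol <- tryCatch(solve(lhs, rhs),
                  error = function(e)
                    stop("mobility system is singular or ill-conditioned: ",
                         conditionMessage(e)))
  fmat <- matrix(sol[seq_len(3 * M)], M, 3)
  omega <- as.numeric(basis %*% sol[3 * M + 1:2])
  ang <- mesh$orientation
  dd <- .cross(omega, ang$d)
  structure(list(force_density = fmat, angular_velocity = omega,
                 torque = c(0, 0, 0),
                 alpha = c(theta = sum(ang$e_theta * dd),
                           phi = sum(ang$e_phi * dd)),
                 farfield = sprintf("shear %g * x3 e1", shear)),
            class = "stokes_solution")
}

#' Tabulate the rotational advection and diffusion coefficients
#'
#' Sweeps the orientation grid, solving a mobility problem (unit shear,
#' zero torque) per `(theta, phi)` node for the advection vector
#' `alpha = (dtheta/dt, sin(theta) dphi/dt)`, and a pair of resistance
#' problems (`omega = e_theta`, `omega = e_phi`; by axisymmetry
#' `phi = 0` suffices) per `theta` node for the 2x2 rotational resistance
#' matrix, inverted to the dimensionless diffusion matrix.  At the wall
#' rim (`theta = 90`) node heights are clamped to `delta` times the rod
#' length so the diffusion coefficients stay regular.
#'
#' Tabulated values are interpolated by cubic splines, periodic in phi.
#'
#' @param geom a [rod_geometry()].
#' @param theta_grid polar tabulation nodes, degrees (must span 0..90).
#' @param phi_grid azimuthal tabulation nodes, degrees (uniform, from 0,
#'   exclusive of 360).
#' @param n_force,n_quad,type,n_ring mesh parameters
#'   (see [build_rod_mesh()]).
#' @param delta wall regularization constant (fraction of rod length).
#' @return a `rotational_coeffs` list: grids, `alpha_theta` and
#'   `alpha_phi` matrices (theta x phi), `Dtt`, `Dpp`, `Dtp` vectors,
#'   `delta`, `epsilon`, and mesh metadata.
#' @export
compute_coefficient_table <- function(geom = rod_geometry(),
                                      theta_grid = seq(0, 90, by = 10),
                                      phi_grid = seq(0, 345, by = 15),
                                      n_force = 24L, n_quad = 96L,
                                      type = "line", n_ring = 6L,
                                      delta = 0.01) {
  nt <- length(theta_grid); np <- length(phi_grid)
  alpha_theta <- matrix(NA_real_, nt, np)
  alpha_phi <- matrix(NA_real_, nt, np)
  Dtt <- Dpp <- Dtp <- numeric(nt)
  for (it in seq_len(nt)) {
    th <- theta_grid[it]
    clamp <- max(geom$radius, if (th >= 90 - 1e-9) delta * geom$length else 0)
    for (ip in seq_len(np)) {
      ang <- orientation_angles(th, phi_grid[ip])
      mesh <- build_rod_mesh(geom, ang, n_force, n_quad, type, n_ring,
                             clamp = clamp)
      mob <- solve_mobility(mesh)
      alpha_theta[it, ip] <- mob$alpha["theta"]
      alpha_phi[it, ip] <- mob$alpha["phi"]
    }
    ang0 <- orientation_angles(th, 0)
    mesh0 <- build_rod_mesh(geom, ang0, n_force, n_quad, type, n_ring,
                            clamp = clamp)
    Rt <- solve_resistance(mesh0, ang0$e_theta)
    Rp <- solve_resistance(mesh0, ang0$e_phi)
    R2 <- matrix(c(sum(ang0$e_theta * Rt$torque),
                   sum(ang0$e_phi   * Rt$torque),
                   sum(ang0$e_theta * Rp$torque),
                   sum(ang0$e_phi   * Rp$torque)), 2, 2)
    R2 <- (R2 + t(R2)) / 2
    ev <- eigen(R2, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      stop(sprintf("resistance matrix not positive definite at theta = %g",
                   th))
    Dm <- solve(R2)
    Dtt[it] <- Dm[1, 1]; Dpp[it] <- Dm[2, 2]; Dtp[it] <- Dm[1, 2]
  }
  structure(list(theta_grid = theta_grid, phi_grid = phi_grid,
                 alpha_theta = alpha_theta, alpha_phi = alpha_phi,
                 Dtt = Dtt, Dpp = Dpp, Dtp = Dtp,
                 delta = delta, epsilon = geom$epsilon, geom = geom,
                 mesh = list(n_force = n_force, n_quad = n_quad,
                             type = type, n_ring = n_ring)),
            class = "rotational_coeffs")
}

#' Evaluate the advection splines
#'
#' Cubic-spline interpolation of the tabulated advection components:
#' periodic end conditions in phi, natural in theta.
#'
#' @param coeffs a [compute_coefficient_table()] result.
#' @param theta,phi query angles in degrees (vectors).
#' @return list of matrices `alpha_theta`, `alpha_phi` of dimension
#'   `length(theta) x length(phi)`.
#' @export
coef_alpha <- function(coeffs, theta, phi) {
  phi <- phi %% 360
  tg <- coeffs$theta_grid; pg <- c(coeffs$phi_grid, 360)
  eval_one <- function(tab) {
    # periodic spline along phi at each tabulated theta
    at_phi <- matrix(0, length(tg), length(phi))
    for (it in seq_along(tg)) {
      y <- c(tab[it, ], tab[it, 1])
      at_phi[it, ] <- splinefun(pg, y, method = "periodic")(phi)
    }
    # then a natural spline across theta per query phi
    out <- matrix(NA_real_, length(theta), length(phi))
    for (ip in seq_along(phi))
      out[, ip] <- splinefun(tg, at_phi[, ip], method = "natural")(theta)
    out
  }
  list(alpha_theta = eval_one(coeffs$alpha_theta),
       alpha_phi = eval_one(coeffs$alpha_phi))
}

#' Evaluate the diffusion splines
#'
#' @param coeffs a [compute_coefficient_table()] result.
#' @param theta query angles in degrees.
#' @return list of vectors `Dtt`, `Dpp`, `Dtp`.
#' @export
coef_D <- function(coeffs, theta) {
  tg <- coeffs$theta_grid
  list(Dtt = splinefun(tg, coeffs$Dtt, method = "natural")(theta),
       Dpp = splinefun(tg, coeffs$Dpp, method = "natural")(theta),
       Dtp = splinefun(tg, coeffs$Dtp, method = "natural")(theta))
}
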