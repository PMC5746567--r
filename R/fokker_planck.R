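#' Hemisphere grid for the orientation density
#'
#' Uniform node-centred grid on the unit hemisphere: polar angle theta from
#' 0 (vertical rod) to 90 degrees (rod in the wall plane), azimuth phi
#' periodic on `[0, 360)` with 0 the flow direction.  The pole row is a
#' single degree of freedom (the density is single-valued there); the rim
#' row at 90 degrees carries a no-flux closure (the rod cannot cross the
#' wall).
#'
#' @param dtheta,dphi grid spacings in degrees; `dtheta` must divide 90 and
#'   `dphi` must divide 360.
#' @return a `hemisphere_grid` list.
#' @export
hemisphere_grid <- function(dtheta = 1.5, dphi = 3) {
  stopifnot(abs(90 %% dtheta) < 1e-9, abs(360 %% dphi) < 1e-9)
  theta <- seq(0, 90, by = dtheta)
  phi <- seq(0, 360 - dphi, by = dphi)
  structure(list(theta = theta, phi = phi,
                 dtheta = dtheta, dphi = dphi,
                 n_theta = length(theta), n_phi = length(phi)),
            class = "hemisphere_grid")
}

# unknown indexing: pole = 1; node (i >= 2, j) = 1 + (i-2)*n_phi + j
.fp_index <- function(i, j, np) {
  n <- max(length(i), length(j))
  i <- rep_len(as.integer(i), n); j <- rep_len(as.integer(j), n)
  out <- 1L + (i - 2L) * np + j
  out[i == 1L] <- 1L
  out
}

# solid-angle quadrature weights per unknown (sums to 2*pi)
.fp_weights <- function(grid) {
  dth <- grid$dtheta * pi / 180
  dph <- grid$dphi * pi / 180
  th <- grid$theta * pi / 180
  nt <- grid$n_theta; np <- grid$n_phi
  w <- numeric(1 + (nt - 1) * np)
  w[1] <- 2 * pi * (1 - cos(dth / 2))
  for (i in 2:nt) {
    lo <- th[i] - dth / 2
    hi <- min(th[i] + dth / 2, pi / 2)
    w[.fp_index(i, seq_len(np), np)] <- (cos(lo) - cos(hi)) * dph
  }
  w
}

# assemble the steady flux-divergence operator as a sparse matrix.
# Equations are extensive flux balances over grid cells, so the columns of
# the operator sum to zero (discrete conservation) before the normalization
# row replaces the pole equation.
.fp_operator <- function(coeffs, pe, grid) {
  nt <- grid$n_theta; np <- grid$n_phi
  dth <- grid$dtheta * pi / 180
  dph <- grid$dphi * pi / 180
  th <- grid$theta * pi / 180
  n_unknown <- 1 + (nt - 1) * np

  acc <- vector("list", 4096L); nacc <- 0L
  add <- function(eq, node, val) {
    n <- max(length(eq), length(node), length(val))
    nacc <<- nacc + 1L
    acc[[nacc]] <<- cbind(rep_len(eq, n), rep_len(node, n), rep_len(val, n))
  }
  jp <- function(j) ifelse(j == np, 1L, j + 1L)   # j+1 with wrap
  jm <- function(j) ifelse(j == 1L, np, j - 1L)   # j-1 with wrap

  ## ---- theta edges between rows i and i+1 (half level i + 1/2) --------
  th_half <- (grid$theta[-nt] + grid$theta[-1]) / 2       # degrees
  Dh <- coef_D(coeffs, th_half)                           # at half levels
  ath_half <- coef_alpha(coeffs, th_half, grid$phi)$alpha_theta
  aph_node <- coef_alpha(coeffs, grid$theta,
                         grid$phi + grid$dphi / 2)$alpha_phi
  for (i in 1:(nt - 1)) {
    j <- seq_len(np)
    ath <- ath_half[i, ]
    sh <- sin(th_half[i] * pi / 180)
    lo <- .fp_index(i, j, np); hi <- .fp_index(i + 1L, j, np)
    # flux F_theta(i+1/2, j) acts on eq(i,j) with +s*dph and eq(i+1,j) -s*dph
    w_up <- sh * dph; w_dn <- -sh * dph
    eq_lo <- lo; eq_hi <- hi
    # advective + D_tt gradient part
    a_lo <- pe * ath / 2 + Dh$Dtt[i] / dth
    a_hi <- pe * ath / 2 - Dh$Dtt[i] / dth
    add(eq_lo, lo, w_up * a_lo); add(eq_lo, hi, w_up * a_hi)
    add(eq_hi, lo, w_dn * a_lo); add(eq_hi, hi, w_dn * a_hi)
    # cross term -D_tp * (1/sin th) * dpsi/dphi (skip at the pole edge,
    # where the lower row is the single pole unknown and the phi-derivative
    # vanishes by single-valuedness)
    if (abs(Dh$Dtp[i]) > 0) {
      c4 <- -Dh$Dtp[i] / (sh * 4 * dph)
      nodes <- function(irow, jshift) .fp_index(irow, if (jshift > 0) jp(j) else jm(j), np)
      if (i > 1) {
        add(eq_lo, nodes(i, +1),  w_up * c4); add(eq_lo, nodes(i, -1), -w_up * c4)
        add(eq_hi, nodes(i, +1),  w_dn * c4); add(eq_hi, nodes(i, -1), -w_dn * c4)
      }
      add(eq_lo, nodes(i + 1L, +1),  w_up * c4); add(eq_lo, nodes(i + 1L, -1), -w_up * c4)
      add(eq_hi, nodes(i + 1L, +1),  w_dn * c4); add(eq_hi, nodes(i + 1L, -1), -w_dn * c4)
    }
  }

  ## ---- phi edges within rows i = 2..nt (half level j + 1/2) -----------
  Dn <- coef_D(coeffs, grid$theta)
  for (i in 2:nt) {
    j <- seq_len(np)
    aph <- aph_node[i, ]
    si <- sin(th[i])
    dth_i <- if (i == nt) dth / 2 else dth
    me <- .fp_index(i, j, np); pr <- .fp_index(i, jp(j), np)
    # flux F_phi(i, j+1/2): +dth_i on eq(i,j), -dth_i on eq(i,j+1)
    a_me <- pe * aph / 2 + Dn$Dpp[i] / (si * dph)
    a_pr <- pe * aph / 2 - Dn$Dpp[i] / (si * dph)
    add(me, me, dth_i * a_me); add(me, pr, dth_i * a_pr)
    add(pr, me, -dth_i * a_me); add(pr, pr, -dth_i * a_pr)
    if (abs(Dn$Dtp[i]) > 0) {
      # cross term -D_tp * dpsi/dtheta averaged onto the phi edge
      if (i < nt) {
        up <- .fp_index(i + 1L, j, np);  up2 <- .fp_index(i + 1L, jp(j), np)
        dn <- .fp_index(i - 1L, j, np);  dn2 <- .fp_index(i - 1L, jp(j), np)
        cc <- -Dn$Dtp[i] / (4 * dth)
        add(me, up,  dth_i * cc); add(me, up2,  dth_i * cc)
        add(me, dn, -dth_i * cc); add(me, dn2, -dth_i * cc)
        add(pr, up, -dth_i * cc); add(pr, up2, -dth_i * cc)
        add(pr, dn,  dth_i * cc); add(pr, dn2,  dth_i * cc)
      } else {
        dn <- .fp_index(i - 1L, j, np); dn2 <- .fp_index(i - 1L, jp(j), np)
        cc <- -Dn$Dtp[i] / (2 * dth)
        add(me, me,  dth_i * cc); add(me, pr,  dth_i * cc)
        add(me, dn, -dth_i * cc); add(me, dn2, -dth_i * cc)
        add(pr, me, -dth_i * cc); add(pr, pr, -dth_i * cc)
        add(pr, dn,  dth_i * cc); add(pr, dn2,  dth_i * cc)
      }
    }
  }

  trip <- do.call(rbind, acc[seq_len(nacc)])
  keep <- trip[, 3] != 0
  Matrix::sparseMatrix(i = trip[keep, 1], j = trip[keep, 2],
                       x = trip[keep, 3], dims = c(n_unknown, n_unknown))
}

#' Solve the steady orientation Fokker-Planck equation
#'
#' Solves the steady dimensionless advection-diffusion equation for the
#' orientation density psi(theta, phi) at rotational Peclet number `pe`:
#' the divergence of the flux `Pe * alpha * psi - D grad psi` vanishes on
#' the hemisphere, with periodicity in phi, regularity at the pole and
#' zero normal flux at the wall rim.  The one-dimensional null space of
#' the steady operator is fixed by the normalization constraint (psi
#' integrates to one over the hemisphere with the sin(theta) measure).
#'
#' Discretization is a conservative finite-volume scheme with centred
#' fluxes, so the discrete flux divergence sums to zero exactly.
#'
#' @param coeffs a [compute_coefficient_table()] result.
#' @param pe rotational Peclet number, `>= 0`.
#' @param grid a [hemisphere_grid()].
#' @return an `orientation_density` list: `psi` (matrix `n_theta x n_phi`,
#'   pole row replicated), `peclet`, `grid`, `weights` (per-node
#'   solid-angle measure matrix), `min_psi`.
#' @export
solve_steady <- function(coeffs, pe, grid = hemisphere_grid()) {
  stopifnot(pe >= 0)
  np <- grid$n_phi; nt <- grid$n_theta
  A <- .fp_operator(coeffs, pe, grid)
  w <- .fp_weights(grid)
  # replace the pole balance with the normalization row (the pole balance
  # is implied by the remaining balances plus conservation)
  A[1, ] <- w
  b <- c(1, numeric(nrow(A) - 1))
  x <- as.numeric(Matrix::solve(A, b))
  x <- x / sum(w * x)   # exact renormalization
  min_psi <- min(x)
  if (min_psi < -1e-3 * max(x))
    warning("orientation density has negative values beyond tolerance; ",
            "refine the grid")
  psi <- matrix(0, nt, np)
  psi[1, ] <- x[1]
  for (i in 2:nt) psi[i, ] <- x[.fp_index(i, seq_len(np), np)]
  wm <- matrix(0, nt, np)
  wm[1, ] <- w[1] / np
  for (i in 2:nt) wm[i, ] <- w[.fp_index(i, seq_len(np), np)]
  structure(list(psi = psi, peclet = pe, grid = grid, weights = wm,
                 min_psi = min_psi), class = "orientation_density")
}

#' Residual of the discrete steady balance
#'
#' Applies the unmodified flux-divergence operator to a solved density;
#' used to verify discrete conservation and that the normalization row did
#' not distort the solution.
#'
#' @param coeffs coefficient table used for the solve.
#' @param density an `orientation_density`.
#' @return vector of cell residuals (pole first).
#' @export
steady_residual <- function(coeffs, density) {
  grid <- density$grid
  np <- grid$n_phi; nt <- grid$n_theta
  A <- .fp_operator(coeffs, density$peclet, grid)
  x <- c(density$psi[1, 1],
         as.numeric(t(density$psi[2:nt, , drop = FALSE])))
  as.numeric(A %*% x)
}

#' Marginal in-plane angle density
#'
#' Integrates the orientation density over the polar angle with the
#' sin(theta) measure, giving the density of the in-plane angle phi that
#' 2-D imaging observes.  Reported on the support `(-180, 180]` with 0 the
#' flow direction.
#'
#' @param density an `orientation_density` from [solve_steady()].
#' @return data frame with `phi` (degrees, sorted on `(-180, 180]`) and
#'   `density` (per radian); integrates to 1.
#' @export
marginalize <- function(density) {
  grid <- density$grid
  dph <- grid$dphi * pi / 180
  mass <- colSums(density$psi * density$weights)   # per phi node
  phi <- grid$phi
  phi_c <- ifelse(phi > 180, phi - 360, phi)
  ord <- order(phi_c)
  data.frame(phi = phi_c[ord], density = (mass / dph)[ord])
}

#' Family of marginal angle distributions over Peclet numbers
#'
#' Solves the steady Fokker-Planck problem at each Peclet number of
#' `pe_grid` and tabulates the marginal density and its CDF, for use in
#' Kolmogorov-Smirnov estimation of Pe from angle samples.  The CDF is
#' piecewise linear over the phi cells (density piecewise constant), with
#' `F(-180) = 0` and `F(180) = 1` exactly.
#'
#' @param coeffs a [compute_coefficient_table()] result.
#' @param pe_grid Peclet values (default 60 log-spaced points on
#'   `[1, 200]`, the experimentally relevant range).
#' @param grid a [hemisphere_grid()].
#' @param window angle window (degrees) to which estimation is restricted;
#'   matches the fit bounds on phi.  Stored with the family.
#' @return a `marginal_family` list: `pe_grid`, `phi` (cell centres),
#'   `edges` (cell edges from -180 to 180), `Phi` (matrix pe x phi),
#'   `F1` (matrix pe x edges), `window`.
#' @export
build_family <- function(coeffs, pe_grid = exp(seq(log(1), log(200),
                                                   length.out = 60)),
                         grid = hemisphere_grid(), window = c(-90, 90)) {
  pe_grid <- sort(pe_grid)
  first <- marginalize(solve_steady(coeffs, pe_grid[1], grid))
  phi <- first$phi
  dphi_deg <- grid$dphi
  edges <- c(phi - dphi_deg / 2, phi[length(phi)] + dphi_deg / 2)
  Phi <- matrix(NA_real_, length(pe_grid), length(phi))
  Phi[1, ] <- first$density
  if (length(pe_grid) > 1)
    for (k in 2:length(pe_grid))
      Phi[k, ] <- marginalize(solve_steady(coeffs, pe_grid[k], grid))$density
  dph <- dphi_deg * pi / 180
  F1 <- t(apply(Phi, 1, function(d) c(0, cumsum(d * dph))))
  F1 <- F1 / F1[, ncol(F1)]
  structure(list(pe_grid = pe_grid, phi = phi, edges = edges,
                 Phi = Phi, F1 = F1, window = window),
            class = "marginal_family")
}

# interpolate the family CDF in Pe (linear between bracketing grid rows)
.family_cdf_at <- function(family, pe) {
  pg <- family$pe_grid
  pe <- min(max(pe, pg[1]), pg[length(pg)])
  k <- findInterval(pe, pg, rightmost.closed = TRUE)
  if (k >= length(pg)) return(family$F1[length(pg), ])
  t <- (pe - pg[k]) / (pg[k + 1] - pg[k])
  (1 - t) * family$F1[k, ] + t * family$F1[k + 1, ]
}

# interpolate the family density in Pe
.family_pdf_at <- function(family, pe) {
  pg <- family$pe_grid
  pe <- min(max(pe, pg[1]), pg[length(pg)])
  k <- findInterval(pe, pg, rightmost.closed = TRUE)
  if (k >= length(pg)) return(family$Phi[length(pg), ])
  t <- (pe - pg[k]) / (pg[k + 1] - pg[k])
  (1 - t) * family$Phi[k, ] + t * family$Phi[k + 1, ]
}
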