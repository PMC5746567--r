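#' Kolmogorov-Smirnov statistic against the model angle distribution
#'
#' Computes `D = sup |F1(phi; pe) - F2(phi)|` between the model CDF at a
#' given Peclet number and the empirical CDF of an angle sample, evaluated
#' on both sides of every sample jump point.  The model CDF is restricted
#' to the family's angle window (the fit bounds on phi) and renormalized,
#' so model and sample share a common support.
#'
#' @param phis angle sample, degrees within the family window.
#' @param family a [build_family()] result.
#' @param pe Peclet number within the family range.
#' @return the KS statistic in `[0, 1]`.
#' @export
ks_statistic <- function(phis, family, pe) {
  if (length(phis) == 0) stop("empty angle sample")
  Fm <- .window_cdf(family, pe)
  x <- sort(phis)
  n <- length(x)
  Fx <- approx(Fm$x, Fm$y, xout = x, rule = 2)$y
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# model CDF restricted to the window and renormalized
.window_cdf <- function(family, pe) {
  F1 <- .family_cdf_at(family, pe)
  w <- family$window
  Flo <- approx(family$edges, F1, xout = w[1], rule = 2)$y
  Fhi <- approx(family$edges, F1, xout = w[2], rule = 2)$y
  keep <- family$edges >= w[1] & family$edges <= w[2]
  x <- c(w[1], family$edges[keep], w[2])
  y <- c(Flo, F1[keep], Fhi)
  o <- !duplicated(x)
  list(x = x[o], y = (y[o] - Flo) / (Fhi - Flo))
}

#' Estimate the Peclet number from an angle sample
#'
#' Minimizes the Kolmogorov-Smirnov statistic over the Peclet range of the
#' model family: a deterministic coarse scan over the family grid followed
#' by golden-section refinement between the bracketing grid values (the
#' model CDF is interpolated continuously in Pe, so `D(pe)` is continuous).
#'
#' @param phis angle sample, degrees.
#' @param family a [build_family()] result.
#' @return a `peclet_estimate` list: `pe_hat`, `D`, and the scan `trace`
#'   (data frame of evaluated pe and D).
#' @export
estimate_peclet <- function(phis, family) {
  if (length(phis) == 0) stop("empty angle sample")
  pg <- family$pe_grid
  Dg <- vapply(pg, function(p) ks_statistic(phis, family, p), numeric(1))
  k <- which.min(Dg)
  lo <- pg[max(k - 1, 1)]; hi <- pg[min(k + 1, length(pg))]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- ks_statistic(phis, family, c1); f2 <- ks_statistic(phis, family, c2)
  for (it in 1:40) {
    if (b - a < 1e-3 * (1 + b)) break
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- ks_statistic(phis, family, c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- ks_statistic(phis, family, c2)
    }
  }
  cand_pe <- c(pg[k], c1, c2)
  cand_D <- c(Dg[k], f1, f2)
  best <- which.min(cand_D)
  structure(list(pe_hat = cand_pe[best], D = cand_D[best],
                 trace = data.frame(pe = pg, D = Dg)),
            class = "peclet_estimate")
}

#' Draw angles from the model marginal density by rejection sampling
#'
#' Samples i.i.d. in-plane angles from the marginal density at a given
#' Peclet number, restricted to the family window and renormalized
#' (matching the support on which angles are fitted and compared).  The
#' density is treated as piecewise constant over the tabulation cells --
#' exactly the distribution whose CDF the family stores -- with a uniform
#' proposal and an envelope 1.05 times the density maximum.
#'
#' @param family a [build_family()] result.
#' @param pe Peclet number.
#' @param n sample size.
#' @param seed integer seed (reproducibility contract).
#' @return numeric vector of `n` angles in degrees.
#' @export
rejection_sample <- function(family, pe, n, seed) {
  stopifnot(n >= 1, !missing(seed))
  set.seed(as.integer(seed))
  dens <- .family_pdf_at(family, pe)
  w <- family$window
  keep <- family$phi >= w[1] & family$phi <= w[2]
  phi_c <- family$phi[keep]
  half <- (family$phi[2] - family$phi[1]) / 2
  d <- dens[keep]
  d <- d / sum(d * 2 * half * pi / 180)    # renormalize on the window
  env <- 1.05 * max(d)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, 2L * as.integer(ceiling((n - length(out)) *
                                           env * (w[2] - w[1]) * pi / 180)))
    x <- runif(m, w[1], w[2])
    idx <- pmin(pmax(findInterval(x, phi_c - half) , 1L), length(phi_c))
    acc <- runif(m) < d[idx] / env
    out <- c(out, x[acc])
  }
  out[seq_len(n)]
}
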