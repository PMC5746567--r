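# Independent oracles and cached heavyweight objects shared across tests.

# Classical singular image-system tensor for a stokeslet above a plane
# no-slip wall (Blake 1971), in the compact form
#   B_jk = S_jk(r) - S_jk(R)
#        + 2 h Delta_k d/dx_k [ h R_j/|R|^3 - delta_j3/|R| - R_j R_3/|R|^3 ]
# with Delta = diag(1, 1, -1) and no sum over k.  The derivative is taken
# numerically, so this implementation shares no code with the package
# kernel.
blake_singular <- function(x, X) {
  stopifnot(X[3] > 0)
  S <- function(v, j, k) {
    r2 <- sum(v^2)
    ((j == k) * r2 + v[j] * v[k]) / r2^1.5
  }
  bracket <- function(x, j) {
    h <- X[3]
    R <- x - c(X[1], X[2], -h)
    Rm <- sqrt(sum(R^2))
    h * R[j] / Rm^3 - (j == 3) / Rm - R[j] * R[3] / Rm^3
  }
  Delta <- c(1, 1, -1)
  B <- matrix(0, 3, 3)
  h <- X[3]
  for (j in 1:3) for (k in 1:3) {
    ek <- numeric(3); ek[k] <- 1e-6
    dbr <- (bracket(x + ek, j) - bracket(x - ek, j)) / 2e-6
    B[j, k] <- S(x - X, j, k) - S(x - c(X[1], X[2], -h), j, k) +
      2 * h * Delta[k] * dbr
  }
  B
}

# session-level cache for the coefficient table, CDF family and the
# synthetic validation corpora used by the acceptance tests
.pf_cache <- new.env(parent = emptyenv())

pf_coeffs <- function() {
  if (is.null(.pf_cache$coeffs))
    .pf_cache$coeffs <- compute_coefficient_table()
  .pf_cache$coeffs
}

pf_family <- function() {
  if (is.null(.pf_cache$family))
    .pf_cache$family <- build_family(pf_coeffs())
  .pf_cache$family
}

# step-1 study at the reduced desk scale (20 Pe conditions x 30 frames),
# fitted twice on the identical seeded corpus: with and without the
# preprocessing step
pf_step1 <- function() {
  if (is.null(.pf_cache$step1)) {
    fam <- pf_family()
    cfg <- validation_config(pe_values = seq(1, 200, length.out = 20),
                             images_per_pe = 30L, seed = 1L, step = 1L)
    pre <- run_validation(cfg, fam)
    cfg_raw <- cfg; cfg_raw$preprocessing <- FALSE
    raw <- run_validation(cfg_raw, fam, frames_override = pre$corpus)
    .pf_cache$step1 <- list(pre = pre, raw = raw)
  }
  .pf_cache$step1
}

# step-2 study: a single plain sample of 180 angles per Pe condition
pf_step2 <- function() {
  if (is.null(.pf_cache$step2)) {
    fam <- pf_family()
    cfg <- validation_config(pe_values = seq(1, 200, length.out = 20),
                             images_per_pe = 180L, seed = 2L, step = 2L)
    .pf_cache$step2 <- run_validation(cfg, fam)
  }
  .pf_cache$step2
}
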