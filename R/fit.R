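#' Sum-squared error between two frames
#'
#' The objective of the inverse problem of image formation: the pixelwise
#' sum of squared differences between the observed and simulated images.
#'
#' @param observed,model numeric matrices of identical dimensions.
#' @return nonnegative scalar; zero iff the frames are identical.
#' @export
sse <- function(observed, model) {
  if (!all(dim(observed) == dim(model)))
    stop("frame dimensions differ")
  sum((observed - model)^2)
}

#' Least-squares optimal intensity scale
#'
#' Given the unit-intensity render `G` and background `B`, the intensity
#' `I0` minimising the SSE has the closed form
#' `I0 = sum((E - B) * G) / sum(G^2)` (cross- over auto-correlation),
#' clamped to be nonnegative.  Used at every objective evaluation so the
#' optimizer never searches over `I0`.
#'
#' @param observed observed frame.
#' @param unit unit-intensity render.
#' @param B background level.
#' @return list with `I0` and the residual `sse` at that intensity.
#' @export
optimal_intensity <- function(observed, unit, B = 0) {
  .sse_with_optimal_intensity(observed, unit, B)
}

#' Parameter bounds for the frame fit
#'
#' The tether must lie within the image, the projected length in
#' `(0, 2]` micrometres and the in-plane angle in `[-90, 90]` degrees.
#' The PSF spread is bracketed around its theoretical value and the
#' residual background between zero and a robust upper bound from the
#' image itself.
#'
#' @param frame a [frame_spec()].
#' @param sigma0 theoretical PSF spread, micrometres.
#' @param img optional frame used to bound the background term; when
#'   missing, `B` is bounded by `[0, 255]`.
#' @return a `fit_bounds` list of `c(lower, upper)` pairs.
#' @export
fit_bounds <- function(frame = frame_spec(), sigma0 = sigma_theory(),
                       img = NULL) {
  half_w <- frame$width  * frame$pitch / 2
  half_h <- frame$height * frame$pitch / 2
  b_hi <- if (is.null(img)) 255 else
    max(0, median(img)) + 3 * max(mad(as.numeric(img)), 1)
  structure(list(
    x0    = c(-half_w, half_w),
    y0    = c(-half_h, half_h),
    L     = c(1e-3, 2),
    phi   = c(-90, 90),
    sigma = c(0.5 * sigma0, 2 * sigma0),
    B     = c(0, b_hi)
  ), class = "fit_bounds")
}

#' Fitting configuration
#'
#' @param sigma0 initial (theoretical) PSF spread, micrometres.
#' @param quad_per_um rendering quadrature density.
#' @param coarse_phi angular grid of the global stage, degrees.
#' @param n_starts local polishes launched from the best global points.
#' @param maxit iteration cap per local stage.
#' @param min_length success floor on fitted length, micrometres.
#' @param min_improvement minimum fractional SSE improvement over the best
#'   constant image for a fit to count as successful.
#' @return a `fit_config` list.
#' @export
fit_config <- function(sigma0 = sigma_theory(), quad_per_um = 60,
                       coarse_phi = seq(-80, 90, by = 17),
                       n_starts = 3L, maxit = 60L,
                       min_length = 0.2, min_improvement = 0.05) {
  structure(list(sigma0 = sigma0, quad_per_um = quad_per_um,
                 coarse_phi = coarse_phi, n_starts = n_starts,
                 maxit = maxit, min_length = min_length,
                 min_improvement = min_improvement),
            class = "fit_config")
}

# unit render for a spatial parameter vector
.unit_render <- function(frame, x0, y0, L, phi, sigma, quad_per_um) {
  nq <- max(16L, as.integer(ceiling(quad_per_um * L)))
  .render_rod_core(frame$width, frame$height, frame$pitch,
                   x0, y0, L, phi, sigma, nq)
}

# SSE with analytic intensity for a full parameter set
.objective <- function(img, frame, x0, y0, L, phi, sigma, B, quad_per_um) {
  if (L <= 0 || sigma <= 0) return(list(I0 = 0, sse = Inf))
  G <- .unit_render(frame, x0, y0, L, phi, sigma, quad_per_um)
  .sse_with_optimal_intensity(img, G, B)
}

# moment-based initial guesses: intensity centroid and principal axis.
# Pixels below 15% of the residual peak are zeroed so weak noise speckle
# far from the rod cannot inflate the second moments.
.moment_init <- function(img, frame, sigma) {
  w <- pmax(img - median(img), 0)
  w[w < 0.15 * max(w)] <- 0
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  xs <- (seq_len(frame$width)  - 0.5 - frame$width  / 2) * frame$pitch
  ys <- (seq_len(frame$height) - 0.5 - frame$height / 2) * frame$pitch
  wx <- colSums(w); wy <- rowSums(w)
  cx <- sum(wx * xs) / tot
  cy <- sum(wy * ys) / tot
  mxx <- sum(wx * (xs - cx)^2) / tot
  myy <- sum(wy * (ys - cy)^2) / tot
  mxy <- sum(w * outer(ys - cy, xs - cx)) / tot
  phi <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  # a uniform segment of length L has axial variance L^2/12; remove the
  # PSF and pixel variance before inverting
  lam <- max(eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE,
                   only.values = TRUE)$values)
  Lsq <- 12 * max(lam - sigma^2 - frame$pitch^2 / 12, 1e-4)
  list(cx = cx, cy = cy, phi = phi, L = sqrt(Lsq))
}

.clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])

# fold an angle to [-90, 90] and the matching tether end
.fold_phi <- function(phi) {
  phi <- ((phi + 90) %% 180) - 90
  if (phi == -90) phi <- 90
  phi
}

#' Fit the rod image model to one frame
#'
#' Solves the inverse problem of image formation for a single frame by
#' minimising the sum-squared error between the frame and the forward
#' model, with the intensity set analytically at every evaluation.  The
#' search follows a five-stage schedule: (1) spatial parameters
#' `(x0, y0, L, phi)` with the theoretical PSF spread and zero background
#' (a deterministic global stage: moment-based and coarse-angle candidates
#' followed by bounded local polishes); (2) the PSF spread `sigma_x` alone;
#' (3) spatial refit; (4) background `B` with a small `sigma_x` adjustment;
#' (5) final spatial refit.  The objective never increases across stages.
#'
#' Success requires an SSE improvement of at least `min_improvement` over
#' the best constant image and a fitted length above `min_length`.
#'
#' @param img observed frame (raw or preprocessed), numeric matrix.
#' @param frame a [frame_spec()].
#' @param bounds a [fit_bounds()]; default derived from `frame` and `img`.
#' @param config a [fit_config()].
#' @return a `frame_fit` list: `rod`, `psf`, `sse`, `success`, `reason`,
#'   `stage_sse`.
#' @export
fit_frame <- function(img, frame = frame_spec(), bounds = NULL,
                      config = fit_config()) {
  if (is.null(bounds)) bounds <- fit_bounds(frame, config$sigma0, img)
  sse_const <- sum((img - mean(img))^2)
  if (max(img) - min(img) < 1e-9 || sse_const <= 0)
    return(structure(list(rod = NULL, psf = NULL, sse = sse_const,
                          success = FALSE, reason = "blank frame",
                          stage_sse = numeric(0)), class = "frame_fit"))

  qpu <- config$quad_per_um
  obj_spatial <- function(p, sigma, B) {
    .objective(img, frame, p[1], p[2], p[3], p[4], sigma, B, qpu)$sse
  }
  lower_sp <- c(bounds$x0[1], bounds$y0[1], bounds$L[1], bounds$phi[1])
  upper_sp <- c(bounds$x0[2], bounds$y0[2], bounds$L[2], bounds$phi[2])
  pscale   <- c(0.1, 0.1, 0.1, 5)

  polish <- function(p, sigma, B, maxit) {
    res <- tryCatch(
      optim(p, obj_spatial, sigma = sigma, B = B, method = "L-BFGS-B",
            lower = lower_sp, upper = upper_sp,
            control = list(maxit = maxit, parscale = pscale,
                           factr = 1e4)),
      error = function(e) list(par = p, value = obj_spatial(p, sigma, B),
                               convergence = 52L))
    res
  }

  sigma <- config$sigma0
  B <- 0
  stage_sse <- numeric(0)

  ## stage 1: global spatial search at sigma0, B = 0
  cands <- list()
  mi <- .moment_init(img, frame, sigma)
  Ls <- c(0.5, 0.8, 1.1)
  if (!is.null(mi)) {
    for (Lc in unique(.clamp(c(mi$L, 0.7 * mi$L, 1.3 * mi$L), bounds$L))) {
      ph <- .fold_phi(mi$phi)
      u <- c(cos(ph * pi / 180), sin(ph * pi / 180))
      cands[[length(cands) + 1]] <-
        c(.clamp(mi$cx - Lc / 2 * u[1], bounds$x0),
          .clamp(mi$cy - Lc / 2 * u[2], bounds$y0), Lc, ph)
    }
    Ls <- unique(.clamp(c(0.6 * mi$L, mi$L), bounds$L))
  }
  anchor <- if (is.null(mi)) c(0, 0) else c(mi$cx, mi$cy)
  for (ph in config$coarse_phi) for (Lc in Ls) {
    u <- c(cos(ph * pi / 180), sin(ph * pi / 180))
    cands[[length(cands) + 1]] <-
      c(.clamp(anchor[1] - Lc / 2 * u[1], bounds$x0),
        .clamp(anchor[2] - Lc / 2 * u[2], bounds$y0), Lc, ph)
  }
  vals <- vapply(cands, obj_spatial, numeric(1), sigma = sigma, B = B)
  ord <- order(vals)
  best <- list(par = cands[[ord[1]]], value = vals[ord[1]])
  converged <- TRUE
  for (k in seq_len(min(config$n_starts, length(ord)))) {
    res <- polish(cands[[ord[k]]], sigma, B, config$maxit)
    if (res$value < best$value) best <- res
  }
  p <- best$par; cur <- best$value
  stage_sse <- c(stage_sse, cur)

  ## stage 2: PSF spread alone
  os <- optimize(function(s) .objective(img, frame, p[1], p[2], p[3], p[4],
                                        s, B, qpu)$sse,
                 interval = bounds$sigma, tol = 1e-4)
  if (os$objective < cur) { sigma <- os$minimum; cur <- os$objective }
  stage_sse <- c(stage_sse, cur)

  ## stage 3: spatial refit with updated sigma
  res <- polish(p, sigma, B, config$maxit)
  if (res$value < cur) { p <- res$par; cur <- res$value }
  stage_sse <- c(stage_sse, cur)

  ## stage 4: background (and small sigma adjustment)
  ob <- tryCatch(
    optim(c(sigma, B),
          function(q) .objective(img, frame, p[1], p[2], p[3], p[4],
                                 q[1], q[2], qpu)$sse,
          method = "L-BFGS-B",
          lower = c(bounds$sigma[1], bounds$B[1]),
          upper = c(bounds$sigma[2], bounds$B[2]),
          control = list(maxit = 25L, parscale = c(0.01, 5), factr = 1e4)),
    error = function(e) list(par = c(sigma, B), value = cur))
  if (ob$value < cur) { sigma <- ob$par[1]; B <- ob$par[2]; cur <- ob$value }
  stage_sse <- c(stage_sse, cur)

  ## stage 5: final spatial refit
  res <- polish(p, sigma, B, config$maxit)
  if (res$value < cur) { p <- res$par; cur <- res$value }
  converged <- converged && is.finite(cur)
  stage_sse <- c(stage_sse, cur)

  fin <- .objective(img, frame, p[1], p[2], p[3], p[4], sigma, B, qpu)
  improvement <- 1 - cur / sse_const
  success <- converged && p[3] >= config$min_length &&
    improvement >= config$min_improvement
  reason <- if (success) "" else if (p[3] < config$min_length)
    "fitted length below floor" else if (improvement < config$min_improvement)
    "no improvement over constant image" else "optimizer did not converge"

  structure(list(
    rod = rod_projection(p[1], p[2], p[3], p[4]),
    psf = psf_model(I0 = max(fin$I0, .Machine$double.eps),
                    sigma_x = sigma, B = B),
    sse = cur, success = success, reason = reason,
    boundary_phi = abs(abs(p[4]) - 90) < 1e-6,
    stage_sse = stage_sse), class = "frame_fit")
}

#' Fit a stack of frames
#'
#' Batch driver: fits every frame, recording per-frame success; failures
#' (including unreadable frames) are recorded and processing continues.
#'
#' @param frames list of frames (numeric matrices) or a 3-D array with the
#'   frame index last.
#' @param frame a [frame_spec()].
#' @param config a [fit_config()].
#' @param preprocess_frames apply [preprocess()] to each frame first.
#' @return data frame with one row per frame: `frame`, `x0`, `y0`, `L`,
#'   `phi`, `sigma_x`, `B`, `I0`, `sse`, `success`.
#' @export
fit_stack <- function(frames, frame = frame_spec(), config = fit_config(),
                      preprocess_frames = TRUE) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  n <- length(frames)
  out <- data.frame(frame = seq_len(n),
                    x0 = rep(NA_real_, n), y0 = rep(NA_real_, n),
                    L = rep(NA_real_, n), phi = rep(NA_real_, n),
                    sigma_x = rep(NA_real_, n), B = rep(NA_real_, n),
                    I0 = rep(NA_real_, n), sse = rep(NA_real_, n),
                    success = rep(FALSE, n))
  for (i in seq_len(n)) {
    ft <- tryCatch({
      img <- frames[[i]]
      if (preprocess_frames) img <- preprocess(img)
      fit_frame(img, frame, config = config)
    }, error = function(e) NULL)
    if (is.null(ft) || is.null(ft$rod)) next
    out$x0[i] <- ft$rod$x0; out$y0[i] <- ft$rod$y0
    out$L[i] <- ft$rod$L;   out$phi[i] <- ft$rod$phi
    out$sigma_x[i] <- ft$psf$sigma_x; out$B[i] <- ft$psf$B
    out$I0[i] <- ft$psf$I0; out$sse[i] <- ft$sse
    out$success[i] <- ft$success
  }
  out
}
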