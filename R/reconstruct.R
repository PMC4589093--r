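#' Reconstruction configuration
#'
#' Defaults are the standard simulation settings: regularization
#' `xi = 0.001`, termination threshold `delta = 0.02` on the relative
#' residual objective, rotation angle `beta_deg` of half the inter-source
#' spacing (computed from the source set when NULL), haar level-1 wavelet
#' compression with 95 % retained PCA energy.
#'
#' @param xi Tikhonov regularization parameter (> 0).
#' @param delta termination threshold on the objective (> 0).
#' @param beta_deg rotation increment in degrees (NULL = half the source
#'   spacing; 0 disables rotation).
#' @param max_outer_iters outer iteration cap.
#' @param variant solver variant passed to [solve_update()].
#' @param wavelet_family,wavelet_level,pca_energy,pca_q,cg_tol,maxiter_factor
#'   accelerated-solver settings (see [algorithm1_solve()]).
#' @param relative_objective normalize the objective by the measured-data
#'   norm (the termination threshold assumes this).
#' @param positivity clamp the parameter map at zero after each update.
#' @param sens_norm compensate the exponential depth decay of sensitivity by
#'   normalizing Jacobian columns before regularization (the update is
#'   mapped back afterwards). Without this, zeroth-order Tikhonov places
#'   all updates at the boundary where sensitivity peaks.
#' @param sens_clip floor for the column-norm scaling, as a fraction of the
#'   largest column norm; bounds the amplification of nearly insensitive
#'   deep nodes.
#' @param whiten weight every measurement row by `1 / |y_meas|` (floored at
#'   `whiten_floor` times the rms measurement) before regularization. This
#'   is the maximum-likelihood weighting for noise whose standard deviation
#'   is proportional to the signal, and balances the large dynamic range of
#'   boundary measurements.
#' @param whiten_floor relative floor for the whitening weights.
#' @return A `fmt_recon_config` list.
#' @export
recon_config <- function(xi = 0.001, delta = 0.02, beta_deg = NULL,
                         max_outer_iters = 50L, variant = "proposed",
                         wavelet_family = "haar", wavelet_level = 1L,
                         pca_energy = 0.95, pca_q = NULL, cg_tol = 1e-8,
                         maxiter_factor = 10L, relative_objective = TRUE,
                         positivity = TRUE, sens_norm = TRUE,
                         sens_clip = 0.5, whiten = TRUE,
                         whiten_floor = 0.1) {
  if (xi <= 0) stop("xi must be > 0")
  if (delta <= 0) stop("delta must be > 0")
  if (!is.null(beta_deg) && (beta_deg < 0 || beta_deg > 180))
    stop("beta_deg must be in [0, 180]")
  structure(list(xi = xi, delta = delta, beta_deg = beta_deg,
                 max_outer_iters = as.integer(max_outer_iters),
                 variant = variant, wavelet_family = wavelet_family,
                 wavelet_level = as.integer(wavelet_level),
                 pca_energy = pca_energy, pca_q = pca_q, cg_tol = cg_tol,
                 maxiter_factor = maxiter_factor,
                 relative_objective = relative_objective,
                 positivity = positivity, sens_norm = sens_norm,
                 sens_clip = sens_clip, whiten = whiten,
                 whiten_floor = whiten_floor),
            class = "fmt_recon_config")
}

#' Half the angular spacing of a uniform source ring
#'
#' The rotation increment used by the rotated-illumination iteration:
#' `beta = 360 / (2 * count)` degrees for a single uniform ring.
#'
#' @param sources an `fmt_sources` with uniformly spaced angles.
#' @return beta in degrees.
#' @export
half_spacing_angle <- function(sources) {
  a <- sort(sources$angles_deg %% 360)
  n <- length(a)
  if (n < 1L) stop("empty source set")
  if (n == 1L) return(180)
  gaps <- diff(c(a, a[1L] + 360))
  if (max(gaps) - min(gaps) > 1e-9)
    stop("sources are not uniformly spaced; supply beta_deg explicitly")
  360 / (2 * n)
}

#' Rotate a source set
#'
#' Adds `theta_deg` to every source's boundary angle (z-coordinates and the
#' detector set are untouched).
#'
#' @param sources an `fmt_sources`.
#' @param theta_deg rotation angle (degrees).
#' @return The rotated `fmt_sources`.
#' @export
rotate_sources <- function(sources, theta_deg) {
  if (!is.finite(theta_deg)) stop("theta must be finite")
  sources$rotation_offset <- sources$rotation_offset + theta_deg
  sources
}

#' Residual objective between measured and predicted data
#'
#' `M = ||y_meas - y_pred||_2`, divided by `||y_meas||_2` in relative mode.
#'
#' @param y_meas,y_pred measurement vectors of equal length.
#' @param relative normalize by the measured-data norm.
#' @return The scalar objective.
#' @export
objective_residual <- function(y_meas, y_pred, relative = TRUE) {
  if (length(y_meas) != length(y_pred))
    stop("y_meas and y_pred lengths differ")
  M <- sqrt(sum(Mod(y_meas - y_pred)^2))
  if (relative) M / sqrt(sum(Mod(y_meas)^2)) else M
}

#' Cached simulated-measurement provider
#'
#' Generates the noisy boundary measurements of the truth phantom for each
#' requested rotation angle, on demand. Each distinct angle's noise is drawn
#' once (seed offset by the angle's first-visit index) and cached, so
#' revisited angles reuse identical data.
#'
#' @param phantom truth `fmt_phantom`.
#' @param mesh an `fmt_mesh`.
#' @param sources,detectors base source and detector sets.
#' @param omega angular modulation frequency (rad/s).
#' @param snr_db measurement SNR in dB (`Inf` = noiseless).
#' @param seed integer RNG seed.
#' @param noise_mode noise convention passed to [add_noise()].
#' @return A function `f(theta_deg)` returning the measurement vector.
#' @export
simulated_measurements <- function(phantom, mesh, sources, detectors,
                                   omega = 0, snr_db = Inf, seed = 1L,
                                   noise_mode = "relative") {
  ras <- rasterize_phantom(phantom, mesh)
  Dmat <- detector_matrix(mesh, detectors)
  cache <- new.env(parent = emptyenv())
  count <- new.env(parent = emptyenv()); count$k <- 0L
  function(theta_deg) {
    key <- sprintf("%.9f", theta_deg %% 360)
    if (!is.null(cache[[key]])) return(cache[[key]])
    y <- forward_map(mesh, ras$props, rotate_sources(sources, theta_deg),
                     detectors, omega, Dmat = Dmat)
    if (is.finite(snr_db)) {
      y <- add_noise(y, snr_db, seed + 1000L * count$k, mode = noise_mode)
      count$k <- count$k + 1L
    }
    cache[[key]] <- y
    y
  }
}

#' Iterative reconstruction with rotated-source illumination
#'
#' Outer loop: at iteration i the sources are rotated by `theta = i * beta`;
#' the residual and Jacobian are computed at the current estimate with the
#' rotated sources; the Tikhonov normal equations are solved with the
#' selected variant; the estimate is updated (and clamped at zero); the
#' relative residual objective is evaluated with the updated estimate
#' against the current angle's data; iteration stops when the objective
#' falls below `delta` or the cap is reached.
#'
#' The linearized system is put in dimensionless form before regularization:
#' rows of J and the residual are scaled by a common factor chosen so the
#' largest diagonal entry of J^T J equals one (the usual
#' Levenberg-Marquardt-style normalization). `xi` therefore acts relative to
#' the peak sensitivity, independent of the arbitrary source-amplitude
#' units.
#'
#' @param mesh an `fmt_mesh`.
#' @param props background `fmt_props`; all fields except `mu_axf` are held
#'   fixed at these values during inversion.
#' @param sources,detectors base source and detector sets.
#' @param data measurement provider: a function `f(theta_deg)` (see
#'   [simulated_measurements()]) or a named list keyed by
#'   `sprintf("%.9f", theta %% 360)`.
#' @param config a [recon_config()].
#' @param omega angular modulation frequency (rad/s).
#' @param x0 initial nodal mu_axf map (default: `props$mu_axf`).
#' @param x_truth optional truth map; per-iteration MSE is recorded when
#'   supplied.
#' @return A `fmt_recon` list: `x`, `history` (data.frame with iter,
#'   theta_deg, objective, mse, solver_iterations), `converged`, `config`.
#' @export
reconstruct <- function(mesh, props, sources, detectors, data,
                        config = recon_config(), omega = 0, x0 = NULL,
                        x_truth = NULL) {
  provider <- if (is.function(data)) data else function(theta_deg) {
    key <- sprintf("%.9f", theta_deg %% 360)
    if (is.null(data[[key]]))
      stop("no measurement data for rotation angle ", theta_deg %% 360)
    data[[key]]
  }
  beta <- if (is.null(config$beta_deg)) half_spacing_angle(sources) else
    config$beta_deg
  x <- if (is.null(x0)) props$mu_axf else rep_len(x0, mesh$N)
  solver_cf <- config[c("wavelet_family", "wavelet_level", "pca_energy",
                        "pca_q", "cg_tol", "maxiter_factor")]
  Dmat <- detector_matrix(mesh, detectors)
  hist <- vector("list", config$max_outer_iters)
  converged <- FALSE
  i <- 0L
  while (i < config$max_outer_iters) {
    theta <- (i * beta) %% 360
    src_i <- rotate_sources(sources, theta)
    y_meas <- provider(theta)
    props_i <- props; props_i$mu_axf <- x
    ctx <- forward_context(mesh, props_i, src_i, detectors, omega,
                           Dmat = Dmat)
    delta_y <- y_meas - as.vector(ctx$y)
    J <- stack_real(jacobian_adjoint(ctx = ctx))
    dy_s <- stack_real(delta_y)
    if (isTRUE(config$whiten)) {
      ym <- stack_real(y_meas)
      w <- 1 / pmax(abs(ym), config$whiten_floor * sqrt(mean(ym^2)))
      J <- J * w
      dy_s <- dy_s * w
    }
    cn <- sqrt(colSums(J^2))
    colscale <- if (isTRUE(config$sens_norm)) {
      pmax(cn, config$sens_clip * max(cn))
    } else rep(max(cn), length(cn))
    J <- sweep(J, 2L, colscale, "/")
    rowscale <- sqrt(max(colSums(J^2)))  # make max diag of J^T J equal one
    ns <- normal_system(J / rowscale, dy_s / rowscale, config$xi)
    i <- i + 1L
    upd <- solve_update(ns$K, ns$b, config$variant, solver_cf)
    x <- x + upd$x / colscale
    if (config$positivity) x <- pmax(x, 0)
    props_i$mu_axf <- x
    y_pred <- forward_map(mesh, props_i, src_i, detectors, omega,
                          Dmat = Dmat)
    M <- objective_residual(y_meas, y_pred,
                            relative = config$relative_objective)
    hist[[i]] <- data.frame(
      iter = i, theta_deg = theta, objective = M,
      mse = if (is.null(x_truth)) NA_real_ else mse(x, x_truth),
      solver_iterations = if (is.na(upd$iterations)) NA_integer_ else
        as.integer(upd$iterations))
    if (M < config$delta) { converged <- TRUE; break }
  }
  structure(list(x = x, history = do.call(rbind, hist[!vapply(hist, is.null,
                                                              logical(1))]),
                 converged = converged, config = config, beta_deg = beta),
            class = "fmt_recon")
}

#' @export
print.fmt_recon <- function(x, ...) {
  cat(sprintf("fmt_recon: %d iterations, converged = %s, final objective %.4g\n",
              nrow(x$history), x$converged,
              x$history$objective[nrow(x$history)]))
  invisible(x)
}
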