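#' Experiment configuration
#'
#' Assembles the full description of a simulation experiment: phantom, mesh
#' settings, source/detector counts, modulation frequency, noise level,
#' seed, reconstruction settings and method variant. Defaults reproduce the
#' standard study conditions (xi = 0.001, delta = 0.02, 10 dB SNR, rotation
#' by half the source spacing).
#'
#' @param phantom a `fmt_phantom`, a built-in phantom name
#'   (`"one_inclusion"`, `"two_inclusion"`, `"cylinder_3d"`) or a phantom
#'   JSON file path.
#' @param target_edge_mm base mesh edge (mm).
#' @param node_budget adaptive refinement budget (NULL = no refinement).
#' @param n_sources,n_detectors counts per ring.
#' @param omega angular modulation frequency (rad/s).
#' @param snr_db measurement SNR (dB); `Inf` = noiseless.
#' @param noise_mode noise convention (see [add_noise()]).
#' @param seed integer RNG seed.
#' @param variant method variant (see [solve_update()]).
#' @param recon a [recon_config()] (variant field is overridden).
#' @param output_dir directory for result files.
#' @return An `fmt_experiment` list.
#' @export
experiment_config <- function(phantom = "one_inclusion",
                              target_edge_mm = 2.5, node_budget = 122L,
                              n_sources = 4L, n_detectors = 30L,
                              omega = 0, snr_db = 10, noise_mode = "relative",
                              seed = 1L, variant = "proposed",
                              recon = recon_config(), output_dir = ".") {
  if (is.character(phantom)) {
    phantom <- if (file.exists(phantom)) read_phantom_json(phantom) else
      switch(phantom,
             one_inclusion = phantom_one_inclusion(),
             two_inclusion = phantom_two_inclusion(),
             cylinder_3d = phantom_cylinder_3d(),
             stop("unknown phantom '", phantom, "'"))
  }
  if (!variant %in% c("proposed", "conventional", "wavelet_only", "pca_only"))
    stop("unknown variant '", variant,
         "'; allowed: proposed, conventional, wavelet_only, pca_only")
  if (seed < 0 || seed != round(seed)) stop("seed must be a non-negative integer")
  recon$variant <- variant
  if (variant == "conventional") recon$beta_deg <- 0
  structure(list(phantom = phantom, target_edge_mm = target_edge_mm,
                 node_budget = node_budget, n_sources = as.integer(n_sources),
                 n_detectors = as.integer(n_detectors), omega = omega,
                 snr_db = snr_db, noise_mode = noise_mode,
                 seed = as.integer(seed), variant = variant, recon = recon,
                 output_dir = output_dir),
            class = "fmt_experiment")
}

#' Load an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; a `recon`
#' block holds [recon_config()] overrides. Missing keys take the defaults,
#' so an empty file reproduces the standard study conditions.
#'
#' @param path YAML file path.
#' @return An `fmt_experiment`.
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  rc <- do.call(recon_config, if (is.null(y$recon)) list() else y$recon)
  y$recon <- NULL
  if (!is.null(y$snr_db) && is.character(y$snr_db)) y$snr_db <- Inf
  do.call(experiment_config, c(y, list(recon = rc)))
}

experiment_setup <- function(config) {
  phantom <- config$phantom
  mesh <- phantom_mesh(phantom, config$target_edge_mm, config$node_budget)
  is3d <- phantom$geometry$type == "cylinder"
  z <- if (is3d) phantom$measurement_planes else NULL
  sources <- uniform_sources(config$n_sources, z = z)
  detectors <- uniform_detectors(config$n_detectors, z = z)
  ras <- rasterize_phantom(phantom, mesh)
  list(mesh = mesh, sources = sources, detectors = detectors,
       props = ras$props, x_act = ras$x_act)
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$phantom <- unclass(cfg$phantom)
  cfg$recon <- unclass(cfg$recon)
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, path, extra = list()) {
  man <- c(list(config_hash = config_fingerprint(config),
                seed = config$seed,
                package_version = as.character(utils::packageVersion("fmtrecon")),
                timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate boundary measurements for every scheduled rotation angle
#'
#' Builds the phantom and mesh, runs the forward model at each rotation
#' angle the reconstruction schedule may visit, adds noise, and writes a
#' flat CSV (`angle_deg, source, detector, y_real, y_imag`) plus a JSON
#' metadata sidecar (`<file>.meta.json`) with angles, SNR, omega and seed.
#'
#' @param config an `fmt_experiment`.
#' @param out_file output CSV path (default inside `config$output_dir`).
#' @return The measurement file path, invisibly.
#' @export
run_simulate <- function(config, out_file = NULL) {
  if (is.null(out_file))
    out_file <- file.path(config$output_dir,
                          paste0(config$phantom$name, "_meas.csv"))
  setup <- experiment_setup(config)
  beta <- if (!is.null(config$recon$beta_deg)) config$recon$beta_deg else
    half_spacing_angle(setup$sources)
  angles <- unique(round(((seq_len(max(config$recon$max_outer_iters, 1L)) - 1L)
                          * beta) %% 360, 9))
  provider <- simulated_measurements(config$phantom, setup$mesh,
                                     setup$sources, setup$detectors,
                                     omega = config$omega,
                                     snr_db = config$snr_db,
                                     seed = config$seed,
                                     noise_mode = config$noise_mode)
  nd <- length(setup$detectors$angles_deg) *
    max(1L, length(setup$detectors$z))
  ns <- length(setup$sources$angles_deg) * max(1L, length(setup$sources$z))
  rows <- lapply(angles, function(th) {
    y <- provider(th)
    data.frame(angle_deg = th,
               source = rep(seq_len(ns), each = nd),
               detector = rep(seq_len(nd), times = ns),
               y_real = Re(y), y_imag = Im(y))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, out_file, row.names = FALSE)
  write_manifest(config, paste0(out_file, ".meta.json"), list(
    angles_deg = angles, omega = config$omega, snr_db = config$snr_db,
    noise_mode = config$noise_mode, n_sources = ns, n_detectors = nd,
    noiseless = !is.finite(config$snr_db)))
  invisible(out_file)
}

read_measurements <- function(meas_file) {
  tab <- utils::read.csv(meas_file)
  out <- list()
  for (th in unique(tab$angle_deg)) {
    sub <- tab[tab$angle_deg == th, ]
    sub <- sub[order(sub$source, sub$detector), ]
    y <- sub$y_real
    if (any(sub$y_imag != 0)) y <- y + 1i * sub$y_imag
    out[[sprintf("%.9f", th %% 360)]] <- y
  }
  out
}

#' Reconstruct from a measurement file
#'
#' Dispatches to the configured method variant, writes the result as JSON
#' (`x_final`, per-iteration history, config hash) and returns the
#' `fmt_recon` object invisibly.
#'
#' @param config an `fmt_experiment` (must match the simulation config).
#' @param meas_file CSV from [run_simulate()].
#' @param out_file output JSON path.
#' @return The `fmt_recon`, invisibly.
#' @export
run_reconstruct <- function(config, meas_file, out_file = NULL) {
  if (is.null(out_file))
    out_file <- file.path(config$output_dir,
                          paste0(config$phantom$name, "_",
                                 config$variant, "_result.json"))
  setup <- experiment_setup(config)
  data <- read_measurements(meas_file)
  t0 <- Sys.time()
  res <- reconstruct(setup$mesh, setup$props, setup$sources,
                     setup$detectors, data, config = config$recon,
                     omega = config$omega,
                     x0 = rep(config$phantom$background$mu_axf,
                              setup$mesh$N),
                     x_truth = setup$x_act)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out <- list(x_final = res$x, history = res$history,
              converged = res$converged, variant = config$variant,
              beta_deg = res$beta_deg, elapsed_seconds = elapsed,
              config_hash = config_fingerprint(config))
  jsonlite::write_json(out, out_file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  write_manifest(config, paste0(out_file, ".meta.json"),
                 list(elapsed_seconds = elapsed))
  attr(res, "file") <- out_file
  invisible(res)
}

#' Evaluate a reconstruction against the truth phantom
#'
#' Reports the nodal MSE, and per inclusion the peak recovered value inside
#' the (dilated) inclusion neighbourhood and the localization error
#' (distance from the inclusion centre to the nearest recovered local
#' maximum).
#'
#' @param result a `fmt_recon` or a result JSON file from
#'   [run_reconstruct()].
#' @param config the matching `fmt_experiment`.
#' @param out_file optional JSON report path.
#' @return The metrics list, invisibly.
#' @export
run_evaluate <- function(result, config, out_file = NULL) {
  setup <- experiment_setup(config)
  x <- if (is.character(result)) {
    obj <- jsonlite::read_json(result, simplifyVector = TRUE)
    as.numeric(obj$x_final)
  } else result$x
  if (length(x) != setup$mesh$N)
    stop("result and truth meshes differ (", length(x), " vs ",
         setup$mesh$N, " nodes)")
  peak_node <- which.max(x)
  inclusions <- lapply(config$phantom$inclusions, function(inc) {
    ctr <- inc$center
    d2 <- rowSums(sweep(setup$mesh$nodes[, seq_along(ctr), drop = FALSE],
                        2L, ctr)^2)
    near <- d2 <= (2 * inc$radius)^2
    best <- which(near)[which.max(x[near])]
    list(center = ctr, radius = inc$radius, true_mu_axf = inc$mu_axf,
         peak_recovered = max(x[near]),
         localization_error_mm = sqrt(d2[best]))
  })
  metrics <- list(mse = mse(x, setup$x_act),
                  peak_value = max(x),
                  peak_node = peak_node,
                  inclusions = inclusions)
  if (!is.null(out_file))
    jsonlite::write_json(metrics, out_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(metrics)
}

#' Run a variant comparison matrix
#'
#' Simulates once per seed and reconstructs with each requested variant,
#' returning (and optionally writing) a tidy data frame of MSE and wall
#' clock per (variant, seed) — the shape of the method-comparison tables.
#'
#' @param config base `fmt_experiment`.
#' @param variants character vector of method variants.
#' @param seeds integer vector of noise seeds.
#' @param out_csv optional output CSV path.
#' @return data.frame(variant, seed, mse, seconds, converged).
#' @export
run_bench <- function(config, variants = c("proposed", "conventional"),
                      seeds = 1:5, out_csv = NULL) {
  setup <- experiment_setup(config)
  rows <- list()
  for (sd in seeds) {
    for (v in variants) {
      cfg <- config
      cfg$seed <- as.integer(sd)
      cfg$variant <- v
      cfg$recon$variant <- v
      cfg$recon$beta_deg <- if (v == "conventional") 0 else
        config$recon$beta_deg
      provider <- simulated_measurements(cfg$phantom, setup$mesh,
                                         setup$sources, setup$detectors,
                                         omega = cfg$omega,
                                         snr_db = cfg$snr_db, seed = sd,
                                         noise_mode = cfg$noise_mode)
      t0 <- Sys.time()
      res <- reconstruct(setup$mesh, setup$props, setup$sources,
                         setup$detectors, provider, config = cfg$recon,
                         omega = cfg$omega,
                         x0 = rep(cfg$phantom$background$mu_axf,
                                  setup$mesh$N),
                         x_truth = setup$x_act)
      secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = sd, mse = mse(res$x, setup$x_act),
        seconds = secs, converged = res$converged)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Canonical study configurations
#'
#' The three benchmark experiments at their standard settings: 10 dB
#' measurement noise, xi = 0.001, delta = 0.02, rotation by half the source
#' spacing, haar level-1 compression with 95 % retained PCA energy.
#' The 2D cases use 4 sources and 30 detectors on the disc phantoms with
#' adaptively refined meshes of about 122 / 148 nodes and an outer budget
#' of 8 iterations; the 3D case uses 6 sources and 16 detectors on each of
#' the three measurement planes, a tetrahedral mesh refined to at most 858
#' nodes, and 6 outer iterations.
#'
#' @param case `"one_inclusion_2d"`, `"two_inclusion_2d"` or
#'   `"cylinder_3d"`.
#' @param seed noise seed.
#' @param variant method variant.
#' @return An `fmt_experiment`.
#' @export
study_config <- function(case = c("one_inclusion_2d", "two_inclusion_2d",
                                  "cylinder_3d"),
                         seed = 1L, variant = "proposed") {
  case <- match.arg(case)
  switch(case,
    one_inclusion_2d = experiment_config(
      phantom = "one_inclusion", target_edge_mm = 2.5, node_budget = 122L,
      n_sources = 4L, n_detectors = 30L, snr_db = 10, seed = seed,
      variant = variant, recon = recon_config(max_outer_iters = 8L)),
    two_inclusion_2d = experiment_config(
      phantom = "two_inclusion", target_edge_mm = 2.5, node_budget = 148L,
      n_sources = 4L, n_detectors = 30L, snr_db = 10, seed = seed,
      variant = variant, recon = recon_config(max_outer_iters = 8L)),
    cylinder_3d = experiment_config(
      phantom = "cylinder_3d", target_edge_mm = 4, node_budget = 858L,
      n_sources = 6L, n_detectors = 16L, snr_db = 10, seed = seed,
      variant = variant, recon = recon_config(max_outer_iters = 6L)))
}
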