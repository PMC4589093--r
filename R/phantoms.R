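#' Built-in simulation phantoms
#'
#' Disc and cylinder phantoms with homogeneous optical backgrounds and
#' circular/cylindrical fluorescent inclusions. Property values are the
#' standard one-inclusion / two-inclusion / 3D-cylinder test cases. The 2D
#' disc geometry (radius 10 mm, inclusion radius 2.5 mm at mid-radius) is a
#' package default chosen to match the optical thickness of the 3D cylinder
#' phantom: with the tabulated optics (mu_eff about 1 mm^-1 at the
#' excitation wavelength) a much larger domain would attenuate the
#' inclusion signature below double precision.
#'
#' @return A `fmt_phantom` list: `name`, `geometry`, `background`
#'   (property values), `inclusions` (list of inclusion specs with property
#'   overrides).
#' @export
phantom_one_inclusion <- function() {
  structure(list(
    name = "one_inclusion_disc",
    geometry = list(type = "disc", radius = 10),
    background = list(mu_axf = 0.06, mu_axi = 0.03, mu_sx_prime = 4.0,
                      mu_amf = 0.005, mu_ami = 0.02, mu_sm_prime = 3.0,
                      eta = 0.2, tau = 0.6),
    inclusions = list(
      list(shape = "circle", center = c(4, 0), radius = 2.5,
           mu_axf = 0.4, mu_amf = 0.2)
    )
  ), class = "fmt_phantom")
}

#' @rdname phantom_one_inclusion
#' @export
phantom_two_inclusion <- function() {
  structure(list(
    name = "two_inclusion_disc",
    geometry = list(type = "disc", radius = 10),
    background = list(mu_axf = 0.06, mu_axi = 0.03, mu_sx_prime = 4.0,
                      mu_amf = 0.003, mu_ami = 0.02, mu_sm_prime = 3.0,
                      eta = 0.2, tau = 0.6),
    inclusions = list(
      list(shape = "circle", center = c(-4, 2), radius = 2.5,
           mu_axf = 0.3, mu_amf = 0.02),
      list(shape = "circle", center = c(4, -2), radius = 2.5,
           mu_axf = 0.4, mu_amf = 0.03)
    )
  ), class = "fmt_phantom")
}

#' @rdname phantom_one_inclusion
#' @export
phantom_cylinder_3d <- function() {
  structure(list(
    name = "cylinder_3d",
    geometry = list(type = "cylinder", radius = 10, height = 40),
    background = list(mu_axf = 0.005, mu_axi = 0.03, mu_sx_prime = 4.0,
                      mu_amf = 0.005, mu_ami = 0.02, mu_sm_prime = 3.0,
                      eta = 0.2, tau = 0.6),
    inclusions = list(
      list(shape = "cylinder", center = c(5, 0, 20), radius = 2, height = 6,
           mu_axf = 0.01, mu_amf = 0.01)
    ),
    measurement_planes = c(15, 20, 25)
  ), class = "fmt_phantom")
}

inclusion_contains <- function(inc, pts) {
  dx <- pts[, 1L] - inc$center[1L]
  dy <- pts[, 2L] - inc$center[2L]
  inside <- dx * dx + dy * dy <= inc$radius^2
  if (ncol(pts) == 3L && !is.null(inc$height))
    inside <- inside & abs(pts[, 3L] - inc$center[3L]) <= inc$height / 2
  inside
}

#' Rasterize a phantom onto a mesh
#'
#' Assigns every node the background property values, overridden inside
#' inclusions (a node belongs to an inclusion when its coordinates fall
#' inside the inclusion shape). Later inclusions take precedence.
#'
#' @param phantom a `fmt_phantom`.
#' @param mesh an `fmt_mesh` of the matching geometry.
#' @return list(props = `fmt_props`, x_act = true nodal mu_axf vector).
#' @export
rasterize_phantom <- function(phantom, mesh) {
  g <- phantom$geometry
  if (g$type == "disc" && mesh$dimension != 2L ||
      g$type == "cylinder" && mesh$dimension != 3L)
    stop("mesh dimension does not match phantom geometry")
  if (mesh_radius(mesh) > g$radius * (1 + 1e-6))
    stop("mesh extends beyond the phantom radius")
  bg <- phantom$background
  fields <- c("mu_axf", "mu_axi", "mu_sx_prime", "mu_amf", "mu_ami",
              "mu_sm_prime", "eta", "tau")
  vals <- lapply(fields, function(f) rep(bg[[f]], mesh$N))
  names(vals) <- fields
  for (inc in phantom$inclusions) {
    inside <- inclusion_contains(inc, mesh$nodes)
    for (f in fields) if (!is.null(inc[[f]])) vals[[f]][inside] <- inc[[f]]
  }
  props <- tissue_properties(mesh,
    mu_axi = vals$mu_axi, mu_axf = vals$mu_axf, mu_sx_prime = vals$mu_sx_prime,
    mu_ami = vals$mu_ami, mu_amf = vals$mu_amf, mu_sm_prime = vals$mu_sm_prime,
    eta = vals$eta, tau = vals$tau)
  list(props = props, x_act = vals$mu_axf)
}

#' Prior image from a phantom's inclusions
#'
#' @param phantom a `fmt_phantom`.
#' @param dilation_mm margin added around each inclusion (mm, >= 0).
#' @return An `fmt_prior` whose regions are the inclusion shapes.
#' @export
prior_from_phantom <- function(phantom, dilation_mm = 0) {
  prior_image(lapply(phantom$inclusions, function(inc)
    list(center = inc$center, radius = inc$radius, height = inc$height)),
    dilation_mm = dilation_mm)
}

#' Add Gaussian measurement noise at a given SNR
#'
#' Amplitude-ratio dB convention (`10^(-snr_db/20)` noise-to-signal).
#' In `"relative"` mode (default) the noise on measurement i has standard
#' deviation `sigma_i = |y_i| * 10^(-snr_db/20)` — appropriate for boundary
#' data spanning several orders of magnitude, and the convention under which
#' every measurement carries the stated SNR. In `"global"` mode a single
#' `sigma = rms(y) * 10^(-snr_db/20)` applies to all entries. Both modes
#' realize the same aggregate `rms(noise) / rms(y)`. Noise is applied
#' independently to real and (for complex data) imaginary components, and is
#' deterministic given `seed`.
#'
#' @param y measurement vector (not all zero).
#' @param snr_db signal-to-noise ratio in dB; `Inf` returns `y` unchanged.
#' @param seed integer RNG seed.
#' @param mode `"relative"` (per-measurement sigma) or `"global"`.
#' @return Noisy copy of `y`.
#' @export
add_noise <- function(y, snr_db, seed, mode = c("relative", "global")) {
  mode <- match.arg(mode)
  if (all(Mod(y) == 0)) stop("SNR undefined for an all-zero measurement vector")
  if (is.infinite(snr_db)) return(y)
  nsr <- 10^(-snr_db / 20)
  sigma <- if (mode == "global") sqrt(mean(Mod(y)^2)) * nsr else Mod(y) * nsr
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- length(y)
  if (is.complex(y)) {
    y + sigma * (stats::rnorm(n) + 1i * stats::rnorm(n))
  } else {
    y + sigma * stats::rnorm(n)
  }
}

#' Mean square error between nodal parameter maps
#'
#' `MSE = (1/N) sum_i (x_rec(i) - x_act(i))^2`.
#'
#' @param x_rec reconstructed nodal vector.
#' @param x_act true nodal vector (same length).
#' @return The scalar MSE.
#' @export
mse <- function(x_rec, x_act) {
  if (length(x_rec) != length(x_act))
    stop("x_rec and x_act lengths differ")
  mean((x_rec - x_act)^2)
}

#' Phantom JSON serialization
#'
#' Phantoms round-trip through JSON bit-exactly (full double precision).
#'
#' @param phantom a `fmt_phantom`.
#' @param path file path.
#' @return `read_phantom_json` returns a `fmt_phantom`; `write_phantom_json`
#'   returns `path` invisibly.
#' @export
write_phantom_json <- function(phantom, path) {
  jsonlite::write_json(unclass(phantom), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  # JSON has one number type: restore double storage throughout
  obj <- rapply(obj, function(x) if (is.integer(x)) as.numeric(x) else x,
                how = "replace")
  obj$inclusions <- lapply(obj$inclusions, function(inc) {
    inc$center <- as.numeric(unlist(inc$center))
    inc
  })
  structure(obj, class = "fmt_phantom")
}

#' Default mesh for a phantom's experiment
#'
#' Builds the base mesh for the phantom geometry and adaptively refines it
#' towards the (dilated) inclusion prior up to the node budget.
#'
#' @param phantom a `fmt_phantom`.
#' @param target_edge_mm base mesh edge length (mm).
#' @param node_budget refinement budget; `NULL` disables refinement.
#' @param dilation_mm prior dilation used for refinement (mm).
#' @return An `fmt_mesh`.
#' @export
phantom_mesh <- function(phantom, target_edge_mm, node_budget = NULL,
                         dilation_mm = 2) {
  g <- phantom$geometry
  mesh <- if (g$type == "disc") {
    build_disc_mesh(g$radius, target_edge_mm)
  } else {
    build_cylinder_mesh(g$radius, g$height, target_edge_mm)
  }
  if (!is.null(node_budget) && node_budget > mesh$N) {
    mesh <- adaptive_refine(mesh, prior_from_phantom(phantom, dilation_mm),
                            node_budget)
  }
  mesh
}
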