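#' Nodal tissue optical and fluorescence properties
#'
#' Builds the per-node property container used by the forward model. Scalar
#' inputs are recycled to all N nodes.
#'
#' @param mesh an `fmt_mesh`.
#' @param mu_axi,mu_axf absorption at the excitation wavelength due to
#'   non-fluorescing chromophore / fluorophore (mm^-1).
#' @param mu_ami,mu_amf same at the emission wavelength (mm^-1).
#' @param mu_sx_prime,mu_sm_prime reduced scattering coefficients (mm^-1).
#' @param eta fluorescence quantum efficiency (dimensionless, in \[0, 1\]).
#' @param tau fluorescence lifetime (ns).
#' @param A_x,A_m boundary internal-reflection parameters (> 0; 1 for a
#'   refractive-index-matched boundary).
#' @param c_mm_per_ns speed of light in the medium (mm/ns).
#' @return A `fmt_props` list of nodal vectors and boundary scalars.
#' @export
tissue_properties <- function(mesh, mu_axi, mu_axf, mu_sx_prime,
                              mu_ami, mu_amf, mu_sm_prime,
                              eta, tau, A_x = 1, A_m = 1,
                              c_mm_per_ns = 299.792458 / 1.4) {
  N <- mesh$N
  rec <- function(v, nm) {
    v <- rep_len(as.numeric(v), N)
    if (any(!is.finite(v)) || any(v < 0)) stop("invalid ", nm, ": must be >= 0")
    v
  }
  eta <- rec(eta, "eta")
  if (any(eta > 1)) stop("invalid eta: must be in [0, 1]")
  if (A_x <= 0 || A_m <= 0) stop("invalid A_x/A_m: must be > 0")
  structure(list(
    mu_axi = rec(mu_axi, "mu_axi"), mu_axf = rec(mu_axf, "mu_axf"),
    mu_sx_prime = rec(mu_sx_prime, "mu_sx_prime"),
    mu_ami = rec(mu_ami, "mu_ami"), mu_amf = rec(mu_amf, "mu_amf"),
    mu_sm_prime = rec(mu_sm_prime, "mu_sm_prime"),
    eta = eta, tau = rec(tau, "tau"),
    A_x = A_x, A_m = A_m, c_mm_per_ns = c_mm_per_ns
  ), class = "fmt_props")
}

#' Derived diffusion-model coefficients
#'
#' Nodal diffusion coefficients `D = 1 / (3 (mu_ai + mu_af + mu_s'))` (mm),
#' complex decay `k = i w / c + mu_ai + mu_af` (mm^-1), emission source
#' coefficient `alpha = eta mu_axf / (1 - i w tau)` (mm^-1), and the Robin
#' boundary coefficients `b = 1 / (2 A)`, for both wavelength bands. At
#' `omega = 0` all quantities are real.
#'
#' @param props an `fmt_props`.
#' @param omega angular modulation frequency (rad/s).
#' @return A list with elements `D_x`, `D_m`, `k_x`, `k_m`, `alpha`,
#'   `robin_b_x`, `robin_b_m`, `omega`.
#' @export
derive_coefficients <- function(props, omega = 0) {
  tx <- props$mu_axi + props$mu_axf + props$mu_sx_prime
  tm <- props$mu_ami + props$mu_amf + props$mu_sm_prime
  if (any(tx == 0) || any(tm == 0))
    stop("zero total attenuation at node ",
         which(tx == 0 | tm == 0)[1L], ": diffusion coefficient undefined")
  w_ns <- omega * 1e-9  # rad/ns, matching tau in ns and c in mm/ns
  iwc <- if (omega == 0) 0 else (1i * w_ns / props$c_mm_per_ns)
  den <- if (omega == 0) 1 else (1 - 1i * w_ns * props$tau)
  list(
    D_x = 1 / (3 * tx), D_m = 1 / (3 * tm),
    k_x = iwc + props$mu_axi + props$mu_axf,
    k_m = iwc + props$mu_ami + props$mu_amf,
    alpha = props$eta * props$mu_axf / den,
    robin_b_x = 1 / (2 * props$A_x), robin_b_m = 1 / (2 * props$A_m),
    omega = omega
  )
}

mass_diag_factor <- function(dim) if (dim == 2L) 1 / 12 else 1 / 20
facet_diag_factor <- function(dim) if (dim == 2L) 1 / 6 else 1 / 12

# Sparse symmetric matrix of mass type: M_ij = integral of (c phi_i phi_j),
# with the nodal coefficient field `coef` averaged per element. Returns
# real sparse (Re) and optional Im part.
mass_matrix_parts <- function(mesh, coef) {
  geo <- element_geometry(mesh)
  el <- mesh$elements
  nv <- geo$nv
  ce <- rowMeans(matrix(coef[el], ncol = nv))
  f <- mass_diag_factor(mesh$dimension)
  ii <- jj <- integer(0); vv <- complex(0)
  tri <- list(i = list(), j = list(), v = list())
  t <- 0L
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    t <- t + 1L
    tri$i[[t]] <- el[, i]
    tri$j[[t]] <- el[, j]
    tri$v[[t]] <- ce * geo$vol * f * (1 + (i == j))
  }
  list(i = unlist(tri$i), j = unlist(tri$j), v = unlist(tri$v), n = mesh$N)
}

stiffness_parts <- function(mesh, coef) {
  geo <- element_geometry(mesh)
  el <- mesh$elements
  nv <- geo$nv
  ce <- rowMeans(matrix(coef[el], ncol = nv))
  tri <- list(i = list(), j = list(), v = list())
  t <- 0L
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    t <- t + 1L
    tri$i[[t]] <- el[, i]
    tri$j[[t]] <- el[, j]
    tri$v[[t]] <- ce * geo$vol * rowSums(geo$grads[[i]] * geo$grads[[j]])
  }
  list(i = unlist(tri$i), j = unlist(tri$j), v = unlist(tri$v), n = mesh$N)
}

boundary_parts <- function(mesh, bcoef) {
  fb <- mesh$boundary_facets
  if (nrow(fb) == 0L) return(list(i = integer(0), j = integer(0),
                                  v = numeric(0), n = mesh$N))
  nvf <- ncol(fb)
  meas <- facet_measures(mesh$nodes, fb)
  bcoef <- rep_len(bcoef, mesh$N)
  be <- rowMeans(matrix(bcoef[fb], ncol = nvf))
  f <- facet_diag_factor(mesh$dimension)
  tri <- list(i = list(), j = list(), v = list())
  t <- 0L
  for (i in seq_len(nvf)) for (j in seq_len(nvf)) {
    t <- t + 1L
    tri$i[[t]] <- fb[, i]
    tri$j[[t]] <- fb[, j]
    tri$v[[t]] <- be * meas * f * (1 + (i == j))
  }
  list(i = unlist(tri$i), j = unlist(tri$j), v = unlist(tri$v), n = mesh$N)
}

parts_to_sparse <- function(parts) {
  Matrix::sparseMatrix(i = parts$i, j = parts$j, x = as.numeric(parts$v),
                       dims = c(parts$n, parts$n))
}

#' Assemble the FEM system A = D + K + B for one wavelength band
#'
#' Piecewise-linear (P1) Galerkin discretization of the diffusion equation
#' with Robin boundary conditions: `D_ij = int D grad(phi_i).grad(phi_j)`,
#' `K_ij = int k phi_i phi_j`, `B_ij = boundary int b phi_i phi_j`. Nodal
#' coefficient fields are element-averaged before integration. At `omega = 0`
#' the system is real symmetric positive definite and factorized by sparse
#' Cholesky; for `omega > 0` the complex-symmetric system is solved through
#' its 2N x 2N real block form with sparse LU.
#'
#' @param mesh an `fmt_mesh`.
#' @param coeffs output of [derive_coefficients()].
#' @param band `"x"` (excitation) or `"m"` (emission).
#' @return An `fmt_system` with fields `Ar`, `Ai` (NULL when real), `n`.
#' @export
assemble_system <- function(mesh, coeffs, band = c("x", "m")) {
  band <- match.arg(band)
  Dc <- if (band == "x") coeffs$D_x else coeffs$D_m
  kc <- if (band == "x") coeffs$k_x else coeffs$k_m
  bc <- if (band == "x") coeffs$robin_b_x else coeffs$robin_b_m
  sp <- stiffness_parts(mesh, Dc)
  mp <- mass_matrix_parts(mesh, kc)
  bp <- boundary_parts(mesh, rep(bc, mesh$N))
  i <- c(sp$i, mp$i, bp$i); j <- c(sp$j, mp$j, bp$j)
  vr <- c(Re(sp$v), Re(mp$v), Re(bp$v))
  Ar <- Matrix::sparseMatrix(i = i, j = j, x = vr, dims = c(mesh$N, mesh$N))
  Ai <- NULL
  if (is.complex(mp$v) && any(Im(mp$v) != 0)) {
    Ai <- Matrix::sparseMatrix(i = mp$i, j = mp$j, x = Im(mp$v),
                               dims = c(mesh$N, mesh$N))
  }
  structure(list(Ar = Ar, Ai = Ai, n = mesh$N, cache = new.env()),
            class = "fmt_system")
}

# Mass matrix weighted by a (possibly complex) nodal coefficient, as a
# plain (complex) sparse-pattern object usable in products: returns a list
# with real sparse Mr and optional Mi.
weighted_mass_matrix <- function(mesh, coef) {
  mp <- mass_matrix_parts(mesh, coef)
  Mr <- Matrix::sparseMatrix(i = mp$i, j = mp$j, x = Re(mp$v),
                             dims = c(mesh$N, mesh$N))
  Mi <- NULL
  if (is.complex(mp$v) && any(Im(mp$v) != 0))
    Mi <- Matrix::sparseMatrix(i = mp$i, j = mp$j, x = Im(mp$v),
                               dims = c(mesh$N, mesh$N))
  list(Mr = Mr, Mi = Mi)
}

mass_apply <- function(M, X) {
  if (is.null(M$Mi) && !is.complex(X)) return(as.matrix(M$Mr %*% X))
  Xr <- Re(X); Xi <- Im(X)
  Rr <- as.matrix(M$Mr %*% Xr); Ri <- as.matrix(M$Mr %*% Xi)
  if (!is.null(M$Mi)) {
    Rr <- Rr - as.matrix(M$Mi %*% Xi)
    Ri <- Ri + as.matrix(M$Mi %*% Xr)
  }
  Rr + 1i * Ri
}

#' Solve an assembled FEM system
#'
#' Direct sparse factorization (cached inside the system object and reused
#' across right-hand sides/sources).
#'
#' @param system an `fmt_system`.
#' @param rhs numeric or complex vector/matrix of right-hand sides.
#' @return Solution with the same shape as `rhs`.
#' @export
solve_system <- function(system, rhs) {
  rhs_mat <- as.matrix(rhs)
  n <- system$n
  if (is.null(system$Ai) && !is.complex(rhs_mat)) {
    if (is.null(system$cache$chol)) {
      system$cache$chol <- tryCatch(
        Matrix::Cholesky(Matrix::forceSymmetric(system$Ar)),
        error = function(e) stop("singular or indefinite forward system: ",
                                 conditionMessage(e)))
    }
    out <- as.matrix(Matrix::solve(system$cache$chol, rhs_mat))
  } else {
    if (is.null(system$cache$lu)) {
      Ai <- if (is.null(system$Ai))
        Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n, n)) else system$Ai
      big <- rbind(cbind(system$Ar, -Ai), cbind(Ai, system$Ar))
      system$cache$lu <- Matrix::lu(big)
    }
    br <- rbind(Re(rhs_mat), Im(rhs_mat))
    sol <- as.matrix(Matrix::solve(system$cache$lu, br))
    out <- sol[seq_len(n), , drop = FALSE] +
      1i * sol[n + seq_len(n), , drop = FALSE]
  }
  if (is.null(dim(rhs))) drop(out) else out
}

#' Excitation source set
#'
#' Sources sit on the boundary (polar angle for discs; angle plus z for
#' cylinders) and are modelled as isotropic point sources offset inward by
#' one transport mean free path.
#'
#' @param angles_deg polar angles of the sources (degrees).
#' @param z z-coordinates (mm) for 3D cylinders; NULL in 2D.
#' @param amplitude source strength (arbitrary units, recycled).
#' @param offset_mm interior offset depth (mm); default one transport mean
#'   free path for mu_s' = 4 mm^-1.
#' @return An `fmt_sources` object.
#' @export
source_set <- function(angles_deg, z = NULL, amplitude = 1,
                       offset_mm = 0.25) {
  if (offset_mm <= 0) stop("offset depth must be > 0")
  structure(list(angles_deg = as.numeric(angles_deg), z = z,
                 amplitude = rep_len(amplitude, length(angles_deg) *
                                       max(1L, length(z))),
                 offset_mm = offset_mm, rotation_offset = 0),
            class = "fmt_sources")
}

#' Uniformly spaced source ring(s)
#'
#' @param n sources per ring.
#' @param z optional vector of ring heights (mm) for cylinders.
#' @param ... passed to [source_set()].
#' @export
uniform_sources <- function(n, z = NULL, ...) {
  source_set(angles_deg = 360 * (seq_len(n) - 1L) / n, z = z, ...)
}

#' Boundary detector set
#'
#' @param angles_deg polar angles (degrees).
#' @param z optional ring heights (mm) for cylinders.
#' @return An `fmt_detectors` object with a fixed ordering: detectors within
#'   a ring are consecutive, rings stacked in the given z order.
#' @export
detector_set <- function(angles_deg, z = NULL) {
  structure(list(angles_deg = as.numeric(angles_deg), z = z),
            class = "fmt_detectors")
}

#' @rdname detector_set
#' @param n detectors per ring.
#' @export
uniform_detectors <- function(n, z = NULL) {
  detector_set(360 * (seq_len(n) - 1L) / n, z = z)
}

# Expand (angles x rings) into a coordinate matrix on the boundary of the
# given geometry. radius: domain radius. For 2D z is NULL.
ring_positions <- function(angles_deg, z, radius, depth = 0) {
  a <- angles_deg * pi / 180
  r <- radius - depth
  xy <- cbind(r * cos(a), r * sin(a))
  if (is.null(z)) return(xy)
  do.call(rbind, lapply(z, function(zz) cbind(xy, zz)))
}

# Domain radius from the mesh (max node distance to the z axis / origin).
mesh_radius <- function(mesh) {
  max(sqrt(rowSums(mesh$nodes[, 1:2, drop = FALSE]^2)))
}

source_positions <- function(sources, mesh) {
  ring_positions(sources$angles_deg + sources$rotation_offset, sources$z,
                 mesh_radius(mesh), depth = sources$offset_mm)
}

detector_positions <- function(detectors, mesh) {
  ring_positions(detectors$angles_deg, detectors$z, mesh_radius(mesh))
}

#' Right-hand-side load vector for a point source
#'
#' Distributes the source amplitude to the nodes of the containing element
#' by barycentric weights (partition of unity: entries sum to the
#' amplitude).
#'
#' @param mesh an `fmt_mesh`.
#' @param position coordinates of the (already offset) source point.
#' @param amplitude source strength.
#' @return A length-N load vector.
#' @export
source_vector <- function(mesh, position, amplitude = 1) {
  s <- numeric(mesh$N)
  if (amplitude == 0) return(s)
  loc <- tryCatch(locate_point(mesh, position),
                  error = function(e) stop("source placement error: ",
                                           conditionMessage(e)))
  s[mesh$elements[loc$element, ]] <- amplitude * loc$weights
  s
}

# N x D sparse sampling matrix: column d holds the interpolation weights of
# detector d (projected onto the nearest boundary facet).
detector_matrix <- function(mesh, detectors) {
  pos <- detector_positions(detectors, mesh)
  D <- nrow(pos)
  ii <- list(); jj <- list(); vv <- list()
  for (d in seq_len(D)) {
    pr <- project_to_boundary(mesh, pos[d, ])
    ii[[d]] <- pr$nodes
    jj[[d]] <- rep(d, length(pr$nodes))
    vv[[d]] <- pr$weights
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(mesh$N, D))
}

# Source load matrix N x S.
source_matrix <- function(mesh, sources) {
  pos <- source_positions(sources, mesh)
  S <- nrow(pos)
  out <- matrix(0, mesh$N, S)
  for (s in seq_len(S))
    out[, s] <- source_vector(mesh, pos[s, ], sources$amplitude[s])
  out
}

#' Full forward context: systems, factorizations and fields
#'
#' Assembles both band systems, solves the excitation fields for every
#' source, forms the emission source loads `S_m = M_alpha Phi_x` and solves
#' the emission fields. Used by [forward_map()] and [jacobian_adjoint()].
#'
#' @inheritParams forward_map
#' @param Dmat optional precomputed detector sampling matrix (reused across
#'   repeated solves on a fixed mesh/detector set).
#' @return A list with systems, `Phi_x`, `Phi_m` (N x S), detector matrix
#'   and the measurement matrix `y` (D x S).
#' @export
forward_context <- function(mesh, props, sources, detectors, omega = 0,
                            Dmat = NULL) {
  coeffs <- derive_coefficients(props, omega)
  sys_x <- assemble_system(mesh, coeffs, "x")
  sys_m <- assemble_system(mesh, coeffs, "m")
  Malpha <- weighted_mass_matrix(mesh, coeffs$alpha)
  S <- source_matrix(mesh, sources)
  Phi_x <- solve_system(sys_x, S)
  Sm <- mass_apply(Malpha, Phi_x)
  Phi_m <- solve_system(sys_m, Sm)
  if (is.null(Dmat)) Dmat <- detector_matrix(mesh, detectors)
  y <- if (is.complex(Phi_m)) {
    as.matrix(Matrix::t(Dmat) %*% Re(Phi_m)) +
      1i * as.matrix(Matrix::t(Dmat) %*% Im(Phi_m))
  } else as.matrix(Matrix::t(Dmat) %*% Phi_m)
  list(mesh = mesh, props = props, sources = sources, detectors = detectors,
       omega = omega, coeffs = coeffs, sys_x = sys_x, sys_m = sys_m,
       Malpha = Malpha, Phi_x = Phi_x, Phi_m = Phi_m, Dmat = Dmat, y = y)
}

#' Forward map: boundary emission measurements
#'
#' Stacks, for each source in order, the emission fluence sampled at each
#' detector (detector-major within source). Real at `omega = 0`, complex
#' otherwise.
#'
#' @param mesh an `fmt_mesh`.
#' @param props an `fmt_props`.
#' @param sources an `fmt_sources`.
#' @param detectors an `fmt_detectors`.
#' @param omega angular modulation frequency (rad/s).
#' @param Dmat optional precomputed detector sampling matrix.
#' @return Measurement vector of length sources x detectors.
#' @export
forward_map <- function(mesh, props, sources, detectors, omega = 0,
                        Dmat = NULL) {
  ctx <- forward_context(mesh, props, sources, detectors, omega, Dmat = Dmat)
  as.vector(ctx$y)
}
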