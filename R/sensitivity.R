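#' Adjoint Jacobian of detector measurements w.r.t. the nodal mu_axf map
#'
#' Row (s, d) holds the derivative of measurement y_(s,d) with respect to
#' every nodal fluorophore absorption value, including all three dependency
#' paths: through the excitation decay coefficient k_x, through the
#' excitation diffusion coefficient D_x, and through the emission source
#' coefficient alpha. Computed with one excitation solve per source, one
#' emission adjoint solve per detector and one excitation adjoint solve per
#' detector:
#' \deqn{dy/dp = w^T (dM_a/dp) Phi_x - v^T (dA_x/dp) Phi_x,}
#' with `w = A_m^{-1} d` and `v = A_x^{-1} M_a w` (all systems are
#' complex-symmetric, so adjoint solves reuse the forward factorizations).
#'
#' @param ctx a [forward_context()] (or the arguments to build one).
#' @inheritParams forward_map
#' @return Complex (or real at omega = 0) matrix of size
#'   (sources x detectors) x N, rows detector-major within source.
#' @export
jacobian_adjoint <- function(mesh, props = NULL, sources = NULL,
                             detectors = NULL, omega = 0, ctx = NULL) {
  if (is.null(ctx)) ctx <- forward_context(mesh, props, sources, detectors,
                                           omega)
  mesh <- ctx$mesh; props <- ctx$props
  geo <- element_geometry(mesh)
  el <- mesh$elements
  nv <- geo$nv
  Ns <- ncol(ctx$Phi_x)
  Dmat_dense <- as.matrix(ctx$Dmat)
  Nd <- ncol(Dmat_dense)
  W <- solve_system(ctx$sys_m, Dmat_dense)          # N x D adjoint emission
  V <- solve_system(ctx$sys_x, mass_apply(ctx$Malpha, W))  # N x D
  U <- ctx$Phi_x                                    # N x S
  cplx <- is.complex(U) || is.complex(W) || is.complex(V)
  mf <- mass_diag_factor(mesh$dimension)
  vol <- geo$vol
  # per-element restrictions and sums
  restr <- function(X) lapply(seq_len(nv), function(i) X[el[, i], , drop = FALSE])
  Wr <- restr(W); Vr <- restr(V); Ur <- restr(U)
  SW <- Reduce(`+`, Wr); SV <- Reduce(`+`, Vr); SU <- Reduce(`+`, Ur)
  # gradient-weighted sums: GV[[c]] (P x D), GU[[c]] (P x S)
  d <- mesh$dimension
  GV <- lapply(seq_len(d), function(cc)
    Reduce(`+`, lapply(seq_len(nv), function(i) geo$grads[[i]][, cc] * Vr[[i]])))
  GU <- lapply(seq_len(d), function(cc)
    Reduce(`+`, lapply(seq_len(nv), function(i) geo$grads[[i]][, cc] * Ur[[i]])))
  P <- mesh$P
  mk <- function() if (cplx) matrix(0i, P, Nd * Ns) else matrix(0, P, Nd * Ns)
  Bv <- mk(); Bw <- mk(); Cs <- mk()
  for (s in seq_len(Ns)) {
    cols <- (s - 1L) * Nd + seq_len(Nd)
    us <- lapply(Ur, function(X) X[, s])
    pv <- Reduce(`+`, lapply(seq_len(nv), function(i) Vr[[i]] * us[[i]]))
    pw <- Reduce(`+`, lapply(seq_len(nv), function(i) Wr[[i]] * us[[i]]))
    Bv[, cols] <- (mf * vol) * (SV * SU[, s] + pv)
    Bw[, cols] <- (mf * vol) * (SW * SU[, s] + pw)
    Cs[, cols] <- -vol * Reduce(`+`, lapply(seq_len(d), function(cc)
      GV[[cc]] * GU[[cc]][, s]))
  }
  # derivative scatter matrices (P x N): dk_e/dmu_n, dD_e/dmu_n, dalpha_e/dmu_n
  tx <- props$mu_axi + props$mu_axf + props$mu_sx_prime
  dDn <- -1 / (3 * tx^2)
  w_ns <- ctx$omega * 1e-9
  dan <- props$eta / (if (ctx$omega == 0) 1 else (1 - 1i * w_ns * props$tau))
  ii <- rep(seq_len(P), nv)
  jj <- as.vector(el)
  Q1 <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(-1 / nv, length(ii)),
                             dims = c(P, mesh$N))
  Q2 <- Matrix::sparseMatrix(i = ii, j = jj, x = dDn[jj] / nv,
                             dims = c(P, mesh$N))
  spxd <- function(X, Q) {  # t(X) %*% Q for dense (possibly complex) X
    if (!is.complex(X)) return(as.matrix(Matrix::t(Q) %*% X))
    as.matrix(Matrix::t(Q) %*% Re(X)) + 1i * as.matrix(Matrix::t(Q) %*% Im(X))
  }
  J <- t(spxd(Bv, Q1)) + t(spxd(Cs, Q2))
  if (ctx$omega == 0) {
    Q3 <- Matrix::sparseMatrix(i = ii, j = jj, x = dan[jj] / nv,
                               dims = c(P, mesh$N))
    J <- J + t(spxd(Bw, Q3))
  } else {
    Q3r <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(dan)[jj] / nv,
                                dims = c(P, mesh$N))
    Q3i <- Matrix::sparseMatrix(i = ii, j = jj, x = Im(dan)[jj] / nv,
                                dims = c(P, mesh$N))
    J <- J + t(spxd(Bw, Q3r)) + 1i * t(spxd(Bw, Q3i))
  }
  J
}

#' Finite-difference Jacobian (brute-force oracle)
#'
#' Central differences of [forward_map()] over each nodal mu_axf value.
#' O(N) forward solves; intended as a test oracle on small meshes.
#'
#' @inheritParams forward_map
#' @param step finite-difference step (mm^-1).
#' @return Matrix of the same shape as [jacobian_adjoint()].
#' @export
jacobian_fd <- function(mesh, props, sources, detectors, omega = 0,
                        step = 1e-6) {
  if (step <= 0) stop("step must be > 0")
  base <- props$mu_axf
  if (any(base - step < 0)) {
    warning("step clipped to keep mu_axf non-negative")
  }
  M <- length(sources$angles_deg) * max(1L, length(sources$z)) *
    length(detectors$angles_deg) * max(1L, length(detectors$z))
  J <- if (omega == 0) matrix(0, M, mesh$N) else matrix(0i, M, mesh$N)
  for (n in seq_len(mesh$N)) {
    hi <- base[n] + step
    lo <- max(base[n] - step, 0)
    p2 <- props; p2$mu_axf[n] <- hi
    y_hi <- forward_map(mesh, p2, sources, detectors, omega)
    p2$mu_axf[n] <- lo
    y_lo <- forward_map(mesh, p2, sources, detectors, omega)
    J[, n] <- (y_hi - y_lo) / (hi - lo)
  }
  J
}

# Stack complex measurements/Jacobians into real rows (real block then
# imaginary block); a no-op for real input.
stack_real <- function(x) {
  if (!is.complex(x)) return(x)
  if (is.matrix(x)) rbind(Re(x), Im(x)) else c(Re(x), Im(x))
}

#' Tikhonov normal equations
#'
#' `K = J^T J + xi I`, `b = J^T delta_y`. Complex inputs are stacked into
#' real rows first (real and imaginary parts as separate rows).
#'
#' @param J Jacobian matrix (M x N), real or complex.
#' @param delta_y residual vector `y_meas - y_pred` (length M).
#' @param xi regularization parameter (>= 0).
#' @return list(K = dense N x N matrix, b = length-N vector).
#' @export
normal_system <- function(J, delta_y, xi) {
  if (xi < 0) stop("xi must be >= 0")
  J <- stack_real(J)
  delta_y <- stack_real(delta_y)
  if (nrow(J) != length(delta_y)) stop("J and delta_y sizes do not match")
  K <- crossprod(J)
  diag(K) <- diag(K) + xi
  list(K = as.matrix(K), b = drop(crossprod(J, delta_y)))
}

#' Solve the Tikhonov normal equations directly
#'
#' Symmetric positive-definite (Cholesky) factorization of K.
#'
#' @param K normal matrix from [normal_system()].
#' @param b right-hand side.
#' @return The update vector delta_x.
#' @export
tikhonov_solve <- function(K, b) {
  ch <- tryCatch(chol(K), error = function(e)
    stop("normal matrix not positive definite; use xi > 0 (",
         conditionMessage(e), ")"))
  drop(backsolve(ch, backsolve(ch, b, transpose = TRUE)))
}

#' Dump the linearized system for inspection
#'
#' Writes J, K and b as plain CSV files (`<prefix>_J.csv` etc.).
#'
#' @param J,K,b components of the sensitivity system.
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
dump_sensitivity <- function(J, K, b, prefix) {
  pj <- paste0(prefix, "_J.csv"); pk <- paste0(prefix, "_K.csv")
  pb <- paste0(prefix, "_b.csv")
  utils::write.table(stack_real(J), pj, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(K, pk, sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(b, pb, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(c(pj, pk, pb))
}
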