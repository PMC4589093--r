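#' Orthonormal discrete wavelet transform operator
#'
#' Builds the n_pad x n_pad orthonormal matrix W of a periodized discrete
#' wavelet transform (zero-padding from n to the next power of two), rows
#' ordered approximation-first. Supported families: `haar`, `db2`, `db4`.
#'
#' @param n original vector length (>= 2).
#' @param family wavelet family name.
#' @param level decomposition level (>= 1).
#' @return A `fmt_wavelet` list: `W`, `n`, `n_pad`, `n1` (approximation
#'   block size n_pad / 2^level), `family`, `level`.
#' @export
wavelet_operator <- function(n, family = "haar", level = 1L) {
  if (n < 2) stop("n must be >= 2")
  h <- wavelet_filters(family)
  n_pad <- 2^ceiling(log2(n))
  if (level < 1 || 2^level > n_pad)
    stop("level must satisfy 1 <= level and 2^level <= padded length")
  W <- diag(n_pad)
  m <- n_pad
  for (l in seq_len(level)) {
    if (m < length(h))
      stop(sprintf("block size %d at level %d too small for %d-tap '%s' filter",
                   m, l, length(h), family))
    Wl <- diag(n_pad)
    Wl[seq_len(m), seq_len(m)] <- single_level_dwt(m, h)
    W <- Wl %*% W
    m <- m / 2L
  }
  structure(list(W = W, n = as.integer(n), n_pad = as.integer(n_pad),
                 n1 = as.integer(n_pad / 2^level),
                 family = family, level = as.integer(level)),
            class = "fmt_wavelet")
}

wavelet_filters <- function(family) {
  switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
            -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
            0.032883011666885197, -0.010597401785069032),
    stop("unsupported wavelet family '", family,
         "'; available: haar, db2, db4"))
}

# One analysis level as an m x m orthonormal matrix, periodic extension;
# first m/2 rows are the scaling (approximation) filters, last m/2 the
# wavelet (detail) filters g_k = (-1)^k h_(L-1-k).
single_level_dwt <- function(m, h) {
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  W <- matrix(0, m, m)
  half <- m / 2L
  for (i in seq_len(half)) {
    cols <- ((2L * (i - 1L) + seq_len(L) - 1L) %% m) + 1L
    for (k in seq_len(L)) {
      W[i, cols[k]] <- W[i, cols[k]] + h[k]
      W[half + i, cols[k]] <- W[half + i, cols[k]] + g[k]
    }
  }
  W
}

# Apply the operator to a length-n vector (pad then transform).
apply_wavelet <- function(op, v) {
  vp <- numeric(op$n_pad)
  vp[seq_len(op$n)] <- v
  drop(op$W %*% vp)
}

#' Wavelet compression of the normal equations
#'
#' Transforms `K hat = W_b K W_x^T`, `b hat = W_b b` (after zero-padding K
#' and b to the padded size) and returns the approximation-approximation
#' block `K1` (n1 x n1) and the approximation half `b1`.
#'
#' @param K normal matrix (N x N).
#' @param b right-hand side (length N).
#' @param W_x,W_b wavelet operators sized for K's columns / rows.
#' @return list(K1, b1, Khat, bhat).
#' @export
compress_system <- function(K, b, W_x, W_b = W_x) {
  if (W_x$n != ncol(K) || W_b$n != nrow(K) || length(b) != nrow(K))
    stop("wavelet operator sizes do not match the system")
  Kp <- matrix(0, W_b$n_pad, W_x$n_pad)
  Kp[seq_len(nrow(K)), seq_len(ncol(K))] <- K
  Khat <- W_b$W %*% Kp %*% t(W_x$W)
  bhat <- apply_wavelet(W_b, b)
  n1 <- W_b$n1
  list(K1 = Khat[seq_len(n1), seq_len(W_x$n1), drop = FALSE],
       b1 = bhat[seq_len(n1)], Khat = Khat, bhat = bhat)
}

#' PCA reduction of the compressed approximation block
#'
#' Covariance of K1's columns about their mean (`L = mean over columns of
#' (col - colmean)(col - colmean)^T`), eigendecomposition `L = Psi Lambda
#' Psi^T` with eigenvalues descending, and projection of the *uncentered*
#' system onto the leading q eigenvectors: `Kq = Psi_q^T K1`,
#' `bq = Psi_q^T b1`.
#'
#' @param K1 approximation block (n1 x n1).
#' @param b1 approximation right-hand side (length n1).
#' @param energy_fraction retain the smallest q whose eigenvalue mass
#'   reaches this fraction (in (0, 1\]); `1.0` retains all nonzero
#'   eigenvalues.
#' @param q explicit retained count (overrides `energy_fraction`).
#' @return A `fmt_pca` list: `L`, `eigenvalues`, `eigenvectors`, `q`,
#'   `Kq`, `bq`.
#' @export
pca_reduce <- function(K1, b1, energy_fraction = 0.95, q = NULL) {
  n1 <- nrow(K1)
  mu <- rowMeans(K1)
  dev <- K1 - mu
  L <- tcrossprod(dev) / n1
  ed <- eigen(L, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  tot <- sum(lam)
  if (is.null(q)) {
    if (tot <= n1 * 1e-300) {
      warning("compressed block has zero variance; retaining q = 1")
      q <- 1L
    } else if (energy_fraction >= 1) {
      q <- max(1L, sum(lam > 1e-12 * lam[1L]))
    } else {
      if (energy_fraction <= 0) stop("energy_fraction must be in (0, 1]")
      q <- which(cumsum(lam) / tot >= energy_fraction)[1L]
    }
  }
  q <- as.integer(min(max(q, 1L), n1))
  Psi_q <- ed$vectors[, seq_len(q), drop = FALSE]
  structure(list(L = L, eigenvalues = ed$values, eigenvectors = ed$vectors,
                 q = q, Kq = crossprod(Psi_q, K1),
                 bq = drop(crossprod(Psi_q, b1))),
            class = "fmt_pca")
}

#' Minimum-norm least-squares solution of the reduced system
#'
#' Solves the q x n1 system `Kq dx = bq` by SVD pseudo-inverse.
#'
#' @param reduction a `fmt_pca` from [pca_reduce()].
#' @return The length-n1 minimum-norm solution.
#' @export
solve_reduced <- function(reduction) {
  Kq <- reduction$Kq; bq <- reduction$bq
  if (all(Kq == 0) && sqrt(sum(bq^2)) > 0)
    stop("reduced system is inconsistent: Kq = 0 but bq != 0")
  pinv_solve(Kq, bq)
}

# Minimum-norm least-squares solve via SVD pseudo-inverse.
pinv_solve <- function(A, b) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(numeric(ncol(A)))
  drop(sv$v[, pos, drop = FALSE] %*%
         (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos]))
}

#' Conjugate gradients for symmetric positive-definite systems
#'
#' @param K SPD matrix.
#' @param b right-hand side.
#' @param x0 initial iterate (defaults to zero).
#' @param tol relative-residual tolerance.
#' @param maxit iteration cap.
#' @return list(x, iterations, converged, relative_residual).
#' @export
cg_solve <- function(K, b, x0 = NULL, tol = 1e-8, maxit = 10L * length(b)) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(length(b)), iterations = 0L,
                           converged = TRUE, relative_residual = 0))
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - drop(K %*% x)
  p <- r
  rs <- sum(r * r)
  it <- 0L
  while (sqrt(rs) / nb > tol && it < maxit) {
    Kp <- drop(K %*% p)
    a <- rs / sum(p * Kp)
    x <- x + a * p
    r <- r - a * Kp
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  rel <- sqrt(sum((b - drop(K %*% x))^2)) / nb
  list(x = x, iterations = it, converged = rel <= tol,
       relative_residual = rel)
}

#' Accelerated solve of the normal equations (wavelet + PCA + warm start)
#'
#' The four steps of the accelerated linear solver: (1) wavelet-compress
#' (K, b) and keep the approximation block; (2) solve the block with PCA
#' reduction (minimum-norm least squares); (3) prolongate by zero-padding
#' the detail half; (4) inverse-transform to obtain the initial guess and
#' finish with conjugate gradients on the full system `K dx = b`.
#'
#' @param K normal matrix from [normal_system()].
#' @param b right-hand side.
#' @param config list of settings: `wavelet_family`, `wavelet_level`,
#'   `pca_energy`, `pca_q`, `cg_tol`, `maxiter_factor`.
#' @return list(x, iterations, converged, warm_start, q).
#' @export
algorithm1_solve <- function(K, b, config = list()) {
  cf <- utils::modifyList(list(wavelet_family = "haar", wavelet_level = 1L,
                               pca_energy = 0.95, pca_q = NULL,
                               cg_tol = 1e-8, maxiter_factor = 10L), config)
  n <- length(b)
  W <- wavelet_operator(n, cf$wavelet_family, cf$wavelet_level)
  cs <- compress_system(K, b, W, W)
  red <- pca_reduce(cs$K1, cs$b1, energy_fraction = cf$pca_energy,
                    q = cf$pca_q)
  dx1 <- solve_reduced(red)
  dxhat0 <- c(dx1, numeric(W$n_pad - W$n1))
  dx0 <- drop(t(W$W) %*% dxhat0)[seq_len(n)]
  out <- cg_solve(K, b, x0 = dx0, tol = cf$cg_tol,
                  maxit = cf$maxiter_factor * n)
  if (!out$converged)
    warning(sprintf("CG stopped at iteration cap (relative residual %.2e)",
                    out$relative_residual))
  list(x = out$x, iterations = out$iterations, converged = out$converged,
       warm_start = dx0, q = red$q)
}

#' Solve one linearized update with the selected method variant
#'
#' `proposed` = wavelet + PCA + warm-started CG ([algorithm1_solve()]);
#' `conventional` = direct Cholesky ([tikhonov_solve()]); `wavelet_only` =
#' wavelet compression with a direct solve of the approximation block (no
#' PCA) then warm-started CG; `pca_only` = PCA reduction of the full system
#' (no wavelet) then warm-started CG.
#'
#' @inheritParams algorithm1_solve
#' @param variant one of `"proposed"`, `"conventional"`, `"wavelet_only"`,
#'   `"pca_only"`.
#' @return list(x, iterations, q) (`iterations`/`q` NA where not relevant).
#' @export
solve_update <- function(K, b, variant = "proposed", config = list()) {
  cf <- utils::modifyList(list(wavelet_family = "haar", wavelet_level = 1L,
                               pca_energy = 0.95, pca_q = NULL,
                               cg_tol = 1e-8, maxiter_factor = 10L), config)
  n <- length(b)
  switch(variant,
    proposed = {
      out <- algorithm1_solve(K, b, cf)
      list(x = out$x, iterations = out$iterations, q = out$q)
    },
    conventional = list(x = tikhonov_solve(K, b), iterations = NA_integer_,
                        q = NA_integer_),
    wavelet_only = {
      W <- wavelet_operator(n, cf$wavelet_family, cf$wavelet_level)
      cs <- compress_system(K, b, W, W)
      # zero-padding can make the approximation block rank-deficient, so a
      # minimum-norm least-squares solve is used throughout
      dx1 <- pinv_solve(cs$K1, cs$b1)
      dx0 <- drop(t(W$W) %*% c(dx1, numeric(W$n_pad - W$n1)))[seq_len(n)]
      out <- cg_solve(K, b, x0 = dx0, tol = cf$cg_tol,
                      maxit = cf$maxiter_factor * n)
      list(x = out$x, iterations = out$iterations, q = NA_integer_)
    },
    pca_only = {
      red <- pca_reduce(K, b, energy_fraction = cf$pca_energy, q = cf$pca_q)
      dx0 <- solve_reduced(red)
      out <- cg_solve(K, b, x0 = dx0, tol = cf$cg_tol,
                      maxit = cf$maxiter_factor * n)
      list(x = out$x, iterations = out$iterations, q = red$q)
    },
    stop("unknown variant '", variant,
         "'; allowed: proposed, conventional, wavelet_only, pca_only")
  )
}
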