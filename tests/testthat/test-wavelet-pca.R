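test_that("wavelet operators are orthonormal and reproduce the hand Haar transform", {
  W <- wavelet_operator(4, "haar", 1)
  expect_equal(apply_wavelet(W, c(4, 2, 6, 0)),
               c(6, 6, 2, 6) / sqrt(2), tolerance = 1e-12)
  for (fam in c("haar", "db2", "db4")) {
    for (lev in 1:2) {
      op <- wavelet_operator(37, fam, lev)
      expect_lt(max(abs(op$W %*% t(op$W) - diag(op$n_pad))), 1e-12)
      expect_equal(op$n1, op$n_pad / 2^lev)
    }
  }
  # vanishing moment: constant vector has zero detail coefficients
  op <- wavelet_operator(16, "haar", 1)
  w <- apply_wavelet(op, rep(3, 16))
  expect_lt(max(abs(w[(op$n1 + 1):op$n_pad])), 1e-12)
  expect_error(wavelet_operator(16, "sym5", 1), "unsupported")
})

test_that("wavelet compression preserves structure and energy", {
  W <- wavelet_operator(8, "haar", 1)
  cs <- compress_system(diag(8), rep(2, 8), W)
  expect_equal(cs$K1, diag(4), tolerance = 1e-12)   # orthonormal similarity
  expect_equal(cs$b1, rep(2 * sqrt(2), 4), tolerance = 1e-12)
  expect_lt(max(abs(cs$bhat[5:8])), 1e-12)          # constant: no detail
  set.seed(5)
  K <- matrix(rnorm(100), 10, 10)
  W10 <- wavelet_operator(10, "db2", 1)
  cs2 <- compress_system(K, rnorm(10), W10)
  Kp <- matrix(0, 16, 16); Kp[1:10, 1:10] <- K
  expect_equal(norm(cs2$Khat, "F"), norm(Kp, "F"), tolerance = 1e-10)
  expect_error(compress_system(K, rnorm(10), wavelet_operator(8, "haar", 1)),
               "do not match")
})

test_that("PCA reduction reproduces the hand-worked covariance example", {
  red <- pca_reduce(matrix(c(2, 0, 0, 1), 2, 2), c(1, 1), q = 1)
  expect_equal(red$L, rbind(c(1, -0.5), c(-0.5, 0.25)), tolerance = 1e-14)
  expect_equal(red$eigenvalues, c(1.25, 0), tolerance = 1e-12)
  v <- red$eigenvectors[, 1]
  expect_equal(abs(v / sqrt(sum(v^2))), abs(c(2, -1) / sqrt(5)),
               tolerance = 1e-12)
})

test_that("PCA respects the energy criterion and full retention is a rotation", {
  set.seed(9)
  J <- matrix(rnorm(300), 30, 10)
  K1 <- crossprod(J) + 0.01 * diag(10)
  b1 <- rnorm(10)
  red <- pca_reduce(K1, b1, energy_fraction = 0.9)
  expect_true(all(diff(red$eigenvalues) <= 1e-12))
  lam <- pmax(red$eigenvalues, 0)
  expect_gte(sum(lam[seq_len(red$q)]) / sum(lam), 0.9)
  # q = n1: orthogonal rotation, reduced solve equals direct solve
  redf <- pca_reduce(K1, b1, q = 10)
  expect_rel_equal(solve_reduced(redf), solve(K1, b1), 1e-10)
  # energy_fraction = 1 retains exactly the nonzero spectrum
  K_rank2 <- tcrossprod(matrix(rnorm(20), 10, 2)) # covariance rank <= 2
  red1 <- pca_reduce(K_rank2, rnorm(10), energy_fraction = 1)
  expect_equal(red1$q, sum(red1$eigenvalues > 1e-12 * red1$eigenvalues[1]))
  expect_warning(pca_reduce(matrix(1, 4, 4) * 0, numeric(4),
                            energy_fraction = 0.9), "zero variance")
})

test_that("the reduced solve is the minimum-norm least-squares solution", {
  red <- structure(list(Kq = matrix(c(1, 1), 1, 2), bq = 2,
                        q = 1L), class = "fmt_pca")
  expect_equal(solve_reduced(red), c(1, 1), tolerance = 1e-12)
  red0 <- structure(list(Kq = matrix(0, 1, 2), bq = 0, q = 1L),
                    class = "fmt_pca")
  expect_equal(solve_reduced(red0), c(0, 0))
  red_bad <- structure(list(Kq = matrix(0, 1, 2), bq = 1, q = 1L),
                       class = "fmt_pca")
  expect_error(solve_reduced(red_bad), "inconsistent")
})

test_that("the accelerated solver reaches the direct solution of the normal equations", {
  set.seed(21)
  n <- 40
  J <- matrix(rnorm(200 * n), 200, n)
  K <- crossprod(J) + 1e-3 * diag(n)
  b <- drop(K %*% sin(seq_len(n) / 5))
  ref <- solve(K, b)
  expect_equal(algorithm1_solve(diag(6), 1:6)$x, 1:6, tolerance = 1e-12)
  a1 <- algorithm1_solve(K, b)
  expect_lt(sqrt(sum((K %*% a1$x - b)^2)) / sqrt(sum(b^2)), 1e-8)
  expect_rel_equal(a1$x, ref, 1e-6)
  for (v in c("conventional", "wavelet_only", "pca_only"))
    expect_rel_equal(solve_update(K, b, v)$x, ref, 1e-6)
  expect_error(solve_update(K, b, "magic"), "unknown variant")
})

test_that("the wavelet-PCA warm start saves CG iterations on compressible systems", {
  set.seed(33)
  n <- 64
  wins <- 0L
  for (trial in 1:50) {
    # wavelet-compressible structure: smoothing-kernel SPD matrix and a
    # smooth solution, so the approximation block carries most energy
    ell <- runif(1, 3, 8)
    G <- outer(seq_len(n), seq_len(n), function(i, j) exp(-((i - j) / ell)^2))
    K <- 0.5 * diag(n) + G
    x_true <- sin(seq_len(n) / 8 + trial) + 1
    b <- drop(K %*% x_true)
    W <- wavelet_operator(n, "haar", 1)
    cs <- compress_system(K, b, W)
    red <- pca_reduce(cs$K1, cs$b1, energy_fraction = 0.95)
    x0 <- drop(t(W$W) %*% c(solve_reduced(red),
                            numeric(W$n_pad - W$n1)))[seq_len(n)]
    warm <- cg_solve(K, b, x0 = x0, tol = 1e-8)
    cold <- cg_solve(K, b, tol = 1e-8)
    if (warm$iterations <= cold$iterations) wins <- wins + 1L
  }
  expect_gte(wins, 45L)  # >= 90 % of trials
})
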