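test_that("derived coefficients match hand-evaluated values", {
  m <- unit_triangle_mesh()
  p <- bg_props(m)
  co <- derive_coefficients(p, 0)
  expect_equal(co$D_x[1], 1 / (3 * 4.09), tolerance = 1e-12)   # 0.08150 mm
  expect_equal(co$k_x[1], 0.09, tolerance = 1e-12)
  expect_equal(co$robin_b_x, 0.5, tolerance = 1e-15)

  # inclusion values: alpha real at CW, reduced in modulus at 100 MHz
  pi_ <- tissue_properties(m, 0.03, 0.4, 4, 0.02, 0.2, 3, 0.2, 0.6)
  expect_equal(derive_coefficients(pi_, 0)$alpha[1], 0.08, tolerance = 1e-12)
  a100 <- derive_coefficients(pi_, 2 * pi * 1e8)$alpha[1]
  expect_equal(Mod(a100), 0.08 / sqrt(1 + (2 * pi * 0.1 * 0.6)^2),
               tolerance = 1e-6)
  expect_equal(Mod(a100), 0.07486, tolerance = 1e-4)

  # degenerate attenuation is refused with the node named
  pz <- p; pz$mu_axi[2] <- 0; pz$mu_axf[2] <- 0; pz$mu_sx_prime[2] <- 0
  expect_error(derive_coefficients(pz, 0), "node 2")
})

test_that("P1 element matrices match symbolic integration on the unit triangle", {
  m <- unit_triangle_mesh()
  K <- as.matrix(parts_to_sparse(stiffness_parts(m, rep(1, 3))))
  expect_equal(K, rbind(c(1, -0.5, -0.5), c(-0.5, 0.5, 0), c(-0.5, 0, 0.5)),
               tolerance = 1e-14)
  M <- as.matrix(parts_to_sparse(mass_matrix_parts(m, rep(1, 3))))
  expect_equal(M, rbind(c(2, 1, 1), c(1, 2, 1), c(1, 1, 2)) / 24,
               tolerance = 1e-14)
  # a single boundary edge (0,0)-(1,0) with b = 1: [[1/3,1/6],[1/6,1/3]]
  m1 <- m; m1$boundary_facets <- rbind(c(1L, 2L))
  B <- as.matrix(parts_to_sparse(boundary_parts(m1, rep(1, 3))))
  expect_equal(B[1:2, 1:2], rbind(c(1/3, 1/6), c(1/6, 1/3)),
               tolerance = 1e-14)
  # assembled A = D + K + B
  co <- derive_coefficients(bg_props(m), 0)
  A <- assemble_system(m, co, "x")
  ref <- co$D_x[1] * K + co$k_x[1] * M * 24 / 24 +
    co$robin_b_x * as.matrix(parts_to_sparse(boundary_parts(m, rep(1, 3))))
  expect_lt(max(abs(as.matrix(A$Ar) - ref)), 1e-13)
})

test_that("point-source load vectors are a partition of unity", {
  m <- small_disc()
  s <- source_vector(m, c(1.1, 0.4), amplitude = 2.5)
  expect_equal(sum(s), 2.5, tolerance = 1e-12)
  expect_lte(sum(s != 0), m$dimension + 1)
  expect_identical(source_vector(m, c(1, 1), amplitude = 0), numeric(m$N))
  # a source exactly at a node loads only that node
  v <- 11L
  sv <- source_vector(m, m$nodes[v, ], amplitude = 1)
  expect_equal(sv[v], 1, tolerance = 1e-9)
  expect_error(source_vector(m, c(50, 50)), "placement")
})

test_that("assembled systems are symmetric, SPD at CW, complex-symmetric when modulated", {
  m <- small_disc()
  co <- derive_coefficients(bg_props(m), 0)
  A <- as.matrix(assemble_system(m, co, "x")$Ar)
  expect_lt(max(abs(A - t(A))), 1e-12 * max(abs(A)))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), 0)

  co2 <- derive_coefficients(bg_props(m), 2 * pi * 1e8)
  sys2 <- assemble_system(m, co2, "m")
  expect_false(is.null(sys2$Ai))
  expect_lt(max(abs(as.matrix(sys2$Ai) - t(as.matrix(sys2$Ai)))),
            1e-12 * max(abs(as.matrix(sys2$Ai))))
})

test_that("field solves satisfy the residual contract and basic physics", {
  m <- small_disc()
  co <- derive_coefficients(bg_props(m), 0)
  sys <- assemble_system(m, co, "x")
  expect_identical(solve_system(sys, numeric(m$N)), numeric(m$N))
  s <- source_vector(m, c(0.5, 0))
  phi <- solve_system(sys, s)
  expect_lt(sqrt(sum((as.vector(sys$Ar %*% phi) - s)^2)) / sqrt(sum(s^2)),
            1e-10)
  # positivity and radial decay in the resolved diffusive regime
  # (one transport mean free path per element)
  md <- build_disc_mesh(10, 1)
  pd <- tissue_properties(md, 0.005, 0.005, 1, 0.005, 0.005, 1, 0.2, 0.6)
  sysd <- assemble_system(md, derive_coefficients(pd, 0), "x")
  phid <- solve_system(sysd, source_vector(md, c(0, 0)))
  expect_true(all(phid > 0))
  r <- sqrt(rowSums(md$nodes^2))
  ord <- order(r)
  interior <- r[ord] > 1 & r[ord] < 9
  expect_lt(stats::cor(r[ord][interior], phid[ord][interior]), -0.9)
})

test_that("the emission field is linear in the fluorescence source", {
  st <- small_setup_2d()
  y0 <- forward_map(st$mesh, bg_props(st$mesh, eta = 0), st$sources,
                    st$detectors)
  expect_identical(y0, rep(0, 8))
  y1 <- forward_map(st$mesh, bg_props(st$mesh, eta = 0.1), st$sources,
                    st$detectors)
  y2 <- forward_map(st$mesh, bg_props(st$mesh, eta = 0.2), st$sources,
                    st$detectors)
  expect_rel_equal(y2, 2 * y1, 1e-12)
  # linearity in source amplitude
  s2 <- st$sources; s2$amplitude <- rep(2, length(s2$amplitude))
  ya <- forward_map(st$mesh, bg_props(st$mesh), s2, st$detectors)
  yb <- forward_map(st$mesh, bg_props(st$mesh), st$sources, st$detectors)
  expect_rel_equal(ya, 2 * yb, 1e-12)
})

test_that("permuting detectors permutes the measurement vector identically", {
  st <- small_setup_2d()
  y <- forward_map(st$mesh, st$props, st$sources, st$detectors)
  perm <- c(3, 1, 4, 2)
  det2 <- detector_set(st$detectors$angles_deg[perm])
  y2 <- forward_map(st$mesh, st$props, st$sources, det2)
  ord <- as.vector(outer(perm, (0:1) * 4, `+`))
  expect_equal(y2, y[ord], tolerance = 1e-14)
})

test_that("single-band measurements are reciprocal at CW", {
  m <- small_disc()
  co <- derive_coefficients(bg_props(m), 0)
  sys <- assemble_system(m, co, "x")
  p <- 8L; q <- 17L
  sp <- numeric(m$N); sp[p] <- 1
  sq <- numeric(m$N); sq[q] <- 1
  phi_p <- solve_system(sys, sp)
  phi_q <- solve_system(sys, sq)
  expect_equal(phi_p[q], phi_q[p], tolerance = 1e-8 * abs(phi_p[q]))
})

test_that("boundary fluence converges under mesh refinement", {
  p_at <- function(edge) {
    m <- build_disc_mesh(10, edge)
    pr <- bg_props(m)
    y <- forward_map(m, pr, uniform_sources(1), uniform_detectors(4))
    y[3]  # detector opposite the source
  }
  v <- vapply(c(4, 2, 1, 0.5), p_at, numeric(1))
  d <- abs(diff(v))
  expect_true(all(diff(d) < 0))  # differences shrink monotonically
})
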