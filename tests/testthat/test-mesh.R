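test_that("disc meshes cover the disc with boundary nodes on the circle", {
  m <- build_disc_mesh(25, 5)
  area <- sum(signed_measure(m$nodes, m$elements))
  expect_lt(abs(area - pi * 25^2) / (pi * 25^2), 0.02)
  expect_true(all(signed_measure(m$nodes, m$elements) > 0))

  m1 <- build_disc_mesh(1, 0.5)
  bn <- unique(as.vector(m1$boundary_facets))
  expect_lt(max(abs(sqrt(rowSums(m1$nodes[bn, ]^2)) - 1)), 1e-9)

  expect_gt(build_disc_mesh(25, 3)$N, build_disc_mesh(25, 6)$N)
  expect_error(build_disc_mesh(-1, 0.5), "invalid parameter")
  expect_error(build_disc_mesh(10, 20), "invalid parameter")
})

test_that("cylinder meshes are conforming, positively oriented and at the 3D study scale", {
  cy <- build_cylinder_mesh(10, 40, 4)
  vol <- sum(signed_measure(cy$nodes, cy$elements))
  expect_lt(abs(vol - pi * 100 * 40) / (pi * 100 * 40), 0.03)
  expect_true(all(signed_measure(cy$nodes, cy$elements) > 0))
  # every facet belongs to one element (boundary) or exactly two (interior)
  counts <- table(facet_keys(all_facets(cy$elements)[, 1:3]))
  expect_true(all(counts <= 2))
  expect_equal(sum(counts == 1), nrow(cy$boundary_facets))
  # boundary facets partition into lateral wall, bottom (z=0), top (z=40)
  fz <- matrix(cy$nodes[cy$boundary_facets, 3], ncol = 3)
  on_bottom <- rowSums(fz == 0) == 3L
  on_top <- rowSums(fz == 40) == 3L
  fb <- cy$boundary_facets[!(on_bottom | on_top), ]
  rads <- sqrt(rowSums(cy$nodes[as.vector(fb), 1:2]^2))
  expect_lt(max(abs(rads - 10)), 1e-9)

  # a tuned edge reproduces the reference 3D mesh scale within a factor of 2
  cy2 <- build_cylinder_mesh(10, 40, 2.5)
  expect_lt(abs(log2(cy2$N / 858)), 1)
  expect_lt(abs(log2(cy2$P / 3208)), 1)
})

test_that("adaptive refinement concentrates nodes in the prior without moving old ones", {
  m <- build_disc_mesh(10, 2)
  pr <- prior_image(list(list(center = c(4, 0), radius = 2.5)),
                    dilation_mm = 2)
  r <- adaptive_refine(m, pr, 180)
  expect_gt(r$N, m$N)
  expect_lte(r$N, 180)
  # nested nodes: original coordinates unchanged
  expect_identical(r$nodes[seq_len(m$N), ], m$nodes)
  # total area invariant
  expect_lt(abs(sum(signed_measure(r$nodes, r$elements)) -
                  sum(signed_measure(m$nodes, m$elements))),
            1e-12 * 100 * pi)
  # conforming after refinement
  counts <- table(facet_keys(all_facets(r$elements)[, 1:2]))
  expect_true(all(counts <= 2))
  # element density higher inside the prior than outside
  cent <- element_centroids(r$nodes, r$elements)
  ins <- points_in_prior(cent, pr)
  a <- signed_measure(r$nodes, r$elements)
  expect_lt(mean(a[ins]), mean(a[!ins]))

  # empty prior: unchanged; exhausted budget: warning, unchanged
  expect_identical(adaptive_refine(m, prior_image(list()), 500)$elements,
                   m$elements)
  expect_warning(same <- adaptive_refine(m, pr, m$N), "unchanged")
  expect_identical(same$nodes, m$nodes)
})

test_that("two-region priors attract refinement into both regions", {
  m <- build_disc_mesh(10, 2.5)
  pr <- prior_image(list(list(center = c(-4, 2), radius = 2.5),
                         list(center = c(4, -2), radius = 2.5)),
                    dilation_mm = 2)
  r <- adaptive_refine(m, pr, 148)
  new_nodes <- r$nodes[(m$N + 1):r$N, , drop = FALSE]
  in1 <- sqrt(rowSums(sweep(new_nodes, 2, c(-4, 2))^2)) <= 5.5
  in2 <- sqrt(rowSums(sweep(new_nodes, 2, c(4, -2))^2)) <= 5.5
  expect_gt(sum(in1), 0)
  expect_gt(sum(in2), 0)
})

test_that("point location returns exact barycentric coordinates", {
  m <- small_disc()
  # centroid of an element -> equal weights
  e <- 7L
  cent <- colMeans(m$nodes[m$elements[e, ], ])
  loc <- locate_point(m, cent)
  expect_equal(sort(m$elements[loc$element, ]), sort(m$elements[e, ]))
  expect_equal(loc$weights, rep(1 / 3, 3), tolerance = 1e-12)
  # a vertex -> unit weight on that vertex
  v <- m$elements[3L, 2L]
  locv <- locate_point(m, m$nodes[v, ])
  expect_equal(max(locv$weights), 1, tolerance = 1e-9)
  expect_equal(m$elements[locv$element, which.max(locv$weights)], v)
  # random interior points reproduce themselves through the weights
  set.seed(42)
  for (i in 1:20) {
    r <- 4.5 * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
    p <- c(r * cos(a), r * sin(a))
    l <- locate_point(m, p)
    rec <- drop(crossprod(l$weights, m$nodes[m$elements[l$element, ], ]))
    expect_lt(max(abs(rec - p)), 1e-9)
  }
  expect_error(locate_point(m, c(100, 100)), "not found")
})
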