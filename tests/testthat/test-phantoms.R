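test_that("built-in phantoms carry the tabulated optical parameters", {
  p1 <- phantom_one_inclusion()
  expect_equal(p1$inclusions[[1]]$mu_axf, 0.4)
  expect_equal(p1$inclusions[[1]]$mu_amf, 0.2)
  expect_equal(p1$background$mu_axf, 0.06)
  expect_equal(p1$background$mu_amf, 0.005)
  expect_equal(p1$background$mu_axi, 0.03)
  expect_equal(p1$background$mu_sx_prime, 4.0)
  expect_equal(p1$background$mu_sm_prime, 3.0)
  expect_equal(p1$background$eta, 0.2)
  expect_equal(p1$background$tau, 0.6)

  p2 <- phantom_two_inclusion()
  expect_equal(sort(vapply(p2$inclusions, `[[`, 1, "mu_axf")), c(0.3, 0.4))
  expect_equal(sort(vapply(p2$inclusions, `[[`, 1, "mu_amf")), c(0.02, 0.03))
  expect_equal(p2$background$mu_amf, 0.003)
  expect_length(p2$inclusions, 2)

  p3 <- phantom_cylinder_3d()
  expect_equal(p3$geometry$radius, 10)
  expect_equal(p3$geometry$height, 40)
  expect_equal(p3$background$mu_axf, 0.005)
  expect_equal(p3$inclusions[[1]]$mu_axf, 0.01)
  expect_equal(p3$inclusions[[1]]$center, c(5, 0, 20))
  expect_equal(p3$inclusions[[1]]$radius, 2)
  expect_equal(p3$inclusions[[1]]$height, 6)
  expect_equal(p3$measurement_planes, c(15, 20, 25))
})

test_that("rasterization assigns inclusion overrides exactly and consistently", {
  ph <- phantom_one_inclusion()
  mesh <- phantom_mesh(ph, 2)
  ras <- rasterize_phantom(ph, mesh)
  ctr <- locate_point(mesh, ph$inclusions[[1]]$center)
  near <- mesh$elements[ctr$element, which.max(ctr$weights)]
  expect_equal(ras$x_act[near], 0.4)
  far <- which.min(mesh$nodes[, 1])  # boundary node opposite the inclusion
  expect_equal(ras$x_act[far], 0.06)
  expect_equal(ras$props$mu_amf[near], 0.2)
  # inclusion node count is geometrically consistent with the disc areas
  frac <- mean(ras$x_act > 0.06)
  expect_lt(abs(frac - (2.5 / 10)^2) / (2.5 / 10)^2, 0.6)
  # refinement never changes the value at a pre-existing node
  fine <- adaptive_refine(mesh, prior_from_phantom(ph, 2), mesh$N + 40)
  ras2 <- rasterize_phantom(ph, fine)
  expect_identical(ras2$x_act[seq_len(mesh$N)], ras$x_act)
})

test_that("measurement noise realizes the requested SNR deterministically", {
  set.seed(1)
  y <- runif(200, 0.5, 1.5)
  # global mode: one sigma = rms * 10^(-snr/20)
  reps <- vapply(1:300, function(s) {
    n <- add_noise(y, 10, seed = s, mode = "global") - y
    sqrt(mean(n^2))
  }, numeric(1))
  expect_lt(abs(mean(reps) / (sqrt(mean(y^2)) * 10^(-0.5)) - 1), 0.03)
  # relative mode: aggregate rms(noise)/rms(y) matches the same ratio
  reps2 <- vapply(1:1000, function(s) {
    n <- add_noise(y, 10, seed = s) - y
    sqrt(mean(n^2)) / sqrt(mean(y^2))
  }, numeric(1))
  expect_lt(abs(mean(reps2) / 10^(-0.5) - 1), 0.03)
  # determinism and seed sensitivity
  expect_identical(add_noise(y, 10, seed = 7), add_noise(y, 10, seed = 7))
  expect_false(identical(add_noise(y, 10, seed = 7),
                         add_noise(y, 10, seed = 8)))
  expect_identical(add_noise(y, Inf, seed = 1), y)
  expect_error(add_noise(numeric(5), 10, 1), "all-zero")
})

test_that("the MSE metric matches its definition and scales quadratically", {
  expect_equal(mse(c(0.1, 0.2), c(0.1, 0.1)), 0.005)
  expect_equal(mse(1:5, 1:5), 0)
  x <- runif(10); y <- runif(10)
  expect_equal(mse(3 * x, 3 * y), 9 * mse(x, y), tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), "lengths differ")
})

test_that("priors copy the inclusion geometry with the requested dilation", {
  ph <- phantom_two_inclusion()
  pr0 <- prior_from_phantom(ph, 0)
  expect_length(pr0$regions, 2)
  expect_equal(pr0$regions[[1]]$radius, ph$inclusions[[1]]$radius)
  pr2 <- prior_from_phantom(ph, 2)
  expect_equal(pr2$dilation_mm, 2)
  pts <- rbind(ph$inclusions[[1]]$center +
                 c(ph$inclusions[[1]]$radius + 1.5, 0))
  expect_true(points_in_prior(pts, pr2))
  expect_false(points_in_prior(pts, pr0))
})

test_that("phantoms round-trip through JSON bit-exactly", {
  for (ph in list(phantom_one_inclusion(), phantom_two_inclusion(),
                  phantom_cylinder_3d())) {
    f <- tempfile(fileext = ".json")
    write_phantom_json(ph, f)
    ph2 <- read_phantom_json(f)
    expect_identical(ph2$background, ph$background)
    expect_identical(ph2$geometry$radius, ph$geometry$radius)
    for (i in seq_along(ph$inclusions)) {
      expect_identical(ph2$inclusions[[i]]$center, ph$inclusions[[i]]$center)
      expect_identical(ph2$inclusions[[i]]$mu_axf, ph$inclusions[[i]]$mu_axf)
    }
    unlink(f)
  }
})
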