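# Shared fixtures, all built in code.

unit_triangle_mesh <- function() {
  fmt_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), rbind(1:3))
}

small_disc <- function(radius = 5, edge = 2) build_disc_mesh(radius, edge)

small_cylinder <- function() build_cylinder_mesh(3, 6, 2.5)

# Homogeneous property set at the standard background values.
bg_props <- function(mesh, mu_axf = 0.06, eta = 0.2) {
  tissue_properties(mesh, mu_axi = 0.03, mu_axf = mu_axf, mu_sx_prime = 4,
                    mu_ami = 0.02, mu_amf = 0.005, mu_sm_prime = 3,
                    eta = eta, tau = 0.6)
}

# Small 2D forward setup used across sensitivity tests.
small_setup_2d <- function() {
  mesh <- small_disc()
  list(mesh = mesh, props = bg_props(mesh),
       sources = uniform_sources(2), detectors = uniform_detectors(4))
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-300), tol)
}
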