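# fmtrecon

Finite-element forward modelling and accelerated inverse reconstruction for
**fluorescence molecular tomography (FMT)** — recovering the spatial map of
the fluorophore absorption coefficient μ_axf inside tissue from emission
fluence measured at the boundary. It is written for people who study FMT /
diffuse-optical reconstruction algorithms on simulated phantoms.

## The model and the method

Light transport is the coupled frequency-domain diffusion model

    −∇·(D_x ∇Φ_x) + k_x Φ_x = S_x
    −∇·(D_m ∇Φ_m) + k_m Φ_m = α Φ_x,    α = η μ_axf / (1 − iωτ)

with Robin boundary conditions Φ + 2AD ∂Φ/∂n = 0, discretized with P1
finite elements on triangle/tetrahedral meshes. The inverse problem is the
Tikhonov-regularized linearization

    K Δx = b,   K = JᵀJ + ξI,   b = JᵀΔy

with the Jacobian J assembled by the adjoint method. Two ideas accelerate
and stabilize the iteration:

1. **Wavelet–PCA compression of the normal equations.** One level of an
   orthonormal wavelet transform compresses (K, b); the approximation block
   is further reduced by PCA onto its leading covariance eigenvectors, the
   reduced system is solved, and the zero-padded, back-transformed solution
   warm-starts a conjugate-gradient solve of the full system. The fixed
   point equals the direct solution; only the path to it is cheaper.
2. **Rotated-source illumination.** Each outer iteration rotates the
   excitation-source ring by half the inter-source angle (45° for four
   sources), so successive linearizations see measurement configurations
   with new information at no extra per-iteration cost.

Built-in generators produce the standard study phantoms (one- and
two-inclusion discs, a 3D cylinder with a small cylindrical inclusion),
structured meshes with prior-guided conforming longest-edge refinement,
Gmsh/VTK mesh I/O, per-measurement Gaussian noise at a configurable SNR,
and the nodal mean-square-error metric.

## Worked example

Noiseless recovery of the one-inclusion disc phantom (radius 10 mm,
inclusion μ_axf = 0.4 mm⁻¹ of radius 2.5 mm at (4, 0) mm, background
0.06 mm⁻¹), 4 sources, 30 detectors:

```r
library(fmtrecon)
ph   <- phantom_one_inclusion()
mesh <- phantom_mesh(ph, 2.5, node_budget = 122)   # 85 nodes, 144 triangles
ras  <- rasterize_phantom(ph, mesh)
src  <- uniform_sources(4); det <- uniform_detectors(30)
data <- simulated_measurements(ph, mesh, src, det, snr_db = Inf)
bg   <- ras$props; bg$mu_axf <- rep(0.06, mesh$N)
res  <- reconstruct(mesh, bg, src, det, data,
                    recon_config(xi = 1e-4, delta = 1e-9,
                                 max_outer_iters = 400,
                                 sens_clip = 0.05, whiten_floor = 0.01),
                    x_truth = ras$x_act)
```

which prints (via `mse()` against the truth map):

```
initial MSE: 0.00816
final MSE:   0.000667
peak mu_axf: 0.401 at (5, 0) mm
```

— a twelvefold error reduction with the recovered maximum inside the true
inclusion and at the true contrast. At the study noise level (10 dB) the
method comparison is run with `run_bench()`:

```r
bench <- run_bench(study_config("one_inclusion_2d"),
                   c("proposed", "conventional"), seeds = 1:5)
aggregate(mse ~ variant, bench, median)
#        variant        mse
# 1 conventional 0.01265591
# 2     proposed 0.01016986
```

the rotated-source wavelet-PCA method attains the lower median nodal MSE.
A thin command-line driver (`inst/cli/fmtrecon`) exposes the same pipeline
as `simulate`, `reconstruct`, `evaluate` and `bench` subcommands over YAML
configs, CSV measurement files and JSON results.

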