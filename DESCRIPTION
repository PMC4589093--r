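Package: fmtrecon
Title: Fluorescence Molecular Tomography Reconstruction with Wavelet-PCA
    Compression and Rotated-Source Illumination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-element forward modelling and regularized inverse
    reconstruction for fluorescence molecular tomography (FMT). Solves the
    coupled frequency-domain diffusion equations for excitation and emission
    photon fluence on simplicial meshes (triangles in 2D, tetrahedra in 3D)
    with Robin boundary conditions, computes adjoint Jacobians of boundary
    measurements with respect to the nodal fluorophore absorption map, and
    inverts the Tikhonov normal equations. The accelerated solver compresses
    the normal equations with an orthonormal wavelet transform, reduces the
    approximation block by principal component analysis, and warm-starts a
    conjugate-gradient solve from the prolongated reduced solution. The outer
    iteration rotates the excitation sources by half the inter-source angle
    each pass. Includes built-in phantoms, mesh generators with prior-guided
    adaptive refinement, Gmsh/VTK mesh I/O, and experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
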