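#' Simplicial meshes for diffuse optical tomography
#'
#' A mesh is a list with class `fmt_mesh`:
#' \describe{
#'   \item{dimension}{2 (triangles) or 3 (tetrahedra)}
#'   \item{nodes}{N x dim numeric matrix of coordinates in mm}
#'   \item{elements}{P x (dim+1) integer matrix of node indices (1-based),
#'     oriented so every signed area/volume is positive}
#'   \item{boundary_facets}{B x dim integer matrix; each facet belongs to
#'     exactly one element and is oriented with outward normal}
#' }
#' Constructors orient elements and extract the boundary automatically.
#'
#' @param nodes N x dim coordinate matrix (mm).
#' @param elements P x (dim+1) integer connectivity matrix.
#' @return An `fmt_mesh` object.
#' @export
fmt_mesh <- function(nodes, elements) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  dim <- ncol(nodes)
  if (!dim %in% c(2L, 3L)) stop("mesh must be 2D or 3D")
  if (ncol(elements) != dim + 1L) stop("elements must have dim+1 vertices")
  if (min(elements) < 1L || max(elements) > nrow(nodes))
    stop("element node index out of range [1, N]")
  elements <- orient_elements(nodes, elements)
  bf <- extract_boundary_facets(nodes, elements)
  structure(list(
    dimension = dim,
    nodes = nodes,
    elements = elements,
    boundary_facets = bf,
    N = nrow(nodes),
    P = nrow(elements)
  ), class = "fmt_mesh")
}

#' @export
print.fmt_mesh <- function(x, ...) {
  cat(sprintf("fmt_mesh: %dD, %d nodes, %d elements, %d boundary facets\n",
              x$dimension, x$N, x$P, nrow(x$boundary_facets)))
  invisible(x)
}

# Signed area (2D) / volume (3D) per element, vectorized.
signed_measure <- function(nodes, elements) {
  d <- ncol(nodes)
  p <- function(i, c) nodes[elements[, i], c]
  if (d == 2L) {
    0.5 * ((p(2, 1) - p(1, 1)) * (p(3, 2) - p(1, 2)) -
           (p(3, 1) - p(1, 1)) * (p(2, 2) - p(1, 2)))
  } else {
    a1 <- p(2, 1) - p(1, 1); a2 <- p(2, 2) - p(1, 2); a3 <- p(2, 3) - p(1, 3)
    b1 <- p(3, 1) - p(1, 1); b2 <- p(3, 2) - p(1, 2); b3 <- p(3, 3) - p(1, 3)
    c1 <- p(4, 1) - p(1, 1); c2 <- p(4, 2) - p(1, 2); c3 <- p(4, 3) - p(1, 3)
    (a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
       a3 * (b1 * c2 - b2 * c1)) / 6
  }
}

orient_elements <- function(nodes, elements) {
  s <- signed_measure(nodes, elements)
  if (any(s == 0)) stop("degenerate element with zero area/volume: ",
                        paste(which(s == 0)[1], collapse = ", "))
  neg <- s < 0
  if (any(neg)) {
    tmp <- elements[neg, 1L]
    elements[neg, 1L] <- elements[neg, 2L]
    elements[neg, 2L] <- tmp
  }
  elements
}

# Facets of each element: edges (2D) or triangular faces (3D), as a list of
# local index subsets.
local_facets <- function(dim) {
  if (dim == 2L) list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  else list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
}

# All element facets with owning element index: (facet nodes ..., elem).
all_facets <- function(elements) {
  dim <- ncol(elements) - 1L
  lf <- local_facets(dim)
  do.call(rbind, lapply(lf, function(ix) {
    cbind(elements[, ix, drop = FALSE], seq_len(nrow(elements)))
  }))
}

facet_keys <- function(f) {
  if (ncol(f) == 2L) {
    paste(pmin(f[, 1L], f[, 2L]), pmax(f[, 1L], f[, 2L]), sep = "_")
  } else {
    lo <- pmin(f[, 1L], f[, 2L], f[, 3L])
    hi <- pmax(f[, 1L], f[, 2L], f[, 3L])
    mid <- f[, 1L] + f[, 2L] + f[, 3L] - lo - hi
    paste(lo, mid, hi, sep = "_")
  }
}

# Boundary facets = facets appearing exactly once; oriented outward relative
# to their owning element centroid.
extract_boundary_facets <- function(nodes, elements) {
  dim <- ncol(nodes)
  af <- all_facets(elements)
  fnodes <- af[, seq_len(dim), drop = FALSE]
  owner <- af[, dim + 1L]
  key <- facet_keys(fnodes)
  cnt <- table(key)
  onb <- cnt[key] == 1L
  fb <- fnodes[onb, , drop = FALSE]
  ob <- owner[onb]
  # outward orientation: normal of facet points away from element centroid
  ec <- element_centroids(nodes, elements)[ob, , drop = FALSE]
  fc <- facet_centroids(nodes, fb)
  n <- facet_normals(nodes, fb)
  flip <- rowSums(n * (fc - ec)) < 0
  if (any(flip)) {
    tmp <- fb[flip, 1L]
    fb[flip, 1L] <- fb[flip, 2L]
    fb[flip, 2L] <- tmp
  }
  storage.mode(fb) <- "integer"
  fb
}

element_centroids <- function(nodes, elements) {
  nv <- ncol(elements)
  out <- nodes[elements[, 1L], , drop = FALSE]
  for (i in 2:nv) out <- out + nodes[elements[, i], , drop = FALSE]
  out / nv
}

facet_centroids <- function(nodes, facets) element_centroids(nodes, facets)

# Un-normalized facet normals consistent with vertex order.
facet_normals <- function(nodes, facets) {
  dim <- ncol(nodes)
  if (dim == 2L) {
    t1 <- nodes[facets[, 2L], , drop = FALSE] -
      nodes[facets[, 1L], , drop = FALSE]
    cbind(t1[, 2L], -t1[, 1L])
  } else {
    u <- nodes[facets[, 2L], , drop = FALSE] -
      nodes[facets[, 1L], , drop = FALSE]
    v <- nodes[facets[, 3L], , drop = FALSE] -
      nodes[facets[, 1L], , drop = FALSE]
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
}

# Facet measures: edge length (2D) or triangle area (3D).
facet_measures <- function(nodes, facets) {
  n <- facet_normals(nodes, facets)
  len <- sqrt(rowSums(n^2))
  if (ncol(nodes) == 2L) len else len / 2
}

#' Build a structured triangulation of a disc
#'
#' Concentric rings of nodes (ring k carries 6k nodes) connected by an
#' annulus walk, giving near-equilateral triangles. All boundary nodes lie
#' exactly on the circle of the requested radius.
#'
#' @param radius_mm disc radius (mm), > 0.
#' @param target_edge_mm approximate edge length (mm), in (0, radius).
#' @return An `fmt_mesh` with `dimension = 2`.
#' @export
build_disc_mesh <- function(radius_mm, target_edge_mm) {
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("invalid parameter: radius_mm must be > 0")
  if (!is.finite(target_edge_mm) || target_edge_mm <= 0 ||
      target_edge_mm >= radius_mm)
    stop("invalid parameter: target_edge_mm must be in (0, radius_mm)")
  R <- max(1L, as.integer(ceiling(radius_mm / target_edge_mm - 1e-9)))
  nodes <- matrix(0, nrow = 1L + 3L * R * (R + 1L), ncol = 2L)
  ring_start <- integer(R + 1L)  # ring_start[k+1] = index of first node of ring k
  ring_start[1L] <- 1L           # ring 0 = center node
  idx <- 1L
  for (k in seq_len(R)) {
    nk <- 6L * k
    ring_start[k + 1L] <- idx + 1L
    ang <- 2 * pi * (seq_len(nk) - 1L) / nk
    r <- radius_mm * k / R
    nodes[idx + seq_len(nk), 1L] <- r * cos(ang)
    nodes[idx + seq_len(nk), 2L] <- r * sin(ang)
    idx <- idx + nk
  }
  tris <- vector("list", R)
  # ring 1: fan around the center
  out1 <- ring_start[2L] + 0:5
  tris[[1L]] <- cbind(1L, out1, out1[c(2:6, 1L)])
  if (R >= 2L) for (k in 2:R) {
    ni <- 6L * (k - 1L); no <- 6L * k
    si <- ring_start[k]; so <- ring_start[k + 1L]
    tris[[k]] <- annulus_walk(si, ni, so, no)
  }
  fmt_mesh(nodes, do.call(rbind, tris))
}

# Triangulate the annulus between an inner ring (ni nodes from index si) and
# an outer ring (no nodes from index so), nodes uniformly spaced in angle
# starting at angle 0. Two-pointer sweep by angle.
annulus_walk <- function(si, ni, so, no) {
  tris <- matrix(0L, nrow = ni + no, ncol = 3L)
  i <- 0L; j <- 0L; t <- 0L
  inner <- function(m) si + (m %% ni)
  outer <- function(m) so + (m %% no)
  while (i < ni || j < no) {
    adv_out <- if (j >= no) FALSE else if (i >= ni) TRUE else {
      (j + 1) / no <= (i + 1) / ni   # compare next angles
    }
    t <- t + 1L
    if (adv_out) {
      tris[t, ] <- c(inner(i), outer(j), outer(j + 1L))
      j <- j + 1L
    } else {
      tris[t, ] <- c(inner(i), inner(i + 1L), outer(j))
      i <- i + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

#' Build a structured tetrahedral mesh of a cylinder
#'
#' Extrudes a disc triangulation along z in uniform layers; each triangular
#' prism is split into three tetrahedra with index-consistent diagonals so
#' the mesh is conforming. The cylinder occupies z in \[0, height\] and is
#' centered on the z axis.
#'
#' @param radius_mm,height_mm cylinder radius and height (mm), > 0.
#' @param target_edge_mm approximate edge length (mm).
#' @return An `fmt_mesh` with `dimension = 3`.
#' @export
build_cylinder_mesh <- function(radius_mm, height_mm, target_edge_mm) {
  if (!is.finite(height_mm) || height_mm <= 0)
    stop("invalid parameter: height_mm must be > 0")
  disc <- build_disc_mesh(radius_mm, target_edge_mm)
  L <- max(1L, as.integer(ceiling(height_mm / target_edge_mm - 1e-9)))
  Nd <- disc$N
  z <- height_mm * (0:L) / L
  nodes <- do.call(rbind, lapply(z, function(zz) cbind(disc$nodes, zz)))
  tets <- vector("list", L)
  tri <- disc$elements
  for (l in seq_len(L)) {
    off_b <- (l - 1L) * Nd
    off_t <- l * Nd
    tets[[l]] <- split_prisms(tri + off_b, tri + off_t)
  }
  fmt_mesh(nodes, do.call(rbind, tets))
}

# Split prisms (bottom triangle `bot`, top triangle `top`, vertex i of top
# above vertex i of bottom) into 3 tets each, choosing quad-face diagonals by
# global index comparisons so adjacent prisms agree (Dompierre-style).
split_prisms <- function(bot, top) {
  P <- nrow(bot)
  # rotate each prism so the smallest bottom index comes first
  rmin <- max.col(-bot, ties.method = "first")
  idx <- function(off) cbind(seq_len(P), ((rmin - 1L + off) %% 3L) + 1L)
  b1 <- bot[idx(0L)]; b2 <- bot[idx(1L)]; b3 <- bot[idx(2L)]
  t1 <- top[idx(0L)]; t2 <- top[idx(1L)]; t3 <- top[idx(2L)]
  # diagonal choice on quad face 2-3-6-5 by global index comparison
  A <- pmin(b2, t3) < pmin(b3, t2)
  out <- matrix(0L, nrow = 3L * P, ncol = 4L)
  ia <- which(A); ib <- which(!A)
  out[3L * (ia - 1L) + 1L, ] <- cbind(b1, b2, b3, t3)[ia, ]
  out[3L * (ia - 1L) + 2L, ] <- cbind(b1, b2, t3, t2)[ia, ]
  out[3L * (ia - 1L) + 3L, ] <- cbind(b1, t2, t3, t1)[ia, ]
  out[3L * (ib - 1L) + 1L, ] <- cbind(b1, b2, b3, t2)[ib, ]
  out[3L * (ib - 1L) + 2L, ] <- cbind(b1, t2, b3, t3)[ib, ]
  out[3L * (ib - 1L) + 3L, ] <- cbind(b1, t2, t3, t1)[ib, ]
  out
}

#' Prior image describing suspected inclusion support
#'
#' A list of circular/cylindrical regions plus a dilation margin, used to
#' guide adaptive mesh refinement towards likely fluorophore locations.
#'
#' @param regions list of regions, each a list with `center` (length 2 or 3,
#'   mm), `radius` (mm) and, for cylinders, `height` (mm).
#' @param dilation_mm non-negative margin added to every region (mm).
#' @return A `fmt_prior` object.
#' @export
prior_image <- function(regions, dilation_mm = 0) {
  if (dilation_mm < 0) stop("dilation_mm must be >= 0")
  structure(list(regions = regions, dilation_mm = dilation_mm),
            class = "fmt_prior")
}

# Which points (rows of pts) fall inside any dilated prior region.
points_in_prior <- function(pts, prior) {
  if (length(prior$regions) == 0L) return(rep(FALSE, nrow(pts)))
  d <- prior$dilation_mm
  inside <- rep(FALSE, nrow(pts))
  for (rg in prior$regions) {
    ctr <- rg$center
    rr <- rg$radius + d
    dx <- pts[, 1L] - ctr[1L]
    dy <- pts[, 2L] - ctr[2L]
    inr <- dx * dx + dy * dy <= rr * rr
    if (ncol(pts) == 3L && !is.null(rg$height)) {
      hz <- rg$height / 2 + d
      inr <- inr & abs(pts[, 3L] - ctr[3L]) <= hz
    }
    inside <- inside | inr
  }
  inside
}

#' Adaptively refine a mesh towards a prior image
#'
#' Conforming longest-edge bisection: in each round, elements intersecting
#' the dilated prior regions are bisected at their longest edge; the marked
#' edge set is closed so that every element containing a split edge is also
#' bisected (no hanging nodes). Rounds stop when the next round would exceed
#' `node_budget`. Existing nodes are never moved.
#'
#' @param mesh an `fmt_mesh`.
#' @param prior an `fmt_prior`.
#' @param node_budget maximum node count of the output mesh.
#' @return A refined `fmt_mesh` (input returned unchanged, with a warning,
#'   when the budget does not allow any refinement).
#' @export
adaptive_refine <- function(mesh, prior, node_budget) {
  if (node_budget <= mesh$N) {
    warning("node_budget <= current node count; mesh returned unchanged")
    return(mesh)
  }
  nodes <- mesh$nodes
  elements <- mesh$elements
  repeat {
    verts_in <- points_in_prior(nodes, prior)
    cent_in <- points_in_prior(element_centroids(nodes, elements), prior)
    elem_in <- cent_in
    for (i in seq_len(ncol(elements)))
      elem_in <- elem_in | verts_in[elements[, i]]
    if (!any(elem_in)) break
    E <- marked_edge_closure(nodes, elements, which(elem_in))
    if (nrow(nodes) + length(E) > node_budget) break
    res <- bisect_elements(nodes, elements, E)
    nodes <- res$nodes
    elements <- res$elements
  }
  fmt_mesh(nodes, elements)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")

elem_edges <- function(dim) {
  if (dim == 2L) list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  else list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
}

# Per-element edge keys, squared lengths and the longest edge of every
# element (deterministic ties via the fixed local edge order), vectorized.
element_edge_table <- function(nodes, elements) {
  dim <- ncol(elements) - 1L
  ee <- elem_edges(dim)
  ne <- length(ee)
  P <- nrow(elements)
  keys <- matrix("", nrow = P, ncol = ne)
  len2 <- matrix(0, nrow = P, ncol = ne)
  A <- matrix(0L, nrow = P, ncol = ne)
  B <- matrix(0L, nrow = P, ncol = ne)
  for (j in seq_len(ne)) {
    a <- elements[, ee[[j]][1L]]
    b <- elements[, ee[[j]][2L]]
    A[, j] <- pmin(a, b); B[, j] <- pmax(a, b)
    keys[, j] <- paste(A[, j], B[, j], sep = "_")
    len2[, j] <- rowSums((nodes[a, , drop = FALSE] - nodes[b, , drop = FALSE])^2)
  }
  jmax <- max.col(len2, ties.method = "first")
  ix <- cbind(seq_len(P), jmax)
  list(keys = keys, longest_key = keys[ix],
       longest_a = A[ix], longest_b = B[ix])
}

# Closure of the marked edge set: start from longest edges of marked
# elements; whenever an element contains a marked edge, its own longest edge
# is marked too; iterate to fixpoint. Returns a named list key -> c(a, b).
marked_edge_closure <- function(nodes, elements, marked_elems) {
  et <- element_edge_table(nodes, elements)
  Ekeys <- unique(et$longest_key[marked_elems])
  repeat {
    has <- matrix(et$keys %in% Ekeys, nrow = nrow(elements))
    touched <- rowSums(has) > 0
    newk <- setdiff(unique(et$longest_key[touched]), Ekeys)
    if (length(newk) == 0L) break
    Ekeys <- c(Ekeys, newk)
  }
  sel <- match(Ekeys, et$longest_key)
  out <- lapply(sel, function(i) c(et$longest_a[i], et$longest_b[i]))
  names(out) <- Ekeys
  out
}

# Split every element containing a marked edge; recursion handles children
# that still contain marked edges. New nodes are edge midpoints.
bisect_elements <- function(nodes, elements, E) {
  nN <- nrow(nodes)
  newpts <- list()
  mid <- new.env(parent = emptyenv())
  for (k in names(E)) {
    ab <- E[[k]]
    nN <- nN + 1L
    newpts[[length(newpts) + 1L]] <- (nodes[ab[1L], ] + nodes[ab[2L], ]) / 2
    assign(k, nN, envir = mid)
  }
  nodes2 <- rbind(nodes, do.call(rbind, newpts))
  dim <- ncol(elements) - 1L
  ee <- elem_edges(dim)
  out <- list()
  emit <- function(el) out[[length(out) + 1L]] <<- el
  split_rec <- function(el) {
    # longest marked edge within this element
    best <- NULL; bl <- -Inf
    for (ix in ee) {
      a <- el[ix[1L]]; b <- el[ix[2L]]
      if (exists(edge_key(a, b), envir = mid)) {
        l <- sum((nodes2[a, ] - nodes2[b, ])^2)
        if (l > bl) { bl <- l; best <- c(a, b) }
      }
    }
    if (is.null(best)) { emit(el); return(invisible()) }
    m <- get(edge_key(best[1L], best[2L]), envir = mid)
    c1 <- el; c1[c1 == best[2L]] <- m
    c2 <- el; c2[c2 == best[1L]] <- m
    split_rec(c1)
    split_rec(c2)
  }
  for (e in seq_len(nrow(elements))) split_rec(elements[e, ])
  list(nodes = nodes2, elements = do.call(rbind, out))
}

#' Locate a point in a mesh
#'
#' Brute-force search (elements ordered by centroid distance) returning the
#' containing element and its barycentric weights.
#'
#' @param mesh an `fmt_mesh`.
#' @param point coordinate vector (length = mesh dimension), mm.
#' @param tol barycentric tolerance for boundary points.
#' @return list(element = index, weights = barycentric weights summing to 1).
#' @export
locate_point <- function(mesh, point, tol = 1e-9) {
  point <- as.numeric(point)
  cent <- element_centroids(mesh$nodes, mesh$elements)
  d2 <- rowSums(sweep(cent, 2L, point)^2)
  ord <- order(d2)
  for (e in ord) {
    w <- barycentric_weights(mesh, e, point)
    if (all(w >= -tol)) {
      w <- pmax(w, 0)
      w <- w / sum(w)
      return(list(element = e, weights = w))
    }
  }
  stop(sprintf("point (%s) not found in any mesh element",
               paste(signif(point, 6), collapse = ", ")))
}

barycentric_weights <- function(mesh, e, point) {
  vi <- mesh$elements[e, ]
  V <- mesh$nodes[vi, , drop = FALSE]
  d <- mesh$dimension
  A <- t(V[-1L, , drop = FALSE]) - V[1L, ]
  rhs <- point - V[1L, ]
  lam <- tryCatch(solve(A, rhs), error = function(err) rep(NA_real_, d))
  if (anyNA(lam)) return(rep(-Inf, d + 1L))
  c(1 - sum(lam), lam)
}

# Project a point onto the mesh boundary: nearest point over the boundary
# facets; returns facet nodes and interpolation weights on that facet. Only
# the facets with the closest centroids are examined (the point is expected
# on or near the boundary).
project_to_boundary <- function(mesh, point, n_candidates = 40L) {
  fb <- mesh$boundary_facets
  if (nrow(fb) > n_candidates) {
    fc <- facet_centroids(mesh$nodes, fb)
    d2 <- rowSums(sweep(fc, 2L, point)^2)
    fb <- fb[order(d2)[seq_len(n_candidates)], , drop = FALSE]
  }
  best <- NULL; bd <- Inf
  for (f in seq_len(nrow(fb))) {
    vi <- fb[f, ]
    V <- mesh$nodes[vi, , drop = FALSE]
    cw <- closest_point_weights(V, point)
    p <- drop(crossprod(cw, V))
    d2 <- sum((p - point)^2)
    if (d2 < bd) { bd <- d2; best <- list(nodes = vi, weights = cw) }
  }
  best
}

# Weights of the closest point to `point` on the simplex with vertex rows V
# (segment in 2D meshes, triangle in 3D meshes), clamped to the simplex.
closest_point_weights <- function(V, point) {
  k <- nrow(V)
  if (k == 2L) {
    d <- V[2L, ] - V[1L, ]
    t <- sum((point - V[1L, ]) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    c(1 - t, t)
  } else {
    # least-squares barycentric on the triangle plane, then clamp to edges
    A <- cbind(V[2L, ] - V[1L, ], V[3L, ] - V[1L, ])
    rhs <- point - V[1L, ]
    ab <- drop(solve(crossprod(A), crossprod(A, rhs)))
    w <- c(1 - sum(ab), ab)
    if (all(w >= 0)) return(w)
    # clamp: best over the three edges
    best <- NULL; bd <- Inf
    for (ed in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      cw <- closest_point_weights(V[ed, , drop = FALSE], point)
      p <- drop(crossprod(cw, V[ed, , drop = FALSE]))
      d2 <- sum((p - point)^2)
      if (d2 < bd) {
        bd <- d2
        w3 <- numeric(3L); w3[ed] <- cw
        best <- w3
      }
    }
    best
  }
}

# Element geometry used by assembly: measures (areas/volumes) and P1 basis
# gradients, grads[[i]] is a P x dim matrix for local vertex i.
element_geometry <- function(mesh) {
  nodes <- mesh$nodes
  el <- mesh$elements
  d <- mesh$dimension
  vol <- signed_measure(nodes, el)
  nv <- d + 1L
  grads <- vector("list", nv)
  if (d == 2L) {
    x <- matrix(nodes[el, 1L], ncol = 3L)
    y <- matrix(nodes[el, 2L], ncol = 3L)
    for (i in 1:3) {
      j <- i %% 3L + 1L; k <- j %% 3L + 1L
      grads[[i]] <- cbind(y[, j] - y[, k], x[, k] - x[, j]) / (2 * vol)
    }
  } else {
    for (i in 1:4) {
      rest <- setdiff(1:4, i)
      p0 <- nodes[el[, rest[1L]], , drop = FALSE]
      u <- nodes[el[, rest[2L]], , drop = FALSE] - p0
      v <- nodes[el[, rest[3L]], , drop = FALSE] - p0
      n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
      pi_ <- nodes[el[, i], , drop = FALSE]
      den <- rowSums(n * (pi_ - p0))
      grads[[i]] <- n / den
    }
  }
  list(vol = vol, grads = grads, nv = nv)
}
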