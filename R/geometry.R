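## Spherocylinder surface geometry: quasi-uniform mesh, discrete
## Laplace-Beltrami operator, analytic tip arc-length.

#' Cell geometry of a spherocylinder
#'
#' A fission yeast cell is modeled as a cylinder of radius `R` capped by two
#' hemispheres, with total tip-to-tip length `L` (so the cylindrical body has
#' length `L - 2R`).
#'
#' @param L Cell length tip-to-tip (um). Must exceed `2 * R`.
#' @param R Cylinder and cap radius (um).
#' @param target_cell_area Desired area of one Voronoi cell of the surface
#'   discretization (um^2). The default 0.03 um^2 is the midpoint of the
#'   working band 0.017--0.046 um^2.
#' @return An object of class `cell_geometry`.
#' @examples
#' g <- cell_geometry(L = 8, R = 2)
#' surface_area(g)   # 32 * pi
#' @export
cell_geometry <- function(L = 8, R = 2, target_cell_area = 0.03) {
  stopifnot(is.numeric(L), is.numeric(R), is.numeric(target_cell_area))
  if (R <= 0) stop("R must be positive")
  if (L <= 2 * R) stop("L must exceed 2*R (need a cylinder segment of positive length)")
  if (target_cell_area <= 0) stop("target_cell_area must be positive")
  structure(list(L = L, R = R, target_cell_area = target_cell_area),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Spherocylinder: L = %g um, R = %g um (area %.2f um^2, volume %.2f um^3)\n",
              x$L, x$R, surface_area(x), cell_volume(x)))
  invisible(x)
}

#' Analytic surface area of a spherocylinder
#'
#' `2*pi*R*(L - 2R) + 4*pi*R^2`.
#'
#' @param geom A [cell_geometry()].
#' @return Surface area (um^2).
#' @export
surface_area <- function(geom) {
  2 * pi * geom$R * (geom$L - 2 * geom$R) + 4 * pi * geom$R^2
}

#' Analytic volume of a spherocylinder
#'
#' `pi*R^2*(L - 2R) + (4/3)*pi*R^3`. The cytoplasmic volume enters the
#' quasi-static GEF field through the recruitment coefficients.
#'
#' @param geom A [cell_geometry()].
#' @return Volume (um^3).
#' @export
cell_volume <- function(geom) {
  pi * geom$R^2 * (geom$L - 2 * geom$R) + 4 / 3 * pi * geom$R^3
}

## Radial distance from the long axis at meridian position m in [0, M],
## where M = pi*R + (L - 2R) is the pole-to-pole meridian length.
.radius_at <- function(m, L, R) {
  qc <- pi * R / 2                      # quarter-meridian over one cap
  M <- pi * R + (L - 2 * R)
  r <- rep(R, length(m))
  r[m < qc] <- R * sin(m[m < qc] / R)
  r[m > M - qc] <- R * sin((M - m[m > M - qc]) / R)
  r
}

## Axial coordinate z at meridian position m (pole 1 at z = -L/2).
.z_at <- function(m, L, R) {
  qc <- pi * R / 2
  M <- pi * R + (L - 2 * R)
  zc1 <- -(L / 2) + R                   # cap-1 sphere center
  zc2 <- (L / 2) - R
  z <- zc1 + (m - qc)                   # cylinder
  i <- m < qc
  z[i] <- zc1 - R * cos(m[i] / R)
  i <- m > M - qc
  z[i] <- zc2 + R * cos((M - m[i]) / R)
  z
}

#' Build a quasi-uniform triangulated Voronoi mesh of the spherocylinder
#'
#' Nodes are placed on rings of constant meridian position, spaced uniformly
#' along the pole-to-pole meridian, with the azimuthal count of each ring
#' proportional to its circumference so that every Voronoi cell has
#' approximately the target area. Adjacent rings are joined by a zipper
#' triangulation and the two cap apices are pinned as single pole nodes.
#' The discrete Laplace-Beltrami operator uses cotangent edge weights on the
#' triangulation; per-node Voronoi areas are barycentric (one third of each
#' incident triangle), so the areas sum exactly to the triangulated surface
#' area and diffusion conserves mass by construction.
#'
#' @param geom A [cell_geometry()].
#' @param seed Integer seed controlling the small random azimuthal offset of
#'   each ring (breaks grid alignment; the mesh is otherwise deterministic).
#' @return An object of class `surface_mesh` with elements
#'   `nodes` (n x 3 coordinates, um), `areas` (per-node Voronoi area, um^2),
#'   `lap` (sparse symmetric operator; `lap %*% f / areas` is the discrete
#'   Laplacian), `s` (per-node arc length to the nearest tip pole, um),
#'   `tip_ids` (indices of the two pole nodes), `faces` (triangles),
#'   `geom`, and `meridian` (per-node meridian coordinate from pole 1).
#' @examples
#' mesh <- build_mesh(cell_geometry(L = 8, R = 2), seed = 1)
#' range(mesh$areas)
#' @export
build_mesh <- function(geom, seed = 1L) {
  stopifnot(inherits(geom, "cell_geometry"))
  L <- geom$L; R <- geom$R
  A_tot <- surface_area(geom)
  n_target <- A_tot / geom$target_cell_area
  if (n_target < 200)
    stop(sprintf(paste0("target_cell_area %.3g um^2 would give only ~%d nodes ",
                        "(< 200); choose a finer resolution"),
                 geom$target_cell_area, round(n_target)))

  M <- pi * R + (L - 2 * R)             # meridian length pole to pole
  ds <- sqrt(geom$target_cell_area)     # lattice spacing
  n_seg <- max(4L, round(M / ds))
  dm <- M / n_seg                       # effective meridian spacing
  m_rings <- dm * seq_len(n_seg - 1L)

  set.seed(as.integer(seed))
  jitter <- runif(length(m_rings), -0.05, 0.05)

  ring_nodes <- vector("list", length(m_rings))
  idx0 <- 1L                            # node 1 is pole 1
  for (k in seq_along(m_rings)) {
    r_k <- .radius_at(m_rings[k], L, R)
    n_k <- max(3L, round(2 * pi * r_k / dm))
    off <- (k %% 2) / 2 + jitter[k]
    th <- 2 * pi * (seq_len(n_k) - 1 + off) / n_k
    ring_nodes[[k]] <- list(theta = th, ids = idx0 + seq_len(n_k), m = m_rings[k])
    idx0 <- idx0 + n_k
  }
  n_nodes <- idx0 + 1L                  # last node is pole 2

  meridian <- numeric(n_nodes)
  theta_all <- numeric(n_nodes)
  meridian[1] <- 0; meridian[n_nodes] <- M
  for (k in seq_along(ring_nodes)) {
    rn <- ring_nodes[[k]]
    meridian[rn$ids] <- rn$m
    theta_all[rn$ids] <- rn$theta
  }
  r_all <- .radius_at(meridian, L, R)
  nodes <- cbind(x = r_all * cos(theta_all),
                 y = r_all * sin(theta_all),
                 z = .z_at(meridian, L, R))
  nodes[1, ] <- c(0, 0, -L / 2)
  nodes[n_nodes, ] <- c(0, 0, L / 2)

  faces <- .triangulate_rings(ring_nodes, pole1 = 1L, pole2 = n_nodes)

  lapA <- .cotan_laplacian(nodes, faces, n_nodes)

  mesh <- structure(list(
    nodes = nodes, areas = lapA$areas, lap = lapA$lap,
    faces = faces, tip_ids = c(1L, n_nodes), geom = geom,
    meridian = meridian, seed = as.integer(seed)
  ), class = "surface_mesh")
  mesh$s <- tip_distance(mesh)
  mesh
}

## Zipper triangulation between consecutive rings plus pole fans.
.triangulate_rings <- function(ring_nodes, pole1, pole2) {
  tris <- vector("list", length(ring_nodes) + 1L)
  ## pole-1 fan
  r1 <- ring_nodes[[1]]
  n1 <- length(r1$ids)
  tris[[1]] <- cbind(pole1, r1$ids, r1$ids[c(2:n1, 1)])
  for (k in seq_len(length(ring_nodes) - 1L)) {
    tris[[k + 1L]] <- .zip_band(ring_nodes[[k]], ring_nodes[[k + 1L]])
  }
  rl <- ring_nodes[[length(ring_nodes)]]
  nl <- length(rl$ids)
  tris[[length(tris)]] <- cbind(pole2, rl$ids[c(2:nl, 1)], rl$ids)
  do.call(rbind, tris)
}

## Triangulate the band between two rings by merging their angle sequences.
.zip_band <- function(A, B) {
  nA <- length(A$ids); nB <- length(B$ids)
  ## rotate B to the first vertex at or just above A's start angle, so the
  ## unwrapped angle sequences interleave monotonically (choosing the
  ## nearest vertex can place it just below the start, which unwraps to the
  ## far end of the band and degenerates the closing triangles)
  rot <- which.min((B$theta - A$theta[1]) %% (2 * pi))
  ordB <- c(rot:nB, seq_len(rot - 1L))
  thB <- B$theta[ordB]
  thB <- A$theta[1] + ((thB - A$theta[1]) %% (2 * pi))  # unwrap from A start
  idsB <- B$ids[ordB]
  thA <- A$theta
  thA <- A$theta[1] + ((thA - A$theta[1]) %% (2 * pi))
  ## sentinel wrap-around angles
  thA_ext <- c(thA, thA[1] + 2 * pi)
  thB_ext <- c(thB, thB[1] + 2 * pi)
  tris <- matrix(0L, nA + nB, 3L)
  i <- 1L; j <- 1L; t <- 0L
  while (i <= nA || j <= nB) {
    advA <- if (i > nA) FALSE else if (j > nB) TRUE else thA_ext[i + 1L] <= thB_ext[j + 1L]
    t <- t + 1L
    if (advA) {
      tris[t, ] <- c(A$ids[i], A$ids[.wrap(i + 1L, nA)], idsB[.wrap(j, nB)])
      i <- i + 1L
    } else {
      tris[t, ] <- c(idsB[j], A$ids[.wrap(i, nA)], idsB[.wrap(j + 1L, nB)])
      j <- j + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

.wrap <- function(i, n) ((i - 1L) %% n) + 1L

## Cotangent-weight Laplacian and barycentric Voronoi areas.
.cotan_laplacian <- function(nodes, faces, n) {
  p1 <- nodes[faces[, 1], , drop = FALSE]
  p2 <- nodes[faces[, 2], , drop = FALSE]
  p3 <- nodes[faces[, 3], , drop = FALSE]
  e12 <- p2 - p1; e13 <- p3 - p1; e23 <- p3 - p2
  cross <- cbind(e12[, 2] * e13[, 3] - e12[, 3] * e13[, 2],
                 e12[, 3] * e13[, 1] - e12[, 1] * e13[, 3],
                 e12[, 1] * e13[, 2] - e12[, 2] * e13[, 1])
  a2 <- sqrt(rowSums(cross^2))          # 2 * triangle area
  f_area <- a2 / 2
  ## cot of angle at vertex v = dot(u, w) / |u x w| for edges u, w from v
  cot1 <- rowSums(e12 * e13) / a2
  cot2 <- rowSums(-e12 * e23) / a2
  cot3 <- rowSums(e13 * e23) / a2
  ## edge (2,3) opposite vertex 1 gets cot1/2, etc.
  ii <- c(faces[, 2], faces[, 1], faces[, 1])
  jj <- c(faces[, 3], faces[, 3], faces[, 2])
  ww <- c(cot1, cot2, cot3) / 2
  W <- sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww), dims = c(n, n))
  ## Clamp the few negative weights from obtuse triangle pairs to zero:
  ## keeps the operator symmetric (mass conservation exact) and makes it an
  ## M-matrix, so explicit diffusion within the stability bound preserves
  ## non-negative concentrations.
  W@x[W@x < 0] <- 0
  W <- Matrix::drop0(W)
  lap <- W - Diagonal(n, Matrix::rowSums(W))
  areas <- as.numeric(rowsum(rep(f_area / 3, 3L), c(faces[, 1], faces[, 2], faces[, 3]),
                             reorder = TRUE))
  list(lap = lap, areas = areas)
}

#' Apply the discrete Laplace-Beltrami operator to a nodal field
#'
#' Computes `(W f)_i / a_i` where `W` is the symmetric cotangent-weight
#' operator and `a_i` the Voronoi area of node `i`. For any field the
#' area-weighted sum of the result is zero (no flux through a closed
#' surface), so pure diffusion conserves total mass.
#'
#' @param mesh A [build_mesh()] result.
#' @param field Numeric vector, one value per node.
#' @return Numeric vector of the same length (units of field / um^2).
#' @export
laplace_beltrami <- function(mesh, field) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(field) != nrow(mesh$nodes))
    stop(sprintf("field has length %d but mesh has %d nodes",
                 length(field), nrow(mesh$nodes)))
  as.numeric(mesh$lap %*% field) / mesh$areas
}

#' Arc-length distance from each node to the nearest cell tip
#'
#' Computed analytically from the node coordinates, not by graph shortest
#' path: on a hemispherical cap `s = R * phi` with `phi` the polar angle
#' from the pole; on the cylinder `s = pi*R/2` plus the axial distance from
#' the nearer cap-cylinder junction. `s = 0` exactly at the two poles and is
#' maximal (`pi*R/2 + (L-2R)/2`) at mid-cell.
#'
#' @param mesh A [build_mesh()] result.
#' @return Numeric vector of arc lengths (um).
#' @export
tip_distance <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  L <- mesh$geom$L; R <- mesh$geom$R
  z <- abs(mesh$nodes[, 3])
  zc <- (L - 2 * R) / 2                 # junction axial position
  s <- pi * R / 2 + (zc - z)            # cylinder part
  on_cap <- z >= zc
  cosphi <- pmin(1, pmax(-1, (z[on_cap] - zc) / R))
  s[on_cap] <- R * acos(cosphi)
  s
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d nodes, %d triangles on L = %g, R = %g um\n",
              nrow(x$nodes), nrow(x$faces), x$geom$L, x$geom$R))
  cat(sprintf("  Voronoi areas: %.4f - %.4f um^2 (total %.2f, analytic %.2f)\n",
              min(x$areas), max(x$areas), sum(x$areas), surface_area(x$geom)))
  invisible(x)
}

#' Explicit-diffusion stability bound and check
#'
#' Maximum stable forward-Euler time step on the mesh for diffusivity `D` is
#' `min_i a_i / (D * sum_j w_ij)` (row-sum bound on the discrete operator).
#'
#' @param p A [model_params()] object (uses its `dt` and largest diffusivity)
#' @param mesh A [build_mesh()] result.
#' @return A list with `dt_max` (s), `dt` (s) and logical `stable`.
#' @export
stability_check <- function(p, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  Dmax <- max(p$DT, p$DD, p$DGAPI, p$DGAPIIfast, p$DGAPIIslow)
  if (Dmax <= 0) {
    return(list(dt_max = Inf, dt = p$dt, stable = TRUE, D = Dmax))
  }
  wsum <- Matrix::rowSums(abs(mesh$lap)) - abs(Matrix::diag(mesh$lap))
  dt_max <- min(mesh$areas / (Dmax * wsum))
  list(dt_max = dt_max, dt = p$dt, stable = p$dt <= dt_max, D = Dmax)
}
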