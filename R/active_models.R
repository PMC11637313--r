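# Local active-force models: cytokinetic ring and protrusion dipole.

#' Direction vector from spherical coordinates
#' @param theta polar angle from +z (radians).
#' @param phi azimuth from +x (radians).
#' @return unit 3-vector.
#' @export
spherical_axis <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Contractile (cytokinetic) ring specification
#'
#' The division plane has normal given by spherical coordinates and offset
#' `d` along that normal from the cell mass center. An elastic spring of
#' constant `k` (rest length zero) along the selected node ring produces the
#' constriction force, smeared with Gaussian weights of width
#' `smoothing_width` to keep the furrow smooth; a proportional area
#' controller of gain `K_D` stabilizes the two sides of the plane.
#'
#' @param cell id of the cell carrying the ring.
#' @param theta,phi spherical coordinates of the division-plane normal.
#' @param d plane offset from the cell mass center.
#' @param k spring constant (force/length).
#' @param K_D side-area controller gain (pressure).
#' @param smoothing_width force-smearing width; NULL = 2 mean edge lengths.
#' @return list of class `ring_spec`.
#' @export
ring_spec <- function(cell, theta, phi, d = 0, k = 1, K_D = 10,
                      smoothing_width = NULL) {
  stopifnot(k >= 0, K_D >= 0)
  structure(list(type = "ring", cell = cell, theta = theta, phi = phi, d = d,
                 k = k, K_D = K_D, smoothing_width = smoothing_width),
            class = c("ring_spec", "active_spec"))
}

#' Protrusion specification
#'
#' Forces are distributed over the mesh with a difference-of-Gaussians
#' weight `G_a - G_2a` in the angle between a node's direction from the cell
#' center and the protrusion axis (`G_s(b) = exp(-b^2/(2 s^2))/s`, `a =
#' alpha`), applied along node normals; outward in the core, inward in the
#' surrounding band, with the residual inverted and redistributed so the net
#' force is exactly zero.
#'
#' @param cell id of the cell carrying the protrusion.
#' @param theta,phi spherical coordinates of the protrusion axis.
#' @param alpha angular width (radians, in (0, pi/2)).
#' @param F_P total protrusive force: the sum of outward force magnitudes.
#' @return list of class `protrusion_spec`.
#' @export
protrusion_spec <- function(cell, theta, phi, alpha = 0.5, F_P = 1) {
  stopifnot(F_P >= 0, alpha > 0, alpha < pi / 2)
  structure(list(type = "protrusion", cell = cell, theta = theta, phi = phi,
                 alpha = alpha, F_P = F_P),
            class = c("protrusion_spec", "active_spec"))
}

mean_edge_length <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(t(apply(he, 1, sort)))
  mean(sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2)))
}

#' Select the node ring where a division plane intersects a cell mesh
#'
#' Edges crossing the plane are found and for each the endpoint nearest the
#' plane is kept; the resulting nodes are ordered by azimuth around the plane
#' normal. Errors if the plane misses the mesh.
#'
#' @param mesh a `cell_mesh`.
#' @param ring a `ring_spec`.
#' @return list: `nodes` (ordered 1-based indices of the closed loop),
#'   `plane_normal`, `plane_point`, `signed_distance` (per node).
#' @export
select_ring <- function(mesh, ring) {
  n <- spherical_axis(ring$theta, ring$phi)
  g <- geometry(mesh)
  ctr <- colSums(mesh$vertices * g$voronoi_area) / sum(g$voronoi_area)
  p0 <- ctr + ring$d * n
  s <- as.numeric((mesh$vertices - matrix(p0, nrow(mesh$vertices), 3,
                                          byrow = TRUE)) %*% n)
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cross <- s[he[, 1]] * s[he[, 2]] < 0
  if (!any(cross)) stop("division plane misses the cell mesh")
  ce <- he[cross, , drop = FALSE]
  pick <- ifelse(abs(s[ce[, 1]]) <= abs(s[ce[, 2]]), ce[, 1], ce[, 2])
  nodes <- unique(pick)
  # order around the plane normal
  e1 <- if (abs(n[1]) < 0.9) crossprod_3(n, c(1, 0, 0)) else crossprod_3(n, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod_3(n, e1)
  rel <- sweep(mesh$vertices[nodes, , drop = FALSE], 2, p0, "-")
  ang <- atan2(rel %*% e2, rel %*% e1)
  nodes <- nodes[order(ang)]
  list(nodes = nodes, plane_normal = n, plane_point = p0, signed_distance = s)
}

# Full realization used by the simulator: node ring, fixed side labels of
# triangles and nodes, reference side areas, smoothing width.
realize_ring <- function(mesh, ring) {
  sel <- select_ring(mesh, ring)
  g <- geometry(mesh)
  f <- mesh$faces
  cent_s <- (sel$signed_distance[f[, 1]] + sel$signed_distance[f[, 2]] +
             sel$signed_distance[f[, 3]]) / 3
  tri_side <- ifelse(cent_s >= 0, 1L, 2L)
  node_side <- ifelse(sel$signed_distance >= 0, 1L, 2L)
  aref1 <- sum(g$tri_area[tri_side == 1L])
  aref2 <- sum(g$tri_area[tri_side == 2L])
  sigma <- ring$smoothing_width %||% (2 * mean_edge_length(mesh))
  list(nodes = sel$nodes, tri_side = tri_side, node_side = node_side,
       aref1 = aref1, aref2 = aref2, sigma = sigma,
       plane_normal = sel$plane_normal, plane_point = sel$plane_point)
}

#' Nodal forces of a contractile ring on its current mesh
#'
#' Reference side areas are captured from the mesh passed as `reference`
#' (defaults to `mesh` itself, i.e. attachment time).
#'
#' @param mesh a `cell_mesh` (current shape).
#' @param ring a `ring_spec`.
#' @param reference optional `cell_mesh` used to fix ring nodes, side labels
#'   and reference areas.
#' @return n x 3 force matrix summing to zero.
#' @export
ring_forces <- function(mesh, ring, reference = mesh) {
  rr <- realize_ring(reference, ring)
  cpp_ring_forces(mesh$vertices, mesh$faces - 1L, rr$nodes - 1L, ring$k,
                  rr$sigma, ring$K_D, rr$tri_side, rr$node_side,
                  rr$aref1, rr$aref2)
}

#' Nodal forces of a protrusion on a mesh
#' @param mesh a `cell_mesh`.
#' @param prot a `protrusion_spec`.
#' @return n x 3 force matrix summing to zero.
#' @export
protrusion_forces <- function(mesh, prot) {
  cpp_protrusion_forces(mesh$vertices, mesh$faces - 1L,
                        spherical_axis(prot$theta, prot$phi),
                        prot$alpha, prot$F_P)
}

#' Zero crossing of the difference-of-Gaussians protrusion weight
#'
#' The angle beta0 where `G_a(beta) - G_2a(beta)` changes sign; nodes with
#' beta < beta0 are pushed outward, a band beyond beta0 pulled inward.
#'
#' @param alpha protrusion angular width.
#' @return beta0 in radians.
#' @export
dog_zero_crossing <- function(alpha) {
  # (1/a) exp(-b^2/(2a^2)) = (1/2a) exp(-b^2/(8a^2))  =>
  # b^2 (1/(2a^2) - 1/(8a^2)) = log 2  =>  b = a * sqrt(8 log(2) / 3)
  alpha * sqrt(8 * log(2) / 3)
}
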