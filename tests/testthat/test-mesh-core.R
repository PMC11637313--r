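# Mesh structures, geometry kernels and file I/O.

test_that("analytic volumes, areas and curvatures are reproduced", {
  cube <- box_mesh(c(-1, -1, -1), c(1, 1, 1))
  g <- geometry(cube)
  expect_equal(g$volume, 8, tolerance = 1e-12)
  expect_equal(g$area, 24, tolerance = 1e-12)

  s <- icosphere(3, radius = 1)
  gs <- geometry(s)
  expect_equal(gs$volume, 4 * pi / 3, tolerance = 0.01)
  expect_equal(sum(gs$voronoi_area), gs$area, tolerance = 1e-6)
  # per-node normals are unit outward radial directions
  expect_true(all(abs(sqrt(rowSums(gs$normals^2)) - 1) < 1e-12))
  rad <- s$vertices / sqrt(rowSums(s$vertices^2))
  expect_gt(min(rowSums(gs$normals * rad)), 0.99)

  s2 <- icosphere(3, radius = 2)
  g2 <- geometry(s2)
  expect_equal(mean(g2$mean_curvature), 0.5, tolerance = 0.02)
})

test_that("accepted meshes are closed genus-0 surfaces; open meshes are rejected", {
  s <- icosphere(2)
  expect_identical(euler_characteristic(s), 2L)
  expect_identical(euler_characteristic(box_mesh()), 2L)
  # deleting one triangle opens the surface
  expect_error(cell_mesh(s$vertices, s$faces[-1, ], id = "open"),
               "non-manifold|open")
  # flipping one face breaks consistent winding
  f <- s$faces
  f[5, ] <- f[5, c(1, 3, 2)]
  expect_error(cell_mesh(s$vertices, f, id = "flipped"), "non-manifold|open")
})

test_that("geometry is invariant under rigid transforms", {
  s <- icosphere(2, radius = 1.3)
  g0 <- geometry(s)
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  v2 <- sweep(s$vertices %*% t(Rz), 2, c(3, -2, 5), "+")
  s2 <- cell_mesh(v2, s$faces, id = "moved", repair = FALSE)
  g2 <- geometry(s2)
  expect_equal(g2$volume, g0$volume, tolerance = 1e-9)
  expect_equal(g2$area, g0$area, tolerance = 1e-9)
})

test_that("raycast distances match radial geometry and the exhaustive oracle", {
  s1 <- icosphere(2, radius = 1)
  rc0 <- raycast_distance(s1, s1)
  expect_true(all(rc0$distance < 1e-9))

  s2 <- icosphere(2, radius = 1.1)
  rc <- raycast_distance(s1, s2)
  expect_true(all(rc$hit))
  expect_equal(mean(rc$distance), 0.1, tolerance = 0.01)
  expect_true(all(abs(rc$distance - 0.1) < 0.001))

  # randomly deformed target versus a brute-force ray/triangle oracle in R
  set.seed(42)
  src <- icosphere(1, radius = 1)
  tgt0 <- icosphere(1, radius = 1)
  vt <- tgt0$vertices * (1 + 0.1 * sin(3 * tgt0$vertices[, 1]) +
                           0.05 * cos(2 * tgt0$vertices[, 2]))
  tgt <- cell_mesh(vt, tgt0$faces, id = "deformed", repair = FALSE)
  rc2 <- raycast_distance(src, tgt)
  g <- geometry(src)
  oracle <- vapply(seq_len(nrow(src$vertices)), function(i) {
    o <- src$vertices[i, ]; d <- g$normals[i, ]
    best <- Inf
    for (t in seq_len(nrow(tgt$faces))) {
      tri <- tgt$vertices[tgt$faces[t, ], ]
      e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
      pv <- fides:::crossprod_3(d, e2)
      det <- sum(e1 * pv)
      if (abs(det) < 1e-14) next
      tv <- o - tri[1, ]
      u <- sum(tv * pv) / det
      if (u < 0 || u > 1) next
      qv <- fides:::crossprod_3(tv, e1)
      v <- sum(d * qv) / det
      if (v < 0 || u + v > 1) next
      tt <- abs(sum(e2 * qv) / det)
      if (tt < best) best <- tt
    }
    best
  }, numeric(1))
  hit <- is.finite(oracle)
  expect_true(mean(hit) > 0.9)
  expect_equal(rc2$distance[hit], oracle[hit], tolerance = 1e-9)
})

test_that("convex hull shell contains its points and reproduces the cube", {
  cube <- box_mesh(c(0, 0, 0), c(2, 2, 2))
  sh <- convex_hull_shell(cube$vertices)
  g <- geometry(cell_mesh(sh$vertices, sh$faces, id = "hull", repair = FALSE))
  expect_equal(g$volume, 8, tolerance = 1e-9)
  expect_true(all(shell_signed_distance(sh, cube$vertices) <= 1e-9))

  set.seed(7)
  pts <- matrix(rnorm(300), ncol = 3)
  sh2 <- convex_hull_shell(pts)
  expect_true(all(shell_signed_distance(sh2, pts) <= 1e-7))
  # sphere point cloud: hull approximates the sphere
  sp <- icosphere(2, radius = 2)
  sh3 <- convex_hull_shell(sp$vertices)
  gh <- geometry(cell_mesh(sh3$vertices, sh3$faces, id = "h", repair = FALSE))
  expect_equal(gh$volume, geometry(sp)$volume, tolerance = 1e-6)
  expect_error(convex_hull_shell(matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2, 3, 3, 3),
                                        ncol = 3, byrow = TRUE)),
               "collinear|coplanar|degenerate")
})

test_that("mesh files round-trip through all supported formats", {
  s <- icosphere(1, radius = 1.5, center = c(0.3, -0.2, 1))
  td <- withr::local_tempdir()
  for (ext in c("ply", "off", "stl", "vtk")) {
    p <- file.path(td, paste0("cell.", ext))
    write_mesh(s, p)
    s2 <- read_mesh(p)
    expect_equal(geometry(s2)$volume, geometry(s)$volume,
                 tolerance = 1e-5, label = ext)
    expect_identical(s2$id, "cell")
  }
})

test_that("load_meshes applies the file naming convention and rejects duplicates", {
  td <- withr::local_tempdir()
  for (id in c("ABa", "ABp", "EMS", "P2"))
    write_mesh(icosphere(1, id = id), file.path(td, paste0(id, ".ply")))
  ms <- load_meshes(td)
  expect_setequal(names(ms), c("ABa", "ABp", "EMS", "P2"))
  expect_identical(ms$ABa$id, "ABa")
})
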