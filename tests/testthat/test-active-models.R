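# Cytokinetic ring and protrusion force models.

test_that("ring selection follows the division plane", {
  s <- icosphere(3, radius = 1)
  sel <- select_ring(s, ring_spec("sphere", theta = 0, phi = 0, d = 0))
  pts <- s$vertices[sel$nodes, ]
  # great circle: |z| small, radius ~ 1, total polygon length ~ 2 pi
  expect_lt(max(abs(pts[, 3])), 0.15)
  rad <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  expect_equal(mean(rad), 1, tolerance = 0.05)
  # perimeter of the intersection curve: project the node ring onto the
  # division plane (the node ring itself zigzags about the plane)
  ppts <- cbind(pts[, 1], pts[, 2], 0)
  per <- sum(sqrt(rowSums((ppts - ppts[c(2:nrow(ppts), 1), ])^2)))
  expect_equal(per, 2 * pi, tolerance = 0.05 * 2 * pi)

  sel2 <- select_ring(s, ring_spec("sphere", theta = 0, phi = 0, d = 0.5))
  rad2 <- sqrt(s$vertices[sel2$nodes, 1]^2 + s$vertices[sel2$nodes, 2]^2)
  expect_equal(mean(rad2), sqrt(1 - 0.25), tolerance = 0.05)

  expect_error(select_ring(s, ring_spec("sphere", theta = 0, phi = 0, d = 1.2)),
               "misses")
})

test_that("ring forces are a zero-net-force constriction", {
  s <- icosphere(2, radius = 1)
  spec <- ring_spec("c", theta = 0, phi = 0, d = 0, k = 1, K_D = 10)
  f <- ring_forces(s, spec)
  expect_lt(max(abs(colSums(f))), 1e-6 * max(1e-12, max(abs(f))))

  # k = 0 and sides at reference areas: no force at attachment time
  f0 <- ring_forces(s, ring_spec("c", theta = 0, phi = 0, d = 0, k = 0,
                                 K_D = 10))
  expect_lt(max(abs(f0)), 1e-9)

  # net force on ring nodes points toward the ring axis
  sel <- select_ring(s, spec)
  fr <- f[sel$nodes, , drop = FALSE]
  pts <- s$vertices[sel$nodes, , drop = FALSE]
  radial <- cbind(pts[, 1], pts[, 2], 0)
  radial <- radial / sqrt(rowSums(radial^2))
  expect_lt(mean(rowSums(fr * radial)), 0)
})

test_that("ring constriction deepens with the spring constant", {
  eq_radius <- function(k) {
    s <- icosphere(2, radius = 1, id = "c")
    st <- embryo_state(list(s),
                       active = list(ring_spec("c", theta = 0, phi = 0,
                                               d = 0, k = k, K_D = 10)))
    r <- relax(st, simulation_config(t_end = 2, divergence_cap = 10))
    v <- r$cells[[1]]$vertices
    band <- abs(v[, 3]) < 0.15
    mean(sqrt(v[band, 1]^2 + v[band, 2]^2))
  }
  radii <- vapply(c(0.5, 1, 2), eq_radius, numeric(1))
  expect_true(all(diff(radii) < 0))
  expect_lt(radii[3], 0.97) # visible furrow at k = 2
})

test_that("ring side volumes stay balanced while constricting", {
  s <- icosphere(2, radius = 1, id = "c")
  st <- embryo_state(list(s),
                     active = list(ring_spec("c", theta = 0, phi = 0,
                                             d = 0, k = 2, K_D = 10)))
  r <- relax(st, simulation_config(t_end = 2, divergence_cap = 10))
  v <- r$cells[[1]]$vertices
  # per-side enclosed volume approximated by hemispheric split of the
  # (symmetric) cell
  expect_equal(sum(v[, 3] > 0) / nrow(v), 0.5, tolerance = 0.1)
})

test_that("protrusion forces are an exact zero-sum DoG dipole", {
  s <- icosphere(2, radius = 1)
  p <- protrusion_spec("c", theta = 0, phi = 0, alpha = 0.5, F_P = 2)
  f <- protrusion_forces(s, p)
  expect_lt(max(abs(colSums(f))), 1e-12 * sum(abs(f)))

  f0 <- protrusion_forces(s, protrusion_spec("c", theta = 0, phi = 0,
                                             alpha = 0.5, F_P = 0))
  expect_identical(max(abs(f0)), 0)

  # sign change at the DoG zero crossing (root-find oracle)
  beta0 <- dog_zero_crossing(0.5)
  root <- stats::uniroot(function(b)
    exp(-b^2 / (2 * 0.25)) / 0.5 - exp(-b^2 / (2 * 1)) / 1,
    c(0.1, 1.5))$root
  expect_equal(beta0, root, tolerance = 1e-4)

  g <- geometry(s)
  beta <- acos(pmin(pmax(s$vertices[, 3] / sqrt(rowSums(s$vertices^2)), -1), 1))
  outward <- rowSums(f * g$normals)
  core <- beta < beta0 - 0.1
  band <- beta > beta0 + 0.1 & beta < 2 * beta0
  expect_true(all(outward[core] > 0))
  expect_true(mean(outward[band] < 0) > 0.9)
})

test_that("protrusion bump grows with the total force", {
  extent <- function(fp) {
    s <- icosphere(2, radius = 1, id = "c")
    st <- embryo_state(list(s),
                       active = list(protrusion_spec("c", theta = 0, phi = 0,
                                                     alpha = 0.5, F_P = fp)))
    r <- relax(st, simulation_config(t_end = 1.5, divergence_cap = 10))
    max(r$cells[[1]]$vertices[, 3]) - colMeans(r$cells[[1]]$vertices)[3]
  }
  ex <- vapply(c(0.5, 1.5, 3), extent, numeric(1))
  expect_true(all(diff(ex) > 0))
})
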