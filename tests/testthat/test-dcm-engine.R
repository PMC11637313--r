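# Forward DCM force fields and relaxation.

test_that("tension forces balance globally and match an energy finite difference", {
  s <- icosphere(2, radius = 1.2)
  tf <- tension_forces(s, gamma = 0.8)
  expect_lt(max(abs(colSums(tf))), 1e-9)
  # net torque about the origin vanishes (area is rotation invariant)
  tq <- colSums(cbind(
    s$vertices[, 2] * tf[, 3] - s$vertices[, 3] * tf[, 2],
    s$vertices[, 3] * tf[, 1] - s$vertices[, 1] * tf[, 3],
    s$vertices[, 1] * tf[, 2] - s$vertices[, 2] * tf[, 1]))
  expect_lt(max(abs(tq)), 1e-9)

  # finite-difference oracle on the energy gamma * area, a few nodes
  gam <- 0.8
  h <- 1e-6
  for (i in c(1, 20, 100)) {
    for (k in 1:3) {
      vp <- s$vertices; vp[i, k] <- vp[i, k] + h
      vm <- s$vertices; vm[i, k] <- vm[i, k] - h
      ap <- geometry(cell_mesh(vp, s$faces, repair = FALSE))$area
      am <- geometry(cell_mesh(vm, s$faces, repair = FALSE))$area
      expect_equal(tf[i, k], -gam * (ap - am) / (2 * h), tolerance = 1e-4)
    }
  }

  # Laplace equivalence: inward traction ~ 2 gamma H = 2 gamma / R
  g <- geometry(s)
  inward <- -rowSums(tf * g$normals)
  expect_equal(mean(inward / (2 * gam / 1.2 * g$voronoi_area)), 1,
               tolerance = 0.03)
})

test_that("volumetric pressure follows P = K (V* - V)/V*", {
  s <- icosphere(2)
  v0 <- geometry(s)$volume
  pf0 <- pressure_forces(s, cell_params(V_star = v0, bulk_modulus = 10))
  expect_equal(pf0$P, 0, tolerance = 1e-12)
  expect_lt(max(abs(pf0$forces)), 1e-12)

  pf <- pressure_forces(s, cell_params(V_star = v0 / 0.9, bulk_modulus = 10))
  expect_equal(pf$P, 10 * (v0 / 0.9 - v0) / (v0 / 0.9), tolerance = 1e-12)
  expect_equal(pf$P, 1, tolerance = 1e-12)
  expect_lt(max(abs(colSums(pf$forces))), 1e-6 * pf$P * geometry(s)$area)
})

test_that("a single relaxed cell obeys the Young-Laplace balance", {
  s <- icosphere(2, radius = 1, id = "c")
  st <- embryo_state(list(s))
  r <- relax(st, simulation_config(t_end = 2, tol = 1e-3))
  d <- attr(r, "diagnostics")
  g <- geometry(r$cells[[1]])
  # P = 2 gamma H at equilibrium; and K (V*-V)/V* ~ 2 gamma / R
  expect_equal(d$pressures[1], 2 * mean(g$mean_curvature), tolerance = 0.03)
  R <- (3 * d$volumes[1] / (4 * pi))^(1 / 3)
  expect_equal(d$pressures[1], 2 / R, tolerance = 0.03)
  # volume conserved within a few percent of the target
  expect_equal(d$volumes[1], geometry(s)$volume, tolerance = 0.05)
  # stays spherical: radius variation small
  ctr <- colMeans(r$cells[[1]]$vertices)
  rads <- sqrt(rowSums(sweep(r$cells[[1]]$vertices, 2, ctr, "-")^2))
  expect_lt(stats::sd(rads) / mean(rads), 0.01)
})

test_that("contact forces obey Newton's third law and vanish out of range", {
  a <- icosphere(2, radius = 1, center = c(-0.99, 0, 0), id = "A")
  b <- icosphere(2, radius = 1, center = c(0.99, 0, 0), id = "B")
  cf <- contact_forces(a, b, omega = 0.5, contact_range = 0.1,
                       repulsion_stiffness = 1000)
  expect_lt(max(abs(colSums(cf$forces_a) + colSums(cf$forces_b))), 1e-9)
  expect_gt(cf$contact_area, 0)

  far <- icosphere(2, radius = 1, center = c(5, 0, 0), id = "B")
  cf2 <- contact_forces(a, far, omega = 0.5, contact_range = 0.1,
                        repulsion_stiffness = 1000)
  expect_identical(max(abs(cf2$forces_a)), 0)
  expect_identical(cf2$contact_area, 0)
})

test_that("relaxed doublets reproduce Young-Dupre junction angles", {
  # the strongest-adhesion case carries the largest discretization error;
  # see the methods vignette for the calibration discussion
  tol_deg <- c("0.2" = 3, "0.5" = 3, "1" = 3)
  for (om in c(0.2, 0.5)) {
    st <- relaxed_doublet(om)
    jx <- measure_junctions(st, classify_interfaces(st))
    expect_length(jx, 1)
    meas <- sort(jx[[1]]$angles) * 180 / pi
    expected <- doublet_sectors(om) * 180 / pi
    expect_lt(max(abs(meas - expected)), tol_deg[[as.character(om)]],
              label = paste("omega", om))
  }
})

test_that("doublet relaxation decays to quasi-static (monotone tail)", {
  a <- icosphere(2, radius = 1, center = c(-1.01, 0, 0), id = "A")
  b <- icosphere(2, radius = 1, center = c(1.01, 0, 0), id = "B")
  st <- embryo_state(list(a, b),
                     contacts = data.frame(a = "A", b = "B", omega = 0.4,
                                           xi = 0.1))
  cfg <- simulation_config(divergence_cap = 10)
  speeds <- numeric(8)
  for (k in 1:8) {
    st <- step_embryo(st, cfg, 1000)
    speeds[k] <- attr(st, "diagnostics")$max_speed
  }
  # after the zipping transient the kinetic proxy stays low
  expect_lt(speeds[8], 0.4 * max(speeds))
  expect_lt(speeds[8], 0.5)
})

test_that("eggshell penalty confines and flattens cells", {
  s <- icosphere(2, radius = 1, id = "c")
  # shell from the sphere's own hull, shrunk: the cell must flatten
  sh <- convex_hull_shell(s$vertices, scale = 0.9)
  f <- shell_forces(s, sh, stiffness = 300)
  # nodes outside the shrunk shell feel inward force; deep nodes none
  sd <- shell_signed_distance(sh, s$vertices)
  expect_true(all(rowSums(f^2)[sd < -0.05] == 0))
  expect_true(any(rowSums(f^2)[sd > 0.01] > 0))
  # penalty magnitude ~ stiffness * depth * node area
  g <- geometry(s)
  i <- which.max(sd)
  expect_equal(sqrt(sum(f[i, ]^2)),
               unname(300 * sd[i] * g$voronoi_area[i]), tolerance = 0.3)

  st <- embryo_state(list(s), eggshell = sh)
  r <- relax(st, simulation_config(t_end = 2, divergence_cap = 10))
  sd2 <- shell_signed_distance(sh, r$cells[[1]]$vertices)
  # relaxed cell hugs the shell: an appreciable fraction of the surface
  # sits within contact range of it
  expect_gt(mean(sd2 > -0.1), 0.2)
  expect_lt(max(sd2), 0.05)
})

test_that("time-step halving leaves the relaxed state nearly unchanged", {
  s <- icosphere(1, radius = 1, id = "c")
  st <- embryo_state(list(s), params = list(c = cell_params(V_star = 3)))
  r1 <- relax(st, simulation_config(dt = 1e-3, t_end = 1.5))
  r2 <- relax(st, simulation_config(dt = 5e-4, t_end = 1.5))
  d <- sqrt(rowSums((r1$cells[[1]]$vertices - r2$cells[[1]]$vertices)^2))
  expect_lt(max(d), 1e-2)
})

test_that("zero total force leaves the state unchanged", {
  # a lone cell with V* = V and gamma = 0 experiences no net drive
  s <- icosphere(1, radius = 1, id = "c")
  st <- embryo_state(list(s), params = list(c = cell_params(gamma = 0)))
  r <- step_embryo(st, simulation_config(), 10)
  d <- max(abs(r$cells[[1]]$vertices - s$vertices))
  expect_lt(d, 1e-6)
})
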