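# Synthetic benchmark generators and embryo bundle I/O.

test_that("the diamond embryo has 4 cells and 5 adhesive contacts and is seeded", {
  se <- simple_embryo_fixture(1)
  expect_length(se$state$cells, 4)
  expect_length(se$truth$omega, 5)
  expect_equal(mean(se$truth$gamma), 1, tolerance = 1e-12)
  expect_true(all(se$truth$gamma_ij > 0))
  ca <- contact_areas(se$state)
  expect_true(all(ca[names(se$truth$omega)] > 0))

  # determinism: the pre-relaxation draw is identical under the same seed
  a <- make_simple_embryo(seed = 9, t_relax = 0.02)
  b <- make_simple_embryo(seed = 9, t_relax = 0.02)
  expect_identical(a$truth, b$truth)
  expect_identical(a$state$cells[[1]]$vertices, b$state$cells[[1]]$vertices)
})

test_that("equal tensions produce 120-degree foam angles", {
  # spread -> 0: all triple-junction sector angles approach 120 degrees
  se <- fixture("simple_flat", function()
    make_simple_embryo(seed = 2, tension_spread = 1e-6, t_relax = 12))
  # equalize adhesion too: redraw with all omegas equal
  st <- se$state
  st$contacts$omega <- mean(st$contacts$omega)
  st <- relax(st, simulation_config(t_end = 6, divergence_cap = 10))
  jx <- measure_junctions(st, classify_interfaces(st))
  cellcell <- vapply(jx, function(j) !any(j$regions == "EXTERIOR"), logical(1))
  if (any(cellcell)) {
    angs <- unlist(lapply(jx[cellcell], function(j) j$angles)) * 180 / pi
    # interior junctions of a compact aggregate carry a few degrees of
    # discretization error even at equal tensions
    expect_lt(max(abs(angs - 120)), 10)
  } else skip("no interior triple junction formed at this seed")
})

test_that("the 7-cell embryo realizes its designed topology and features", {
  adv <- fixture("advanced_1", function()
    make_advanced_embryo(seed = 1, eggshell = TRUE, active = TRUE))
  expect_length(adv$state$cells, 7)
  expect_length(adv$truth$omega, 15)
  types <- vapply(adv$state$active, function(a) a$type, character(1))
  expect_identical(sum(types == "ring"), 1L)
  expect_identical(sum(types == "protrusion"), 4L)
  # all 15 ground-truth contacts have positive area
  ca <- contact_areas(adv$state)
  expect_true(all(names(adv$truth$omega) %in% names(ca)))
  expect_true(all(ca[names(adv$truth$omega)] > 0))
  # confinement: some exterior surface presses against the shell
  sd <- unlist(lapply(adv$state$cells, function(m)
    shell_signed_distance(adv$state$eggshell, m$vertices)))
  expect_gt(mean(sd > -0.15), 0.02)
})

test_that("the unconfined passive 7-cell embryo has no shell contact", {
  adv <- fixture("advanced_passive_1", function()
    make_advanced_embryo(seed = 1, eggshell = FALSE, active = FALSE))
  expect_null(adv$state$eggshell)
  expect_length(adv$state$active, 0)
})

test_that("ground truth and embryo bundles round-trip through disk", {
  se <- simple_embryo_fixture(1)
  td <- withr::local_tempdir()
  write_embryo_bundle(se$state, td, truth = se$truth)
  back <- read_embryo_bundle(td)
  expect_setequal(names(back$state$cells), names(se$state$cells))
  expect_equal(back$truth$gamma, se$truth$gamma, tolerance = 1e-12)
  expect_equal(back$truth$omega, se$truth$omega, tolerance = 1e-12)
  expect_equal(back$truth$gamma_ij, se$truth$gamma_ij, tolerance = 1e-12)
  g1 <- geometry(se$state$cells[[1]])
  g2 <- geometry(back$state$cells[[1]])
  expect_equal(g2$volume, g1$volume, tolerance = 1e-5)
  # active specs round-trip for an active embryo
  adv <- fixture("advanced_1", function()
    make_advanced_embryo(seed = 1, eggshell = TRUE, active = TRUE))
  td2 <- withr::local_tempdir()
  write_embryo_bundle(adv$state, td2, truth = adv$truth)
  back2 <- read_embryo_bundle(td2)
  expect_length(back2$state$active, 5)
  expect_false(is.null(back2$state$eggshell))
})
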