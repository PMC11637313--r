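# Foam force inference: classification, junction measurement, solves.

test_that("interface classification separates contacts from exterior", {
  s <- icosphere(2, radius = 1, id = "solo")
  st1 <- embryo_state(list(s))
  im1 <- classify_interfaces(st1)
  expect_identical(im1$interfaces$key, "EXTERIOR|solo")

  st <- relaxed_doublet(0.5)
  imap <- classify_interfaces(st)
  expect_setequal(imap$interfaces$key,
                  c("A|B", "A|EXTERIOR", "B|EXTERIOR"))
  # the two facing patches have similar triangle counts; A|B pools both
  labA <- imap$labels$A
  labB <- imap$labels$B
  nA <- sum(labA == "B"); nB <- sum(labB == "A")
  expect_lt(abs(nA - nB) / max(nA, nB), 0.2)
})

test_that("junction count matches the brute-force label-adjacency oracle", {
  se <- simple_embryo_fixture(1)
  imap <- classify_interfaces(se$state)
  jx <- measure_junctions(se$state, imap, min_triangles = 10)
  # oracle: enumerate label triples over adjacent triangle pairs
  triples <- character()
  for (id in names(se$state$cells)) {
    m <- se$state$cells[[id]]
    lab <- imap$labels[[id]]
    adj <- fides:::tri_adjacency(m$faces)
    for (t in seq_len(nrow(m$faces))) for (s in 1:3) {
      t2 <- adj[t, s]
      if (is.na(t2) || t2 < t || lab[t] == lab[t2]) next
      reg <- sort(unique(c(id, lab[t], lab[t2])))
      if (length(reg) == 3) triples <- c(triples, paste(reg, collapse = "|"))
    }
  }
  expect_setequal(vapply(jx, function(j) paste(j$regions, collapse = "|"),
                         character(1)),
                  unique(triples))
})

test_that("measured doublet junction matches the law-of-cosines closed form", {
  st <- relaxed_doublet(0.5)
  jx <- measure_junctions(st, classify_interfaces(st))
  meas <- sort(jx[[1]]$angles) * 180 / pi
  expected <- doublet_sectors(0.5) * 180 / pi
  expect_lt(max(abs(meas - expected)), 3)
  # the three sector angles always close up to 2 pi
  expect_equal(sum(jx[[1]]$angles), 2 * pi, tolerance = 1e-9)
})

test_that("tangent solve recovers tensions from analytic angles exactly", {
  # a doublet junction: two cell-exterior surfaces (tensions 0.8 and 1.0)
  # and their contact (interfacial tension 1.2), with sector angles
  # generated from the force-balance closed form
  gam <- c(0.8, 1.0, 1.2)
  sector <- function(gi, gj, gk)
    unname(acos((gk^2 - gi^2 - gj^2) / (2 * gi * gj)))
  s_ab <- sector(gam[1], gam[2], gam[3]) # between the two exterior surfaces
  s_ac <- sector(gam[1], gam[3], gam[2])
  s_bc <- sector(gam[2], gam[3], gam[1])
  expect_equal(s_ab + s_ac + s_bc, 2 * pi, tolerance = 1e-12)
  ids <- c("A", "B")
  cells <- lapply(seq_along(ids), function(i)
    icosphere(1, center = c(3 * i, 0, 0), id = ids[i]))
  st <- embryo_state(cells)
  jx <- list(list(
    regions = c("A", "B", "EXTERIOR"),
    ifaces = c("A|EXTERIOR", "B|EXTERIOR", "A|B"),
    angles = stats::setNames(
      c(s_ab, s_ac, s_bc),
      c("A|EXTERIOR~B|EXTERIOR", "A|B~A|EXTERIOR", "A|B~B|EXTERIOR")),
    n_samples = 10, points = matrix(0, 1, 3)))
  imap <- structure(list(labels = list(), ambiguous = 0L,
                         interfaces = data.frame(
                           key = c("A|B", "A|EXTERIOR", "B|EXTERIOR"),
                           n_triangles = 100, area = 1)),
                    class = "interface_map")
  sol <- solve_ffi(st, jx, imap, mode = "tangent")
  got <- c(sol$gamma[["A"]], sol$gamma[["B"]], sol$gamma_ij[["A|B"]])
  expect_equal(got / got[1], gam / gam[1], tolerance = 1e-6)
})

test_that("symmetric 120-degree junction yields equal tensions", {
  ids <- c("A", "B")
  cells <- lapply(seq_along(ids), function(i)
    icosphere(1, center = c(3 * i, 0, 0), id = ids[i]))
  st <- embryo_state(cells)
  a120 <- 2 * pi / 3
  jx <- list(list(regions = c("A", "B", "EXTERIOR"),
                  ifaces = c("A|EXTERIOR", "B|EXTERIOR", "A|B"),
                  angles = stats::setNames(
                    rep(a120, 3),
                    c("A|EXTERIOR~B|EXTERIOR", "A|B~A|EXTERIOR",
                      "A|B~B|EXTERIOR")),
                  n_samples = 5, points = matrix(0, 1, 3)))
  imap <- structure(list(labels = list(), ambiguous = 0L,
                         interfaces = data.frame(
                           key = c("A|B", "A|EXTERIOR", "B|EXTERIOR"),
                           n_triangles = 100, area = 1)),
                    class = "interface_map")
  sol <- solve_ffi(st, jx, imap, mode = "tangent")
  expect_equal(unname(c(sol$gamma[["A"]], sol$gamma[["B"]],
                        sol$gamma_ij[["A|B"]])), rep(1, 3),
               tolerance = 1e-9)
})

test_that("curved mode is self-consistent with Young-Laplace on a doublet", {
  st <- relaxed_doublet(0.5)
  sol <- ffi(st, "curved")
  imap <- classify_interfaces(st)
  jx <- measure_junctions(st, imap)
  H <- interface_curvatures(st, imap, jx)
  k <- "A|B"
  dP <- sol$pressure[["A"]] - sol$pressure[["B"]]
  expect_lt(abs(dP - 2 * H[[k]] * sol$gamma_ij[[k]]),
            0.05 * max(abs(sol$pressure)))
  # exterior interfaces: P = 2 H gamma within tolerance
  expect_equal(unname(sol$pressure["A"]),
               unname(2 * H["A|EXTERIOR"] * sol$gamma["A"]), tolerance = 0.1)
})

test_that("FFI solutions are invariant under global mesh rescaling", {
  st <- relaxed_doublet(0.5)
  lam <- 17.3
  st2 <- st
  for (id in names(st2$cells))
    st2$cells[[id]]$vertices <- st2$cells[[id]]$vertices * lam
  s1 <- ffi(st, "tangent"); s2 <- ffi(st2, "tangent")
  expect_equal(s2$gamma, s1$gamma, tolerance = 1e-5)
  expect_equal(s2$gamma_ij, s1$gamma_ij, tolerance = 1e-5)
  c1 <- ffi(st, "curved"); c2 <- ffi(st2, "curved")
  expect_equal(c2$gamma, c1$gamma, tolerance = 0.02)
  # pressures scale as 1/length
  expect_lt(abs(c2$pressure[["A"]] * lam - c1$pressure[["A"]]) /
              abs(c1$pressure[["A"]]), 0.02)
})

test_that("the diamond embryo recovers its five contacts", {
  se <- simple_embryo_fixture(1)
  imap <- classify_interfaces(se$state)
  ck <- imap$interfaces$key
  ck <- ck[!grepl("EXTERIOR", ck, fixed = TRUE)]
  expect_setequal(ck, names(se$truth$omega))
  expect_length(ck, 5)
})

test_that("rank-deficient systems are reported with the unconstrained unknowns", {
  ids <- c("A", "B")
  cells <- lapply(seq_along(ids), function(i)
    icosphere(1, center = c(3 * i, 0, 0), id = ids[i]))
  st <- embryo_state(cells)
  imap <- structure(list(labels = list(), ambiguous = 0L,
                         interfaces = data.frame(key = "A|B",
                                                 n_triangles = 100, area = 1)),
                    class = "interface_map")
  # a single junction that never references cell B's surface tension
  jx <- list(list(regions = c("A", "B", "EXTERIOR"),
                  ifaces = c("A|B", "A|EXTERIOR", "A|EXTERIOR"),
                  angles = stats::setNames(rep(2 * pi / 3, 3),
                                           c("A|B~A|EXTERIOR",
                                             "A|EXTERIOR~A|EXTERIOR",
                                             "A|EXTERIOR~A|B")),
                  n_samples = 5, points = matrix(0, 1, 3)))
  expect_error(solve_ffi(st, jx, imap, mode = "tangent"),
               "rank-deficient|unconstrained")
})
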