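# FIDES objective and stochastic shape-fitting optimization.

test_that("deformation error matches analytic and oracle values", {
  s <- icosphere(2, radius = 1, id = "c")
  st <- embryo_state(list(s))
  expect_equal(deformation_error(st, st)$E_D, 0, tolerance = 1e-12)

  # uniform inflation by delta: E_D ~ area * delta
  s2 <- cell_mesh(s$vertices * 1.01, s$faces, id = "c", repair = FALSE)
  st2 <- embryo_state(list(s2))
  g <- geometry(s)
  expect_equal(deformation_error(st, st2)$E_D, g$area * 0.01,
               tolerance = 0.02 * g$area * 0.01 + 1e-6)

  # arbitrary perturbation equals the brute-force sum A_i * raycast oracle
  set.seed(3)
  v3 <- s$vertices * (1 + 0.05 * sin(2 * s$vertices[, 2]))
  s3 <- cell_mesh(v3, s$faces, id = "c", repair = FALSE)
  st3 <- embryo_state(list(s3))
  ed <- deformation_error(st, st3)$E_D
  rc <- raycast_distance(s, s3)
  expect_equal(ed, sum(g$voronoi_area * rc$distance), tolerance = 1e-9)
})

test_that("the evaluation objective is deterministic and penalizes drift", {
  se <- simple_embryo_fixture(1)
  observed <- se$state
  cfg <- fides_config(sim_time = 0.5, seed = 1)
  imap <- classify_interfaces(observed)
  ck <- imap$interfaces$key[!grepl("EXTERIOR", imap$interfaces$key, fixed = TRUE)]
  cp <- do.call(rbind, lapply(ck, function(k) {
    p <- strsplit(k, "[|]")[[1]]
    data.frame(a = p[1], b = p[2], omega = 0, xi = 0.1)
  }))
  tab <- fides:::build_parameter_table(observed, list(), ck, 0.3)
  lam <- c(adh = 0, ring = 0, prot = 0)
  e1 <- fides:::fides_evaluate(observed, tab, list(), cp, cfg, lam)
  e2 <- fides:::fides_evaluate(observed, tab, list(), cp, cfg, lam)
  expect_identical(e1$total, e2$total)

  # all-zero tensions: shapes drift, error larger than with sane tensions
  tab0 <- tab
  tab0$value[tab0$kind == "gamma"] <- 0
  tab0$value[tab0$kind == "omega"] <- 0
  e0 <- fides:::fides_evaluate(observed, tab0, list(), cp, cfg, lam)
  expect_gt(e0$total, 0)

  # ground-truth parameters hold the shapes better than perturbed ones
  tabt <- tab
  for (id in names(se$truth$gamma))
    tabt$value[tabt$kind == "gamma" & tabt$target == id] <- se$truth$gamma[id]
  for (k in names(se$truth$omega))
    tabt$value[tabt$kind == "omega" & tabt$target == k] <- se$truth$omega[k]
  et <- fides:::fides_evaluate(observed, tabt, list(), cp, cfg, lam)
  set.seed(42)
  worse <- 0
  for (rep in 1:6) {
    tabp <- tabt
    gsel <- tabp$kind %in% c("gamma", "omega")
    tabp$value[gsel] <- pmax(tabp$value[gsel] * exp(rnorm(sum(gsel), 0, 0.3)), 0)
    ep <- fides:::fides_evaluate(observed, tabp, list(), cp, cfg, lam)
    if (ep$total > et$total) worse <- worse + 1
  }
  expect_gte(worse, 5)
})

test_that("normalization reports tensions in units of the mean surface tension", {
  out <- normalize_solution(c(a = 2, b = 2, c = 2, d = 2),
                            c(`a|b` = 1, `c|d` = 0.5))
  expect_equal(unname(out$gamma), rep(1, 4))
  expect_equal(unname(out$omega), c(0.5, 0.25))
  out2 <- normalize_solution(c(a = 1.5, b = 0.5), c(`a|b` = 0.4))
  expect_equal(mean(out2$gamma), 1)
  expect_equal(unname(out2$gamma), c(1.5, 0.5))
})

test_that("the optimizer descends and recovers a doublet adhesion", {
  # doublet generated with known omega; fit started away from it
  st <- relaxed_doublet(0.5, subdiv = 2)
  observed <- st
  cfg <- fides_config(max_iters = 25, patience = 25, sim_time = 1.5,
                      seed = 2, step_omega = 0.08)
  fit <- fides_fit(observed, list(), cfg, omega0 = 0.25)
  # objective trace: final baseline never exceeds the initial one
  expect_lte(fit$trace$total[nrow(fit$trace)], fit$trace$total[1])
  expect_equal(unname(fit$omega[["A|B"]]), 0.5, tolerance = 0.2)
  expect_equal(unname(mean(fit$gamma)), 1, tolerance = 1e-9)
})
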