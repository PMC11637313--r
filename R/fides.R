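# FIDES: inverse force inference by shape-fitting simulation. Observed cell
# shapes are loaded into the forward DCM; surface tensions, adhesive
# tensions, target volumes and active-model parameters are optimized by a
# stochastic accept-if-improves search on the area-weighted raycast
# deformation error.

#' Deformation error between two embryo states
#'
#' `E_D = sum_i A_i * d_i` where `d_i` is the normal-raycast distance from
#' node i of the initial meshes to the deformed meshes and `A_i` the
#' initial Voronoi node area, summed over all cells. Zero iff the deformed
#' surfaces coincide with the initial ones along all node normals.
#'
#' @param initial,deformed `embryo_state` objects with identical mesh
#'   topology.
#' @return list of class `objective_report`: `E_D`, `per_cell` breakdown.
#' @export
deformation_error <- function(initial, deformed) {
  ids <- names(initial$cells)
  if (!identical(ids, names(deformed$cells)))
    stop("cell sets differ between states")
  per <- vapply(ids, function(id) {
    mi <- initial$cells[[id]]
    md <- deformed$cells[[id]]
    if (!identical(dim(mi$vertices), dim(md$vertices)))
      stop("mesh topology mismatch for cell ", id)
    g <- geometry(mi)
    rc <- cpp_raycast(mi$vertices, g$normals, md$vertices, md$faces - 1L)
    sum(g$voronoi_area * rc$distance)
  }, numeric(1))
  structure(list(E_D = sum(per), per_cell = per), class = "objective_report")
}

#' Optimizer configuration for FIDES
#'
#' @param max_iters iteration cap (default 150).
#' @param patience stop after this many iterations without improvement.
#' @param sim_time nondimensional simulation time per evaluation
#'   (default 2.5).
#' @param sim_config `simulation_config` used for the evaluations
#'   (its `t_end` is replaced by `sim_time`).
#' @param step_gamma,step_omega Gaussian proposal s.d. for tensions
#'   (fraction of the mean tension).
#' @param step_vstar proposal s.d. for target volumes (fraction of cell
#'   volume).
#' @param step_angle proposal s.d. for ring/protrusion orientation (radians).
#' @param step_d proposal s.d. for ring offset (fraction of cell radius).
#' @param step_scale proposal s.d. for k, F_P, alpha (fractional).
#' @param lambda_adh,lambda_ring,lambda_prot penalty weights per unit of
#'   adhesion energy, ring spring constant and protrusive force; NULL =
#'   1e-3 of the initial deformation error per unit.
#' @param seed RNG seed of the proposal stream.
#' @return list of class `fides_config`.
#' @export
fides_config <- function(max_iters = 150, patience = 15, sim_time = 2.5,
                         sim_config = simulation_config(),
                         step_gamma = 0.05, step_omega = 0.05,
                         step_vstar = 0.02, step_angle = 0.05,
                         step_d = 0.05, step_scale = 0.05,
                         lambda_adh = NULL, lambda_ring = NULL,
                         lambda_prot = NULL, seed = 1) {
  stopifnot(max_iters >= patience, patience >= 1)
  structure(as.list(environment()), class = "fides_config")
}

# flat parameter table for one embryo + schedule
build_parameter_table <- function(state, schedule, contact_keys, omega0) {
  ids <- names(state$cells)
  vols <- vapply(state$cells, function(m) geometry(m)$volume, numeric(1))
  R0 <- mean((3 * vols / (4 * pi))^(1 / 3))
  rows <- list()
  for (id in ids)
    rows[[length(rows) + 1]] <- data.frame(
      kind = "gamma", target = id, index = NA, value = 1,
      lower = 0, upper = Inf, step = NA, stringsAsFactors = FALSE)
  for (k in contact_keys)
    rows[[length(rows) + 1]] <- data.frame(
      kind = "omega", target = k, index = NA, value = omega0,
      lower = 0, upper = Inf, step = NA, stringsAsFactors = FALSE)
  for (id in ids)
    rows[[length(rows) + 1]] <- data.frame(
      kind = "V_star", target = id, index = NA, value = vols[[id]],
      lower = 0.2 * vols[[id]], upper = 3 * vols[[id]], step = NA,
      stringsAsFactors = FALSE)
  for (si in seq_along(schedule)) {
    a <- schedule[[si]]
    if (a$type == "ring") {
      for (f in c("theta", "phi", "d", "k"))
        rows[[length(rows) + 1]] <- data.frame(
          kind = paste0("ring_", f), target = a$cell, index = si,
          value = a[[f]],
          lower = if (f == "k") 0 else if (f == "d") -0.9 * R0 else -Inf,
          upper = if (f == "d") 0.9 * R0 else Inf,
          step = NA, stringsAsFactors = FALSE)
    } else {
      for (f in c("theta", "phi", "alpha", "F_P"))
        rows[[length(rows) + 1]] <- data.frame(
          kind = paste0("prot_", f), target = a$cell, index = si,
          value = a[[f]],
          lower = if (f == "F_P") 0 else if (f == "alpha") 0.05 else -Inf,
          upper = if (f == "alpha") pi / 2 - 0.05 else Inf,
          step = NA, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

param_steps <- function(tab, cfg, vols, R0) {
  step <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    step[i] <- switch(sub("_.*", "", tab$kind[i]),
      gamma = cfg$step_gamma,
      omega = cfg$step_omega,
      V = cfg$step_vstar * vols[[tab$target[i]]],
      ring = switch(sub("ring_", "", tab$kind[i]),
                    theta = cfg$step_angle, phi = cfg$step_angle,
                    d = cfg$step_d * R0, k = cfg$step_scale * 1),
      prot = switch(sub("prot_", "", tab$kind[i]),
                    theta = cfg$step_angle, phi = cfg$step_angle,
                    alpha = cfg$step_scale, F_P = cfg$step_scale * 1))
  }
  step
}

# instantiate an embryo_state from observed meshes + a parameter table
state_from_params <- function(observed, tab, schedule, contact_pairs) {
  ids <- names(observed$cells)
  params <- list()
  for (id in ids) {
    g <- tab$value[tab$kind == "gamma" & tab$target == id]
    v <- tab$value[tab$kind == "V_star" & tab$target == id]
    params[[id]] <- cell_params(gamma = g, V_star = v)
  }
  contacts <- contact_pairs
  for (i in seq_len(nrow(contacts))) {
    k <- iface_key(contacts$a[i], contacts$b[i])
    o <- tab$value[tab$kind == "omega" & tab$target == k]
    contacts$omega[i] <- if (length(o)) o else 0
  }
  active <- list()
  for (si in seq_along(schedule)) {
    a <- schedule[[si]]
    sel <- !is.na(tab$index) & tab$index == si
    vals <- stats::setNames(tab$value[sel], sub("^(ring|prot)_", "", tab$kind[sel]))
    if (a$type == "ring")
      active[[si]] <- ring_spec(a$cell, vals["theta"], vals["phi"],
                                vals["d"], vals["k"], a$K_D %||% 10,
                                a$smoothing_width)
    else
      active[[si]] <- protrusion_spec(a$cell, vals["theta"], vals["phi"],
                                      vals["alpha"], vals["F_P"])
  }
  st <- observed
  st$params <- params
  st$contacts <- contacts
  st$active <- active
  st
}

#' Evaluate one FIDES parameter proposal
#'
#' Simulates the observed shapes under the DCM with the proposed parameters
#' for `sim_time` and returns the deformation error plus linear penalties on
#' total adhesion energy, ring spring constants and protrusive forces.
#' Simulation divergence yields an infinite objective (rejected move).
#'
#' @param observed observed `embryo_state` (meshes define the target).
#' @param tab parameter table (internal format).
#' @param schedule list of active-model specs.
#' @param contact_pairs data.frame of candidate contacts.
#' @param cfg a `fides_config`.
#' @param lambdas named penalty weights.
#' @return list: `total`, `E_D`, `penalty`, `per_cell`.
#' @keywords internal
fides_evaluate <- function(observed, tab, schedule, contact_pairs, cfg,
                           lambdas) {
  st <- state_from_params(observed, tab, schedule, contact_pairs)
  sc <- cfg$sim_config
  sc$t_end <- cfg$sim_time
  sc$tol <- 0
  deformed <- tryCatch(relax(st, sc), error = function(e) NULL)
  if (is.null(deformed))
    return(list(total = Inf, E_D = Inf, penalty = Inf))
  er <- deformation_error(observed, deformed)
  diag <- attr(deformed, "diagnostics")
  adh_energy <- 0
  if (nrow(contact_pairs) && length(diag$contact_areas))
    adh_energy <- sum(contact_pairs$omega * diag$contact_areas)
  ringk <- sum(tab$value[tab$kind == "ring_k"])
  protF <- sum(tab$value[tab$kind == "prot_F_P"])
  pen <- lambdas["adh"] * adh_energy + lambdas["ring"] * ringk +
    lambdas["prot"] * protF
  list(total = er$E_D + pen, E_D = er$E_D, penalty = pen,
       per_cell = er$per_cell)
}

#' Fit forces to observed cell shapes (FIDES)
#'
#' Starting from equal surface tensions (with counteracting pressures via
#' target volumes equal to the observed volumes) and equal adhesive
#' tensions on every detected cell-cell contact, each parameter is
#' perturbed with a Gaussian step and evaluated by an independent forward
#' simulation against the iteration's baseline; all improving changes are
#' applied jointly at the end of the iteration, surface tensions are
#' renormalized to mean 1 (adhesive tensions rescaled proportionally), and
#' the search stops after `patience` iterations without improvement or at
#' `max_iters`.
#'
#' @param observed observed `embryo_state` (typically segmented or
#'   synthetic meshes; its eggshell, if any, is kept as confinement).
#' @param schedule list of initial active-model placements
#'   (`ring_spec`/`protrusion_spec`), usually from a staging schedule.
#' @param config a `fides_config`.
#' @param omega0 initial adhesive tension for every contact.
#' @param contact_range gap used to detect candidate contacts.
#' @param verbose print per-iteration objectives.
#' @return object of class `fides_result`: `gamma`, `omega`, `gamma_ij`,
#'   `V_star`, `active` (fitted specs), `trace` (per-iteration totals),
#'   `baseline` (final objective), `n_iters`.
#' @export
fides_fit <- function(observed, schedule = list(), config = fides_config(),
                      omega0 = 0.3, contact_range = NULL, verbose = FALSE) {
  set.seed(config$seed)
  ids <- names(observed$cells)
  # detect contacts on the observed shapes; on coarse meshes the default
  # classification gap must not fall below the facet scale, and
  # over-detection is harmless here (unused adhesions are optimized to
  # zero and pruned by the penalty)
  if (is.null(contact_range)) {
    R0 <- mean_cell_radius(observed)
    medge <- mean(vapply(observed$cells, mean_edge_length, numeric(1)))
    contact_range <- max(0.12 * R0, 0.5 * medge)
  }
  imap <- classify_interfaces(observed, contact_range)
  ckeys <- imap$interfaces$key
  ckeys <- ckeys[!grepl(EXTERIOR, ckeys, fixed = TRUE)]
  contact_pairs <- do.call(rbind, lapply(ckeys, function(k) {
    p <- strsplit(k, "\\|")[[1]]
    data.frame(a = p[1], b = p[2], omega = 0, xi = 0.1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(contact_pairs))
    contact_pairs <- data.frame(a = character(), b = character(),
                                omega = numeric(), xi = numeric())
  tab <- build_parameter_table(observed, schedule, ckeys, omega0)
  vols <- vapply(observed$cells, function(m) geometry(m)$volume, numeric(1))
  R0 <- mean((3 * vols / (4 * pi))^(1 / 3))
  tab$step <- param_steps(tab, config, vols, R0)
  # penalty weights: small relative to the initial deformation error
  lam0 <- list(adh = config$lambda_adh, ring = config$lambda_ring,
               prot = config$lambda_prot)
  ev0 <- fides_evaluate(observed, tab, schedule, contact_pairs, config,
                        c(adh = 0, ring = 0, prot = 0))
  if (!is.finite(ev0$total)) stop("initial evaluation diverged")
  lambdas <- c(adh = lam0$adh %||% (1e-3 * ev0$E_D),
               ring = lam0$ring %||% (1e-3 * ev0$E_D),
               prot = lam0$prot %||% (1e-3 * ev0$E_D))
  baseline <- fides_evaluate(observed, tab, schedule, contact_pairs, config,
                             lambdas)
  trace <- data.frame(iter = 0, total = baseline$total, E_D = baseline$E_D,
                      accepted = 0)
  best_total <- baseline$total
  stall <- 0
  np <- nrow(tab)
  for (iter in seq_len(config$max_iters)) {
    proposals <- stats::rnorm(np, 0, tab$step)
    accepted <- logical(np)
    # each parameter is perturbed and evaluated independently against the
    # same baseline (order must not matter)
    for (p in seq_len(np)) {
      tp <- tab
      tp$value[p] <- min(max(tp$value[p] + proposals[p], tp$lower[p]),
                         tp$upper[p])
      if (tp$value[p] == tab$value[p]) next
      ev <- fides_evaluate(observed, tp, schedule, contact_pairs, config,
                           lambdas)
      if (ev$total < baseline$total) accepted[p] <- TRUE
    }
    if (any(accepted)) {
      tab$value[accepted] <- pmin(pmax(tab$value[accepted] +
                                         proposals[accepted],
                                       tab$lower[accepted]),
                                  tab$upper[accepted])
      # gauge: mean surface tension fixed at 1; adhesions rescale with it
      gsel <- tab$kind == "gamma"
      sc <- mean(tab$value[gsel])
      if (sc > 0) {
        tab$value[gsel] <- tab$value[gsel] / sc
        osel <- tab$kind == "omega"
        tab$value[osel] <- tab$value[osel] / sc
      }
      baseline <- fides_evaluate(observed, tab, schedule, contact_pairs,
                                 config, lambdas)
    }
    trace <- rbind(trace, data.frame(iter = iter, total = baseline$total,
                                     E_D = baseline$E_D,
                                     accepted = sum(accepted)))
    if (verbose)
      message(sprintf("iter %3d: total %.5g (E_D %.5g), %d/%d accepted",
                      iter, baseline$total, baseline$E_D, sum(accepted), np))
    if (baseline$total < best_total - 1e-12) {
      best_total <- baseline$total
      stall <- 0
    } else stall <- stall + 1
    if (stall >= config$patience) break
  }
  gamma <- stats::setNames(tab$value[tab$kind == "gamma"],
                           tab$target[tab$kind == "gamma"])
  omega <- stats::setNames(tab$value[tab$kind == "omega"],
                           tab$target[tab$kind == "omega"])
  res <- normalize_solution(gamma, omega)
  vstar <- stats::setNames(tab$value[tab$kind == "V_star"],
                           tab$target[tab$kind == "V_star"])
  fitted_state <- state_from_params(observed, tab, schedule, contact_pairs)
  structure(list(gamma = res$gamma, omega = res$omega,
                 gamma_ij = res$gamma_ij, V_star = vstar,
                 active = fitted_state$active, trace = trace,
                 baseline = baseline$total, n_iters = max(trace$iter)),
            class = "fides_result")
}

#' Normalize a tension solution to mean surface tension 1
#'
#' Reported tensions are `gamma / gamma0` and `omega / gamma0` with
#' `gamma0` the mean surface tension, so the reported surface tensions
#' average exactly 1.
#'
#' @param gamma named per-cell surface tensions.
#' @param omega named per-contact adhesive tensions.
#' @return list with normalized `gamma`, `omega` and derived `gamma_ij`.
#' @export
normalize_solution <- function(gamma, omega) {
  g0 <- mean(gamma)
  gamma <- gamma / g0
  omega <- omega / g0
  gij <- vapply(names(omega), function(k) {
    p <- strsplit(k, "\\|")[[1]]
    gamma[p[1]] + gamma[p[2]] - omega[k]
  }, numeric(1))
  list(gamma = gamma, omega = omega, gamma_ij = gij)
}

#' @export
print.fides_result <- function(x, ...) {
  cat(sprintf("<fides_result: %d cells, %d contacts, %d active models, %d iterations, objective %.4g>\n",
              length(x$gamma), length(x$omega), length(x$active),
              x$n_iters, x$baseline))
  cat("gamma:\n"); print(round(x$gamma, 4))
  cat("omega:\n"); print(round(x$omega, 4))
  invisible(x)
}
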