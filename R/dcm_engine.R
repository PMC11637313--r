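# Forward deformable cell model: parameters, embryo state, nodal forces,
# overdamped relaxation to quasi-static equilibrium.

#' Per-cell mechanical parameters
#'
#' @param gamma surface tension (force/length; nondimensional internally).
#' @param V_star equilibrium volume; pressure follows `P = K (V*-V)/V*`.
#' @param bulk_modulus volume-conservation bulk modulus K (pressure units).
#' @return list of class `cell_params`.
#' @export
cell_params <- function(gamma = 1, V_star = NULL, bulk_modulus = 50) {
  stopifnot(gamma >= 0, bulk_modulus > 0)
  structure(list(gamma = gamma, V_star = V_star, bulk_modulus = bulk_modulus),
            class = "cell_params")
}

#' Simulation configuration
#'
#' Lengths are resolved relative to the mean cell radius R0 and the mean
#' surface tension gamma0 of the embryo at run time, so the same
#' configuration applies to micrometre-scale and nondimensional meshes.
#' Time is nondimensional (cortical viscous time eta*t_c/gamma).
#'
#' @param dt time step.
#' @param t_end duration; the shape-fitting evaluations use 2.5.
#' @param medium_drag nodal drag coefficient per unit area.
#' @param contact_range contact detection gap, in units of R0.
#' @param repulsion_stiffness contact penalty stiffness, gamma0/R0^2 units.
#' @param shell_stiffness eggshell penalty stiffness, gamma0/R0^2 units.
#' @param friction_xi default tangential contact friction.
#' @param contact_extra_drag additional drag multiplier on nodes currently
#'   in contact (wet interface friction; damps stiff contact dynamics
#'   without changing the static balance).
#' @param cortex_viscosity in-plane damping on edge-length rate.
#' @param mesh_smoothing per-step tangential mesh-regularization coefficient
#'   (nodes relax toward their neighbor average within the tangent plane;
#'   keeps the triangulation sliver-free without changing the shape).
#' @param tol quasi-static stop tolerance on max nodal speed (R0 per unit
#'   time); 0 disables early stopping.
#' @param check_every steps between stop checks.
#' @param neighbor_every steps between contact neighbor-list rebuilds.
#' @param penetration_cap cap on penalty penetration depth, units of R0.
#' @param divergence_cap abort if any node moves further than this (units of
#'   R0) in one step.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1e-3, t_end = 2.5, medium_drag = 1,
                              contact_range = 0.1, repulsion_stiffness = 1000,
                              shell_stiffness = 1000, friction_xi = 0.1,
                              contact_extra_drag = 4, cortex_viscosity = 0.05,
                              mesh_smoothing = 0.05, tol = 0,
                              check_every = 50, neighbor_every = 10,
                              penetration_cap = 0.05, divergence_cap = 0.1) {
  stopifnot(dt > 0, t_end > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Assemble an embryo state
#'
#' @param cells named list of `cell_mesh` objects.
#' @param params named list of `cell_params` (one per cell); missing entries
#'   get defaults with `V_star` set to the current mesh volume.
#' @param contacts data.frame with columns `a`, `b` (cell ids), `omega`
#'   (adhesive tension) and optionally `xi` (friction); if NULL, every pair
#'   of cells whose bounding boxes approach is given a potential contact with
#'   `omega = 0`.
#' @param eggshell optional `eggshell` object.
#' @param active list of active model specs (`ring_spec`/`protrusion_spec`
#'   entries tagged with `cell`).
#' @return object of class `embryo_state`.
#' @export
embryo_state <- function(cells, params = NULL, contacts = NULL,
                         eggshell = NULL, active = list()) {
  stopifnot(length(cells) >= 1)
  ids <- vapply(cells, function(m) m$id, character(1))
  names(cells) <- ids
  if (is.null(params)) params <- list()
  for (id in ids) {
    if (is.null(params[[id]])) params[[id]] <- cell_params()
    if (is.null(params[[id]]$V_star))
      params[[id]]$V_star <- geometry(cells[[id]])$volume
  }
  if (is.null(contacts)) contacts <- candidate_contacts(cells)
  if (is.null(contacts$xi)) contacts$xi <- 0.1
  # interfacial tension must be non-negative
  gam <- vapply(params[ids], function(p) p$gamma, numeric(1))
  if (nrow(contacts)) {
    gij <- gam[contacts$a] + gam[contacts$b] - contacts$omega
    if (any(gij < 0))
      stop("contact with negative interfacial tension (omega too large): ",
           paste(contacts$a[gij < 0], contacts$b[gij < 0], collapse = ", "))
  }
  structure(list(cells = cells, params = params[ids], contacts = contacts,
                 eggshell = eggshell, active = active),
            class = "embryo_state")
}

candidate_contacts <- function(cells, slack = 0.3) {
  ids <- vapply(cells, function(m) m$id, character(1))
  out <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      bi <- apply(cells[[i]]$vertices, 2, range)
      bj <- apply(cells[[j]]$vertices, 2, range)
      gap <- pmax(bj[1, ] - bi[2, ], bi[1, ] - bj[2, ])
      scale <- mean(bi[2, ] - bi[1, ])
      if (all(gap < slack * scale))
        out[[length(out) + 1]] <- data.frame(a = ids[i], b = ids[j],
                                             omega = 0, xi = 0.1,
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(), omega = numeric(),
                      xi = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Mean cell radius of an embryo (sphere-equivalent)
#' @param state an `embryo_state`.
#' @return numeric R0.
#' @export
mean_cell_radius <- function(state) {
  vols <- vapply(state$cells, function(m) geometry(m)$volume, numeric(1))
  mean((3 * vols / (4 * pi))^(1 / 3))
}

# ---------------------------------------------------------------------------
# Individual force fields (mainly for testing and diagnostics; the relax loop
# recomputes them internally in C++).

#' Surface-tension nodal forces (negative gradient of gamma * area)
#' @param mesh a `cell_mesh`.
#' @param gamma surface tension.
#' @return n x 3 force matrix.
#' @export
tension_forces <- function(mesh, gamma) {
  cpp_tension_forces(mesh$vertices, mesh$faces - 1L, gamma)
}

#' Volumetric pressure and its nodal forces
#' @param mesh a `cell_mesh`.
#' @param params a `cell_params` (uses `bulk_modulus`, `V_star`).
#' @return list with scalar `P`, `forces` (n x 3), `volume`.
#' @export
pressure_forces <- function(mesh, params) {
  V_star <- if (is.null(params$V_star)) geometry(mesh)$volume else params$V_star
  cpp_pressure_forces(mesh$vertices, mesh$faces - 1L, params$bulk_modulus, V_star)
}

#' Contact forces between two cells
#' @param cell_a,cell_b `cell_mesh` objects.
#' @param omega adhesive tension.
#' @param xi tangential friction (needs velocities; zero in this static call).
#' @param contact_range detection gap (absolute length).
#' @param repulsion_stiffness penalty stiffness (absolute units).
#' @return list with `forces_a`, `forces_b`, `contact_area`.
#' @export
contact_forces <- function(cell_a, cell_b, omega, xi = 0,
                           contact_range = 0.1, repulsion_stiffness = 600) {
  cpp_contact_forces(cell_a$vertices, cell_a$faces - 1L,
                     cell_b$vertices, cell_b$faces - 1L,
                     omega, xi, contact_range, repulsion_stiffness)
}

#' Eggshell penalty forces on one cell
#' @param mesh a `cell_mesh`.
#' @param shell an `eggshell`.
#' @param stiffness penalty stiffness (absolute units).
#' @param cap penetration depth cap (absolute length).
#' @return n x 3 force matrix (inward on penetrating nodes).
#' @export
shell_forces <- function(mesh, shell, stiffness = 600, cap = Inf) {
  cpp_shell_forces(mesh$vertices, mesh$faces - 1L, shell$normals,
                   shell$offsets, stiffness, cap)
}

# ---------------------------------------------------------------------------

# Discrete-contact adhesion calibration.
#
# With ~1300-triangle cell meshes and a contact range of 0.1 R0, the
# emergent work of separation of the Maugis-style traction differs from the
# nominal adhesive tension: the finite range adds spurious adhesion across
# shallow junction wedges and zipping resistance removes some at wide
# wedges. The internal traction parameter is therefore set through a fixed
# monotone map measured once on relaxed equal-tension doublets (junction
# angle -> effective omega via the Young-Dupre relation), so that the
# emergent adhesive tension matches the requested one. The map is applied
# in units of the mean surface tension of the contacting pair.
.adhesion_calibration <- data.frame(
  eff = c(0, 0.170, 0.354, 0.502, 0.664, 0.801, 0.898),
  int = c(0, 0.05, 0.20, 0.383, 0.60, 1.20, 1.84))

calibrate_adhesion <- function(omega, gamma_pair_mean) {
  if (omega <= 0) return(0)
  x <- omega / gamma_pair_mean
  cal <- .adhesion_calibration
  if (x >= max(cal$eff)) {
    # extrapolate with the last segment's slope
    n <- nrow(cal)
    sl <- (cal$int[n] - cal$int[n - 1]) / (cal$eff[n] - cal$eff[n - 1])
    xi <- cal$int[n] + sl * (x - cal$eff[n])
  } else {
    xi <- stats::approx(cal$eff, cal$int, xout = x)$y
  }
  xi * gamma_pair_mean
}

resolve_config <- function(state, config) {
  R0 <- mean_cell_radius(state)
  gamma0 <- mean(vapply(state$params, function(p) p$gamma, numeric(1)))
  gamma0 <- max(gamma0, 1e-8)
  list(
    dt = config$dt,
    n_steps = as.integer(ceiling(config$t_end / config$dt)),
    drag = config$medium_drag,
    contact_range = config$contact_range * R0,
    k_rep = config$repulsion_stiffness * gamma0 / R0^2,
    shell_stiffness = config$shell_stiffness * gamma0 / R0^2,
    eta_edge = config$cortex_viscosity,
    tol = config$tol * R0,
    check_every = as.integer(config$check_every),
    nl_every = as.integer(config$neighbor_every),
    pen_cap = config$penetration_cap * R0,
    div_cap = config$divergence_cap * R0,
    contact_extra_drag = config$contact_extra_drag,
    mesh_smoothing = config$mesh_smoothing,
    R0 = R0, gamma0 = gamma0)
}

build_sim_inputs <- function(state, config) {
  cfg <- resolve_config(state, config)
  ids <- names(state$cells)
  cells <- lapply(ids, function(id) {
    m <- state$cells[[id]]
    p <- state$params[[id]]
    list(V = m$vertices, F = m$faces - 1L, gamma = p$gamma,
         K = p$bulk_modulus, V_star = p$V_star)
  })
  contacts <- list()
  if (nrow(state$contacts)) {
    for (k in seq_len(nrow(state$contacts))) {
      ga <- state$params[[state$contacts$a[k]]]$gamma
      gb <- state$params[[state$contacts$b[k]]]$gamma
      contacts[[k]] <- list(a = match(state$contacts$a[k], ids) - 1L,
                            b = match(state$contacts$b[k], ids) - 1L,
                            omega = calibrate_adhesion(state$contacts$omega[k],
                                                       max((ga + gb) / 2, 1e-8)),
                            xi = state$contacts$xi[k] %||% 0.1)
    }
  }
  shell <- NULL
  if (!is.null(state$eggshell))
    shell <- list(N = state$eggshell$normals, d = state$eggshell$offsets)
  rings <- list(); prots <- list()
  for (a in state$active) {
    ci <- match(a$cell, ids)
    if (is.na(ci)) stop("active model references unknown cell: ", a$cell)
    if (identical(a$type, "ring")) {
      rr <- realize_ring(state$cells[[ci]], a)
      rings[[length(rings) + 1]] <- list(
        cell = ci - 1L, nodes = rr$nodes - 1L, k = a$k,
        K_D = a$K_D %||% 10, sigma = rr$sigma,
        tri_side = rr$tri_side, node_side = rr$node_side,
        aref1 = rr$aref1, aref2 = rr$aref2)
    } else if (identical(a$type, "protrusion")) {
      prots[[length(prots) + 1]] <- list(
        cell = ci - 1L, axis = spherical_axis(a$theta, a$phi),
        alpha = a$alpha, F_P = a$F_P)
    } else stop("unknown active model type: ", a$type)
  }
  list(cells = cells, contacts = contacts, shell = shell,
       rings = rings, prots = prots, cfg = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relax an embryo to (quasi-)static equilibrium
#'
#' Explicit overdamped integration `x <- x + dt * F / (drag * A_i)` of all
#' DCM forces until `t_end`, or earlier once the maximum nodal speed falls
#' below `tol`.
#'
#' @param state an `embryo_state`.
#' @param config a `simulation_config`.
#' @return updated `embryo_state`, with attributes `diagnostics` (volumes,
#'   pressures, areas, contact areas, steps run, final max nodal speed).
#' @export
relax <- function(state, config = simulation_config()) {
  inp <- build_sim_inputs(state, config)
  res <- cpp_relax(inp$cells, inp$contacts, inp$shell, inp$rings, inp$prots,
                   inp$cfg)
  if (res$diverged)
    stop("simulation diverged (per-step displacement exceeded ",
         config$divergence_cap, " * R0); reduce dt or stiffnesses")
  out <- state
  for (i in seq_along(out$cells))
    out$cells[[i]]$vertices <- res$positions[[i]]
  attr(out, "diagnostics") <- list(
    volumes = as.numeric(res$volumes), pressures = as.numeric(res$pressures),
    areas = as.numeric(res$areas),
    contact_areas = as.numeric(res$contact_areas),
    steps = res$steps, max_speed = res$max_speed)
  out
}

#' Relax with adhesion annealing
#'
#' Discrete contact lines pin: a junction stalls within a hysteresis band
#' around its equilibrium angle because single mesh nodes must snap in or
#' out of the adhesion well. Cycling all adhesive tensions around their
#' nominal values with a decaying amplitude drives every junction
#' repeatedly through zip and peel so it settles at the true equilibrium;
#' a final quiet phase relaxes at the nominal parameters. Used by the
#' synthetic-embryo generators to reach quasi-static foam states.
#'
#' @param state an `embryo_state`.
#' @param config a `simulation_config` (its `t_end` is ignored).
#' @param cycles number of up/down adhesion cycles.
#' @param amplitude initial relative amplitude of the adhesion modulation.
#' @param t_segment duration of each half-cycle.
#' @param t_final duration of the final quiet phase.
#' @return relaxed `embryo_state`.
#' @export
relax_annealed <- function(state, config = simulation_config(),
                           cycles = 6, amplitude = 0.35,
                           t_segment = 0.7, t_final = 5) {
  om0 <- state$contacts$omega
  cfg <- config
  cfg$divergence_cap <- max(cfg$divergence_cap, 10)
  for (k in seq_len(cycles)) {
    amp <- amplitude * (cycles - k + 1) / cycles
    for (sgn in c(1, -1)) {
      state$contacts$omega <- pmax(om0 * (1 + sgn * amp), 0)
      cfg$t_end <- t_segment
      state <- relax(state, cfg)
    }
  }
  state$contacts$omega <- om0
  cfg$t_end <- t_final
  relax(state, cfg)
}

#' Advance an embryo by a few steps (thin wrapper over [relax()])
#' @param state an `embryo_state`.
#' @param config a `simulation_config`.
#' @param n_steps number of steps to take.
#' @return updated `embryo_state`.
#' @export
step_embryo <- function(state, config = simulation_config(), n_steps = 1) {
  cfg <- config
  cfg$t_end <- n_steps * cfg$dt
  cfg$tol <- 0
  relax(state, cfg)
}

#' @export
print.embryo_state <- function(x, ...) {
  cat(sprintf("<embryo_state: %d cells (%s), %d contacts, eggshell: %s, %d active models>\n",
              length(x$cells), paste(names(x$cells), collapse = ", "),
              nrow(x$contacts), if (is.null(x$eggshell)) "no" else "yes",
              length(x$active)))
  invisible(x)
}
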