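# Ground-truth benchmark embryos: seeded generators that build foam-like and
# active/confined synthetic embryos by forward DCM relaxation with known
# parameters, for validating force-inference methods.

#' @rdname make_simple_embryo
#' @format NULL
NULL

new_ground_truth <- function(gamma, omega, V_star, active = list(),
                             eggshell = FALSE, seed = NA_integer_) {
  gamma <- gamma / mean(gamma) # reported tensions average 1
  keys <- names(omega)
  gij <- vapply(keys, function(k) {
    p <- strsplit(k, "\\|")[[1]]
    gamma[p[1]] + gamma[p[2]] - omega[k]
  }, numeric(1))
  structure(list(gamma = gamma, omega = omega, gamma_ij = gij,
                 V_star = V_star, active = active, eggshell = eggshell,
                 seed = seed),
            class = "ground_truth")
}

#' Four-cell diamond synthetic embryo
#'
#' Four cells of different volumes and surface tensions in a rhombus
#' ("diamond") arrangement with five distinct cell-cell contacts of varying
#' adhesive tension, relaxed to quasi-static equilibrium without eggshell
#' confinement. Surface tensions are drawn uniformly in
#' `[1 - spread, 1 + spread]` and normalized to mean 1; adhesive tensions
#' are drawn so all interfacial tensions stay positive.
#'
#' @param seed RNG seed (all randomness is drawn before simulation).
#' @param tension_spread half-width of the surface-tension distribution,
#'   in (0, 0.5].
#' @param subdiv icosphere subdivision of the initial cell meshes.
#' @param t_relax nondimensional initial relaxation time.
#' @param config base `simulation_config`.
#' @param anneal settle junctions with [relax_annealed()] after the initial
#'   relaxation.
#' @return list with `state` (relaxed `embryo_state`) and `truth`
#'   (`ground_truth`).
#' @export
make_simple_embryo <- function(seed = 1, tension_spread = 0.3, subdiv = 3,
                               t_relax = 6,
                               config = simulation_config(dt = 1.25e-3),
                               anneal = TRUE) {
  stopifnot(tension_spread > 0, tension_spread <= 0.5)
  set.seed(seed)
  ids <- c("C1", "C2", "C3", "C4")
  radii <- stats::runif(4, 0.9, 1.15)
  gamma <- stats::runif(4, 1 - tension_spread, 1 + tension_spread)
  gamma <- gamma / mean(gamma)
  names(gamma) <- ids
  # rhombus: C1/C2 on the long axis (not touching), C3/C4 on the short axis
  d34 <- 0.5 * (radii[3] + radii[4]) * 0.995
  ax1 <- sqrt(max((0.995 * (radii[1] + (radii[3] + radii[4]) / 2))^2 - d34^2, 0.2))
  ax2 <- sqrt(max((0.995 * (radii[2] + (radii[3] + radii[4]) / 2))^2 - d34^2, 0.2))
  centers <- rbind(c(-ax1, 0, 0), c(ax2, 0, 0), c(0, d34, 0), c(0, -d34, 0))
  pairs <- list(c("C1", "C3"), c("C1", "C4"), c("C2", "C3"), c("C2", "C4"),
                c("C3", "C4"))
  omega <- stats::setNames(stats::runif(5, 0.25, 0.65),
                           vapply(pairs, function(p) iface_key(p[1], p[2]),
                                  character(1)))
  # redraw any contact that would have negative interfacial tension
  for (k in names(omega)) {
    p <- strsplit(k, "\\|")[[1]]
    tries <- 0
    while (gamma[p[1]] + gamma[p[2]] - omega[k] <= 0.05 && tries < 100) {
      omega[k] <- stats::runif(1, 0.25, 0.65)
      tries <- tries + 1
    }
  }
  cells <- lapply(seq_along(ids), function(i)
    icosphere(subdiv, radius = radii[i], center = centers[i, ], id = ids[i]))
  contacts <- do.call(rbind, lapply(names(omega), function(k) {
    p <- strsplit(k, "\\|")[[1]]
    data.frame(a = p[1], b = p[2], omega = unname(omega[k]), xi = 0.1,
               stringsAsFactors = FALSE)
  }))
  params <- lapply(ids, function(id) cell_params(gamma = unname(gamma[id])))
  names(params) <- ids
  state <- embryo_state(cells, params, contacts)
  cfg <- config
  cfg$t_end <- t_relax
  cfg$divergence_cap <- max(cfg$divergence_cap, 10)
  state <- relax(state, cfg)
  if (anneal) state <- relax_annealed(state, config)
  V_star <- vapply(state$params, function(p) p$V_star, numeric(1))
  truth <- new_ground_truth(gamma, omega, V_star, seed = seed)
  list(state = state, truth = truth)
}

# canonical 7-cell arrangement (AP = x, DV = y, LR = z); positions and radii
# are a schematic layout chosen so that exactly the 15 intended contacts
# form under confinement
.seven_cell_layout <- function() {
  list(
    ids = c("ABal", "ABar", "ABpl", "ABpr", "MS", "E", "P2"),
    # the posterior AB pair is skewed toward -z (the left-right asymmetry
    # of the AB quartet), which also selects a single diagonal AB contact
    centers = rbind(
      ABal = c(-1.45, 0.45, -0.62),
      ABar = c(-1.45, 0.45, 0.62),
      ABpl = c(-0.25, 0.75, -0.83),
      ABpr = c(-0.25, 0.75, 0.53),
      MS   = c(-0.55, -0.72, 0.00),
      E    = c(0.75, -0.72, 0.00),
      P2   = c(1.50, 0.25, 0.00)),
    radii = c(ABal = 1.02, ABar = 1.02, ABpl = 1.00, ABpr = 1.00,
              MS = 0.92, E = 0.88, P2 = 0.95),
    contacts = list(
      c("ABal", "ABar"), c("ABal", "ABpl"), c("ABar", "ABpr"),
      c("ABpl", "ABpr"), c("ABal", "MS"), c("ABar", "MS"),
      c("ABpl", "MS"), c("ABpr", "MS"), c("ABpl", "E"), c("ABpr", "E"),
      c("MS", "E"), c("E", "P2"), c("ABpl", "P2"), c("ABpr", "P2"),
      c("ABal", "ABpr")))
}

#' Seven-cell confined active synthetic embryo
#'
#' A synthetic embryo modeled after the 7-cell stage: seven differently
#' parametrized cells with 15 cell-cell contacts of varying interfacial
#' tension, optionally confined by a rigid convex eggshell and optionally
#' carrying local force models (one cytokinetic ring on P2, three
#' protrusions on ABpl and one on ABpr). The four combinations of
#' `eggshell` and `active` reproduce the benchmark conditions under which
#' foam force inference degrades.
#'
#' @param seed RNG seed.
#' @param eggshell add rigid convex confinement (hull of the initial cells,
#'   shrunk to induce roughly 20% confinement strain).
#' @param active attach the ring and protrusions.
#' @param tension_spread half-width of the surface-tension distribution.
#' @param subdiv icosphere subdivision.
#' @param t_relax nondimensional relaxation time.
#' @param config base `simulation_config`.
#' @param shell_scale isotropic shrink factor of the hull eggshell; the
#'   default presses every cell against the shell while keeping clearly
#'   curved exterior surfaces (close encapsulation, not engulfment).
#' @param anneal settle junctions with [relax_annealed()] after the initial
#'   relaxation.
#' @return list with `state` and `truth`.
#' @export
make_advanced_embryo <- function(seed = 1, eggshell = TRUE, active = TRUE,
                                 tension_spread = 0.3, subdiv = 3,
                                 t_relax = 5,
                                 config = simulation_config(dt = 1.25e-3),
                                 shell_scale = 0.965, anneal = TRUE) {
  set.seed(seed)
  lay <- .seven_cell_layout()
  ids <- lay$ids
  gamma <- stats::runif(7, 1 - tension_spread, 1 + tension_spread)
  gamma <- gamma / mean(gamma)
  names(gamma) <- ids
  keys <- vapply(lay$contacts, function(p) iface_key(p[1], p[2]), character(1))
  omega <- stats::setNames(stats::runif(length(keys), 0.25, 0.65), keys)
  for (k in keys) {
    p <- strsplit(k, "\\|")[[1]]
    tries <- 0
    while (gamma[p[1]] + gamma[p[2]] - omega[k] <= 0.05 && tries < 100) {
      omega[k] <- stats::runif(1, 0.25, 0.65)
      tries <- tries + 1
    }
  }
  active_specs <- list()
  if (active) {
    active_specs <- list(
      ring_spec("P2", theta = 0.35, phi = pi / 2, d = 0.1, k = 1.5, K_D = 10),
      protrusion_spec("ABpl", theta = pi - 0.25, phi = -pi / 2, alpha = 0.5,
                      F_P = 1.5),
      protrusion_spec("ABpl", theta = 0.35, phi = pi / 2, alpha = 0.45,
                      F_P = 1.0),
      protrusion_spec("ABpl", theta = pi / 2, phi = pi, alpha = 0.45,
                      F_P = 1.0),
      protrusion_spec("ABpr", theta = pi - 0.25, phi = -pi / 2, alpha = 0.5,
                      F_P = 1.5))
  }
  cells <- lapply(ids, function(id)
    icosphere(subdiv, radius = lay$radii[id], center = lay$centers[id, ],
              id = id))
  # all pairs carry repulsion; only the intended 15 get adhesion
  contacts <- candidate_contacts(cells, slack = 2)
  contacts$omega <- 0
  for (k in keys) {
    p <- strsplit(k, "\\|")[[1]]
    hit <- (contacts$a == p[1] & contacts$b == p[2]) |
           (contacts$a == p[2] & contacts$b == p[1])
    contacts$omega[hit] <- omega[k]
  }
  params <- lapply(ids, function(id) cell_params(gamma = unname(gamma[id])))
  names(params) <- ids
  shell <- NULL
  if (eggshell) {
    allv <- do.call(rbind, lapply(cells, function(m) m$vertices))
    shell <- convex_hull_shell(allv, scale = shell_scale)
  }
  state <- embryo_state(cells, params, contacts, eggshell = shell,
                        active = active_specs)
  cfg <- config
  cfg$t_end <- t_relax
  cfg$divergence_cap <- max(cfg$divergence_cap, 10)
  state <- relax(state, cfg)
  if (anneal)
    state <- relax_annealed(state, config, cycles = 4, t_final = 4)
  V_star <- vapply(state$params, function(p) p$V_star, numeric(1))
  truth <- new_ground_truth(gamma, omega, V_star, active = active_specs,
                            eggshell = eggshell, seed = seed)
  list(state = state, truth = truth)
}

# ---------------------------------------------------------------------------
# Embryo bundle I/O: directory of per-cell meshes + annotation JSON
# (+ ground truth for synthetic embryos)

#' Write an embryo bundle to a directory
#' @param state an `embryo_state`.
#' @param dir output directory (created if missing).
#' @param truth optional `ground_truth` to include.
#' @param format mesh format extension.
#' @export
write_embryo_bundle <- function(state, dir, truth = NULL, format = "ply") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(state$cells))
    write_mesh(state$cells[[id]], file.path(dir, paste0(id, ".", format)))
  ann <- list(
    cells = names(state$cells),
    eggshell = !is.null(state$eggshell),
    params = lapply(state$params, function(p)
      list(gamma = p$gamma, V_star = p$V_star, bulk_modulus = p$bulk_modulus)),
    contacts = state$contacts,
    active = lapply(state$active, function(a) {
      a <- unclass(a)
      a[!vapply(a, is.null, logical(1))]
    }))
  jsonlite::write_json(ann, file.path(dir, "annotation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(state$eggshell)) {
    sh <- state$eggshell
    shm <- list(vertices = sh$vertices, faces = sh$faces)
    jsonlite::write_json(shm, file.path(dir, "eggshell.json"), digits = NA)
  }
  if (!is.null(truth)) {
    tr <- unclass(truth)
    for (f in c("gamma", "omega", "gamma_ij", "V_star"))
      tr[[f]] <- as.list(tr[[f]])
    tr$active <- lapply(tr$active, function(a) unclass(a))
    jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read an embryo bundle written by [write_embryo_bundle()]
#' @param dir bundle directory.
#' @return list with `state` and (if present) `truth`.
#' @export
read_embryo_bundle <- function(dir) {
  ann <- jsonlite::read_json(file.path(dir, "annotation.json"),
                             simplifyVector = TRUE)
  cells <- lapply(ann$cells, function(id) {
    for (ext in c("ply", "off", "stl", "vtk")) {
      p <- file.path(dir, paste0(id, ".", ext))
      if (file.exists(p)) return(read_mesh(p, id = id))
    }
    stop("mesh file for cell ", id, " not found in ", dir)
  })
  names(cells) <- ann$cells
  params <- lapply(ann$cells, function(id) {
    p <- ann$params[[id]]
    cell_params(gamma = p$gamma, V_star = p$V_star,
                bulk_modulus = p$bulk_modulus)
  })
  names(params) <- ann$cells
  shell <- NULL
  shp <- file.path(dir, "eggshell.json")
  if (isTRUE(ann$eggshell) && file.exists(shp)) {
    shm <- jsonlite::read_json(shp, simplifyVector = TRUE)
    V <- matrix(unlist(shm$vertices), ncol = 3)
    F3 <- matrix(as.integer(unlist(shm$faces)), ncol = 3)
    e1 <- V[F3[, 2], ] - V[F3[, 1], ]
    e2 <- V[F3[, 3], ] - V[F3[, 1], ]
    N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    N <- N / sqrt(rowSums(N^2))
    shell <- structure(list(vertices = V, faces = F3, normals = N,
                            offsets = rowSums(N * V[F3[, 1], ]),
                            centroid = colMeans(V)),
                       class = "eggshell")
  }
  active <- list()
  if (length(ann$active)) {
    active <- lapply(seq_len(if (is.data.frame(ann$active)) nrow(ann$active)
                             else length(ann$active)), function(i) {
      a <- if (is.data.frame(ann$active)) as.list(ann$active[i, ])
           else ann$active[[i]]
      if (a$type == "ring")
        ring_spec(a$cell, a$theta, a$phi, a$d, a$k, a$K_D,
                  if (is.null(a$smoothing_width) || is.na(a$smoothing_width))
                    NULL else a$smoothing_width)
      else
        protrusion_spec(a$cell, a$theta, a$phi, a$alpha, a$F_P)
    })
  }
  state <- embryo_state(cells, params,
                        contacts = as.data.frame(ann$contacts),
                        eggshell = shell, active = active)
  out <- list(state = state)
  gtp <- file.path(dir, "ground_truth.json")
  if (file.exists(gtp)) {
    g <- jsonlite::read_json(gtp, simplifyVector = TRUE)
    out$truth <- structure(list(
      gamma = unlist(g$gamma), omega = unlist(g$omega),
      gamma_ij = unlist(g$gamma_ij), V_star = unlist(g$V_star),
      active = active, eggshell = isTRUE(g$eggshell),
      seed = g$seed), class = "ground_truth")
  }
  out
}

#' Contact areas of a relaxed embryo (geometric, by interface)
#' @param state an `embryo_state`.
#' @param contact_range classification gap (default from mesh scale).
#' @return named numeric vector of interface areas (cell-cell only).
#' @export
contact_areas <- function(state, contact_range = NULL) {
  imap <- classify_interfaces(state, contact_range)
  sel <- !grepl(EXTERIOR, imap$interfaces$key, fixed = TRUE)
  # each interface is counted from both sides; halve the summed area
  stats::setNames(imap$interfaces$area[sel] / 2, imap$interfaces$key[sel])
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d cells, %d contacts, eggshell %s, %d active models, seed %s>\n",
              length(x$gamma), length(x$omega),
              if (isTRUE(x$eggshell)) "yes" else "no",
              length(x$active), x$seed))
  invisible(x)
}
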