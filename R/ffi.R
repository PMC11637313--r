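# Foam force inference: interface classification, triple-junction angle
# measurement, interface mean curvature, and least-squares solves of the
# Young-Dupre (tangent mode) and Young-Dupre + Young-Laplace (curved mode)
# systems.

EXTERIOR <- "EXTERIOR"

iface_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Classify mesh triangles into interfaces
#'
#' Each triangle of each cell is labeled with the partner cell whose surface
#' lies within `contact_range` of its centroid (nearest partner if several;
#' ambiguous triangles are counted), or EXTERIOR. The two facing patches of
#' a cell-cell contact form one interface with a shared interfacial tension.
#'
#' @param state an `embryo_state` (relaxed).
#' @param contact_range classification gap; default 1.2 x the simulation
#'   contact range (0.1 R0).
#' @return object of class `interface_map`: per-cell triangle labels,
#'   per-interface triangle counts and areas, ambiguous-triangle count.
#' @export
classify_interfaces <- function(state, contact_range = NULL) {
  ids <- names(state$cells)
  R0 <- mean_cell_radius(state)
  if (is.null(contact_range)) contact_range <- 0.12 * R0
  geos <- lapply(state$cells, geometry)
  labels <- list()
  ambiguous <- 0L
  for (i in seq_along(ids)) {
    mi <- state$cells[[i]]
    cen <- (mi$vertices[mi$faces[, 1], ] + mi$vertices[mi$faces[, 2], ] +
            mi$vertices[mi$faces[, 3], ]) / 3
    dmat <- matrix(Inf, nrow(cen), length(ids))
    for (j in seq_along(ids)) {
      if (i == j) next
      mj <- state$cells[[j]]
      # cheap reject: bounding boxes
      bi <- apply(cen, 2, range); bj <- apply(mj$vertices, 2, range)
      if (any(pmax(bj[1, ] - bi[2, ], bi[1, ] - bj[2, ]) > contact_range)) next
      dmat[, j] <- cpp_closest_point(cen, mj$vertices, mj$faces - 1L)$distance
    }
    near <- dmat <= contact_range
    nnear <- rowSums(near)
    ambiguous <- ambiguous + sum(nnear > 1)
    lab <- rep(EXTERIOR, nrow(cen))
    hasp <- nnear > 0
    if (any(hasp)) lab[hasp] <- ids[apply(dmat[hasp, , drop = FALSE], 1, which.min)]
    labels[[ids[i]]] <- lab
  }
  # interface table
  keys <- character(); count <- integer(); area <- numeric()
  tab <- new.env()
  for (i in seq_along(ids)) {
    lab <- labels[[ids[i]]]
    ta <- geos[[i]]$tri_area
    for (l in unique(lab)) {
      k <- iface_key(ids[i], l)
      cur <- tab[[k]] %||% c(0, 0)
      sel <- lab == l
      tab[[k]] <- cur + c(sum(sel), sum(ta[sel]))
    }
  }
  keys <- ls(tab)
  info <- do.call(rbind, lapply(keys, function(k) tab[[k]]))
  structure(list(labels = labels,
                 interfaces = data.frame(key = keys,
                                         n_triangles = as.integer(info[, 1]),
                                         area = info[, 2],
                                         stringsAsFactors = FALSE),
                 ambiguous = ambiguous, contact_range = contact_range),
            class = "interface_map")
}

# adjacency of triangles over shared edges: returns matrix m x 3 of neighbor
# triangle indices (NA on boundary, which cannot happen for closed meshes)
tri_adjacency <- function(faces) {
  m <- nrow(faces)
  he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tri_of <- rep(seq_len(m), 3)
  sp <- split(tri_of, key)
  adj <- matrix(NA_integer_, m, 3)
  slot <- rep(1L, m)
  for (p in sp) {
    if (length(p) == 2) {
      adj[p[1], slot[p[1]]] <- p[2]; slot[p[1]] <- slot[p[1]] + 1L
      adj[p[2], slot[p[2]]] <- p[1]; slot[p[2]] <- slot[p[2]] + 1L
    }
  }
  adj
}

#' Measure triple-junction angles
#'
#' Junction polylines are extracted where, on a cell mesh, triangles of two
#' different interface labels meet; at samples along the polyline, the
#' tangent direction of each of the three meeting surfaces is estimated from
#' interface triangles within a geodesic-radius neighborhood, projected into
#' the plane normal to the local junction tangent. The three sector angles
#' (summing to 2 pi) are averaged along the junction. Junctions touching an
#' interface with fewer than `min_triangles` triangles are omitted.
#'
#' @param state an `embryo_state`.
#' @param imap an `interface_map` from [classify_interfaces()].
#' @param min_triangles interface-size filter (default 50).
#' @param sample_radius tangent-estimation radius in mean edge lengths.
#' @return list of triple junctions; each has `regions` (3 region ids, cells
#'   or EXTERIOR), `angles` (named averaged sector angles, radians),
#'   `n_samples`, `points` (sample positions).
#' @export
measure_junctions <- function(state, imap, min_triangles = 50,
                              sample_radius = 2.5) {
  ids <- names(state$cells)
  small <- imap$interfaces$key[imap$interfaces$n_triangles < min_triangles]
  # collect interface triangle centroids/areas/normals once
  iface_tris <- new.env()
  for (i in seq_along(ids)) {
    m <- state$cells[[i]]
    g <- geometry(m)
    cen <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
            m$vertices[m$faces[, 3], ]) / 3
    e1 <- m$vertices[m$faces[, 2], ] - m$vertices[m$faces[, 1], ]
    e2 <- m$vertices[m$faces[, 3], ] - m$vertices[m$faces[, 1], ]
    trn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    trn <- trn / pmax(sqrt(rowSums(trn^2)), 1e-300)
    lab <- imap$labels[[ids[i]]]
    for (l in unique(lab)) {
      k <- iface_key(ids[i], l)
      sel <- lab == l
      cur <- iface_tris[[k]]
      add <- list(cen = cen[sel, , drop = FALSE], area = g$tri_area[sel],
                  normal = trn[sel, , drop = FALSE],
                  mesh = rep(i, sum(sel)))
      iface_tris[[k]] <- if (is.null(cur)) add else
        list(cen = rbind(cur$cen, add$cen), area = c(cur$area, add$area),
             normal = rbind(cur$normal, add$normal),
             mesh = c(cur$mesh, add$mesh))
    }
  }
  junctions <- list()
  seen <- character()
  for (i in seq_along(ids)) {
    m <- state$cells[[i]]
    lab <- imap$labels[[ids[i]]]
    adj <- tri_adjacency(m$faces)
    medge <- mean_edge_length(m)
    f <- m$faces
    # junction edges: shared edge between triangles with different labels
    for (t in seq_len(nrow(f))) {
      for (s in 1:3) {
        t2 <- adj[t, s]
        if (is.na(t2) || t2 < t) next
        if (lab[t] == lab[t2]) next
        regions <- sort(unique(c(ids[i], lab[t], lab[t2])))
        if (length(regions) != 3) next
        key <- paste(regions, collapse = "|")
        ve <- intersect(f[t, ], f[t2, ])
        if (length(ve) != 2) next
        ent <- list(key = key, v1 = ve[1], v2 = ve[2], cell = i)
        junctions[[length(junctions) + 1]] <- ent
        seen <- c(seen, key)
      }
    }
  }
  if (!length(junctions)) return(list())
  # flag interface triangles near ANY junction line: their orientation is
  # contaminated by the rounded junction cores and must not enter surface
  # fits
  medge_all <- mean(vapply(state$cells, mean_edge_length, numeric(1)))
  jv <- unique(do.call(rbind, lapply(junctions, function(e)
    rbind(state$cells[[e$cell]]$vertices[e$v1, ],
          state$cells[[e$cell]]$vertices[e$v2, ]))))
  jv2 <- rowSums(jv^2)
  for (k in ls(iface_tris)) {
    tr <- iface_tris[[k]]
    # min squared distance centroids -> junction vertices, vectorized
    cc2 <- rowSums(tr$cen^2)
    cross <- tr$cen %*% t(jv)
    d2min <- apply(sweep(-2 * cross, 2, jv2, "+") + cc2, 1, min)
    tr$clear <- d2min > (1.2 * medge_all)^2
    iface_tris[[k]] <- tr
  }
  ekey <- vapply(junctions, function(e) e$key, character(1))
  ecell <- vapply(junctions, function(e) e$cell, numeric(1))
  out <- list()
  for (key in unique(ekey)) {
    regions <- strsplit(key, "\\|")[[1]]
    pairs <- combn(regions, 2)
    pkeys <- apply(pairs, 2, function(p) iface_key(p[1], p[2]))
    if (any(pkeys %in% small)) next
    if (any(vapply(pkeys, function(k) is.null(iface_tris[[k]]), logical(1)))) next
    samp_angles <- list()
    samp_pts <- NULL
    # pool samples over the polylines of every member mesh, so per-mesh
    # sampling biases at two-sided interfaces cancel in the average
    for (ci in unique(ecell[ekey == key])) {
    ents <- junctions[ekey == key & ecell == ci]
    m <- state$cells[[ci]]
    medge <- mean_edge_length(m)
    # junction vertex chain(s)
    vids <- unique(unlist(lapply(ents, function(e) c(e$v1, e$v2))))
    edges <- unique(t(vapply(ents, function(e) sort(c(e$v1, e$v2)), numeric(2))))
    if (nrow(edges) < 2) next
    nbr <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    ordered <- order_polyline(vids, nbr)
    P <- m$vertices
    rgeo <- sample_radius * medge
    rfit <- 1.6 * rgeo
    npts <- length(ordered)
    if (npts < 3) next
    for (qi in seq_along(ordered)) {
      v <- ordered[qi]
      vp <- ordered[if (qi == 1) npts else qi - 1]
      vn <- ordered[if (qi == npts) 1 else qi + 1]
      jt <- P[vn, ] - P[vp, ]
      njt <- sqrt(sum(jt^2))
      if (njt < 1e-12) next
      jt <- jt / njt
      s0 <- P[v, ]
      # in-plane basis
      u <- if (abs(jt[1]) < 0.9) crossprod_3(jt, c(1, 0, 0)) else crossprod_3(jt, c(0, 1, 0))
      u <- u / sqrt(sum(u^2))
      w <- crossprod_3(jt, u)
      phis <- rep(NA_real_, 3)
      ok <- TRUE
      for (pi_ in 1:3) {
        tr <- iface_tris[[pkeys[pi_]]]
        rel <- sweep(tr$cen, 2, s0, "-")
        d2 <- rowSums(rel^2)
        # relaxed foam interfaces are spherical caps, so the surface
        # orientation at the junction is estimated by fitting a sphere (or
        # a plane if nearly flat) to interface triangles in a generous
        # neighborhood, excluding the rounded junction core; the tangent at
        # the junction sample follows from the fitted surface
        sel <- d2 < rfit^2 & tr$clear
        # a two-sided (cell-cell) interface is a parallel double layer; fit
        # only the sheet on the sampling mesh so the sphere fit is not
        # ill-conditioned by the twin sheet
        if (any(tr$mesh[sel] == ci)) sel <- sel & tr$mesh == ci
        if (sum(sel) < 6) sel <- d2 < rfit^2 & tr$mesh == ci & d2 > medge^2
        if (sum(sel) < 6) sel <- d2 < rfit^2 & d2 > medge^2
        if (sum(sel) < 3) { ok <- FALSE; break }
        relq <- rel[sel, , drop = FALSE]
        ww <- tr$area[sel]
        npatch <- fit_surface_normal(relq, ww, tr$normal[sel, , drop = FALSE])
        if (is.null(npatch)) { ok <- FALSE; break }
        # in-plane tangent of the surface, perpendicular to the junction
        tg <- crossprod_3(npatch, jt)
        # nearby centroids fix the sign (point away from the junction);
        # distant parts of a wrapped patch must not vote
        nearsel <- d2 < rgeo^2
        if (!any(nearsel)) nearsel <- sel
        reln <- rel[nearsel, , drop = FALSE]
        wwn <- tr$area[nearsel]
        if (sum(colSums(reln * wwn) * tg) < 0) tg <- -tg
        du <- sum(tg * u); dw <- sum(tg * w)
        if (du^2 + dw^2 < 1e-24) { ok <- FALSE; break }
        phis[pi_] <- atan2(dw, du)
      }
      if (!ok) next
      # sector angles between cyclically adjacent interfaces
      o <- order(phis)
      sect <- diff(c(phis[o], phis[o[1]] + 2 * pi))
      nm <- c(paste(pkeys[o[1]], pkeys[o[2]], sep = "~"),
              paste(pkeys[o[2]], pkeys[o[3]], sep = "~"),
              paste(pkeys[o[3]], pkeys[o[1]], sep = "~"))
      ang <- stats::setNames(sect, nm)
      samp_angles[[length(samp_angles) + 1]] <- ang
      samp_pts <- rbind(samp_pts, s0)
    }
    }
    if (length(samp_angles) < 3) next
    # average sector angles; sectors are keyed by ordered interface pairs --
    # normalize key orientation (a~b vs b~a describe the same sector only in
    # a consistent cyclic order, so collect both namings)
    allnm <- unique(unlist(lapply(samp_angles, names)))
    canon <- function(nm) {
      parts <- strsplit(nm, "~")[[1]]
      paste(sort(parts), collapse = "~")
    }
    acc <- new.env()
    for (ang in samp_angles) {
      for (nm in names(ang)) {
        ck <- canon(nm)
        acc[[ck]] <- c(acc[[ck]] %||% numeric(0), ang[[nm]])
      }
    }
    cks <- ls(acc)
    if (length(cks) != 3) next
    mean_ang <- vapply(cks, function(k) mean(acc[[k]]), numeric(1))
    # renormalize to sum exactly 2 pi
    mean_ang <- mean_ang * (2 * pi / sum(mean_ang))
    out[[length(out) + 1]] <- list(regions = regions, ifaces = pkeys,
                                   angles = mean_ang,
                                   n_samples = length(samp_angles),
                                   points = samp_pts)
  }
  out
}

# Surface normal at the local origin from a weighted algebraic sphere fit
# of triangle centroids (relative coordinates); falls back to the
# sign-aligned average triangle normal when the fit is ill-conditioned.
# `normals` supplies the orientation reference.
fit_surface_normal <- function(rel, w, normals) {
  ref <- normals[which.min(rowSums(rel^2)), ]
  flip <- sign(as.numeric(normals %*% ref))
  flip[flip == 0] <- 1
  nn <- normals * flip
  avg <- colSums(nn * w)
  if (sqrt(sum(avg^2)) < 1e-12) return(NULL)
  avg <- avg / sqrt(sum(avg^2))
  # linear extrapolation of the (aligned) normals in arc distance back to
  # the junction: first-order-exact on curved patches, robust on saddles
  ss <- sqrt(rowSums(rel^2))
  next_ <- avg
  if (length(unique(round(ss, 9))) >= 2) {
    sw <- sum(w); sm <- sum(w * ss) / sw
    den <- sum(w * (ss - sm)^2)
    if (den > 1e-18) {
      slope <- colSums(nn * (w * (ss - sm))) / den
      cand <- colSums(nn * w) / sw - slope * sm
      nl <- sqrt(sum(cand^2))
      if (nl > 1e-12) next_ <- cand / nl
    }
  }
  # algebraic sphere fit of the centroids: exact for the spherical caps of
  # a relaxed foam, used when consistent with the extrapolated normal
  sw2 <- sqrt(w / mean(w))
  A <- cbind(2 * rel, 1) * sw2
  y <- rowSums(rel^2) * sw2
  fit <- tryCatch(qr.solve(A, y), error = function(e) NULL)
  if (is.null(fit)) return(next_)
  ctr <- fit[1:3]
  R2 <- fit[4] + sum(ctr^2)
  if (!is.finite(R2) || R2 <= 0) return(next_)
  R <- sqrt(R2)
  n <- -ctr / max(sqrt(sum(ctr^2)), 1e-300)
  if (sum(n * next_) < 0) n <- -n
  # flatness threshold relative to the neighborhood extent, so the
  # estimator is invariant under global rescaling of the meshes
  if (R > 25 * max(ss)) return(next_)
  if (sum(n * next_) < cos(25 * pi / 180)) return(next_)
  n
}

order_polyline <- function(vids, nbr) {
  # greedy walk over the junction edge graph; works for loops and chains
  visited <- new.env()
  deg <- vapply(as.character(vids), function(v) length(nbr[[v]]), numeric(1))
  start <- vids[which.min(ifelse(deg == 2, 2, 1))]
  if (any(deg != 2)) start <- vids[which(deg != 2)[1]]
  path <- start
  visited[[as.character(start)]] <- TRUE
  cur <- start
  repeat {
    nxt <- setdiff(nbr[[as.character(cur)]],
                   path[max(1, length(path) - 1):length(path)])
    nxt <- nxt[vapply(as.character(nxt), function(v)
      is.null(visited[[v]]), logical(1))]
    if (!length(nxt)) break
    cur <- nxt[1]
    visited[[as.character(cur)]] <- TRUE
    path <- c(path, cur)
  }
  path
}

#' Per-interface mean curvature
#'
#' Area-weighted average of per-node mean curvature over the triangles of
#' each interface, excluding triangles within `junction_margin` mean edge
#' lengths of any triple junction. Sign convention: for interface key
#' `a|b` with `a < b`, H > 0 when the interface bows away from region `a`
#' (surface normal oriented a -> b); for cell-exterior interfaces, H > 0
#' when bowing outward. Interfaces with fewer than `min_triangles` triangles
#' are omitted (NA).
#'
#' @param state an `embryo_state`.
#' @param imap an `interface_map`.
#' @param junctions output of [measure_junctions()].
#' @param min_triangles size filter.
#' @param junction_margin exclusion margin in mean edge lengths.
#' @return named numeric vector of curvatures keyed like
#'   `interface_map$interfaces$key`.
#' @export
interface_curvatures <- function(state, imap, junctions, min_triangles = 50,
                                 junction_margin = 2) {
  ids <- names(state$cells)
  jpts <- do.call(rbind, lapply(junctions, function(j) j$points))
  acc <- new.env()
  for (i in seq_along(ids)) {
    m <- state$cells[[i]]
    g <- geometry(m)
    medge <- mean_edge_length(m)
    cen <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
            m$vertices[m$faces[, 3], ]) / 3
    Htri <- (g$mean_curvature[m$faces[, 1]] + g$mean_curvature[m$faces[, 2]] +
             g$mean_curvature[m$faces[, 3]]) / 3
    lab <- imap$labels[[ids[i]]]
    keep <- rep(TRUE, nrow(cen))
    if (!is.null(jpts) && nrow(jpts)) {
      # exclude triangles near any junction
      for (b in seq_len(nrow(cen))) {
        d2 <- min(colSums((t(jpts) - cen[b, ])^2))
        if (d2 < (junction_margin * medge)^2) keep[b] <- FALSE
      }
    }
    for (l in unique(lab)) {
      k <- iface_key(ids[i], l)
      sel <- lab == l & keep
      if (!any(sel)) next
      # orientation: mesh-i outward normal points from i toward partner; for
      # key a|b the convention is a -> b, so flip when i is the higher id
      parts <- strsplit(k, "\\|")[[1]]
      sgn <- if (l == EXTERIOR) 1 else if (ids[i] == parts[1]) 1 else -1
      cur <- acc[[k]] %||% c(0, 0)
      acc[[k]] <- cur + c(sum(sgn * Htri[sel] * g$tri_area[sel]),
                          sum(g$tri_area[sel]))
    }
  }
  keys <- imap$interfaces$key
  H <- stats::setNames(rep(NA_real_, length(keys)), keys)
  for (k in keys) {
    n_tri <- imap$interfaces$n_triangles[imap$interfaces$key == k]
    if (n_tri < min_triangles) next
    v <- acc[[k]]
    if (!is.null(v) && v[2] > 0) H[k] <- v[1] / v[2]
  }
  H
}

#' Solve the foam force inference system
#'
#' Tangent mode: two force-balance equations per triple junction (the
#' Young-Dupre balance of the three interfacial tensions in the plane normal
#' to the junction) plus one gauge row fixing the mean surface tension to 1;
#' solved by pseudo-inverse. Curved mode adds one Young-Laplace equation
#' `P_a - P_b = 2 H_ab gamma_ab` per measured interface curvature, with the
#' exterior pressure as reference 0, and returns per-cell pressures.
#'
#' @param state an `embryo_state` (used for the cell list).
#' @param junctions from [measure_junctions()].
#' @param imap from [classify_interfaces()].
#' @param mode `"tangent"` or `"curved"`.
#' @param min_triangles interface filter passed to curvature measurement.
#' @return object of class `tension_solution`: `gamma` (per cell, mean 1),
#'   `gamma_ij` (per contact), `omega` (adhesive tensions), `pressure`
#'   (curved mode), `residual`, `mode`, `n_equations`.
#' @export
solve_ffi <- function(state, junctions, imap, mode = c("tangent", "curved"),
                      min_triangles = 50) {
  mode <- match.arg(mode)
  ids <- names(state$cells)
  if (!length(junctions)) stop("no usable triple junctions")
  contact_keys <- sort(unique(unlist(lapply(junctions, function(j) {
    k <- j$ifaces
    k[!grepl(EXTERIOR, k, fixed = TRUE)]
  }))))
  # also include contacts present in the map (for curvature rows)
  ck2 <- imap$interfaces$key
  ck2 <- ck2[!grepl(EXTERIOR, ck2, fixed = TRUE) &
             imap$interfaces$n_triangles >= min_triangles]
  contact_keys <- sort(unique(c(contact_keys, ck2)))
  unknowns <- c(paste0("g:", ids), paste0("c:", contact_keys))
  if (mode == "curved") unknowns <- c(unknowns, paste0("P:", ids))
  nu <- length(unknowns)
  uidx <- function(u) match(u, unknowns)
  iface_unknown <- function(key) {
    parts <- strsplit(key, "\\|")[[1]]
    if (EXTERIOR %in% parts) paste0("g:", setdiff(parts, EXTERIOR))
    else paste0("c:", key)
  }
  A <- NULL; brhs <- numeric(0)
  for (j in junctions) {
    ang <- j$angles
    # reconstruct directions in a common junction plane from sector angles:
    # interfaces in cyclic order from the sector keys
    pk <- j$ifaces
    # sector key "x~y" (sorted); recover cyclic order: start at pk[1]
    cyc <- pk[1]
    remaining <- setdiff(pk, cyc)
    angs <- numeric(0)
    cur <- cyc
    for (q in 1:2) {
      found <- FALSE
      for (r in remaining) {
        kk <- paste(sort(c(cur, r)), collapse = "~")
        if (kk %in% names(ang)) {
          angs <- c(angs, ang[[kk]])
          cyc <- c(cyc, r)
          remaining <- setdiff(remaining, r)
          cur <- r
          found <- TRUE
          break
        }
      }
      if (!found) break
    }
    if (length(cyc) != 3) next
    phi <- c(0, angs[1], angs[1] + angs[2])
    rowc <- rep(0, nu); rows <- rep(0, nu)
    okrow <- TRUE
    for (q in 1:3) {
      un <- iface_unknown(cyc[q])
      pos <- uidx(un)
      if (is.na(pos)) { okrow <- FALSE; break }
      rowc[pos] <- rowc[pos] + cos(phi[q])
      rows[pos] <- rows[pos] + sin(phi[q])
    }
    if (!okrow) next
    A <- rbind(A, rowc, rows)
    brhs <- c(brhs, 0, 0)
  }
  if (mode == "curved") {
    H <- interface_curvatures(state, imap, junctions, min_triangles)
    for (k in names(H)) {
      if (is.na(H[k])) next
      parts <- strsplit(k, "\\|")[[1]]
      row <- rep(0, nu)
      if (EXTERIOR %in% parts) {
        cell <- setdiff(parts, EXTERIOR)
        if (!(paste0("P:", cell) %in% unknowns)) next
        row[uidx(paste0("P:", cell))] <- 1
        row[uidx(paste0("g:", cell))] <- -2 * H[k]
      } else {
        row[uidx(paste0("P:", parts[1]))] <- 1
        row[uidx(paste0("P:", parts[2]))] <- -1
        row[uidx(paste0("c:", k))] <- -2 * H[k]
      }
      A <- rbind(A, row)
      brhs <- c(brhs, 0)
    }
  }
  # gauge: mean surface tension = 1
  gau <- rep(0, nu)
  gau[seq_along(ids)] <- 1 / length(ids)
  A <- rbind(A, gau)
  brhs <- c(brhs, 1)
  sv <- svd(A, nu = min(dim(A)), nv = nu)
  rank <- sum(sv$d > max(dim(A)) * .Machine$double.eps * max(sv$d))
  if (rank < nu) {
    ns <- sv$v[, (rank + 1):nu, drop = FALSE]
    bad <- unknowns[rowSums(abs(ns)) > 1e-8]
    stop("FFI system is rank-deficient; unconstrained unknowns: ",
         paste(bad, collapse = ", "))
  }
  keep <- seq_len(rank)
  x <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% brhs) / sv$d[keep])
  x <- as.numeric(x)
  names(x) <- unknowns
  gam <- x[paste0("g:", ids)]
  # exact gauge: homogeneous rows are scale-invariant
  sc <- mean(gam)
  gam <- gam / sc
  gij <- x[paste0("c:", contact_keys)] / sc
  names(gam) <- ids
  names(gij) <- contact_keys
  omega <- vapply(contact_keys, function(k) {
    parts <- strsplit(k, "\\|")[[1]]
    gam[parts[1]] + gam[parts[2]] - gij[k]
  }, numeric(1))
  press <- NULL
  if (mode == "curved") {
    press <- x[paste0("P:", ids)] / sc
    names(press) <- ids
  }
  resid <- sqrt(sum((A %*% (x / sc) - c(rep(0, length(brhs) - 1), 1 / sc))^2))
  structure(list(gamma = gam, gamma_ij = gij, omega = omega,
                 pressure = press, residual = resid, mode = mode,
                 n_equations = nrow(A)),
            class = "tension_solution")
}

#' Run foam force inference end to end
#' @param state a relaxed `embryo_state`.
#' @param mode `"tangent"` or `"curved"`.
#' @param contact_range classification gap (default from mesh scale).
#' @param min_triangles interface-size filter.
#' @return a `tension_solution`.
#' @export
ffi <- function(state, mode = c("tangent", "curved"), contact_range = NULL,
                min_triangles = 50) {
  mode <- match.arg(mode)
  imap <- classify_interfaces(state, contact_range)
  jx <- measure_junctions(state, imap, min_triangles)
  solve_ffi(state, jx, imap, mode, min_triangles)
}

#' Pooled Pearson correlation between a solution and ground truth
#'
#' Pools normalized surface tensions (per cell) and interfacial tensions
#' (per contact) of the inferred solution and the generating ground truth.
#'
#' @param solution a `tension_solution` (or FIDES result with `gamma` and
#'   `omega`).
#' @param truth a `ground_truth` (from the synthetic generators).
#' @return Pearson r.
#' @export
tension_correlation <- function(solution, truth) {
  ids <- names(truth$gamma)
  g_inf <- solution$gamma[ids]
  keys <- names(truth$gamma_ij)
  gij_inf <- if (!is.null(solution$gamma_ij)) solution$gamma_ij[keys] else {
    vapply(keys, function(k) {
      parts <- strsplit(k, "\\|")[[1]]
      solution$gamma[parts[1]] + solution$gamma[parts[2]] - solution$omega[k]
    }, numeric(1))
  }
  x <- c(truth$gamma[ids], truth$gamma_ij[keys])
  y <- c(g_inf, gij_inf)
  ok <- is.finite(x) & is.finite(y)
  stats::cor(x[ok], y[ok])
}

#' @export
print.tension_solution <- function(x, ...) {
  cat(sprintf("<tension_solution (%s FFI): %d cells, %d contacts, residual %.3g>\n",
              x$mode, length(x$gamma), length(x$gamma_ij), x$residual))
  cat("gamma:\n"); print(round(x$gamma, 4))
  cat("gamma_ij:\n"); print(round(x$gamma_ij, 4))
  invisible(x)
}
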