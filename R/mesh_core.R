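# Mesh data structures, geometry kernels and mesh file I/O.

#' Create a validated cell mesh
#'
#' A cell surface is a closed, consistently wound triangle mesh with outward
#' normals and positive enclosed volume. Duplicate vertices are merged (at
#' 1e-6 of the bounding-box diagonal) before validation; meshes that remain
#' open or non-manifold are rejected rather than repaired.
#'
#' @param vertices numeric matrix (n x 3) of node positions (micrometres or
#'   nondimensional length).
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param id character label for the cell.
#' @param repair merge duplicate vertices before validating.
#' @return an object of class `cell_mesh` with elements `vertices`, `faces`,
#'   `id`.
#' @export
cell_mesh <- function(vertices, faces, id = "cell", repair = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (repair) {
    diag_len <- sqrt(sum((apply(vertices, 2, max) - apply(vertices, 2, min))^2))
    tol <- 1e-6 * max(diag_len, .Machine$double.eps)
    key <- apply(round(vertices / tol), 1, paste, collapse = "_")
    first <- !duplicated(key)
    if (!all(first)) {
      map <- match(key, key[first])
      vertices <- vertices[first, , drop = FALSE]
      faces[] <- map[faces]
    }
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces, id = as.character(id)),
                 class = "cell_mesh")
  validate_cell_mesh(m)
  m
}

validate_cell_mesh <- function(m) {
  f <- m$faces
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("mesh '", m$id, "' has degenerate (repeated-vertex) triangles")
  # closed 2-manifold: every directed edge appears exactly once and its
  # reverse exactly once (consistent winding)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fwd <- paste(he[, 1], he[, 2])
  rev <- paste(he[, 2], he[, 1])
  if (anyDuplicated(fwd))
    stop("non-manifold/open mesh '", m$id, "': duplicated directed edge")
  if (!all(fwd %in% rev))
    stop("non-manifold/open mesh '", m$id, "': boundary edge present")
  # Euler characteristic of a closed genus-0 surface
  n_e <- nrow(he) / 2
  chi <- nrow(m$vertices) - n_e + nrow(f)
  if (chi != 2)
    warning("mesh '", m$id, "' has Euler characteristic ", chi, " (expected 2)")
  vol <- cpp_mesh_geometry(m$vertices, m$faces - 1L)$volume
  if (vol <= 0)
    stop("mesh '", m$id, "' has non-positive enclosed volume (inward winding?)")
  invisible(m)
}

#' Per-node geometry of a cell mesh
#'
#' Computes outward unit node normals (area-weighted), mixed-Voronoi node
#' areas, discrete mean curvature (cotangent-Laplacian mean-curvature normal;
#' magnitude |Laplace(x)|/2, sign positive where the surface is locally
#' convex w.r.t. the outward normal), signed enclosed volume and total area.
#'
#' @param mesh a `cell_mesh`.
#' @return list with `normals` (n x 3), `voronoi_area` (n), `mean_curvature`
#'   (n), `volume`, `area`, `tri_area` (m).
#' @export
geometry <- function(mesh) {
  g <- cpp_mesh_geometry(mesh$vertices, mesh$faces - 1L)
  bad <- which(g$tri_area < 1e-12 * (g$area / nrow(mesh$faces)))
  if (length(bad))
    stop("mesh '", mesh$id, "' has degenerate triangles at indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  g
}

#' Euler characteristic of a mesh
#' @param mesh a `cell_mesh`.
#' @return integer V - E + F.
#' @export
euler_characteristic <- function(mesh) {
  f <- m_faces <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- nrow(unique(t(apply(he, 1, sort))))
  nrow(mesh$vertices) - e + nrow(f)
}

#' Normal-raycast distances between two meshes
#'
#' For each node of `source`, casts a ray along its outward normal in both
#' orientations and keeps the nearest intersection with `target`; nodes whose
#' rays miss the target fall back to the nearest-point distance and are
#' flagged.
#'
#' @param source,target `cell_mesh` objects.
#' @return list with `distance` (per source node) and `hit` (logical).
#' @export
raycast_distance <- function(source, target) {
  g <- geometry(source)
  cpp_raycast(source$vertices, g$normals, target$vertices, target$faces - 1L)
}

#' Convex eggshell from a point cloud
#'
#' Builds the convex hull of the supplied points (typically all embryo cell
#' nodes), optionally offset outward by `margin`, and returns a rigid shell
#' usable as confinement in the simulation.
#'
#' @param points numeric matrix (n x 3); at least 4 non-coplanar points.
#' @param margin outward plane offset (same units as points).
#' @param scale optional isotropic scaling of the hull about its centroid
#'   applied before the margin (values < 1 shrink the shell to confine).
#' @return object of class `eggshell`: `vertices`, `faces` (hull triangles,
#'   1-based into `vertices`), `normals` (outward unit face normals),
#'   `offsets` (plane offsets d with n . x <= d inside).
#' @export
convex_hull_shell <- function(points, margin = 0, scale = 1,
                              max_points = 400) {
  points <- as.matrix(points)
  # the hull of a dense embryo point cloud has far more faces than the
  # confinement needs; an even subsample keeps the shell cheap while
  # changing its shape by well under the mesh resolution
  if (nrow(points) > max_points)
    points <- points[round(seq(1, nrow(points), length.out = max_points)), ,
                     drop = FALSE]
  hull <- cpp_convex_hull(points)
  fidx <- hull$faces + 1L
  used <- sort(unique(as.vector(fidx)))
  vmap <- match(seq_len(nrow(points)), used)
  V <- points[used, , drop = FALSE]
  F3 <- matrix(vmap[fidx], ncol = 3)
  ctr <- colMeans(V)
  if (scale != 1) V <- sweep(sweep(V, 2, ctr, "-") * scale, 2, ctr, "+")
  e1 <- V[F3[, 2], ] - V[F3[, 1], ]
  e2 <- V[F3[, 3], ] - V[F3[, 1], ]
  N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  N <- N / sqrt(rowSums(N^2))
  d <- rowSums(N * V[F3[, 1], ]) + margin
  structure(list(vertices = V, faces = F3, normals = N, offsets = d,
                 centroid = ctr),
            class = "eggshell")
}

#' Signed distance of points to an eggshell (negative inside)
#' @param shell an `eggshell`.
#' @param points matrix (n x 3).
#' @return numeric vector; `max_f (n_f . x - d_f)`, exact near faces of a
#'   convex shell and a lower bound near edges.
#' @export
shell_signed_distance <- function(shell, points) {
  points <- as.matrix(points)
  s <- points %*% t(shell$normals)
  apply(sweep(s, 2, shell$offsets, "-"), 1, max)
}

# ---------------------------------------------------------------------------
# Mesh primitives

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; the standard well-conditioned
#' test and seed geometry (subdiv 2 = 320 triangles, 3 = 1280).
#'
#' @param subdiv number of 4-to-1 subdivisions of the icosahedron.
#' @param radius sphere radius.
#' @param center length-3 center.
#' @param id cell id.
#' @return a `cell_mesh`.
#' @export
icosphere <- function(subdiv = 2, radius = 1, center = c(0, 0, 0), id = "sphere") {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  V <- V / sqrt(rowSums(V^2))
  F3 <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    newF <- matrix(0L, nrow = 4 * nrow(F3), ncol = 3)
    Vlist <- V
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      p <- (Vlist[a, ] + Vlist[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      Vlist <<- rbind(Vlist, p)
      mid_cache[[key]] <- nrow(Vlist)
      nrow(Vlist)
    }
    for (i in seq_len(nrow(F3))) {
      a <- F3[i, 1]; b <- F3[i, 2]; cc <- F3[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4 * i - 3, ] <- c(a, ab, ca)
      newF[4 * i - 2, ] <- c(b, bc, ab)
      newF[4 * i - 1, ] <- c(cc, ca, bc)
      newF[4 * i, ] <- c(ab, bc, ca)
    }
    V <- Vlist; F3 <- newF
  }
  V <- V * radius
  V <- sweep(V, 2, center, "+")
  cell_mesh(V, F3, id = id, repair = FALSE)
}

#' Axis-aligned box mesh (12 triangles)
#' @param lo,hi length-3 corners.
#' @param id cell id.
#' @return a `cell_mesh`.
#' @export
box_mesh <- function(lo = c(-1, -1, -1), hi = c(1, 1, 1), id = "box") {
  V <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corners: 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  F3 <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = lo
    c(5, 6, 7), c(6, 8, 7),  # z = hi
    c(1, 2, 5), c(2, 6, 5),  # y = lo
    c(3, 7, 4), c(4, 7, 8),  # y = hi
    c(1, 5, 3), c(3, 5, 7),  # x = lo
    c(2, 4, 6), c(4, 8, 6))  # x = hi
  cell_mesh(V, F3, id = id, repair = FALSE)
}

# ---------------------------------------------------------------------------
# Mesh file I/O (PLY ascii/binary_little_endian, OFF, STL ascii, VTK legacy)

#' Read a triangle mesh file
#'
#' Supports PLY (ascii and binary little-endian), OFF, ascii STL and legacy
#' ascii VTK POLYDATA. The cell id defaults to the file name without
#' extension.
#'
#' @param path file path.
#' @param id optional cell id.
#' @return a `cell_mesh`.
#' @export
read_mesh <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  vf <- switch(ext,
               ply = read_ply(path),
               off = read_off(path),
               stl = read_stl_ascii(path),
               vtk = read_vtk_legacy(path),
               stop("unsupported mesh format: .", ext))
  cell_mesh(vf$vertices, vf$faces, id = id)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    header <- c(header, line)
    if (grepl("^end_header", line)) break
    if (length(header) > 200) stop("malformed PLY header")
  }
  fmt <- header[grepl("^format", header)][1]
  nv <- as.integer(sub(".*element vertex +", "", header[grepl("element vertex", header)][1]))
  nf <- as.integer(sub(".*element face +", "", header[grepl("element face", header)][1]))
  if (grepl("ascii", fmt)) {
    txt <- readLines(con)
    vl <- txt[seq_len(nv)]
    V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    fl <- txt[nv + seq_len(nf)]
    F3 <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
      x <- as.integer(x)
      if (x[1] != 3) stop("PLY contains non-triangular face")
      x[2:4] + 1L
    }))
  } else if (grepl("binary_little_endian", fmt)) {
    # assume x,y,z float32 vertex properties and uchar + 3 int32 face lists
    vprops <- sum(grepl("^property float", header))
    V <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv)) {
      vals <- readBin(con, "numeric", n = vprops, size = 4, endian = "little")
      V[i, ] <- vals[1:3]
    }
    F3 <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      if (cnt != 3) stop("PLY contains non-triangular face")
      F3[i, ] <- idx + 1L
    }
  } else stop("unsupported PLY format line: ", fmt)
  list(vertices = V, faces = F3)
}

read_off <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (!grepl("^OFF", txt[1])) stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  V <- do.call(rbind, lapply(strsplit(trimws(txt[2 + seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  F3 <- do.call(rbind, lapply(strsplit(trimws(txt[2 + nv + seq_len(nf)]), "\\s+"),
                              function(x) {
                                x <- as.integer(x)
                                if (x[1] != 3) stop("OFF contains non-triangular face")
                                x[2:4] + 1L
                              }))
  list(vertices = V, faces = F3)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  if (nrow(V) %% 3 != 0) stop("malformed STL")
  F3 <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F3) # duplicate vertices merged by cell_mesh()
}

read_vtk_legacy <- function(path) {
  txt <- readLines(path)
  ip <- grep("^POINTS", txt)[1]
  np <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  vals <- numeric(0)
  i <- ip + 1
  while (length(vals) < 3 * np) {
    vals <- c(vals, as.numeric(strsplit(trimws(txt[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  V <- matrix(vals[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  ic <- grep("^POLYGONS|^CELLS", txt)[1]
  ncl <- as.integer(strsplit(txt[ic], "\\s+")[[1]][2])
  F3 <- matrix(NA_integer_, ncl, 3)
  for (j in seq_len(ncl)) {
    x <- as.integer(strsplit(trimws(txt[ic + j]), "\\s+")[[1]])
    if (x[1] != 3) stop("VTK contains non-triangular cell")
    F3[j, ] <- x[2:4] + 1L
  }
  list(vertices = V, faces = F3)
}

#' Write a triangle mesh file (PLY ascii, OFF, STL ascii or VTK legacy)
#' @param mesh a `cell_mesh`.
#' @param path output path; format chosen by extension.
#' @export
write_mesh <- function(mesh, path) {
  V <- mesh$vertices; F3 <- mesh$faces
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(V)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(F3)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(V, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
    writeLines(apply(F3 - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
  } else if (ext == "off") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("OFF", paste(nrow(V), nrow(F3), 0)), con)
    writeLines(apply(V, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
    writeLines(apply(F3 - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("solid", mesh$id), con)
    for (i in seq_len(nrow(F3))) {
      tri <- V[F3[i, ], , drop = FALSE]
      n <- crossprod_3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      n <- n / max(sqrt(sum(n^2)), 1e-300)
      writeLines(c(paste("facet normal", paste(format(n, digits = 9), collapse = " ")),
                   "  outer loop",
                   paste("    vertex", apply(tri, 1, function(r)
                     paste(format(r, digits = 9), collapse = " "))),
                   "  endloop", "endfacet"), con)
    }
    writeLines(paste("endsolid", mesh$id), con)
  } else if (ext == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", mesh$id, "ASCII",
                 "DATASET POLYDATA", paste("POINTS", nrow(V), "double")), con)
    writeLines(apply(V, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
    writeLines(paste("POLYGONS", nrow(F3), 4 * nrow(F3)), con)
    writeLines(apply(F3 - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Load all cell meshes from files or a directory
#'
#' @param paths vector of mesh file paths, or a single directory containing
#'   them; ids are taken from file names.
#' @return named list of `cell_mesh` objects.
#' @export
load_meshes <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(ply|off|stl|vtk)$",
                        ignore.case = TRUE, full.names = TRUE)
  if (!length(paths)) stop("no mesh files found")
  meshes <- lapply(paths, read_mesh)
  ids <- vapply(meshes, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate cell ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(meshes) <- ids
  meshes
}

#' @export
print.cell_mesh <- function(x, ...) {
  g <- geometry(x)
  cat(sprintf("<cell_mesh '%s': %d nodes, %d triangles, volume %.4g, area %.4g>\n",
              x$id, nrow(x$vertices), nrow(x$faces), g$volume, g$area))
  invisible(x)
}
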