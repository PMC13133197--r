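#' Tetrahedral mesh container
#'
#' @param nodes numeric `n x 3` matrix of node coordinates (mm).
#' @param elems integer `m x 4` connectivity (1-based, positive volume).
#' @param elem_label integer per-element region label.
#' @return object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elems, elem_label = rep(1L, nrow(elems))) {
  nodes <- as.matrix(nodes)
  elems <- matrix(as.integer(elems), ncol = 4)
  if (max(elems) > nrow(nodes) || min(elems) < 1) stop("connectivity out of range")
  used <- sort(unique(as.vector(elems)))
  if (length(used) < nrow(nodes)) {
    # drop orphan nodes
    remap <- integer(nrow(nodes))
    remap[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]
    elems <- matrix(remap[elems], ncol = 4)
  }
  structure(list(nodes = nodes, elems = elems,
                 elem_label = as.integer(elem_label)),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  q <- mesh_quality(x)
  cat(sprintf("tet_mesh: %d nodes, %d elements, %d region(s)\n",
              nrow(x$nodes), nrow(x$elems), length(unique(x$elem_label))))
  cat(sprintf("  volume %.4g mm^3, quality (6*sqrt2*V/lmax^3) min %.3f mean %.3f\n",
              sum(q$volume), min(q$quality), mean(q$quality)))
  invisible(x)
}

#' Element volumes and shape quality
#'
#' Quality is the normalized volume `6*sqrt(2)*V / lmax^3` (1 for the
#' regular tetrahedron, 0 for degenerate).
#'
#' @param mesh a [tet_mesh].
#' @return list with `volume` and `quality` per element.
#' @export
mesh_quality <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elems
  a <- nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 2], , drop = FALSE]
  c_ <- nd[el[, 3], , drop = FALSE]
  d <- nd[el[, 4], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  vol <- (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
          u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
          u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  edge2 <- function(p, q) rowSums((p - q)^2)
  lmax <- sqrt(pmax(edge2(a, b), edge2(a, c_), edge2(a, d),
                    edge2(b, c_), edge2(b, d), edge2(c_, d)))
  list(volume = vol, quality = 6 * sqrt(2) * vol / lmax^3)
}

#' Element centroids
#' @param mesh a [tet_mesh].
#' @return `m x 3` matrix.
#' @export
element_centroids <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elems
  (nd[el[, 1], , drop = FALSE] + nd[el[, 2], , drop = FALSE] +
   nd[el[, 3], , drop = FALSE] + nd[el[, 4], , drop = FALSE]) / 4
}

# The six Kuhn tetrahedra of the unit cube (corner indices 0..7 with bit
# order x + 2y + 4z), all sharing the main diagonal 0-7; identical in every
# cell, hence face-conforming across cells.
kuhn_tets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  bits <- c(1L, 2L, 4L)
  t(vapply(perms, function(p) {
    v0 <- 0L
    v1 <- bits[p[1]]
    v2 <- v1 + bits[p[2]]
    v3 <- 7L
    c(v0, v1, v2, v3)
  }, integer(4)))
}

#' Tetrahedral mesh of labelled voxel regions
#'
#' Resamples the label grid to cubic cells of approximately
#' `target_edge_mm`, then splits every labelled cell into six Kuhn
#' tetrahedra (all cells identical, so the mesh is conforming). Element
#' labels inherit the cell label; total mesh volume equals the number of
#' labelled cells times the cell volume.
#'
#' @param labels an [image_volume] whose values are integer region labels
#'   (0 = outside), or a plain integer/logical array with attribute-free
#'   unit spacing.
#' @param target_edge_mm requested cell edge length in mm.
#' @param priority optional two-column matrix `(label, min_fraction)`: a
#'   cell is assigned the first listed label whose voxel fraction inside
#'   the cell reaches the given minimum, then the majority label among the
#'   rest. Preserves thin structures (a cortical shell thinner than the
#'   cell size) that plain centre-sampling loses. Default: centre
#'   sampling.
#' @param connectivity `"all"` keeps every labelled cell; `"largest"`
#'   keeps only the largest face-connected cell component (dropping
#'   floating fragments that would introduce rigid-body modes in a solve).
#' @return a [tet_mesh] with `cell_mm` and `grid` attributes.
#' @export
make_tet_mesh <- function(labels, target_edge_mm, priority = NULL,
                          connectivity = c("all", "largest")) {
  connectivity <- match.arg(connectivity)
  if (!inherits(labels, "image_volume"))
    labels <- image_volume(array(as.integer(labels), dim(labels)))
  lab <- labels$values
  if (!any(lab > 0)) stop("empty label region: nothing to mesh")
  step <- pmax(1L, as.integer(round(target_edge_mm / labels$spacing)))
  cell_mm <- step * labels$spacing
  d <- dim(lab)
  nc <- pmax(1L, d %/% step)
  if (is.null(priority)) {
    # sample the label at cell centres
    ci <- lapply(1:3, function(a) pmin((seq_len(nc[a]) - 1L) * step[a] +
                                         (step[a] + 1L) %/% 2L + 1L, d[a]))
    cl <- lab[ci[[1]], ci[[2]], ci[[3]], drop = FALSE]
    dim(cl) <- nc
  } else {
    vals <- sort(unique(lab[lab > 0]))
    fracs <- lapply(vals, function(v)
      aggregate_cells((lab == v) * 1, step, nc) / prod(step))
    names(fracs) <- as.character(vals)
    cl <- array(0L, nc)
    assigned <- array(FALSE, nc)
    for (r in seq_len(nrow(priority))) {
      v <- priority[r, 1]
      f <- fracs[[as.character(v)]]
      pick <- !assigned & f >= priority[r, 2]
      cl[pick] <- as.integer(v)
      assigned <- assigned | pick
    }
    # remaining cells: majority label, provided the cell is mostly inside
    solid <- Reduce(`+`, fracs)
    best_f <- array(0, nc)
    best_v <- array(0L, nc)
    for (v in vals) {
      f <- fracs[[as.character(v)]]
      upd <- f > best_f
      best_f[upd] <- f[upd]
      best_v[upd] <- as.integer(v)
    }
    pick <- !assigned & solid >= 0.5
    cl[pick] <- best_v[pick]
  }
  if (connectivity == "largest") {
    keep <- largest_component6(cl > 0)
    dropped <- sum(cl > 0) - sum(keep)
    if (dropped > 0)
      message("dropping ", dropped, " cells in floating fragments")
    cl[!keep] <- 0L
  }
  cells <- which(cl > 0, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("no labelled cells at this mesh size; refine target_edge_mm")
  nn <- nc + 1L
  node_id <- function(i, j, k) (k - 1L) * nn[1] * nn[2] + (j - 1L) * nn[1] + i
  corner_off <- cbind(x = bitwAnd(0:7, 1L), y = bitwAnd(0:7, 2L) %/% 2L,
                      z = bitwAnd(0:7, 4L) %/% 4L)
  kt <- kuhn_tets() + 1L  # corner indices 1..8
  ncell <- nrow(cells)
  corner_ids <- matrix(0L, ncell, 8)
  for (c8 in 1:8)
    corner_ids[, c8] <- node_id(cells[, 1] + corner_off[c8, 1],
                                cells[, 2] + corner_off[c8, 2],
                                cells[, 3] + corner_off[c8, 3])
  elems <- matrix(0L, ncell * 6, 4)
  for (t6 in 1:6)
    elems[seq(t6, by = 6, length.out = ncell), ] <- corner_ids[, kt[t6, ]]
  elem_label <- rep(as.integer(cl[cells]), each = 6)
  # only keep used global nodes
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nn[1] * nn[2] * nn[3])
  remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 4)
  uk <- used - 1L
  iz <- uk %/% (nn[1] * nn[2])
  iy <- (uk %% (nn[1] * nn[2])) %/% nn[1]
  ix <- uk %% nn[1]
  nodes <- cbind(labels$origin[1] - labels$spacing[1] / 2 + ix * cell_mm[1],
                 labels$origin[2] - labels$spacing[2] / 2 + iy * cell_mm[2],
                 labels$origin[3] - labels$spacing[3] / 2 + iz * cell_mm[3])
  # fix orientation: make every tet positive-volume
  mesh <- tet_mesh(nodes, elems, elem_label)
  q <- mesh_quality(mesh)
  neg <- q$volume < 0
  if (any(neg)) {
    tmp <- mesh$elems[neg, 2]
    mesh$elems[neg, 2] <- mesh$elems[neg, 3]
    mesh$elems[neg, 3] <- tmp
  }
  q <- mesh_quality(mesh)
  if (any(q$volume <= 0))
    stop("meshing failure: ", sum(q$volume <= 0), " non-positive elements")
  attr(mesh, "cell_mm") <- cell_mm
  attr(mesh, "grid") <- nc
  mesh
}

#' Select nodes by a coordinate predicate
#'
#' @param mesh a [tet_mesh].
#' @param predicate function of `(x, y, z)` vectors returning logical.
#' @return integer node indices.
#' @export
select_nodes <- function(mesh, predicate) {
  which(predicate(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
}

# ---- text-format mesh IO ---------------------------------------------------

#' Write a mesh as Abaqus INP
#'
#' Nodes, C3D4 elements, one element set per region label, and (optionally)
#' per-region anisotropic elastic blocks in Abaqus ordering.
#'
#' @param mesh a [tet_mesh].
#' @param path output path.
#' @param materials optional list mapping label -> 6x6 stiffness (package
#'   Voigt order) written as `*ELASTIC, TYPE=ANISOTROPIC`.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path, materials = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING\nhapcage tetrahedral mesh\n*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  for (lb in sort(unique(mesh$elem_label))) {
    sel <- which(mesh$elem_label == lb)
    writeLines(sprintf("*ELEMENT, TYPE=C3D4, ELSET=REGION%d", lb), con)
    e <- mesh$elems[sel, , drop = FALSE]
    writeLines(sprintf("%d, %d, %d, %d, %d", sel, e[, 1], e[, 2], e[, 3],
                       e[, 4]), con)
  }
  if (!is.null(materials)) {
    for (lb in names(materials)) {
      C <- materials[[lb]]
      writeLines(sprintf("*MATERIAL, NAME=MAT_REGION%s", lb), con)
      writeLines("*ELASTIC, TYPE=ANISOTROPIC", con)
      v <- voigt_to_abaqus_aniso(C)
      rows <- split(v, ceiling(seq_along(v) / 8))
      for (r in rows) writeLines(paste(sprintf("%.8g", r), collapse = ", "), con)
      writeLines(sprintf("*SOLID SECTION, ELSET=REGION%s, MATERIAL=MAT_REGION%s",
                         lb, lb), con)
    }
  }
  invisible(path)
}

# Package Voigt order (11,22,33,23,13,12) -> Abaqus anisotropic input, which
# uses order (11,22,33,12,13,23) and lower-triangle-by-row input.
voigt_to_abaqus_aniso <- function(C) {
  perm <- c(1, 2, 3, 6, 5, 4)
  Ca <- C[perm, perm]
  v <- numeric(21)
  k <- 1
  for (i in 1:6) for (j in 1:i) { v[k] <- Ca[i, j]; k <- k + 1 }
  v
}

#' Read an Abaqus INP tetrahedral mesh (minimal subset)
#'
#' Parses `*NODE`, `*ELEMENT TYPE=C3D4` (element sets from the `ELSET`
#' keyword) blocks.
#'
#' @param path INP file path.
#' @return a [tet_mesh].
#' @export
read_inp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "**")]
  upper <- toupper(lines)
  mode <- "none"
  nodes <- list(); node_ids <- list()
  elems <- list(); elem_labels <- list()
  lbl <- 1L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "*")) {
      u <- upper[i]
      if (startsWith(u, "*NODE") && !startsWith(u, "*NODE OUTPUT")) {
        mode <- "node"
      } else if (startsWith(u, "*ELEMENT") && grepl("C3D4", u)) {
        mode <- "elem"
        m <- regmatches(u, regexpr("ELSET=([A-Z0-9_]+)", u))
        lbl <- if (length(m)) {
          nm <- sub("ELSET=", "", m)
          num <- suppressWarnings(as.integer(gsub("[^0-9]", "", nm)))
          if (is.na(num)) lbl + 1L else num
        } else lbl + 1L
      } else mode <- "none"
      next
    }
    if (mode == "node") {
      v <- as.numeric(strsplit(ln, ",")[[1]])
      node_ids[[length(node_ids) + 1]] <- v[1]
      nodes[[length(nodes) + 1]] <- v[2:4]
    } else if (mode == "elem") {
      v <- as.integer(strsplit(ln, ",")[[1]])
      elems[[length(elems) + 1]] <- v[2:5]
      elem_labels[[length(elem_labels) + 1]] <- lbl
    }
  }
  ids <- unlist(node_ids)
  nd <- do.call(rbind, nodes)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  el <- matrix(remap[do.call(rbind, elems)], ncol = 4)
  tet_mesh(nd, el, unlist(elem_labels))
}

#' Write a mesh (and optional per-element data) as legacy ASCII VTK
#'
#' @param mesh a [tet_mesh].
#' @param path output path.
#' @param cell_data optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "hapcage mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  e0 <- mesh$elems - 1L
  writeLines(sprintf("4 %d %d %d %d", e0[, 1], e0[, 2], e0[, 3], e0[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  cell_data <- c(list(region = as.numeric(mesh$elem_label)), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", cell_data[[nm]]), con)
  }
  invisible(path)
}

#' Write a triangulated surface as ASCII STL
#'
#' @param vertices `n x 3` matrix.
#' @param faces `m x 3` 1-based triangle connectivity.
#' @param path output path.
#' @param name solid name.
#' @return `path`, invisibly.
#' @export
write_stl <- function(vertices, faces, path, name = "hapcage") {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  txt <- sprintf(paste0("facet normal %.6g %.6g %.6g\n outer loop\n",
                        "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
                        "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
                 n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
                 b[, 1], b[, 2], b[, 3], c_[, 1], c_[, 2], c_[, 3])
  writeLines(txt, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

# Sum array values over step-sized cells (cropping any remainder).
aggregate_cells <- function(x, step, nc) {
  x <- x[seq_len(nc[1] * step[1]), seq_len(nc[2] * step[2]),
         seq_len(nc[3] * step[3]), drop = FALSE]
  d1 <- dim(x)
  dim(x) <- c(step[1], nc[1], step[2] * nc[2] * step[3] * nc[3])
  x <- colSums(x)
  dim(x) <- c(nc[1], step[2], nc[2] * step[3] * nc[3])
  x <- aperm(x, c(2, 1, 3))
  x <- colSums(x)
  dim(x) <- c(nc[1], nc[2], step[3], nc[3])
  x <- aperm(x, c(3, 1, 2, 4))
  x <- colSums(x)
  array(x, nc)
}

# Largest 6-connected component of a logical array (vectorized flood fill).
largest_component6 <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, d)
  cid <- 0L
  repeat {
    seed <- which(mask & comp == 0L)
    if (length(seed) == 0) break
    cid <- cid + 1L
    cur <- array(FALSE, d)
    cur[seed[1]] <- TRUE
    repeat {
      grown <- dilate6(cur) & mask & comp == 0L
      if (!any(grown & !cur)) break
      cur <- cur | grown
    }
    comp[cur] <- cid
  }
  sizes <- tabulate(comp[comp > 0L], nbins = cid)
  comp == which.max(sizes)
}

dilate6 <- function(x) {
  out <- x
  out <- out | shift3(x, c(1, 0, 0)) > 0 | shift3(x, c(-1, 0, 0)) > 0
  out <- out | shift3(x, c(0, 1, 0)) > 0 | shift3(x, c(0, -1, 0)) > 0
  out <- out | shift3(x, c(0, 0, 1)) > 0 | shift3(x, c(0, 0, -1)) > 0
  out
}
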