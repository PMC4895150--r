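# File formats: SWC morphologies, Gmsh MSH v4.1 (writer and a reader for the
# dialect subset written here), legacy VTK unstructured grids, and CSV/JSON
# serialization of placements and records.

swc_type_codes <- c(soma = 1L, ais = 2L, internode = 2L, node = 2L, terminal = 2L,
                    axon = 2L, basal = 3L, apical = 4L)

# SWC node table of a morphology (um; radius = diam/2). The first point of a
# non-root section coincides with a sample of its parent and is not repeated.
as_swc_table <- function(m) {
  rows <- list()
  node_of_section_point <- list()  # section id -> node ids of its points
  nid <- 0L
  for (sec in m$sections) {
    p <- sec$points
    npts <- nrow(p)
    ids <- integer(npts)
    if (sec$parent == 0L) {
      start <- 1L
      prev <- -1L
    } else {
      parent_nodes <- node_of_section_point[[sec$parent]]
      pp <- m$sections[[sec$parent]]$points
      d2 <- rowSums((pp - matrix(p[1, ], nrow(pp), 3, byrow = TRUE))^2)
      prev <- parent_nodes[which.min(d2)]
      ids[1] <- prev
      start <- 2L
    }
    for (k in start:npts) {
      nid <- nid + 1L
      rows[[nid]] <- c(nid, swc_type_codes[[sec$kind]],
                       p[k, ] * 1e3, sec$diam / 2, prev)
      ids[k] <- nid
      prev <- nid
    }
    node_of_section_point[[sec$id]] <- ids
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
  tab
}

#' Write a morphology to SWC
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; um; root parent
#' -1). Axonal subtypes (initial segment, internode, node) all map to SWC
#' type 2 and are therefore not preserved across a round trip; re-imported
#' axons carry the generic `axon` kind.
#'
#' @param m A `sucs_morphology`.
#' @param path Output file.
#' @export
write_swc <- function(m, path) {
  tab <- as_swc_table(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC export (%s pyramidal template)", m$layer), con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     tab$id, tab$type, tab$x, tab$y, tab$z, tab$radius,
                     tab$parent), con)
  invisible(path)
}

#' Read an SWC morphology
#'
#' Accepts the standard dialect: 7 whitespace-separated columns, `#`
#' comments, 1-based ids, parent -1 for roots. Maximal unbranched runs of a
#' single type become sections. A single-node type-1 file yields a valid
#' one-compartment spherical soma.
#'
#' @param path SWC file.
#' @return A `sucs_morphology` (layer tag `"imported"`).
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("format error: empty SWC file")
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7))
    stop("format error: SWC rows must have 7 columns")
  tab <- as.data.frame(do.call(rbind, lapply(fields, as.numeric)))
  names(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (anyNA(tab)) stop("format error: non-numeric SWC fields")
  if (!all(tab$type %in% 1:4))
    stop("format error: unknown SWC type code(s)")
  ids <- as.integer(tab$id)
  parents <- as.integer(tab$parent)
  if (anyDuplicated(ids)) stop("format error: duplicate SWC ids")
  idx <- match(parents, ids)
  if (any(parents != -1 & is.na(idx)))
    stop("format error: SWC parent refers to unknown id")
  # cycle check: every node must reach a root through parent links
  n <- nrow(tab)
  for (s in seq_len(n)) {
    cur <- s
    steps <- 0L
    while (parents[cur] != -1) {
      cur <- idx[cur]
      steps <- steps + 1L
      if (steps > n) stop("format error: SWC parent links contain a cycle")
    }
  }
  kind_of <- c("soma", "axon", "basal", "apical")
  children <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  um <- 1e-3
  secs <- list()
  node_sec <- integer(n)    # section owning each node
  node_secpt <- integer(n)  # point row within the section
  roots <- which(parents == -1)
  if (!length(roots)) stop("format error: SWC has no root")
  queue <- roots
  while (length(queue)) {
    start <- queue[1]
    queue <- queue[-1]
    # maximal run of nodes with one same-type, same-radius continuation;
    # children of other types/radii branch off mid-run and are queued
    run <- start
    repeat {
      last <- run[length(run)]
      ch <- children[[last]]
      same <- ch[tab$type[ch] == tab$type[last] &
                 abs(tab$radius[ch] - tab$radius[last]) < 1e-9]
      other <- setdiff(ch, same)
      queue <- c(queue, other)
      if (length(same) == 1) run <- c(run, same)
      else {
        queue <- c(queue, same)
        break
      }
    }
    pr <- parents[start]
    pts <- as.matrix(tab[run, c("x", "y", "z")]) * um
    if (pr != -1) {
      pn <- idx[start]
      pts <- rbind(as.matrix(tab[pn, c("x", "y", "z")]) * um, pts)
    } else if (nrow(pts) == 1) {
      # single-node (spherical) soma: represent as a cylinder of length 2r
      r_mm <- tab$radius[start] * um
      pts <- rbind(pts[1, ] - c(0, r_mm, 0), pts[1, ] + c(0, r_mm, 0))
    }
    id <- length(secs) + 1L
    parent_sec <- if (pr == -1) 0L else node_sec[idx[start]]
    parent_frac <- if (pr == -1) 0 else {
      ps <- secs[[parent_sec]]
      pp <- ps$points
      d <- c(0, cumsum(sqrt(rowSums(diff(pp)^2))))
      d[node_secpt[idx[start]]] / max(d[length(d)], 1e-300)
    }
    secs[[id]] <- new_section(id, kind_of[tab$type[start]], parent_sec,
                              parent_frac, pts,
                              2 * tab$radius[start])
    off <- nrow(pts) - length(run)
    node_sec[run] <- id
    node_secpt[run] <- seq_along(run) + off
  }
  m <- list(layer = "imported", sections = secs, params = NULL,
            lengthen = NA, placed = TRUE, bend = NULL)
  class(m) <- "sucs_morphology"
  m
}

#' Write a mesh as Gmsh MSH v4.1 (ASCII)
#'
#' Physical groups encode the tissue labels. The writer emits the dialect
#' subset that [read_msh()] parses; third-party readers accepting MSH 4.1
#' volumes with physical groups can consume it as well.
#'
#' @param mesh A `sucs_mesh`.
#' @param path Output file.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tis <- levels(droplevels(mesh$tissue))
  w <- function(...) writeLines(sprintf(...), con)
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat"), con)
  writeLines("$PhysicalNames", con)
  w("%d", length(tis))
  for (i in seq_along(tis)) w("3 %d \"%s\"", i, tis[i])
  writeLines("$EndPhysicalNames", con)
  writeLines("$Entities", con)
  w("0 0 0 %d", length(tis))
  for (i in seq_along(tis)) w("%d 0 0 0 0 0 0 1 %d 0", i, i)
  writeLines("$EndEntities", con)
  n <- nrow(mesh$nodes)
  writeLines("$Nodes", con)
  w("1 %d 1 %d", n, n)
  w("3 1 0 %d", n)
  writeLines(sprintf("%d", seq_len(n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines("$EndNodes", con)
  writeLines("$Elements", con)
  m <- nrow(mesh$elems)
  w("%d %d 1 %d", length(tis), m, m)
  eid <- 0L
  for (i in seq_along(tis)) {
    sel <- which(mesh$tissue == tis[i])
    w("3 %d 4 %d", i, length(sel))
    e <- mesh$elems[sel, , drop = FALSE]
    writeLines(sprintf("%d %d %d %d %d", eid + seq_along(sel),
                       e[, 1], e[, 2], e[, 3], e[, 4]), con)
    eid <- eid + length(sel)
  }
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH v4.1 mesh written by [write_msh()]
#'
#' @param path MSH file.
#' @return A `sucs_mesh` (unstructured: no grid fast paths).
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop(sprintf("format error: missing $%s", name))
    lines[(i0 + 1):(i1 - 1)]
  }
  fmt <- strsplit(sec("MeshFormat")[1], " ")[[1]]
  if (fmt[1] != "4.1") stop("format error: only MSH 4.1 is supported")
  pn <- sec("PhysicalNames")
  npn <- as.integer(pn[1])
  phys <- character(npn)
  for (i in seq_len(npn)) {
    parts <- strsplit(pn[1 + i], " ")[[1]]
    phys[as.integer(parts[2])] <- gsub('"', "", parts[3])
  }
  nd <- sec("Nodes")
  hdr <- as.integer(strsplit(nd[1], " ")[[1]])
  nnode <- hdr[2]
  coords <- do.call(rbind, lapply(nd[(3 + nnode):(2 + 2 * nnode)],
    function(s) as.numeric(strsplit(s, " ")[[1]])))
  el <- sec("Elements")
  hdr <- as.integer(strsplit(el[1], " ")[[1]])
  nblocks <- hdr[1]
  pos <- 2L
  elems <- NULL
  tissue <- character(0)
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(el[pos], " ")[[1]])
    nb <- bh[4]
    rows <- do.call(rbind, lapply(el[pos + seq_len(nb)],
      function(s) as.integer(strsplit(s, " ")[[1]])))
    elems <- rbind(elems, rows[, 2:5, drop = FALSE])
    tissue <- c(tissue, rep(phys[bh[2]], nb))
    pos <- pos + nb + 1L
  }
  m <- list(nodes = coords, elems = elems,
            tissue = factor(tissue, levels = TISSUES),
            elem_contact = integer(nrow(elems)),
            xs = NULL, ys = NULL, zs = NULL, is_grid = FALSE,
            nhex = NA, geom = NULL, resolution = NA_real_)
  m$boundary_nodes <- boundary_nodes_by_faces(m)
  class(m) <- "sucs_mesh"
  m
}

#' Write a mesh (with optional fields) as legacy VTK
#'
#' @param mesh A `sucs_mesh`.
#' @param path Output file.
#' @param point_data Optional named list of per-node numeric vectors (e.g. a
#'   solved potential).
#' @param cell_tensors Optional elements x 6 symmetric tensor matrix (xx, yy,
#'   zz, xy, xz, yz), written as full 3x3 tensors.
#' @export
write_vtk <- function(mesh, path, point_data = NULL, cell_tensors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "cortistim mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  e0 <- mesh$elems - 1L
  writeLines(sprintf("4 %d %d %d %d", e0[, 1], e0[, 2], e0[, 3], e0[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.integer(mesh$tissue)), con)
  if (!is.null(cell_tensors)) {
    writeLines("TENSORS conductivity double", con)
    writeLines(sprintf("%.9g %.9g %.9g %.9g %.9g %.9g %.9g %.9g %.9g",
                       cell_tensors[, "xx"], cell_tensors[, "xy"],
                       cell_tensors[, "xz"], cell_tensors[, "xy"],
                       cell_tensors[, "yy"], cell_tensors[, "yz"],
                       cell_tensors[, "xz"], cell_tensors[, "yz"],
                       cell_tensors[, "zz"]), con)
  }
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}
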