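# Structured graded tetrahedral meshing. A graded axis-aligned grid covers the
# bounding box; every hexahedral cell is split into six tetrahedra along its
# main diagonal (Kuhn subdivision, conforming across faces because all cells
# share the same orientation); elements are labeled by the tissue at their
# centroid. The grid structure makes point location and barycentric
# interpolation O(1) per query.

TISSUES <- c("scalp", "skull", "dura", "csf", "gm", "wm",
             "electrode", "substrate")

# coordinate vector with target spacing per interval; every break is a node
graded_coords <- function(breaks, hs) {
  stopifnot(length(hs) == length(breaks) - 1, !is.unsorted(breaks))
  out <- breaks[1]
  for (i in seq_along(hs)) {
    len <- breaks[i + 1] - breaks[i]
    if (len <= 0) next
    n <- max(1L, ceiling(len / hs[i]))
    out <- c(out, breaks[i] + seq_len(n) * (len / n))
  }
  unique(out)
}

kuhn_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Structured tetrahedral mesh of a box
#'
#' Low-level mesher: builds the Kuhn six-tetrahedra subdivision of the graded
#' grid spanned by the given coordinate vectors. Used by [generate_mesh()] and
#' directly for homogeneous oracle meshes.
#'
#' @param xs,ys,zs Strictly increasing node coordinate vectors (mm).
#' @return An object of class `sucs_mesh` with all elements labeled `"gm"`.
#' @export
mesh_box <- function(xs, ys, zs) {
  if (any(diff(xs) <= 0) || any(diff(ys) <= 0) || any(diff(zs) <= 0) ||
      length(xs) < 2 || length(ys) < 2 || length(zs) < 2)
    stop("mesh error: coordinate vectors must be strictly increasing, length >= 2")
  nxn <- length(xs); nyn <- length(ys); nzn <- length(zs)
  nodes <- cbind(x = rep(xs, times = nyn * nzn),
                 y = rep(rep(ys, each = nxn), times = nzn),
                 z = rep(zs, each = nxn * nyn))
  nx <- nxn - 1L; ny <- nyn - 1L; nz <- nzn - 1L
  ii <- rep(seq_len(nx), times = ny * nz)
  jj <- rep(rep(seq_len(ny), each = nx), times = nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  nid <- function(i, j, k) i + (j - 1L) * nxn + (k - 1L) * (nxn * nyn)
  corner <- function(di, dj, dk) nid(ii + di, jj + dj, kk + dk)
  offs <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L),
                c(0L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 1L))
  cn <- lapply(seq_len(8), function(q) corner(offs[q, 1], offs[q, 2], offs[q, 3]))
  corner_index <- function(o) 1L + o[1] + 2L * o[2] + 4L * o[3]
  elems <- vector("list", 6L)
  for (q in seq_len(6)) {
    p <- kuhn_perms[q, ]
    o0 <- c(0L, 0L, 0L)
    o1 <- o0; o1[p[1]] <- 1L
    o2 <- o1; o2[p[2]] <- 1L
    o3 <- c(1L, 1L, 1L)
    elems[[q]] <- cbind(cn[[corner_index(o0)]], cn[[corner_index(o1)]],
                        cn[[corner_index(o2)]], cn[[corner_index(o3)]])
  }
  elems <- do.call(rbind, elems)
  m <- list(nodes = nodes, elems = elems,
            tissue = factor(rep("gm", nrow(elems)), levels = TISSUES),
            elem_contact = integer(nrow(elems)),
            xs = xs, ys = ys, zs = zs, is_grid = TRUE,
            nhex = nx * ny * nz, geom = NULL, resolution = NA_real_)
  class(m) <- "sucs_mesh"
  m
}

elem_centroids <- function(mesh) {
  e <- mesh$elems
  (mesh$nodes[e[, 1], , drop = FALSE] + mesh$nodes[e[, 2], , drop = FALSE] +
   mesh$nodes[e[, 3], , drop = FALSE] + mesh$nodes[e[, 4], , drop = FALSE]) / 4
}

#' Generate a labeled tetrahedral mesh for a gyral geometry
#'
#' Grid spacing is refined around the fold, the cortical layers and the
#' electrode bodies, and coarsened in deep white matter, skull and scalp.
#' Tissue-layer interfaces and electrode tops/bottoms fall exactly on grid
#' planes.
#'
#' @param geom A `sucs_geometry` (with electrodes placed, if any).
#' @param resolution Target element size (mm) in the refined cortical zone.
#' @return A `sucs_mesh` with tissue labels and electrode contact ids.
#' @export
generate_mesh <- function(geom, resolution = 0.8) {
  if (!is.finite(resolution) || resolution <= 0)
    stop("mesh error: resolution must be positive")
  cs <- geom$cs
  res <- resolution
  # lateral refinement over the sulcal walls and their GM (where the GM/WM
  # boundary is vertical), plus the fold zone generally
  xb1 <- max(cs$xf - cs$a - cs$gm - 1.5, 1)
  xb2 <- cs$xf + cs$a + cs$gm + 1.5
  xfold <- cs$xf + cs$a + cs$r + cs$gm + 1
  xh <- graded_coords(c(0, xb1, xb2, xfold, cs$x_end, cs$x_max),
                      c(res, 0.6 * res, res, 1.4 * res, 2.2 * res))
  xs <- sort(unique(c(-rev(xh), xh)))
  ydeep <- max(cs$yb - cs$a - cs$gm - 1.5, 0.5)
  ygmwm <- cs$Hb - cs$gm - 1.5  # refine across the horizontal GM/WM boundary
  if (length(geom$electrodes)) {
    ct <- max(vapply(geom$electrodes, `[[`, 0, "contact_thickness"))
    st <- max(vapply(geom$electrodes, `[[`, 0, "substrate_thickness"))
    ybr <- c(0, ydeep, ygmwm, cs$Hb, cs$Hb + ct, cs$Hb + ct + st,
             cs$y_csf_top, cs$y_dura_top, cs$y_skull_top, cs$y_top)
    yhs <- c(2.6 * res, res, 0.45 * res, min(res, ct / 2 + 1e-9),
             min(res, st + 1e-9), min(res, 0.4),
             cs$y_dura_top - cs$y_csf_top, 2.2 * res, 2.6 * res)
  } else {
    ybr <- c(0, ydeep, ygmwm, cs$Hb, cs$y_csf_top, cs$y_dura_top,
             cs$y_skull_top, cs$y_top)
    yhs <- c(2.6 * res, res, 0.45 * res, min(res, 0.4),
             cs$y_dura_top - cs$y_csf_top, 2.2 * res, 2.6 * res)
  }
  ys <- graded_coords(ybr, yhs)
  if (length(geom$electrodes)) {
    ez <- vapply(geom$electrodes, `[[`, 0, "z")
    er <- max(vapply(geom$electrodes, `[[`, 0, "substrate_extent")) / 2
    z1 <- max(min(ez) - er - 2, 0)
    z2 <- min(max(ez) + er + 2, cs$z_len)
    zs <- graded_coords(c(0, z1, z2, cs$z_len),
                        c(2.6 * res, 1.4 * res, 2.6 * res))
  } else {
    zs <- graded_coords(c(0, cs$z_len), 2.2 * res)
  }
  m <- mesh_box(xs, ys, zs)
  cen <- elem_centroids(m)
  m$tissue <- factor(tissue_at(geom, cen), levels = TISSUES)
  if (anyNA(m$tissue))
    stop("mesh error: unclassified element centroids (labeling failure)")
  contact <- integer(nrow(cen))
  roles <- vapply(geom$electrodes, `[[`, "", "role")
  for (i in seq_along(geom$electrodes)) {
    e <- geom$electrodes[[i]]
    hit <- m$tissue == "electrode" &
      sqrt((cen[, 1] - e$x)^2 + (cen[, 3] - e$z)^2) <= e$substrate_extent / 2
    contact[hit] <- i
  }
  if (length(geom$electrodes) &&
      !all(seq_along(geom$electrodes) %in% contact[contact > 0]))
    stop("mesh error: an electrode body received no elements; refine the mesh")
  m$elem_contact <- contact
  m$contact_roles <- roles
  m$geom <- geom
  m$resolution <- resolution
  m
}

#' @export
print.sucs_mesh <- function(x, ...) {
  cat(sprintf("<sucs_mesh: %d nodes, %d tetrahedra%s>\n", nrow(x$nodes),
              nrow(x$elems), if (x$is_grid) " (structured)" else ""))
  print(table(x$tissue))
  invisible(x)
}

tet_volumes <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elems
  a <- n[e[, 2], ] - n[e[, 1], ]
  b <- n[e[, 3], ] - n[e[, 1], ]
  c3 <- n[e[, 4], ] - n[e[, 1], ]
  det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
         a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
         a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(det) / 6
}

#' Total mesh volume
#' @param mesh A `sucs_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

#' Keep a subset of elements (renumbering nodes)
#'
#' Used to carve non-box domains (e.g. a ball for the point-source oracle)
#' out of a structured grid. The result loses the fast grid point-location
#' path and records its exterior boundary nodes explicitly.
#'
#' @param mesh A `sucs_mesh`.
#' @param keep Logical or integer element selector.
#' @return A `sucs_mesh`.
#' @export
mesh_subset <- function(mesh, keep) {
  e <- mesh$elems[keep, , drop = FALSE]
  used <- sort(unique(as.vector(e)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  m <- mesh
  m$elems <- matrix(remap[e], ncol = 4)
  m$nodes <- mesh$nodes[used, , drop = FALSE]
  m$tissue <- mesh$tissue[keep]
  m$elem_contact <- mesh$elem_contact[keep]
  m$is_grid <- FALSE
  m$boundary_nodes <- boundary_nodes_by_faces(m)
  m
}

# exterior faces: triangles appearing in exactly one tetrahedron
boundary_faces_raw <- function(mesh) {
  e <- mesh$elems
  faces <- rbind(e[, c(2, 3, 4)], e[, c(1, 3, 4)],
                 e[, c(1, 2, 4)], e[, c(1, 2, 3)])
  fs <- t(apply(faces, 1, sort))
  key <- fs[, 1] + fs[, 2] * 2^17 + fs[, 3] * 2^34
  tab <- table(key)
  single <- as.numeric(names(tab)[tab == 1])
  faces[key %in% single, , drop = FALSE]
}

boundary_nodes_by_faces <- function(mesh) {
  sort(unique(as.vector(boundary_faces_raw(mesh))))
}

#' Exterior boundary facets with tags
#'
#' For structured meshes every exterior facet lies on one of the six box
#' planes; the tag records the plane (`skull_top` for the top, `bottom`,
#' `x_min`, `x_max`, `z_min`, `z_max`). How tags map to grounded/insulated is
#' decided by the grounding scheme at solve time.
#'
#' @param mesh A `sucs_mesh`.
#' @return Data frame with node columns `n1, n2, n3` and a `tag` column.
#' @export
boundary_facets <- function(mesh) {
  if (!mesh$is_grid) {
    faces <- boundary_faces_raw(mesh)
    return(data.frame(n1 = faces[, 1], n2 = faces[, 2], n3 = faces[, 3],
                      tag = "exterior"))
  }
  # On every hex face the Kuhn subdivision induces the diagonal from the
  # face's minimum corner to its maximum corner; exterior faces lie on the
  # six box planes, so triangles can be generated directly.
  nxn <- length(mesh$xs); nyn <- length(mesh$ys); nzn <- length(mesh$zs)
  nid <- function(i, j, k) i + (j - 1L) * nxn + (k - 1L) * (nxn * nyn)
  plane_tris <- function(ia, ja, tag, corner) {
    g <- expand.grid(a = seq_len(ia - 1L), b = seq_len(ja - 1L))
    c00 <- corner(g$a, g$b); c10 <- corner(g$a + 1L, g$b)
    c01 <- corner(g$a, g$b + 1L); c11 <- corner(g$a + 1L, g$b + 1L)
    data.frame(n1 = c(c00, c00), n2 = c(c10, c01), n3 = c(c11, c11),
               tag = tag)
  }
  rbind(
    plane_tris(nxn, nzn, "bottom", function(a, b) nid(a, 1L, b)),
    plane_tris(nxn, nzn, "skull_top", function(a, b) nid(a, nyn, b)),
    plane_tris(nyn, nzn, "x_min", function(a, b) nid(1L, a, b)),
    plane_tris(nyn, nzn, "x_max", function(a, b) nid(nxn, a, b)),
    plane_tris(nxn, nyn, "z_min", function(a, b) nid(a, b, 1L)),
    plane_tris(nxn, nyn, "z_max", function(a, b) nid(a, b, nzn)))
}

# node set to be grounded under a scheme
grounded_nodes <- function(mesh, scheme) {
  n <- mesh$nodes
  if (!mesh$is_grid || identical(scheme, "all_exterior")) {
    if (is.null(mesh$boundary_nodes))
      mesh$boundary_nodes <- boundary_nodes_by_faces(mesh)
    return(mesh$boundary_nodes)
  }
  tol <- 1e-9
  on <- function(v, val) abs(v - val) < tol
  bottom <- on(n[, 2], min(mesh$ys))
  sides <- on(n[, 1], min(mesh$xs)) | on(n[, 1], max(mesh$xs)) |
           on(n[, 3], min(mesh$zs)) | on(n[, 3], max(mesh$zs))
  if (scheme == "exterior_grounded_except_skull_top") {
    which(bottom | sides)
  } else if (scheme == "bottom_grounded") {
    which(bottom)
  } else if (scheme == "distant_patch") {
    patch <- if (!is.null(mesh$geom$warp)) mesh$geom$warp$patch else 5
    zmid <- mean(range(mesh$zs))
    which(bottom & abs(n[, 1]) <= patch & abs(n[, 3] - zmid) <= patch)
  } else stop(sprintf("configuration error: unknown grounding scheme '%s'", scheme))
}

# Locate points in a structured grid mesh and return barycentric
# interpolation weights on the Kuhn tetrahedron containing each point.
# Returns list(nodes = n x 4 matrix of node ids, w = n x 4 weights).
grid_interp_weights <- function(mesh, pts) {
  if (!mesh$is_grid) stop("sampling error: interpolation requires a grid mesh")
  pts <- rbind(pts)
  xs <- mesh$xs; ys <- mesh$ys; zs <- mesh$zs
  tol <- 1e-9
  bad <- pts[, 1] < xs[1] - tol | pts[, 1] > xs[length(xs)] + tol |
         pts[, 2] < ys[1] - tol | pts[, 2] > ys[length(ys)] + tol |
         pts[, 3] < zs[1] - tol | pts[, 3] > zs[length(zs)] + tol
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("sampling error: point (%.3f, %.3f, %.3f) outside the mesh domain",
                 pts[i, 1], pts[i, 2], pts[i, 3]))
  }
  clampi <- function(i, nmax) pmin(pmax(i, 1L), nmax)
  ix <- clampi(findInterval(pts[, 1], xs, rightmost.closed = TRUE), length(xs) - 1L)
  iy <- clampi(findInterval(pts[, 2], ys, rightmost.closed = TRUE), length(ys) - 1L)
  iz <- clampi(findInterval(pts[, 3], zs, rightmost.closed = TRUE), length(zs) - 1L)
  u <- (pts[, 1] - xs[ix]) / (xs[ix + 1L] - xs[ix])
  v <- (pts[, 2] - ys[iy]) / (ys[iy + 1L] - ys[iy])
  w3 <- (pts[, 3] - zs[iz]) / (zs[iz + 1L] - zs[iz])
  loc <- cbind(u, v, w3)
  nxn <- length(xs); nyn <- length(ys)
  nid <- function(i, j, k) i + (j - 1L) * nxn + (k - 1L) * (nxn * nyn)
  n <- nrow(pts)
  nd <- matrix(0L, n, 4)
  wt <- matrix(0, n, 4)
  ord <- t(apply(loc, 1, order, decreasing = TRUE))
  s1 <- loc[cbind(seq_len(n), ord[, 1])]
  s2 <- loc[cbind(seq_len(n), ord[, 2])]
  s3 <- loc[cbind(seq_len(n), ord[, 3])]
  wt[, 1] <- 1 - s1; wt[, 2] <- s1 - s2; wt[, 3] <- s2 - s3; wt[, 4] <- s3
  o0 <- matrix(0L, n, 3)
  o1 <- o0; o1[cbind(seq_len(n), ord[, 1])] <- 1L
  o2 <- o1; o2[cbind(seq_len(n), ord[, 2])] <- 1L
  o3 <- matrix(1L, n, 3)
  for (q in 1:4) {
    o <- list(o0, o1, o2, o3)[[q]]
    nd[, q] <- nid(ix + o[, 1], iy + o[, 2], iz + o[, 3])
  }
  list(nodes = nd, w = wt)
}
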