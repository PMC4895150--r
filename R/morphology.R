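# Stylized parametric L3/L5 pyramidal morphologies. The exact reconstructions
# behind the published cat-visual-cortex models are not available, so a
# parametric template preserves the structural features that drive
# stimulation responses: an apical trunk toward the pia with obliques and a
# tuft, basal dendrites, and a myelinated axon (initial segment, alternating
# internodes and nodes of Ranvier, unmyelinated terminal node). L3 axons stay
# within gray matter; L5 axons cross the GM/WM boundary. Coordinates are mm
# in a local frame (y: apical axis, x: in-plane, z: along the gyrus);
# diameters are um. All neurite path lengths are multiplied by the
# human-adaptation lengthening factor (default 1.6) at build time.

#' Default morphometric template for a cortical layer
#'
#' Base (pre-lengthening) section lengths in um; these defaults are
#' configuration, not derived from any printed reconstruction.
#'
#' @param layer `"L3"` or `"L5"`.
#' @return Named list of template parameters.
#' @export
morphology_params <- function(layer = c("L5", "L3")) {
  layer <- match.arg(layer)
  if (layer == "L5") {
    list(soma_length = 20, soma_diam = 20,
         apical_length = 1700, apical_diam = 4,
         oblique_length = 250, oblique_diam = 1.5, oblique_frac = 0.4,
         tuft_length = 250, tuft_diam = 1.2,
         basal_length = 180, basal_diam = 2, n_basal = 4,
         ais_length = 30, ais_diam = 1.8,
         axon_length = 3000, axon_diam = 1.4,
         internode_length = 62.5, node_length = 1.25,
         terminal_length = 125)
  } else {
    list(soma_length = 15, soma_diam = 15,
         apical_length = 1000, apical_diam = 3,
         oblique_length = 180, oblique_diam = 1.2, oblique_frac = 0.4,
         tuft_length = 180, tuft_diam = 1,
         basal_length = 150, basal_diam = 1.5, n_basal = 4,
         ais_length = 30, ais_diam = 1.5,
         axon_length = 1060, axon_diam = 1.2,
         internode_length = 62.5, node_length = 1.25,
         terminal_length = 530)
  }
}

new_section <- function(id, kind, parent, parent_frac, pts, diam) {
  list(id = id, kind = kind, parent = parent, parent_frac = parent_frac,
       points = pts, diam = diam)
}

section_length_mm <- function(sec) {
  p <- sec$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Build a stylized pyramidal morphology
#'
#' @param layer `"L3"` or `"L5"`.
#' @param params Template from [morphology_params()].
#' @param lengthen Path-length multiplier applied to every neurite
#'   (default 1.6, the 60 percent human-adaptation lengthening).
#' @return Object of class `sucs_morphology` in the local frame (soma at the
#'   origin, apical axis +y, axon along -y).
#' @export
build_morphology <- function(layer = c("L5", "L3"),
                             params = morphology_params(layer),
                             lengthen = 1.6) {
  layer <- match.arg(layer)
  tp <- params
  um <- 1e-3  # um -> mm
  L <- function(base_um) lengthen * base_um * um
  secs <- list()
  add <- function(kind, parent, parent_frac, from, dir, len_mm, diam,
                  via = NULL) {
    dir <- dir / sqrt(sum(dir^2))
    pts <- if (is.null(via)) rbind(from, from + dir * len_mm)
           else rbind(from, from + dir * len_mm * via, from + dir * len_mm)
    id <- length(secs) + 1L
    secs[[id]] <<- new_section(id, kind, parent, parent_frac, pts, diam)
    id
  }
  # soma: single vertical section centered at the origin
  sl <- tp$soma_length * um
  secs[[1]] <- new_section(1L, "soma", 0L, 0,
                           rbind(c(0, -sl / 2, 0), c(0, sl / 2, 0)),
                           tp$soma_diam)
  soma_top <- c(0, sl / 2, 0)
  soma_bot <- c(0, -sl / 2, 0)
  # apical trunk with an interior point at the oblique attachment
  ap_len <- L(tp$apical_length)
  ap <- add("apical", 1L, 1, soma_top, c(0, 1, 0), ap_len, tp$apical_diam,
            via = tp$oblique_frac)
  ap_branch <- soma_top + c(0, 1, 0) * ap_len * tp$oblique_frac
  ap_tip <- soma_top + c(0, 1, 0) * ap_len
  for (sx in c(-1, 1))
    add("apical", ap, tp$oblique_frac, ap_branch,
        c(sx * sin(40 * pi / 180), cos(40 * pi / 180), 0),
        L(tp$oblique_length), tp$oblique_diam)
  for (sx in c(-1, 1))
    add("apical", ap, 1, ap_tip,
        c(sx * sin(30 * pi / 180), cos(30 * pi / 180), 0),
        L(tp$tuft_length), tp$tuft_diam)
  # basal dendrites: four symmetric downward-lateral directions
  dirs <- rbind(c(1, -1, 1), c(-1, -1, 1), c(1, -1, -1), c(-1, -1, -1))
  for (i in seq_len(tp$n_basal))
    add("basal", 1L, 0, soma_bot, dirs[i, ], L(tp$basal_length), tp$basal_diam)
  # axon: initial segment, alternating myelinated internodes and nodes of
  # Ranvier, ending in an unmyelinated active terminal segment (real
  # pyramidal axon terminations lose their myelin, which keeps the terminal
  # length constant short)
  ais_len <- L(tp$ais_length)
  ais <- add("ais", 1L, 0, soma_bot, c(0, -1, 0), ais_len, tp$ais_diam)
  term_len <- L(tp$terminal_length)
  rem <- L(tp$axon_length) - ais_len - term_len
  inode <- L(tp$internode_length)
  nodel <- L(tp$node_length)
  cur <- soma_bot + c(0, -1, 0) * ais_len
  parent <- ais
  while (rem > 1e-9) {
    li <- min(inode, max(rem - nodel, 0))
    if (li > 1e-9) {
      parent <- add("internode", parent, 1, cur, c(0, -1, 0), li,
                    tp$axon_diam)
      cur <- cur + c(0, -1, 0) * li
      rem <- rem - li
    }
    ln <- min(nodel, rem)
    if (ln > 1e-9) {
      parent <- add("node", parent, 1, cur, c(0, -1, 0), ln, tp$axon_diam)
      cur <- cur + c(0, -1, 0) * ln
      rem <- rem - ln
    }
  }
  add("terminal", parent, 1, cur, c(0, -1, 0), term_len, tp$axon_diam)
  m <- list(layer = layer, sections = secs, params = tp, lengthen = lengthen,
            placed = FALSE, bend = NULL)
  class(m) <- "sucs_morphology"
  m
}

#' @export
print.sucs_morphology <- function(x, ...) {
  kinds <- vapply(x$sections, `[[`, "", "kind")
  cat(sprintf("<sucs_morphology %s: %d sections (%s)%s>\n", x$layer,
              length(x$sections),
              paste(sprintf("%s:%d", names(table(kinds)), table(kinds)),
                    collapse = ", "),
              if (x$placed) " [placed]" else ""))
  invisible(x)
}

#' Total path length per section kind
#' @param m A `sucs_morphology`.
#' @return Named numeric vector (mm).
#' @export
morphology_lengths <- function(m) {
  kinds <- vapply(m$sections, `[[`, "", "kind")
  lens <- vapply(m$sections, section_length_mm, 0)
  tapply(lens, kinds, sum)
}

#' Place a morphology instance in the head geometry
#'
#' Maps the local frame (x, y, z) onto (tangent, apical, extrusion) at the
#' soma position: the apical trunk points along the outward cortical normal.
#'
#' @param m A local-frame `sucs_morphology`.
#' @param soma Soma center (x, y, z) in mm.
#' @param apical Unit outward-normal (apical) direction.
#' @param tangent Unit path-tangent direction (orthogonal to `apical`).
#' @param roll Rotation (degrees) of the dendritic tree about the apical axis.
#' @return A placed `sucs_morphology` (world coordinates).
#' @export
place_morphology <- function(m, soma, apical, tangent, roll = 0) {
  ey <- apical / sqrt(sum(apical^2))
  ex <- tangent - sum(tangent * ey) * ey
  ex <- ex / sqrt(sum(ex^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- cbind(ex, ey, ez)
  if (roll != 0) {
    th <- roll * pi / 180
    # rotation about the local y (apical) axis
    Ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
    R <- R %*% Ry
  }
  m$sections <- lapply(m$sections, function(s) {
    s$points <- t(R %*% t(s$points)) + rep(soma, each = nrow(s$points))
    s
  })
  m$placed <- TRUE
  m$soma <- soma
  m$frame <- R
  m
}

# ordered chain of axonal sections (ais -> terminal) with cumulative arc
axon_chain <- function(m) {
  kinds <- vapply(m$sections, `[[`, "", "kind")
  ax <- which(kinds %in% c("ais", "internode", "node", "terminal", "axon"))
  ax[order(vapply(m$sections[ax], `[[`, 0L, "id"))]
}

#' Bend an L5 axon at the GM/WM boundary
#'
#' Beyond the first crossing of the boundary the axon is deflected along a
#' circular arc of the given radius toward the local white-matter fiber
#' direction (then continues straight), preserving total axon arc length.
#' An infinite radius (or an axon that never reaches the boundary) leaves the
#' morphology unchanged.
#'
#' @param m A placed `sucs_morphology`.
#' @param geom The `sucs_geometry` providing the boundary surface and fibers.
#' @param radius Bend radius (mm); `Inf` disables bending.
#' @param angle Optional explicit bend angle (degrees); by default the bend
#'   continues until the tangent aligns with the fiber direction.
#' @return The morphology with the distal axon re-routed; the bent arc is
#'   recorded in `m$bend` for initiation-site classification.
#' @export
bend_axon_at_boundary <- function(m, geom, radius = 0.5, angle = NULL) {
  if (!m$placed) stop("morphology error: bend requires a placed morphology")
  if (!is.finite(radius)) return(m)
  if (radius <= 0) stop("parameter error: bend radius must be positive")
  chain <- axon_chain(m)
  # polyline of the whole axon with cumulative arc length
  pts <- NULL
  brk <- numeric(0)  # cumulative section end arcs
  for (id in chain) {
    p <- m$sections[[id]]$points
    pts <- if (is.null(pts)) p else rbind(pts, p[-1, , drop = FALSE])
    brk <- c(brk, 0)
  }
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  sd <- gmwm_signed_distance(geom, pts)
  cross_i <- which(sd[-1] >= 0 & sd[-length(sd)] < 0)
  if (length(cross_i)) {
    i <- cross_i[1]
    f <- sd[i] / (sd[i] - sd[i + 1])
    pc <- pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
    s_cross <- arc[i] + f * seg[i]
    t0 <- (pts[i + 1, ] - pts[i, ]) / seg[i]
  } else {
    # An axon running obliquely through the gyral stalk (or along the GM
    # medial axis) may never meet the boundary. Redirect it toward the
    # nearest white matter at the first point where the WM-ward direction
    # (gradient of the signed boundary distance) deviates from the current
    # course and enough axon remains to get there.
    margin <- (arc[length(arc)] - arc) - abs(sd)
    h <- 1e-3
    gx <- (gmwm_signed_distance(geom, cbind(pts[, 1] + h, pts[, 2])) -
           gmwm_signed_distance(geom, cbind(pts[, 1] - h, pts[, 2]))) / (2 * h)
    gy <- (gmwm_signed_distance(geom, cbind(pts[, 1], pts[, 2] + h)) -
           gmwm_signed_distance(geom, cbind(pts[, 1], pts[, 2] - h))) / (2 * h)
    gn <- sqrt(gx^2 + gy^2)
    tx <- c(diff(pts[, 1]), 0) / c(seg, 1)
    ty <- c(diff(pts[, 2]), 0) / c(seg, 1)
    ang_ok <- gn > 0.2 & (gx * tx + gy * ty) / pmax(gn, 1e-12) < cos(20 * pi / 180)
    cand <- which(ang_ok & margin >= 0.5)
    i <- if (length(cand)) cand[1] else which.max(margin)
    if (margin[i] < 0.2) {
      warning("axon does not reach the GM/WM boundary; no bend applied")
      return(m)
    }
    i <- max(i, 2L)
    pc <- pts[i, ]
    s_cross <- arc[i]
    t0 <- (pts[i, ] - pts[i - 1, ]) / max(seg[i - 1], 1e-12)
  }
  if (length(cross_i)) {
    # continuation into WM along the local fiber direction
    if (geom$kind == "asym") {
      s <- unwarp_xy(geom, pc[1], pc[2])
      J <- warp_jacobian(geom, s[1, 1], s[1, 2])
      fib <- c(J$dxdy[1], J$dydy[1], 0)
    } else fib <- c(0, 1, 0)
    fib <- fib / sqrt(sum(fib^2))
    dt <- sum(t0 * fib)
    target <- if (abs(dt) > 1e-9) fib * sign(dt) else -abs(c(0, 1, 0))
  } else {
    # redirect toward the nearest white matter: steepest ascent of the
    # signed boundary distance (an axon parallel to a vertical boundary
    # cannot reach it along the fiber direction)
    h <- 1e-3
    gx <- (gmwm_signed_distance(geom, cbind(pc[1] + h, pc[2])) -
           gmwm_signed_distance(geom, cbind(pc[1] - h, pc[2]))) / (2 * h)
    gy <- (gmwm_signed_distance(geom, cbind(pc[1], pc[2] + h)) -
           gmwm_signed_distance(geom, cbind(pc[1], pc[2] - h))) / (2 * h)
    target <- c(gx, gy, 0)
    nt <- sqrt(sum(target^2))
    target <- if (nt > 1e-9) target / nt else c(0, -1, 0)
  }
  cosang <- max(-1, min(1, sum(t0 * target)))
  theta <- if (is.null(angle)) acos(cosang) else angle * pi / 180
  if (theta < 1e-4) {
    if (!length(cross_i))
      warning("axon does not reach the GM/WM boundary; no bend applied")
    return(m)
  }
  nperp <- target - sum(target * t0) * t0
  if (sqrt(sum(nperp^2)) < 1e-9) {
    # tangent (anti)parallel to target: bend in the sagittal plane
    nperp <- c(0, -1, 0) - sum(c(0, -1, 0) * t0) * t0
  }
  nperp <- nperp / sqrt(sum(nperp^2))
  total_rem <- arc[length(arc)] - s_cross
  arc_len <- min(theta * radius, total_rem)
  # new distal centerline: circular arc then straight
  path_pt <- function(s) {
    if (s <= arc_len) {
      phi <- s / radius
      pc + radius * (sin(phi) * t0 + (1 - cos(phi)) * nperp)
    } else {
      phi <- arc_len / radius
      tend <- cos(phi) * t0 + sin(phi) * nperp
      pend <- pc + radius * (sin(phi) * t0 + (1 - cos(phi)) * nperp)
      pend + (s - arc_len) * tend
    }
  }
  # remap every axon point beyond the crossing onto the new centerline
  sec_arc0 <- 0
  for (id in chain) {
    p <- m$sections[[id]]$points
    n <- nrow(p)
    d <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    for (k in seq_len(n)) {
      s_abs <- sec_arc0 + d[k]
      if (s_abs > s_cross + 1e-12)
        m$sections[[id]]$points[k, ] <- path_pt(s_abs - s_cross)
    }
    sec_arc0 <- sec_arc0 + d[n]
  }
  m$bend <- list(point = pc, s_cross = s_cross, arc_len = arc_len,
                 radius = radius, angle_deg = theta * 180 / pi)
  m
}

#' Discretize a morphology into compartments
#'
#' Splits every section into compartments no longer than
#' `max_compartment_length`, with centers on the section polylines and axial
#' linkage mirroring the tree topology.
#'
#' @param m A `sucs_morphology` (local or placed).
#' @param max_compartment_length Maximum compartment length (um).
#' @return Object of class `sucs_compartments`: a data frame with columns
#'   `x, y, z` (mm), `len_um`, `diam_um`, `kind`, `section`, `parent`
#'   (0 for the root compartment), `axon_arc` (mm from the start of the
#'   initial segment, NA off-axon) and `terminal` (last axonal compartment).
#' @export
discretize <- function(m, max_compartment_length = 50) {
  if (!is.finite(max_compartment_length) || max_compartment_length <= 0)
    stop("parameter error: max_compartment_length must be positive")
  rows <- list()
  first_comp <- last_comp <- integer(length(m$sections))
  comp_count <- 0L
  # arc offset of each axonal section from the start of the AIS
  kinds_all <- vapply(m$sections, `[[`, "", "kind")
  chain <- axon_chain(m)
  axon_arc0 <- setNames(rep(NA_real_, length(m$sections)),
                        seq_along(m$sections))
  s0 <- 0
  for (id in chain) {
    axon_arc0[id] <- s0
    s0 <- s0 + section_length_mm(m$sections[[id]])
  }
  interp_at <- function(p, d, s) {
    k <- findInterval(s, d, rightmost.closed = TRUE)
    k <- max(1L, min(k, nrow(p) - 1L))
    w <- (s - d[k]) / max(d[k + 1] - d[k], 1e-300)
    p[k, ] + w * (p[k + 1, ] - p[k, ])
  }
  for (sec in m$sections) {
    p <- sec$points
    d <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    len_mm <- d[length(d)]
    len_um <- len_mm * 1e3
    nseg <- max(1L, ceiling(len_um / max_compartment_length - 1e-9))
    centers_s <- (seq_len(nseg) - 0.5) / nseg * len_mm
    xyz <- t(vapply(centers_s, function(s) interp_at(p, d, s), numeric(3)))
    is_ax <- sec$kind %in% c("ais", "internode", "node", "terminal", "axon")
    for (q in seq_len(nseg)) {
      comp_count <- comp_count + 1L
      if (q == 1L) first_comp[sec$id] <- comp_count
      parent <- if (q > 1L) comp_count - 1L
        else if (sec$parent == 0L) 0L
        else {
          # attach to the parent's compartment containing parent_frac
          pf <- min(max(sec$parent_frac, 0), 1)
          np <- last_comp[sec$parent] - first_comp[sec$parent] + 1L
          first_comp[sec$parent] + min(np - 1L, floor(pf * np))
        }
      rows[[comp_count]] <- c(xyz[q, ], len_um / nseg, sec$diam,
                              parent, sec$id,
                              if (is_ax) axon_arc0[sec$id] + centers_s[q]
                              else NA_real_)
      last_comp[sec$id] <- comp_count
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("x", "y", "z", "len_um", "diam_um", "parent", "section",
                 "axon_arc")
  df$kind <- kinds_all[df$section]
  df$terminal <- FALSE
  if (length(chain)) {
    df$terminal[last_comp[chain[length(chain)]]] <- TRUE
  }
  attr(df, "layer") <- m$layer
  attr(df, "bend") <- m$bend
  attr(df, "max_len") <- max_compartment_length
  class(df) <- c("sucs_compartments", class(df))
  df
}
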