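# Distribution of neuron instances over the cortical geometry and the
# perturbation operators used for sensitivity analyses.

soma_height_above_gmwm <- c(L5 = 0.6, L3 = 1.8)

#' Distribute neuron somata along the cortical path
#'
#' Somata are placed at uniform arc-length intervals along the
#' crown-to-opposite-crown path at the layer's depth (0.6 mm above the GM/WM
#' boundary for L5, 1.8 mm for L3), centered on the path midpoint so the slab
#' placement is mirror-symmetric; cross-sections (planes) are replicated
#' along z at uniform spacing spanning the region of interest.
#'
#' @param geom A `sucs_geometry`.
#' @param layer `"L5"` or `"L3"`.
#' @param spacing_along_path In-plane soma spacing (mm).
#' @param plane_spacing Plane spacing along z (mm).
#' @param roi Region-of-interest edge length (mm); planes span `roi` in z,
#'   centered on the extrusion midpoint. Must fit within the geometry.
#' @param planes Optional explicit z coordinates of the planes (overrides
#'   `roi`/`plane_spacing`); e.g. a single plane through the active electrode.
#' @param both_sides If TRUE, additionally place the mirror image of the path
#'   on the x < 0 half (`side = -1`), sharing the crown-center soma; used for
#'   symmetry and bank-asymmetry analyses.
#' @return Object of class `sucs_placement`: a data frame with soma
#'   coordinates, path coordinates, region labels, plane index, a `side`
#'   column and orientation frame columns (`ax, ay, az`, `tx, ty, tz`,
#'   `roll`).
#' @export
distribute_neurons <- function(geom, layer = c("L5", "L3"),
                               spacing_along_path = 1, plane_spacing = 1,
                               roi = 50, planes = NULL, both_sides = FALSE) {
  layer <- match.arg(layer)
  if (spacing_along_path <= 0 || plane_spacing <= 0)
    stop("placement error: spacings must be positive")
  cs <- geom$cs
  depth <- cs$gm - soma_height_above_gmwm[[layer]]
  if (depth <= 0 || depth >= cs$r)
    stop("placement error: soma depth outside the valid offset range")
  if (is.null(planes)) {
    if (roi > cs$z_len + 1e-9)
      stop("placement error: ROI larger than the geometry extrusion")
    zmid <- cs$z_len / 2
    kz <- floor(roi / (2 * plane_spacing) + 1e-9)
    planes <- zmid + (-kz:kz) * plane_spacing
  }
  path <- cortical_path(geom, depth, n = 4001)
  Lw <- max(path$sw)
  sw_target <- (0:floor(Lw / spacing_along_path + 1e-9)) * spacing_along_path
  cols <- c("s", "x", "y", "ax", "ay", "tx", "ty")
  ip <- lapply(cols, function(cn) approx(path$sw, path[[cn]], sw_target)$y)
  names(ip) <- cols
  nr <- vapply(sw_target, function(s) which.min(abs(path$sw - s)), 0L)
  one <- data.frame(
    side = 1, s = ip$s, sw = sw_target,
    region = as.character(path$region[nr]),
    x = ip$x, y = ip$y,
    ax = ip$ax, ay = ip$ay, az = 0,
    tx = ip$tx, ty = ip$ty, tz = 0,
    stringsAsFactors = FALSE)
  if (both_sides) {
    mir <- one[one$sw > spacing_along_path / 2, ]
    mir$side <- -1
    mir$x <- -mir$x
    mir$ax <- -mir$ax
    mir$tx <- -mir$tx
    one <- rbind(one, mir)
  }
  per_plane <- nrow(one)
  np <- length(planes)
  out <- data.frame(
    id = seq_len(per_plane * np),
    layer = layer,
    plane = rep(seq_len(np), each = per_plane),
    side = rep(one$side, np),
    s = rep(one$s, np),
    sw = rep(one$sw, np),
    region = rep(one$region, np),
    x = rep(one$x, np),
    y = rep(one$y, np),
    z = rep(planes, each = per_plane),
    ax = rep(one$ax, np),
    ay = rep(one$ay, np),
    az = 0,
    tx = rep(one$tx, np),
    ty = rep(one$ty, np),
    tz = 0,
    roll = 0,
    stringsAsFactors = FALSE
  )
  # renormalize interpolated frames
  na <- sqrt(out$ax^2 + out$ay^2)
  out$ax <- out$ax / na; out$ay <- out$ay / na
  nt <- sqrt(out$tx^2 + out$ty^2)
  out$tx <- out$tx / nt; out$ty <- out$ty / nt
  attr(out, "geom") <- geom
  attr(out, "per_plane") <- per_plane
  attr(out, "planes") <- planes
  attr(out, "depth") <- depth
  class(out) <- c("sucs_placement", class(out))
  out
}

#' Shift somata along the local cortical normal
#'
#' @param set A `sucs_placement`.
#' @param offset Shift magnitude (mm).
#' @param sign `"up"` (toward the pia) or `"down"` (toward the WM).
#' @return The shifted placement; somata that leave the gray matter are
#'   excluded with a warning (count in `attr(, "excluded")`).
#' @export
perturb_positions <- function(set, offset, sign = c("up", "down")) {
  sign <- match.arg(sign)
  if (offset == 0) return(set)
  sgn <- if (sign == "up") 1 else -1
  geom <- attr(set, "geom")
  set$x <- set$x + sgn * offset * set$ax
  set$y <- set$y + sgn * offset * set$ay
  if (abs(offset) > 0) {
    tis <- tissue_at(geom, cbind(set$x, set$y), electrodes = FALSE)
    drop <- tis != "gm"
    if (any(drop)) {
      warning(sprintf("%d soma(s) left the gray matter and were excluded",
                      sum(drop)))
      att <- attributes(set)
      set <- set[!drop, ]
      attr(set, "geom") <- att$geom
      attr(set, "per_plane") <- att$per_plane
      attr(set, "planes") <- att$planes
      attr(set, "depth") <- att$depth
      class(set) <- c("sucs_placement", "data.frame")
    }
    attr(set, "excluded") <- sum(drop)
  } else attr(set, "excluded") <- 0L
  set
}

#' Rotate dendritic trees about the apical axis
#'
#' Orientation frames are rotated about each soma's local apical axis; soma
#' coordinates are unchanged. Rotations compose additively.
#'
#' @param set A `sucs_placement`.
#' @param angle Rotation in degrees (0 to 90 in the sensitivity protocol).
#' @return The placement with updated `roll`.
#' @export
rotate_dendrites <- function(set, angle) {
  if (!is.finite(angle)) stop("placement error: angle must be finite")
  set$roll <- set$roll + angle
  set
}

#' Orientation frame of one placed instance
#'
#' @param set A `sucs_placement`.
#' @param i Row index.
#' @return 3x3 rotation matrix with columns (tangent, apical, third axis),
#'   including the dendritic roll about the apical axis.
#' @export
placement_frame <- function(set, i) {
  ey <- c(set$ax[i], set$ay[i], set$az[i])
  ex <- c(set$tx[i], set$ty[i], set$tz[i])
  ex <- ex - sum(ex * ey) * ey
  ex <- ex / sqrt(sum(ex^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- cbind(ex, ey, ez)
  th <- set$roll[i] * pi / 180
  Ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  R %*% Ry
}

#' Build the placed, bent morphology of one instance
#'
#' @param set A `sucs_placement`.
#' @param i Row index.
#' @param lengthen Neurite lengthening factor.
#' @param bend_radius L5 axon bend radius at the GM/WM boundary (mm).
#' @return A placed `sucs_morphology`.
#' @export
instance_morphology <- function(set, i, lengthen = 1.6, bend_radius = 0.5) {
  geom <- attr(set, "geom")
  m <- build_morphology(set$layer[i], lengthen = lengthen)
  m <- place_morphology(m, soma = c(set$x[i], set$y[i], set$z[i]),
                        apical = c(set$ax[i], set$ay[i], set$az[i]),
                        tangent = c(set$tx[i], set$ty[i], set$tz[i]),
                        roll = set$roll[i])
  if (set$layer[i] == "L5")
    m <- bend_axon_at_boundary(m, geom, radius = bend_radius)
  m
}
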