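# Gyral volume-conductor geometries: a mirror-symmetric extruded slab and an
# asymmetric folded surrogate. Coordinates in mm: x lateral, y vertical
# (perpendicular to the skull), z along the gyrus (extrusion axis). y = 0 is
# the bottom of the white matter; the brain (pial crown) surface is at y = Hb.
#
# The cross-section is symmetric about the stimulated gyrus: the electrode
# sits at x = 0 on the crown, a sulcal fold lies on each side (cavity centers
# x = +-xf), and an outer crown continues beyond each fold. The cortical path
# ("crown to opposite crown") runs over the +x half: crown center -> lip ->
# bank -> sulcal bottom -> opposite bank -> opposite lip -> opposite crown.
# Most cross-section machinery works in fold-local coordinates
# xi = |x| - xf, which makes the two folds share one set of primitives.

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

derive_cross_section <- function(p) {
  a <- p$sulcus_half_width
  r <- p$lip_radius
  gw <- p$precentral_gyrus_width
  gm <- p$gm_thickness
  cf <- gw / 2        # half-width of the stimulated (flat) crown
  c_opp <- gw         # run length over the opposite crown
  if (is.null(p$sulcal_depth)) {
    L <- p$crown_to_crown_path_length
    wall <- (L - cf - c_opp - pi * (r + a)) / 2
    d <- wall + r + a
  } else {
    d <- p$sulcal_depth
    wall <- d - r - a
    L <- cf + c_opp + 2 * wall + pi * (r + a)
  }
  if (wall <= 0)
    stop("geometry error: fold is degenerate (sulcal depth <= lip radius + sulcus half width)")
  if (gm >= p$wm_margin)
    stop("geometry error: wm_margin must exceed gm_thickness")
  Hb <- d + p$wm_margin
  lt <- p$layer_thicknesses
  ybreaks <- Hb + cumsum(c(csf = unname(lt["csf"]), dura = unname(lt["dura"]),
                           skull = unname(lt["skull"]), scalp = unname(lt["scalp"])))
  xf <- cf + r + a
  x_end <- xf + a + r + c_opp
  list(a = a, r = r, gw = gw, gm = gm, cf = cf, c_opp = c_opp, d = d,
       wall = wall, L = L, Hb = Hb, yb = Hb - d + a, xf = xf,
       x_end = x_end, x_max = x_end + p$lateral_margin,
       xi_max = x_end + p$lateral_margin - xf,
       y_csf_top = ybreaks[["csf"]], y_dura_top = ybreaks[["dura"]],
       y_skull_top = ybreaks[["skull"]], y_top = ybreaks[["scalp"]],
       z_len = p$extrusion_length_z)
}

#' Build the mirror-symmetric extruded-slab geometry
#'
#' The cross-section is constant along z (extruded); tissue compartments are
#' ordered scalp, skull, dura, CSF, GM, WM from outside in, and the geometry
#' is exactly mirror-symmetric about the stimulated-gyrus midplane x = 0.
#'
#' @param params A [slab_params()] object.
#' @return An object of class `sucs_geometry`.
#' @export
build_slab_geometry <- function(params = slab_params()) {
  if (!inherits(params, "sucs_slab_params"))
    stop("parameter error: params must come from slab_params()")
  cs <- derive_cross_section(params)
  g <- list(kind = "slab", params = params, cs = cs, electrodes = list(),
            grounding = "exterior_grounded_except_skull_top")
  class(g) <- "sucs_geometry"
  g
}

#' Build the asymmetric folded-gyrus surrogate geometry
#'
#' A stand-in for the MRI-derived full-head model: a smooth, invertible warp
#' elongates the bank of the cortical-path-side fold (the central-sulcus
#' surrogate, region B) by `asymmetry_factor` relative to its mirrored twin
#' (the precentral-sulcus surrogate), optionally bowing it. At factor 1 with
#' zero curvature the warp is the identity and the slab is reproduced
#' exactly.
#'
#' @param params An [asym_params()] object.
#' @return An object of class `sucs_geometry` with `kind = "asym"`.
#' @export
build_asymmetric_geometry <- function(params = asym_params()) {
  if (!inherits(params, "sucs_asym_params"))
    stop("parameter error: params must come from asym_params()")
  cs <- derive_cross_section(params)
  f <- params$asymmetry_factor
  # depth ramp: ramp in over the lip (t1..t2), full stretch through the bank
  # (t2..t3), fade out below the sulcal bottom (t4) so deep WM is only
  # rigidly shifted, never stretched indefinitely. The crown itself is
  # protected by the lateral mask, not by the depth gate, so the asymmetry
  # reaches the upper bank (where minimum thresholds live).
  t1 <- 1.5
  t2 <- 3
  t3 <- cs$d - cs$a
  t4 <- cs$d
  if (t2 >= t3)
    stop("geometry error: fold too shallow for the asymmetry warp ramp")
  w0 <- list(t1 = t1, t2 = t2, t3 = t3, t4 = t4)
  f_eff <- 1 + (f - 1) * cs$wall / (warp_Gd2(w0, t3) - warp_Gd2(w0, cs$r))
  Gd_max <- 0.5 * (t2 - t1) + (t4 - t2) - 0.5 * (t4 - t3)
  # deepen the domain to absorb the maximal downward shift of deep tissue
  p2 <- params
  p2$wm_margin <- params$wm_margin + (f_eff - 1) * Gd_max
  cs <- derive_cross_section(p2)
  g <- list(kind = "asym", params = params, cs = cs, electrodes = list(),
            grounding = if (params$closure == "hull") "distant_patch"
                        else "exterior_grounded_except_skull_top",
            warp = list(f = f, f_eff = f_eff, t1 = t1, t2 = t2, t3 = t3,
                        t4 = t4, Gd_max = Gd_max,
                        u1 = 0.25 * cs$a, u2 = cs$a,
                        u3 = cs$a + cs$gm + 0.5, u4 = cs$a + cs$gm + 2,
                        kappa = params$bank_curvature,
                        patch = params$ground_patch_halfwidth))
  class(g) <- "sucs_geometry"
  g
}

#' @export
print.sucs_geometry <- function(x, ...) {
  cs <- x$cs
  cat(sprintf("<sucs_geometry: %s>\n", x$kind))
  cat(sprintf("  gyral width %.2f mm, sulcal depth %.2f mm, GM %.2f mm\n",
              cs$gw, cs$d, cs$gm))
  cat(sprintf("  crown-to-crown path %.2f mm; domain %.1f x %.1f x %.1f mm\n",
              cs$L, 2 * cs$x_max, cs$y_top, cs$z_len))
  cat(sprintf("  electrodes: %d (%s)\n", length(x$electrodes),
              paste(vapply(x$electrodes, `[[`, "", "role"), collapse = ", ")))
  invisible(x)
}

# integral from 0 to depth of smoothstep((t - t1)/(t2 - t1))
warp_Gd <- function(depth, t1, t2) {
  u <- pmin(pmax((depth - t1) / (t2 - t1), 0), 1)
  ramp <- (t2 - t1) * (u^3 - 0.5 * u^4)
  ramp + pmax(depth - t2, 0)
}

# ramped depth-stretch profile (up over t1..t2, down over t3..t4) and integral
warp_sd2 <- function(w, t) {
  smoothstep((t - w$t1) / (w$t2 - w$t1)) - smoothstep((t - w$t3) / (w$t4 - w$t3))
}

warp_Gd2 <- function(w, t) {
  warp_Gd(t, w$t1, w$t2) - warp_Gd(t, w$t3, w$t4)
}

# lateral mask: a bump over the inner (gyrus-side) wall of the +x fold only;
# vanishes at the cavity center and again toward the gyral interior so the
# warp is smooth across x = 0
warp_sx <- function(geom, x) {
  w <- geom$warp
  u <- geom$cs$xf - x  # distance from the +x cavity center toward the gyrus
  s <- smoothstep((u - w$u1) / (w$u2 - w$u1)) *
       (1 - smoothstep((u - w$u3) / (w$u4 - w$u3)))
  s[x <= 0] <- 0
  s
}

warp_bow <- function(geom, depth) {
  cs <- geom$cs
  sin(pi * pmin(pmax((depth - cs$r) / (cs$wall), 0), 1))
}

# forward warp: slab coordinates -> surrogate coordinates
warp_xy <- function(geom, x, y) {
  if (geom$kind != "asym") return(cbind(x = x, y = y))
  w <- geom$warp
  cs <- geom$cs
  depth <- pmax(cs$Hb - y, 0)
  k <- (w$f_eff - 1) * warp_sx(geom, x)
  dwarp <- depth + k * warp_Gd2(w, depth)
  yw <- ifelse(y < cs$Hb, cs$Hb - dwarp, y)
  xw <- x - w$kappa * warp_bow(geom, pmax(cs$Hb - yw, 0)) * warp_sx(geom, x)
  cbind(x = xw, y = yw)
}

# inverse warp: surrogate coordinates -> slab coordinates. The depth map
# F(depth) = depth + k * Gd(depth) has slope in [1, 1 + k] with k < 1, so the
# fixed-point iteration depth <- dwarp - k * Gd(depth) is a global contraction.
unwarp_xy <- function(geom, xw, yw) {
  if (geom$kind != "asym") return(cbind(x = xw, y = yw))
  w <- geom$warp
  cs <- geom$cs
  dwarp <- pmax(cs$Hb - yw, 0)
  x <- xw
  if (w$kappa > 0) {
    bow <- w$kappa * warp_bow(geom, dwarp)
    for (i in 1:20) x <- xw + bow * warp_sx(geom, x)
  }
  k <- (w$f_eff - 1) * warp_sx(geom, x)
  depth <- dwarp
  act <- which(k > 0 & dwarp > w$t1)
  if (length(act)) {
    dd <- dwarp[act]
    kk <- k[act]
    est <- dd
    for (i in 1:40) est <- dd - kk * warp_Gd2(w, est)
    depth[act] <- est
  }
  y <- ifelse(yw < cs$Hb, cs$Hb - depth, yw)
  cbind(x = x, y = y)
}

# Jacobian of the forward warp at slab coordinates, by central differences
warp_jacobian <- function(geom, x, y, h = 1e-4) {
  px <- (warp_xy(geom, x + h, y) - warp_xy(geom, x - h, y)) / (2 * h)
  py <- (warp_xy(geom, x, y + h) - warp_xy(geom, x, y - h)) / (2 * h)
  list(dxdx = px[, 1], dydx = px[, 2], dxdy = py[, 1], dydy = py[, 2])
}

# cavity (sulcal CSF cleft) test in fold-local coordinates xi = |x| - xf
in_cavity <- function(cs, xi, y) {
  bound <- rep(-Inf, length(xi))
  hi <- y <= cs$Hb & y >= cs$Hb - cs$r
  mid <- y < cs$Hb - cs$r & y >= cs$yb
  lo <- y < cs$yb & y >= cs$Hb - cs$d
  bound[hi] <- (cs$a + cs$r) -
    sqrt(pmax(cs$r^2 - (y[hi] - (cs$Hb - cs$r))^2, 0))
  bound[mid] <- cs$a
  bound[lo] <- sqrt(pmax(cs$a^2 - (y[lo] - cs$yb)^2, 0))
  abs(xi) < bound
}

# distance from tissue points (fold-local coordinates, below the crown plane
# and outside the cavity) to the pial surface
dist_to_pia <- function(cs, xi, y) {
  xa <- abs(xi)
  d_crown <- sqrt(pmax(xa - cs$xi_max, 0)^2 +
                  pmax(cs$a + cs$r - xa, 0)^2 + (y - cs$Hb)^2)
  # lip arc; in-sector when the angle from the center lies in [0, 90] deg
  dxl <- xa - (cs$a + cs$r)
  dyl <- y - (cs$Hb - cs$r)
  dcl <- sqrt(dxl^2 + dyl^2)
  lip_ok <- dxl <= 0 & dyl >= 0
  d_lip <- ifelse(lip_ok, abs(dcl - cs$r), Inf)
  # sulcal wall segment |xi| = a, y in [yb, Hb - r]
  ycl <- pmin(pmax(y, cs$yb), cs$Hb - cs$r)
  d_wall <- sqrt((xa - cs$a)^2 + (y - ycl)^2)
  # sulcal bottom arc, radius a around (0, yb), lower half
  dcb <- sqrt(xi^2 + (y - cs$yb)^2)
  d_bot <- ifelse(y <= cs$yb, abs(dcb - cs$a), Inf)
  pmin(d_crown, d_lip, d_wall, d_bot)
}

#' Classify tissue at points of a gyral geometry
#'
#' @param geom A `sucs_geometry`.
#' @param pts Numeric matrix with columns x, y and (optionally) z in mm.
#'   z is only needed when electrode bodies have been placed.
#' @param electrodes Whether electrode/substrate bodies override CSF.
#' @return Character vector of tissue labels among `scalp, skull, dura, csf,
#'   gm, wm, electrode, substrate`.
#' @export
tissue_at <- function(geom, pts, electrodes = TRUE) {
  pts <- rbind(pts)
  cs <- geom$cs
  xw <- pts[, 1]
  yw <- pts[, 2]
  out <- character(nrow(pts))
  above <- yw >= cs$Hb
  out[above & yw <= cs$y_csf_top] <- "csf"
  out[yw > cs$y_csf_top & yw <= cs$y_dura_top] <- "dura"
  out[yw > cs$y_dura_top & yw <= cs$y_skull_top] <- "skull"
  out[yw > cs$y_skull_top] <- "scalp"
  below <- which(!above)
  if (length(below)) {
    s <- unwarp_xy(geom, xw[below], yw[below])
    xi <- abs(s[, 1]) - cs$xf
    cav <- in_cavity(cs, xi, s[, 2])
    dp <- dist_to_pia(cs, xi, s[, 2])
    out[below] <- ifelse(cav, "csf", ifelse(dp <= cs$gm, "gm", "wm"))
  }
  if (electrodes && length(geom$electrodes) && ncol(pts) >= 3) {
    z <- pts[, 3]
    for (e in geom$electrodes) {
      rr <- sqrt((xw - e$x)^2 + (z - e$z)^2)
      yc0 <- cs$Hb
      yc1 <- cs$Hb + e$contact_thickness
      ys1 <- yc1 + e$substrate_thickness
      sub <- rr <= e$substrate_extent / 2 & yw >= yc0 & yw <= ys1
      con <- rr <= e$diameter / 2 & yw >= yc0 & yw <= yc1
      out[sub] <- "substrate"
      out[con] <- "electrode"
    }
  }
  out
}

#' Signed distance to the GM/WM boundary
#'
#' Negative inside gray matter, positive inside white matter. For the
#' asymmetric surrogate the distance is evaluated in unwarped coordinates
#' (mild-warp approximation).
#'
#' @param geom A `sucs_geometry`.
#' @param pts Matrix with columns x, y (z ignored).
#' @return Numeric vector (mm).
#' @export
gmwm_signed_distance <- function(geom, pts) {
  pts <- rbind(pts)
  cs <- geom$cs
  s <- unwarp_xy(geom, pts[, 1], pts[, 2])
  dist_to_pia(cs, abs(s[, 1]) - cs$xf, s[, 2]) - cs$gm
}

#' Gyral (crown) width measured from the geometry
#'
#' Width of the flat crown top of the stimulated gyrus.
#'
#' @param geom A `sucs_geometry`.
#' @return Width in mm.
#' @export
gyral_width <- function(geom) 2 * geom$cs$cf

crown_center_x <- function(geom) 0

# Segment table of the cortical path at a given depth below the pia.
# Segment lengths depend on depth but their sum does not (the convex lip arcs
# and the concave bottom arc cancel exactly).
path_segments <- function(geom, depth) {
  cs <- geom$cs
  if (depth < 0 || depth >= cs$r)
    stop("path error: depth must lie in [0, lip_radius)")
  len <- c(cs$cf, (pi / 2) * (cs$r - depth), cs$wall,
           pi * (cs$a + depth), cs$wall, (pi / 2) * (cs$r - depth), cs$c_opp)
  data.frame(region = c("C", "L", "B", "BS", "OB", "OL", "OC"),
             length = len, s1 = cumsum(len) - len, s2 = cumsum(len))
}

# Point, outward (pial) normal and tangent of the slab cross-section path at
# arc positions s for a given depth, over the +x half. Vectorized over s.
# Returns slab (unwarped) coordinates; asymmetric geometries warp afterwards.
slab_path_point <- function(geom, s, depth) {
  cs <- geom$cs
  seg <- path_segments(geom, depth)
  idx <- findInterval(pmin(s, seg$s2[7] - 1e-12), seg$s1,
                      rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  u <- s - seg$s1[idx]
  rho <- cs$r - depth
  R <- cs$a + depth
  x <- y <- ax <- ay <- tx <- ty <- numeric(length(s))
  i <- idx == 1  # crown from the electrode axis outward
  x[i] <- u[i]; y[i] <- cs$Hb - depth
  ax[i] <- 0; ay[i] <- 1; tx[i] <- 1; ty[i] <- 0
  i <- idx == 2  # lip, center (cf, Hb - r)
  phi <- pi / 2 - u[i] / rho
  x[i] <- cs$cf + rho * cos(phi); y[i] <- (cs$Hb - cs$r) + rho * sin(phi)
  ax[i] <- cos(phi); ay[i] <- sin(phi); tx[i] <- sin(phi); ty[i] <- -cos(phi)
  i <- idx == 3  # bank (inner wall of the +x fold)
  x[i] <- cs$xf - (cs$a + depth); y[i] <- (cs$Hb - cs$r) - u[i]
  ax[i] <- 1; ay[i] <- 0; tx[i] <- 0; ty[i] <- -1
  i <- idx == 4  # sulcal bottom, center (xf, yb)
  phi <- pi + u[i] / R
  x[i] <- cs$xf + R * cos(phi); y[i] <- cs$yb + R * sin(phi)
  ax[i] <- -cos(phi); ay[i] <- -sin(phi); tx[i] <- -sin(phi); ty[i] <- cos(phi)
  i <- idx == 5  # opposite bank (outer wall)
  x[i] <- cs$xf + cs$a + depth; y[i] <- cs$yb + u[i]
  ax[i] <- -1; ay[i] <- 0; tx[i] <- 0; ty[i] <- 1
  i <- idx == 6  # opposite lip, center (xf + a + r, Hb - r)
  phi <- pi - u[i] / rho
  x[i] <- (cs$xf + cs$a + cs$r) + rho * cos(phi)
  y[i] <- (cs$Hb - cs$r) + rho * sin(phi)
  ax[i] <- cos(phi); ay[i] <- sin(phi); tx[i] <- sin(phi); ty[i] <- -cos(phi)
  i <- idx == 7  # opposite crown
  x[i] <- (cs$xf + cs$a + cs$r) + u[i]; y[i] <- cs$Hb - depth
  ax[i] <- 0; ay[i] <- 1; tx[i] <- 1; ty[i] <- 0
  data.frame(s = s, x = x, y = y, ax = ax, ay = ay, tx = tx, ty = ty,
             region = seg$region[idx])
}

#' Cortical path from crown to opposite crown at a given depth
#'
#' Samples the crown-lip-bank-bottom-bank-lip-crown path (over the +x half of
#' the symmetric cross-section) together with the outward pial normal
#' ("apical" direction) and tangent at each sample.
#'
#' @param geom A `sucs_geometry`.
#' @param depth Depth below the pial surface (mm), in `[0, lip_radius)`.
#' @param n Number of samples.
#' @return Data frame with columns `s` (slab parameter), `sw` (realized arc
#'   length), `x`, `y`, `ax`, `ay` (outward normal), `tx`, `ty` (tangent),
#'   `region`.
#' @export
cortical_path <- function(geom, depth, n = 563) {
  cs <- geom$cs
  sg <- seq(0, cs$L, length.out = max(n, 3))
  pp <- slab_path_point(geom, sg, depth)
  if (geom$kind == "asym") {
    wp <- warp_xy(geom, pp$x, pp$y)
    J <- warp_jacobian(geom, pp$x, pp$y)
    axw <- J$dxdx * pp$ax + J$dxdy * pp$ay
    ayw <- J$dydx * pp$ax + J$dydy * pp$ay
    nrm <- sqrt(axw^2 + ayw^2)
    txw <- J$dxdx * pp$tx + J$dxdy * pp$ty
    tyw <- J$dydx * pp$tx + J$dydy * pp$ty
    nrt <- sqrt(txw^2 + tyw^2)
    pp$x <- wp[, 1]; pp$y <- wp[, 2]
    pp$ax <- axw / nrm; pp$ay <- ayw / nrm
    pp$tx <- txw / nrt; pp$ty <- tyw / nrt
  }
  dx <- diff(pp$x); dy <- diff(pp$y)
  pp$sw <- c(0, cumsum(sqrt(dx^2 + dy^2)))
  pp
}

#' Arc lengths of the central-sulcus-side bank and its mirrored twin
#'
#' Measured numerically on the generated cortical path (region B) and on the
#' mirrored path at x < 0 (the precentral-sulcus surrogate); for the
#' asymmetric surrogate the ratio equals the asymmetry factor.
#'
#' @param geom A `sucs_geometry`.
#' @param depth Depth below the pia (mm) at which to measure.
#' @return Named vector `c(central = , precentral = )` of arc lengths (mm).
#' @export
bank_arc_lengths <- function(geom, depth = 0) {
  cs <- geom$cs
  sg <- seq(0, cs$L, length.out = 4001)
  pp <- slab_path_point(geom, sg, depth)
  bank <- function(sign_x) {
    i <- which(pp$region == "B")
    x <- sign_x * pp$x[i]
    y <- pp$y[i]
    w <- warp_xy(geom, x, y)
    sum(sqrt(diff(w[, 1])^2 + diff(w[, 2])^2))
  }
  c(central = bank(1), precentral = bank(-1))
}

#' Place subdural electrodes on a geometry
#'
#' Contacts must lie on a flat gyral crown (the subdural surface beneath the
#' dura); substrate discs must also fit the crown, and electrodes may not
#' overlap each other.
#'
#' @param geom A `sucs_geometry`.
#' @param specs A list of [electrode_spec()] objects (or a single one).
#' @return The geometry with electrodes embedded.
#' @export
place_electrodes <- function(geom, specs) {
  if (inherits(specs, "sucs_electrode")) specs <- list(specs)
  cs <- geom$cs
  if (length(specs) >= 2) {
    for (i in seq_along(specs)) for (j in seq_len(i - 1)) {
      sep <- sqrt((specs[[i]]$x - specs[[j]]$x)^2 +
                  (specs[[i]]$z - specs[[j]]$z)^2)
      if (sep < (specs[[i]]$diameter + specs[[j]]$diameter) / 2)
        stop(sprintf(
          "placement error: electrodes %d and %d overlap (separation %.2f mm < contact radii sum %.2f mm)",
          j, i, sep, (specs[[i]]$diameter + specs[[j]]$diameter) / 2))
    }
  }
  tol <- 1e-9
  for (e in specs) {
    half <- e$substrate_extent / 2
    on_central <- abs(e$x) + half <= cs$cf + tol
    on_outer <- abs(e$x) - half >= cs$xf + cs$a + cs$r - tol &
                abs(e$x) + half <= cs$x_end + tol
    if (!(on_central || on_outer))
      stop(sprintf(
        "placement error: electrode at x = %.2f mm does not project onto a flat crown surface",
        e$x))
    if (e$z - half < 0 || e$z + half > cs$z_len)
      stop("placement error: electrode extends beyond the extruded domain in z")
    if (e$contact_thickness + e$substrate_thickness >
        geom$params$layer_thicknesses[["csf"]])
      stop("placement error: electrode body thicker than the subdural CSF layer")
  }
  geom$electrodes <- specs
  geom
}

electrode_by_role <- function(geom, role) {
  for (e in geom$electrodes) if (e$role == role) return(e)
  NULL
}

#' Measured active-to-return electrode separation
#'
#' @param geom A `sucs_geometry` with electrodes placed.
#' @return Center distance in mm.
#' @export
electrode_separation <- function(geom) {
  act <- electrode_by_role(geom, "active")
  ret <- electrode_by_role(geom, "return")
  if (is.null(act) || is.null(ret))
    stop("geometry error: need both an active and a return electrode")
  sqrt((act$x - ret$x)^2 + (act$z - ret$z)^2)
}

#' Region map of the cortical surface
#'
#' Partitions the gray matter under the region of interest into arc-length
#' bands along the crown-to-opposite-crown path: crown (C) directly beneath
#' the active electrode, lip (L), bank (B), bottom sulcus (BS), then the
#' opposite bank (OB), lip (OL) and crown (OC). Band boundaries are the
#' tangency points of the parametric fold. Labels are invariant along z and
#' under the x mirror (the mirrored half carries the same bands).
#'
#' @param geom A `sucs_geometry` with (at least) an active electrode.
#' @param active Optionally an explicit active [electrode_spec()].
#' @return An object of class `sucs_region_map`.
#' @export
label_regions <- function(geom, active = NULL) {
  if (is.null(active)) active <- electrode_by_role(geom, "active")
  if (is.null(active))
    stop("region error: geometry has no active electrode")
  ref <- slab_path_point(geom, seq(0, geom$cs$L, by = 0.02),
                         depth = geom$cs$gm / 2)
  m <- list(geom = geom, active = active,
            bands = path_segments(geom, 0),
            ref = ref)
  class(m) <- "sucs_region_map"
  m
}

#' Region label of arbitrary points
#'
#' Projects points onto the cortical path (nearest point at mid-GM depth, in
#' unwarped coordinates for the surrogate) and returns the band label.
#'
#' @param map A `sucs_region_map` from [label_regions()].
#' @param pts Matrix with columns x, y (z ignored: labels are invariant along
#'   the extrusion).
#' @return Character vector of labels `C, L, B, BS, OB, OL, OC`.
#' @export
region_of <- function(map, pts) {
  pts <- rbind(pts)
  s <- unwarp_xy(map$geom, pts[, 1], pts[, 2])
  ref <- map$ref
  out <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    j <- which.min((ref$x - abs(s[i, 1]))^2 + (ref$y - s[i, 2])^2)
    out[i] <- as.character(ref$region[j])
  }
  out
}
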