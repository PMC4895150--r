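#' Parameters of the extruded-slab gyral model
#'
#' The cross-section (x: lateral, y: vertical, both mm) is a smooth parametric
#' fold: two flat gyral crowns joined by convex lip arcs, straight sulcal
#' banks, and a semicircular sulcal bottom; the fold is mirror-symmetric about
#' the midplane x = 0 and extruded uniformly along z. Tissue compartments from
#' outside in are scalp, skull, dura, CSF, gray matter (GM) and white matter
#' (WM); the published gyral width (8.5 mm) fixes the crown, while the
#' sulcal depth is, by default, calibrated so the crown-to-crown cortical path
#' has the requested length (56.5 mm by default, which reproduces 57 somata
#' per plane at 1 mm spacing).
#'
#' @param precentral_gyrus_width Width (mm) of the gyral top surface (flat
#'   crown plus lip) on each side of the fold.
#' @param sulcal_depth Depth (mm) of the sulcal fold below the crown surface.
#'   `NULL` (default) calibrates it from `crown_to_crown_path_length`.
#' @param gm_thickness Cortical gray-matter thickness (mm).
#' @param layer_thicknesses Named lengths (mm) for `scalp`, `skull`, `dura`,
#'   `csf` above the brain compartment.
#' @param sulcus_half_width Half width (mm) of the CSF-filled sulcal cleft.
#' @param lip_radius Radius (mm) of the convex lip arc joining crown and bank.
#' @param extrusion_length_z Extrusion length (mm) along the gyrus (z axis).
#' @param crown_to_crown_path_length Target arc length (mm) of the cortical
#'   path from the precentral crown to the opposite crown. For this curve
#'   family the path length is independent of the depth at which the path is
#'   offset below the pia, so one calibration serves every cortical layer.
#' @param wm_margin White-matter margin (mm) kept below the sulcal bottom.
#' @param lateral_margin Lateral tissue margin (mm) beyond the crown ends.
#' @return An object of class `sucs_slab_params`.
#' @export
slab_params <- function(precentral_gyrus_width = 8.5,
                        sulcal_depth = NULL,
                        gm_thickness = 3.5,
                        layer_thicknesses = c(scalp = 4, skull = 4,
                                              dura = 0.5, csf = 1.2),
                        sulcus_half_width = 0.8,
                        lip_radius = 3,
                        extrusion_length_z = 70,
                        crown_to_crown_path_length = 56.5,
                        wm_margin = 10,
                        lateral_margin = 6) {
  p <- list(precentral_gyrus_width = precentral_gyrus_width,
            sulcal_depth = sulcal_depth,
            gm_thickness = gm_thickness,
            layer_thicknesses = layer_thicknesses,
            sulcus_half_width = sulcus_half_width,
            lip_radius = lip_radius,
            extrusion_length_z = extrusion_length_z,
            crown_to_crown_path_length = crown_to_crown_path_length,
            wm_margin = wm_margin,
            lateral_margin = lateral_margin)
  lens <- c(precentral_gyrus_width, gm_thickness, layer_thicknesses,
            sulcus_half_width, lip_radius, extrusion_length_z,
            wm_margin, lateral_margin)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("slab parameter error: all lengths must be positive and finite")
  if (!all(c("scalp", "skull", "dura", "csf") %in% names(layer_thicknesses)))
    stop("slab parameter error: layer_thicknesses must name scalp, skull, dura, csf")
  class(p) <- "sucs_slab_params"
  p
}

#' Parameters of the asymmetric folded-gyrus surrogate
#'
#' A stand-in for the MRI-derived anatomically realistic head model, which is
#' out of scope: the mirror-symmetric slab cross-section is warped so the bank
#' standing in for the central-sulcus side is elongated relative to the bank
#' standing in for the precentral-sulcus side. The warp acts only below the
#' cortical crown (depths beyond the gray matter), leaves the crowns and their
#' soma-depth rules untouched, and at `asymmetry_factor = 1` (and zero bank
#' curvature) is the identity, reproducing the slab exactly.
#'
#' @param ... Arguments forwarded to [slab_params()].
#' @param asymmetry_factor Ratio (>= 1) of central-sulcus-side bank arc length
#'   to precentral-side bank arc length.
#' @param bank_curvature Non-negative bow amplitude (mm) applied to the
#'   elongated bank; 0 keeps the bank straight. Must be < 0.35 to keep the
#'   warp invertible (no self-intersection).
#' @param closure Outer-boundary closure mode: `"box"` grounds the exterior as
#'   in the slab; `"hull"` treats the exterior as an insulated head-like hull
#'   with a distant ground patch (standing in for a chest reference electrode).
#' @param ground_patch_halfwidth Half-width (mm) of the bottom ground patch
#'   used by the `"hull"` closure / `distant_patch` grounding scheme.
#' @return An object of class `sucs_asym_params` (inherits `sucs_slab_params`).
#' @export
asym_params <- function(..., asymmetry_factor = 1.3, bank_curvature = 0,
                        closure = c("box", "hull"),
                        ground_patch_halfwidth = 5) {
  p <- slab_params(...)
  closure <- match.arg(closure)
  if (!is.finite(asymmetry_factor) || asymmetry_factor < 1)
    stop("geometry error: asymmetry_factor must be >= 1")
  if (!is.finite(bank_curvature) || bank_curvature < 0)
    stop("geometry error: bank_curvature must be non-negative")
  if (bank_curvature >= 0.35)
    stop("geometry error: bank_curvature >= 0.35 self-intersects the warp")
  p$asymmetry_factor <- asymmetry_factor
  p$bank_curvature <- bank_curvature
  p$closure <- closure
  p$ground_patch_halfwidth <- ground_patch_halfwidth
  class(p) <- c("sucs_asym_params", "sucs_slab_params")
  p
}

#' Specify a subdural disc electrode
#'
#' Covered disc-type contacts lie on the crown of the gyrus in the subdural
#' CSF space: the conductive contact sits on the pial surface and an
#' insulating substrate disc covers it from above.
#'
#' @param role One of `"active"`, `"return"`, `"reference"`.
#' @param x,z Center position (mm) on the cortical crown surface.
#' @param diameter Contact diameter (mm).
#' @param substrate_extent Substrate (cover) diameter (mm); must be >= the
#'   contact diameter.
#' @param contact_thickness,substrate_thickness Body thicknesses (mm).
#' @return An object of class `sucs_electrode`.
#' @export
electrode_spec <- function(role = c("active", "return", "reference"),
                           x, z, diameter = 4,
                           substrate_extent = diameter + 1,
                           contact_thickness = 0.4,
                           substrate_thickness = 0.5) {
  role <- match.arg(role)
  if (diameter <= 0 || substrate_extent < diameter)
    stop("electrode spec error: need 0 < diameter <= substrate_extent")
  e <- list(role = role, x = x, z = z, diameter = diameter,
            substrate_extent = substrate_extent,
            contact_thickness = contact_thickness,
            substrate_thickness = substrate_thickness)
  class(e) <- "sucs_electrode"
  e
}

#' Default electrode pair for a gyral geometry
#'
#' Two covered disc electrodes on the crown of the active (precentral) gyrus,
#' separated along the gyrus (z axis) and centered on the extrusion midpoint.
#' The separation defaults to the clinically reported 13 mm; separations below 10 mm are
#' outside the regime where bipolar stimulation behaves as a superposition of
#' the two monopolar fields and are refused by [place_electrodes()] only when
#' the discs geometrically overlap.
#'
#' @param geom A `sucs_geometry`.
#' @param separation Center-to-center distance (mm) between active and return.
#' @param diameter Contact diameter (mm).
#' @param ... Further arguments passed to [electrode_spec()].
#' @return List of two `sucs_electrode` objects (active, return).
#' @export
default_electrodes <- function(geom, separation = 13, diameter = 4, ...) {
  xc <- crown_center_x(geom)
  zm <- geom$params$extrusion_length_z / 2
  list(electrode_spec("active", x = xc, z = zm - separation / 2,
                      diameter = diameter, ...),
       electrode_spec("return", x = xc, z = zm + separation / 2,
                      diameter = diameter, ...))
}
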