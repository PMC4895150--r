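# Tissue conductivities. Isotropic values follow the published SuCS modeling
# literature; white matter is optionally transversely isotropic with fixed
# eigenvalues (longitudinal along the local fiber direction).

#' Isotropic tissue conductivity table
#'
#' Defaults (S/m): scalp 0.465, skull 0.01, dura 0.065, CSF 1.65, gray matter
#' 0.276, white matter 0.126 (the isotropic-control value), electrode
#' 9.4e6, substrate 1e-10 (effectively insulating, kept finite so the bodies
#' remain part of the model).
#'
#' @param ... Named overrides, e.g. `wm = 0.2`.
#' @return Named numeric vector of class `sucs_cond_table`.
#' @export
conductivity_table <- function(...) {
  tab <- c(scalp = 0.465, skull = 0.01, dura = 0.065, csf = 1.65,
           gm = 0.276, wm = 0.126, electrode = 9.4e6, substrate = 0.1e-9)
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || !all(names(dots) %in% names(tab)))
      stop("configuration error: unknown tissue name in conductivity table")
    tab[names(dots)] <- dots
  }
  if (any(tab <= 0)) stop("configuration error: conductivities must be > 0")
  class(tab) <- "sucs_cond_table"
  tab
}

#' Assign isotropic conductivity tensors to a mesh
#'
#' Every element receives sigma * I with sigma taken from its tissue label.
#'
#' @param mesh A `sucs_mesh`.
#' @param table A [conductivity_table()].
#' @return An object of class `sucs_conductivity`: an elements x 6 matrix of
#'   symmetric tensor components (xx, yy, zz, xy, xz, yz) in S/m.
#' @export
assign_isotropic <- function(mesh, table = conductivity_table()) {
  tis <- as.character(mesh$tissue)
  missing <- setdiff(unique(tis), names(table))
  if (length(missing))
    stop(sprintf("configuration error: no conductivity for tissue(s): %s",
                 paste(missing, collapse = ", ")))
  sig <- unclass(table)[tis]
  out <- cbind(xx = sig, yy = sig, zz = sig,
               xy = 0, xz = 0, yz = 0)
  class(out) <- c("sucs_conductivity", class(out))
  out
}

#' Per-element white-matter fiber directions
#'
#' In `slab_perpendicular` mode every fiber points along the y axis
#' (perpendicular to the skull). In `surrogate_streamline` mode the slab
#' field is carried through the asymmetry warp (normalized Jacobian image of
#' the y axis), yielding a smooth field that follows the stretched bank into
#' the gyral stalk; for a slab geometry the two modes coincide.
#'
#' @param geom A `sucs_geometry`.
#' @param mesh A `sucs_mesh` generated from it.
#' @param mode `"slab_perpendicular"` or `"surrogate_streamline"`.
#' @return Matrix (elements x 3) of unit vectors; non-WM rows are NA.
#' @export
fiber_direction_field <- function(geom, mesh,
                                  mode = c("slab_perpendicular",
                                           "surrogate_streamline")) {
  mode <- match.arg(mode)
  wm <- which(mesh$tissue == "wm")
  if (!length(wm)) stop("conductivity error: mesh has no white-matter elements")
  out <- matrix(NA_real_, nrow(mesh$elems), 3)
  if (mode == "slab_perpendicular" || geom$kind != "asym") {
    out[wm, ] <- matrix(rep(c(0, 1, 0), each = length(wm)), ncol = 3)
  } else {
    cen <- elem_centroids(mesh)[wm, , drop = FALSE]
    s <- unwarp_xy(geom, cen[, 1], cen[, 2])
    J <- warp_jacobian(geom, s[, 1], s[, 2])
    fx <- J$dxdy
    fy <- J$dydy
    nrm <- sqrt(fx^2 + fy^2)
    out[wm, ] <- cbind(fx / nrm, fy / nrm, 0)
  }
  out
}

#' Transversely isotropic conductivity tensor from an eigenframe
#'
#' Builds `S diag(sigma_L, sigma_T, sigma_T) S^T` where the first column of
#' the orthonormal matrix `S` is the longitudinal (fiber) direction.
#'
#' @param S Orthonormal 3x3 eigenvector matrix (columns).
#' @param sigma_L,sigma_T Longitudinal and transverse conductivities (S/m);
#'   defaults are the white-matter values 1.1 and 0.13.
#' @param tol Orthonormality tolerance.
#' @return Symmetric positive-definite 3x3 matrix.
#' @export
anisotropic_tensor <- function(S, sigma_L = 1.1, sigma_T = 0.13, tol = 1e-8) {
  S <- as.matrix(S)
  if (!all(dim(S) == c(3, 3)) || max(abs(crossprod(S) - diag(3))) > tol)
    stop("validation error: S must be an orthonormal 3x3 eigenvector matrix")
  if (sigma_L <= 0 || sigma_T <= 0)
    stop("validation error: sigma_L and sigma_T must be > 0")
  S %*% diag(c(sigma_L, sigma_T, sigma_T)) %*% t(S)
}

#' Replace white-matter tensors with anisotropic ones
#'
#' For a transversely isotropic medium the tensor reduces to
#' `sigma_T I + (sigma_L - sigma_T) f f^T` with `f` the unit fiber direction,
#' which is what is stored per element.
#'
#' @param cond A `sucs_conductivity` from [assign_isotropic()].
#' @param mesh The mesh the field belongs to.
#' @param fibers Fiber field from [fiber_direction_field()].
#' @param sigma_L,sigma_T Eigenvalues (S/m).
#' @return Updated `sucs_conductivity`.
#' @export
apply_wm_anisotropy <- function(cond, mesh, fibers,
                                sigma_L = 1.1, sigma_T = 0.13) {
  if (sigma_L <= 0 || sigma_T <= 0)
    stop("validation error: sigma_L and sigma_T must be > 0")
  wm <- which(mesh$tissue == "wm")
  f <- fibers[wm, , drop = FALSE]
  if (anyNA(f)) stop("conductivity error: fiber field missing WM directions")
  dLT <- sigma_L - sigma_T
  cond[wm, "xx"] <- sigma_T + dLT * f[, 1]^2
  cond[wm, "yy"] <- sigma_T + dLT * f[, 2]^2
  cond[wm, "zz"] <- sigma_T + dLT * f[, 3]^2
  cond[wm, "xy"] <- dLT * f[, 1] * f[, 2]
  cond[wm, "xz"] <- dLT * f[, 1] * f[, 3]
  cond[wm, "yz"] <- dLT * f[, 2] * f[, 3]
  cond
}

#' Conductivity field for a campaign arm
#'
#' Convenience wrapper: isotropic assignment everywhere plus, in
#' `"anisotropic"` mode, transversely isotropic white matter (1.1/0.13 S/m)
#' along the geometry's fiber field. `"isotropic_control"` keeps WM at the
#' isotropic-control value from the table (0.126 S/m by default).
#'
#' @param mesh A `sucs_mesh`.
#' @param mode `"anisotropic"` or `"isotropic_control"`.
#' @param table Isotropic [conductivity_table()].
#' @param sigma_L,sigma_T WM eigenvalues for the anisotropic mode.
#' @return A `sucs_conductivity`.
#' @export
conductivity_field <- function(mesh,
                               mode = c("anisotropic", "isotropic_control"),
                               table = conductivity_table(),
                               sigma_L = 1.1, sigma_T = 0.13) {
  mode <- match.arg(mode)
  cond <- assign_isotropic(mesh, table)
  if (mode == "anisotropic") {
    fib <- fiber_direction_field(mesh$geom, mesh,
                                 if (!is.null(mesh$geom) && mesh$geom$kind == "asym")
                                   "surrogate_streamline" else "slab_perpendicular")
    cond <- apply_wm_anisotropy(cond, mesh, fib, sigma_L, sigma_T)
  }
  cond
}
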