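# Quasi-static volume conductor: first-order tetrahedral FEM for
# div(sigma grad phi) = 0 with anisotropic per-element tensors. Electrode
# contacts are floating equipotential bodies (all their nodes collapse onto
# one unknown) with a prescribed net injected current, matching a
# current-controlled stimulator; grounded boundary nodes are eliminated.
# Working units: coordinates mm (converted to m), sigma S/m, current mA,
# potential mV (S^-1 * mA = mV, so no explicit scaling is needed).

#' Specify a stimulus drive
#'
#' @param polarity `"anodal"` (+I on the active contact), `"cathodal"` (-I on
#'   the active contact) or `"bipolar"` (+I active, -I return, simultaneous).
#' @param amplitude Stimulus amplitude in mA (> 0).
#' @param grounding Grounding scheme: `"exterior_grounded_except_skull_top"`,
#'   `"bottom_grounded"`, `"distant_patch"`, or `NULL` to use the geometry's
#'   default.
#' @return Object of class `sucs_drive`.
#' @export
stimulus_drive <- function(polarity = c("anodal", "cathodal", "bipolar"),
                           amplitude = 1, grounding = NULL) {
  polarity <- match.arg(polarity)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("drive error: amplitude must be > 0")
  structure(list(polarity = polarity, amplitude = amplitude,
                 grounding = grounding), class = "sucs_drive")
}

# element stiffness triplets for the full mesh (K in siemens)
assemble_stiffness <- function(mesh, cond) {
  n <- mesh$nodes * 1e-3  # mm -> m
  e <- mesh$elems
  p1 <- n[e[, 1], , drop = FALSE]
  e1 <- n[e[, 2], , drop = FALSE] - p1
  e2 <- n[e[, 3], , drop = FALSE] - p1
  e3 <- n[e[, 4], , drop = FALSE] - p1
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cross(e2, e3); c31 <- cross(e3, e1); c12 <- cross(e1, e2)
  det <- rowSums(e1 * c23)
  vol <- abs(det) / 6
  g <- vector("list", 4)
  g[[2]] <- c23 / det; g[[3]] <- c31 / det; g[[4]] <- c12 / det
  g[[1]] <- -(g[[2]] + g[[3]] + g[[4]])
  sxx <- cond[, "xx"]; syy <- cond[, "yy"]; szz <- cond[, "zz"]
  sxy <- cond[, "xy"]; sxz <- cond[, "xz"]; syz <- cond[, "yz"]
  sigdot <- function(gi, gj) {
    sxx * gi[, 1] * gj[, 1] + syy * gi[, 2] * gj[, 2] + szz * gi[, 3] * gj[, 3] +
      sxy * (gi[, 1] * gj[, 2] + gi[, 2] * gj[, 1]) +
      sxz * (gi[, 1] * gj[, 3] + gi[, 3] * gj[, 1]) +
      syz * (gi[, 2] * gj[, 3] + gi[, 3] * gj[, 2])
  }
  m <- nrow(e)
  ti <- tj <- integer(16 * m)
  tx <- numeric(16 * m)
  idx <- 0L
  for (i in 1:4) for (j in 1:4) {
    rng <- idx + seq_len(m)
    ti[rng] <- e[, i]
    tj[rng] <- e[, j]
    tx[rng] <- vol * sigdot(g[[i]], g[[j]])
    idx <- idx + m
  }
  list(i = ti, j = tj, x = tx, n = nrow(mesh$nodes))
}

# unknown map: 0 = grounded; contacts share one unknown each
unknown_map <- function(mesh, scheme) {
  nnode <- nrow(mesh$nodes)
  map <- integer(nnode)
  gnd <- grounded_nodes(mesh, scheme)
  contact_ids <- sort(unique(mesh$elem_contact[mesh$elem_contact > 0]))
  contact_nodes <- lapply(contact_ids, function(cid) {
    unique(as.vector(mesh$elems[mesh$elem_contact == cid, , drop = FALSE]))
  })
  free <- setdiff(seq_len(nnode), c(gnd, unlist(contact_nodes)))
  map[free] <- seq_along(free)
  nu <- length(free)
  contact_unknown <- integer(length(contact_ids))
  for (k in seq_along(contact_ids)) {
    nu <- nu + 1L
    map[contact_nodes[[k]]] <- nu
    contact_unknown[k] <- nu
  }
  list(map = map, nu = nu, grounded = gnd,
       contact_ids = contact_ids, contact_unknown = contact_unknown)
}

# factorized reduced system; reusable across right-hand sides
fem_system <- function(mesh, cond, scheme) {
  trip <- assemble_stiffness(mesh, cond)
  um <- unknown_map(mesh, scheme)
  if (length(um$grounded) == 0)
    stop("configuration error: no ground in circuit (empty grounded node set)")
  ri <- um$map[trip$i]
  rj <- um$map[trip$j]
  keep <- ri > 0 & rj > 0
  K <- Matrix::sparseMatrix(i = ri[keep], j = rj[keep], x = trip$x[keep],
                            dims = c(um$nu, um$nu))
  K <- Matrix::forceSymmetric(K, uplo = "U")
  fac <- Matrix::Cholesky(K, LDL = FALSE, super = TRUE)
  list(K = K, fac = fac, um = um, mesh = mesh)
}

fem_solve_rhs <- function(sys, contact_currents) {
  um <- sys$um
  f <- numeric(um$nu)
  for (k in seq_along(contact_currents)) {
    cid <- as.integer(names(contact_currents)[k])
    pos <- match(cid, um$contact_ids)
    if (is.na(pos))
      stop(sprintf("configuration error: contact %d has no mesh elements", cid))
    f[um$contact_unknown[pos]] <- contact_currents[k]
  }
  phi_red <- as.numeric(Matrix::solve(sys$fac, f))
  res <- sqrt(sum((as.numeric(sys$K %*% phi_red) - f)^2))
  ref <- sqrt(sum(f^2))
  if (ref > 0 && res / ref > 1e-6)
    stop(sprintf("solver error: relative residual %.3e exceeds 1e-6", res / ref))
  phi <- numeric(nrow(sys$mesh$nodes))
  phi[um$map > 0] <- phi_red[um$map[um$map > 0]]
  phi
}

make_field <- function(mesh, phi, drive, injected) {
  structure(list(mesh = mesh, phi = phi, drive = drive, injected = injected),
            class = "sucs_potential")
}

#' Solve the extracellular potential for a stimulus drive
#'
#' Current-controlled contacts are modeled as floating equipotential bodies
#' with prescribed net current; the reduced symmetric positive-definite
#' system is solved by sparse Cholesky factorization (relative residual
#' checked against 1e-6).
#'
#' @param mesh A labeled `sucs_mesh` with electrode bodies.
#' @param cond A `sucs_conductivity`.
#' @param drive A [stimulus_drive()].
#' @return A `sucs_potential` with nodal potentials in mV.
#' @export
solve_potential <- function(mesh, cond, drive = stimulus_drive()) {
  scheme <- drive$grounding
  if (is.null(scheme)) scheme <- mesh$geom$grounding
  if (is.null(scheme)) scheme <- "all_exterior"
  roles <- mesh$contact_roles
  active <- which(roles == "active")
  ret <- which(roles == "return")
  if (!length(active)) stop("configuration error: mesh has no active contact")
  amp <- drive$amplitude
  cur <- switch(drive$polarity,
    anodal = setNames(amp, active[1]),
    cathodal = setNames(-amp, active[1]),
    bipolar = {
      if (!length(ret))
        stop("configuration error: bipolar drive requires a return contact")
      setNames(c(amp, -amp), c(active[1], ret[1]))
    })
  sys <- fem_system(mesh, cond, scheme)
  phi <- fem_solve_rhs(sys, cur)
  make_field(mesh, phi, drive, injected = sum(cur))
}

#' Unit-amplitude fields for all polarities with one factorization
#'
#' Exploits linearity: the stiffness matrix is factorized once; the cathodal
#' field is the negated anodal field and the bipolar field is the sum of the
#' active (+1 mA) and return (-1 mA) solves.
#'
#' @param mesh,cond As in [solve_potential()].
#' @param polarities Character subset of anodal/cathodal/bipolar.
#' @param grounding Optional scheme override.
#' @return Named list of `sucs_potential` objects (1 mA reference amplitude).
#' @export
solve_unit_fields <- function(mesh, cond,
                              polarities = c("anodal", "cathodal", "bipolar"),
                              grounding = NULL) {
  scheme <- if (is.null(grounding)) mesh$geom$grounding else grounding
  roles <- mesh$contact_roles
  active <- which(roles == "active")
  if (!length(active)) stop("configuration error: mesh has no active contact")
  sys <- fem_system(mesh, cond, scheme)
  phi_a <- fem_solve_rhs(sys, setNames(1, active[1]))
  out <- list()
  for (p in polarities) {
    if (p == "anodal") {
      out$anodal <- make_field(mesh, phi_a, stimulus_drive("anodal", 1, scheme), 1)
    } else if (p == "cathodal") {
      out$cathodal <- make_field(mesh, -phi_a,
                                 stimulus_drive("cathodal", 1, scheme), -1)
    } else if (p == "bipolar") {
      ret <- which(roles == "return")
      if (!length(ret))
        stop("configuration error: bipolar drive requires a return contact")
      phi_r <- fem_solve_rhs(sys, setNames(-1, ret[1]))
      out$bipolar <- make_field(mesh, phi_a + phi_r,
                                stimulus_drive("bipolar", 1, scheme), 0)
    } else stop(sprintf("drive error: unknown polarity '%s'", p))
  }
  out
}

#' Solve for an interior point source
#'
#' Injects the given current at a single mesh node; used for oracle
#' comparisons against closed-form point-source solutions.
#'
#' @param mesh A `sucs_mesh`.
#' @param cond A `sucs_conductivity`.
#' @param node Node index of the source.
#' @param current Injected current (mA).
#' @param grounding Grounding scheme (default: all exterior nodes).
#' @return A `sucs_potential`.
#' @export
solve_point_source <- function(mesh, cond, node, current = 1,
                               grounding = "all_exterior") {
  sys <- fem_system(mesh, cond, grounding)
  if (sys$um$map[node] == 0)
    stop("configuration error: source node is grounded")
  f <- numeric(sys$um$nu)
  f[sys$um$map[node]] <- current
  phi_red <- as.numeric(Matrix::solve(sys$fac, f))
  phi <- numeric(nrow(mesh$nodes))
  phi[sys$um$map > 0] <- phi_red[sys$um$map[sys$um$map > 0]]
  make_field(mesh, phi, list(polarity = "point_source", amplitude = current),
             injected = current)
}

#' Sample a potential field at arbitrary points
#'
#' Barycentric (piecewise-linear, FEM-consistent) interpolation within the
#' containing tetrahedron; deterministic; errors on points outside the domain.
#'
#' @param field A `sucs_potential`.
#' @param pts Matrix with columns x, y, z (mm).
#' @return Potentials in mV.
#' @export
sample_potential <- function(field, pts) {
  gw <- grid_interp_weights(field$mesh, pts)
  rowSums(matrix(field$phi[gw$nodes], ncol = 4) * gw$w)
}

#' Activating function along a fiber path
#'
#' Central second difference of uniformly spaced potential samples: for a
#' quadratic profile a*x^2 every interior value equals 2*a*spacing^2. The two
#' end samples have no defined value and are dropped.
#'
#' @param potentials Ordered potential samples (mV) along the path.
#' @param spacing Uniform sample spacing (mm).
#' @return Numeric vector of length `length(potentials) - 2`, with the
#'   spacing recorded as an attribute.
#' @export
activating_function <- function(potentials, spacing) {
  n <- length(potentials)
  if (n < 3) stop("input error: need at least 3 samples")
  if (!is.finite(spacing) || spacing <= 0)
    stop("input error: spacing must be positive")
  af <- potentials[3:n] - 2 * potentials[2:(n - 1)] + potentials[1:(n - 2)]
  attr(af, "spacing") <- spacing
  af
}

#' Current balance of a solved field
#'
#' Reaction currents at the grounded nodes must return the injected current.
#'
#' @param field A `sucs_potential`.
#' @param cond The conductivity used for the solve.
#' @param grounding The grounding scheme used.
#' @return List with `injected` and `ground_return` (mA).
#' @export
current_balance <- function(field, cond, grounding = NULL) {
  mesh <- field$mesh
  scheme <- grounding
  if (is.null(scheme)) scheme <- field$drive$grounding
  if (is.null(scheme)) scheme <- mesh$geom$grounding
  if (is.null(scheme)) scheme <- "all_exterior"
  trip <- assemble_stiffness(mesh, cond)
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(trip$n, trip$n))
  r <- as.numeric(K %*% field$phi)
  gnd <- grounded_nodes(mesh, scheme)
  list(injected = field$injected, ground_return = sum(r[gnd]))
}
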