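# Volume-conductor solver: point-source oracle, linearity, superposition,
# conservation, activating function.

test_that("point source in a grounded homogeneous ball matches the closed form", {
  mesh <- fx_ball()
  cond <- assign_isotropic(mesh, conductivity_table(gm = 0.276))
  # source at the node nearest the center
  src <- which.min(rowSums(mesh$nodes^2))
  field <- solve_point_source(mesh, cond, src, current = 1)
  # The grounded staircase boundary adds a constant (image) term whose
  # magnitude is only known to O(h); comparing shell-mean potential
  # differences cancels it exactly and tests the 1/(4 pi sigma r) law.
  r <- sqrt(rowSums(mesh$nodes^2))
  shell <- function(r0) mean(field$phi[abs(r - r0) < 0.7])
  k <- 1 / (4 * pi * 0.276e-3)  # mV * mm per mA
  r0 <- 5  # > 3 element diameters from the source
  for (rr in 6:12) {
    rel <- abs((shell(rr) - shell(r0)) - k * (1 / rr - 1 / r0)) /
      abs(k * (1 / rr - 1 / r0))
    expect_lt(rel, 0.05)
  }
})

test_that("solution is linear in the drive and superposes", {
  mesh <- fx_ball()
  cond <- assign_isotropic(mesh)
  src <- which.min(rowSums(mesh$nodes^2))
  f1 <- solve_point_source(mesh, cond, src, current = 1)
  f2 <- solve_point_source(mesh, cond, src, current = 2)
  expect_equal(f2$phi, 2 * f1$phi, tolerance = 1e-9)
})

test_that("gyral solve: polarity flip, superposition, ground, conservation", {
  g <- fx_slab_elec()
  mesh <- generate_mesh(g, 2)
  cond <- conductivity_field(mesh, "anisotropic")
  flds <- solve_unit_fields(mesh, cond, c("anodal", "cathodal", "bipolar"))
  # cathodal is exactly the negated anodal field
  expect_equal(flds$cathodal$phi, -flds$anodal$phi, tolerance = 1e-12)
  # bipolar equals the sum of the anodal and return-cathodal solves
  f_bi <- solve_potential(mesh, cond, stimulus_drive("bipolar", 1))
  expect_equal(f_bi$phi, flds$bipolar$phi, tolerance = 1e-8)
  # grounded boundary nodes are at 0 mV
  gnd <- cortistim:::grounded_nodes(mesh, "exterior_grounded_except_skull_top")
  expect_equal(max(abs(flds$anodal$phi[gnd])), 0)
  # net reaction current at ground returns the injected current within 1%
  bal <- current_balance(flds$anodal, cond)
  expect_equal(bal$ground_return, -bal$injected, tolerance = 0.01)
  # mirror symmetry about the gyral midplane with the centered electrode:
  # exact for the continuum problem; the fixed-handedness tetrahedral split
  # leaves a discretization-level asymmetry
  cs <- g$cs
  zs <- cortistim:::electrode_by_role(g, "active")$z
  set.seed(5)
  pts <- cbind(runif(30, 1, 20), runif(30, 3, cs$Hb - 0.5), zs)
  pa <- sample_potential(flds$anodal, pts)
  pb <- sample_potential(flds$anodal, cbind(-pts[, 1], pts[, 2:3]))
  expect_lt(max(abs(pa - pb) / pmax(abs(pa), 0.5)), 0.10)  # 2 mm test mesh
})

test_that("drive validation and grounding configuration errors", {
  g <- fx_slab_elec()
  mesh <- fx_mesh_coarse()
  cond <- assign_isotropic(mesh)
  expect_error(stimulus_drive("anodal", amplitude = -1), "amplitude")
  expect_error(solve_potential(mesh, cond,
                               stimulus_drive("anodal", 1, "no_such_scheme")),
               "grounding scheme")
  # monopolar with an empty ground set
  m1 <- place_electrodes(build_slab_geometry(), default_electrodes(g)[1])
  mesh1 <- generate_mesh(m1, 2.5)
  cond1 <- assign_isotropic(mesh1)
  expect_error(solve_potential(mesh1, cond1,
                               stimulus_drive("bipolar", 1)),
               "return contact")
})

test_that("activating function is the central second difference", {
  x <- seq(0, 10, by = 0.5)
  # affine profile: identically zero
  expect_equal(as.numeric(activating_function(3 - 2 * x, 0.5)),
               rep(0, length(x) - 2), tolerance = 1e-12)
  # quadratic a x^2: constant 2 a h^2
  a <- 1.7
  af <- activating_function(a * x^2, 0.5)
  expect_equal(as.numeric(af), rep(2 * a * 0.25, length(x) - 2),
               tolerance = 1e-12)
  # polarity flip negates the values
  prof <- sin(x)
  expect_equal(as.numeric(activating_function(-prof, 0.5)),
               -as.numeric(activating_function(prof, 0.5)), tolerance = 1e-12)
  expect_error(activating_function(c(1, 2), 0.5), "at least 3")
  expect_error(activating_function(1:5, -1), "spacing")
})

test_that("potential at fixed probes converges under mesh refinement", {
  g <- fx_slab_elec()
  cond_of <- function(mesh) conductivity_field(mesh, "anisotropic")
  zs <- cortistim:::electrode_by_role(g, "active")$z
  probes <- cbind(c(0, 3, 5), g$cs$Hb - c(2.9, 1.7, 8), zs)
  phi <- lapply(c(2.0, 1.4), function(res) {
    mesh <- generate_mesh(g, res)
    f <- solve_unit_fields(mesh, cond_of(mesh), "anodal")$anodal
    sample_potential(f, probes)
  })
  expect_lt(max(abs(phi[[2]] - phi[[1]]) / abs(phi[[2]])), 0.08)
})
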