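# Slab and surrogate geometry: calibration, symmetry, electrodes, regions.

test_that("slab cross-section reproduces the printed gyral width and path calibration", {
  g <- fx_slab()
  expect_equal(gyral_width(g), 8.5)
  # path length equals the calibrated crown-to-crown length at every soma
  # depth (convex/concave offsets cancel)
  for (depth in c(0, g$cs$gm - 1.8, g$cs$gm - 0.6)) {
    pp <- cortical_path(g, depth, n = 4001)
    expect_equal(max(pp$sw), g$cs$L, tolerance = 1e-4)
  }
})

test_that("degenerate and invalid slab parameters are refused", {
  expect_error(slab_params(gm_thickness = -1), "positive")
  expect_error(build_slab_geometry(slab_params(sulcal_depth = 0)),
               "geometry error")
  expect_error(build_slab_geometry(slab_params(sulcal_depth = 2)),
               "degenerate")
  expect_error(build_slab_geometry("not params"), "parameter error")
})

test_that("slab tissue classification is mirror-symmetric and layered outside-in", {
  g <- fx_slab()
  cs <- g$cs
  set.seed(42)
  x <- runif(400, 0, cs$x_max)
  y <- runif(400, 0.2, cs$y_top - 1e-6)
  expect_identical(tissue_at(g, cbind(x, y)), tissue_at(g, cbind(-x, y)))
  # vertical transect through the crown center crosses the layers in order
  yy <- seq(cs$y_top - 0.01, 0.01, length.out = 400)
  lab <- tissue_at(g, cbind(0, yy))
  expect_equal(rle(lab)$values, c("scalp", "skull", "dura", "csf", "gm", "wm"))
})

test_that("asymmetric surrogate at factor 1 reproduces the slab exactly", {
  g1 <- build_asymmetric_geometry(asym_params(asymmetry_factor = 1))
  g0 <- fx_slab()
  for (depth in c(0.5, 1.7, 2.9)) {
    p0 <- cortical_path(g0, depth, n = 801)
    p1 <- cortical_path(g1, depth, n = 801)
    expect_lt(max(abs(p0$x - p1$x)), 1e-9)
    expect_lt(max(abs(p0$y - p1$y)), 1e-9)
  }
})

test_that("asymmetry factor sets the bank arc-length ratio", {
  for (f in c(1.15, 1.3)) {
    ga <- build_asymmetric_geometry(asym_params(asymmetry_factor = f))
    bl <- bank_arc_lengths(ga)
    expect_equal(unname(bl["central"] / bl["precentral"]), f, tolerance = 0.01)
  }
})

test_that("asymmetry warp is invertible and rejects invalid parameters", {
  ga <- build_asymmetric_geometry(asym_params(asymmetry_factor = 1.3,
                                              bank_curvature = 0.2))
  set.seed(7)
  x <- runif(300, -ga$cs$x_max, ga$cs$x_max)
  y <- runif(300, 0, ga$cs$Hb)
  w <- cortistim:::warp_xy(ga, x, y)
  u <- cortistim:::unwarp_xy(ga, w[, 1], w[, 2])
  expect_lt(max(abs(u[, 1] - x)), 1e-8)
  expect_lt(max(abs(u[, 2] - y)), 1e-8)
  expect_error(asym_params(asymmetry_factor = 0.8), "asymmetry_factor")
  expect_error(asym_params(bank_curvature = -0.1), "geometry error")
})

test_that("electrode placement enforces separation, crown fit and overlap", {
  g <- fx_slab()
  g2 <- place_electrodes(g, default_electrodes(g))
  expect_equal(electrode_separation(g2), 13, tolerance = 0.01)
  # monopolar: a single active contact is fine
  g3 <- place_electrodes(g, default_electrodes(g)[1])
  expect_null(cortistim:::electrode_by_role(g3, "return"))
  # overlap: 11.5 mm contacts 5 mm apart
  big <- list(electrode_spec("active", 0, 20, diameter = 11.5,
                             substrate_extent = 11.5),
              electrode_spec("return", 0, 25, diameter = 11.5,
                             substrate_extent = 11.5))
  expect_error(place_electrodes(g, big), "overlap")
  # off-crown placement
  off <- electrode_spec("active", x = g$cs$xf, z = 25)
  expect_error(place_electrodes(g, off), "crown")
})

test_that("region labels follow the crown-to-sulcus-to-opposite-crown bands", {
  g <- fx_slab_elec()
  map <- label_regions(g)
  cs <- g$cs
  # directly beneath the active electrode center
  expect_identical(region_of(map, cbind(0, cs$Hb - 1)), "C")
  # deepest point of the sulcus
  expect_identical(region_of(map, cbind(cs$xf, cs$Hb - cs$d + 0.3)), "BS")
  # opposite crown, and the mirror of a crown point stays in its band
  oc <- cbind(cs$xf + cs$a + cs$r + 5, cs$Hb - 1)
  expect_identical(region_of(map, oc), "OC")
  expect_identical(region_of(map, cbind(-oc[1], oc[2])), "OC")
  expect_error(label_regions(fx_slab()), "active electrode")
})

test_that("region labels are invariant along the extrusion axis", {
  g <- fx_slab_elec()
  set <- distribute_neurons(g, "L5", planes = c(10, 25, 40))
  per <- split(set$region, set$plane)
  expect_identical(per[[1]], per[[2]])
  expect_identical(per[[2]], per[[3]])
})
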