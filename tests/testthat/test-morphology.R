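# Morphology templates, lengthening, bending, SWC IO, discretization.

test_that("neurites are lengthened by the human-adaptation factor", {
  for (layer in c("L5", "L3")) {
    tp <- morphology_params(layer)
    m <- build_morphology(layer)
    lens <- morphology_lengths(m)
    expect_equal(unname(lens["apical"]),
                 1.6 * (tp$apical_length + 2 * tp$oblique_length +
                        2 * tp$tuft_length) * 1e-3, tolerance = 1e-9)
    expect_equal(unname(lens["basal"]),
                 1.6 * tp$n_basal * tp$basal_length * 1e-3, tolerance = 1e-9)
    ax <- sum(lens[c("ais", "internode", "node", "terminal")])
    expect_equal(unname(ax), 1.6 * tp$axon_length * 1e-3, tolerance = 1e-9)
    # no lengthening at factor 1
    m0 <- build_morphology(layer, lengthen = 1)
    expect_equal(unname(morphology_lengths(m0)["apical"]) * 1.6,
                 unname(lens["apical"]), tolerance = 1e-9)
  }
})

test_that("L3 axons stay in GM and L5 axons cross into WM when placed", {
  g <- fx_slab()
  for (layer in c("L5", "L3")) {
    set <- distribute_neurons(g, layer, planes = 25)
    for (i in c(1, 25, 40)) {
      m <- instance_morphology(set, i)
      ax <- cortistim:::axon_chain(m)
      tips <- do.call(rbind, lapply(m$sections[ax], function(s)
        s$points[nrow(s$points), , drop = FALSE]))
      sd <- gmwm_signed_distance(g, tips)
      if (layer == "L3") expect_true(all(sd < 0)) else expect_gt(max(sd), 0)
    }
  }
})

test_that("axon bending preserves arc length and honors explicit angles", {
  g <- fx_slab()
  set <- distribute_neurons(g, "L5", planes = 25)
  i_bank <- which(set$region == "B")[8]
  m0 <- build_morphology("L5")
  m0 <- place_morphology(m0, c(set$x[i_bank], set$y[i_bank], set$z[i_bank]),
                         c(set$ax[i_bank], set$ay[i_bank], 0),
                         c(set$tx[i_bank], set$ty[i_bank], 0))
  len0 <- sum(morphology_lengths(m0))
  # infinite radius: identity
  expect_identical(bend_axon_at_boundary(m0, g, radius = Inf), m0)
  mb <- bend_axon_at_boundary(m0, g, radius = 0.5)
  expect_false(is.null(mb$bend))
  expect_equal(sum(morphology_lengths(mb)), len0, tolerance = 0.01 * len0)
  # 90-degree bend: post-arc tangent orthogonal to the pre-boundary tangent
  m90 <- bend_axon_at_boundary(m0, g, radius = 0.3, angle = 90)
  ax <- cortistim:::axon_chain(m90)
  last <- m90$sections[[ax[length(ax)]]]$points
  tang <- last[nrow(last), ] - last[nrow(last) - 1, ]
  tang <- tang / sqrt(sum(tang^2))
  pre <- c(-set$ax[i_bank], -set$ay[i_bank], 0)
  ang <- acos(abs(sum(tang * pre))) * 180 / pi
  expect_gt(ang, 89)
  # a morphology that never reaches the boundary: warning, no-op
  set3 <- distribute_neurons(g, "L3", planes = 25)
  i_c <- which(set3$region == "C")[1]
  m3l <- build_morphology("L3")
  m3l <- place_morphology(m3l, c(set3$x[i_c], set3$y[i_c], set3$z[i_c]),
                          c(0, 1, 0), c(1, 0, 0))
  expect_warning(bend_axon_at_boundary(m3l, g, radius = 0.5), "no bend")
})

test_that("discretization respects maximum compartment lengths", {
  # 100 um straight section, max 25 um -> exactly 4 compartments
  sec <- cortistim:::new_section(1L, "axon", 0L, 0,
                                 rbind(c(0, 0, 0), c(0.1, 0, 0)), 2)
  m <- structure(list(layer = "fixture", sections = list(sec), placed = TRUE,
                      bend = NULL), class = "sucs_morphology")
  cc <- discretize(m, 25)
  expect_equal(nrow(cc), 4)
  expect_equal(cc$len_um, rep(25, 4))
  # centers lie on the section line
  expect_equal(cc$y, rep(0, 4))
  expect_equal(cc$x, c(0.0125, 0.0375, 0.0625, 0.0875))
  # halving the max length at least doubles long-section counts
  m5 <- build_morphology("L5")
  expect_gte(nrow(discretize(m5, 25)), 2 * nrow(discretize(m5, 50)) * 0.9)
  expect_error(discretize(m5, 0), "parameter error")
  # parent linkage mirrors the tree: every non-root parent precedes its child
  cc5 <- discretize(m5, 50)
  expect_true(all(cc5$parent < seq_len(nrow(cc5))))
  expect_equal(sum(cc5$parent == 0), 1)
  expect_equal(sum(cc5$terminal), 1)
})

test_that("SWC round trip preserves nodes, types and coordinates", {
  m <- build_morphology("L5")
  f <- tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  f2 <- tempfile(fileext = ".swc")
  write_swc(m2, f2)
  t1 <- cortistim:::as_swc_table(m)
  t2 <- cortistim:::as_swc_table(m2)
  expect_equal(nrow(t1), nrow(t2))
  # same multiset of (type, x, y, z, radius); ids may be renumbered
  key <- function(t) {
    k <- sprintf("%d|%.6f|%.6f|%.6f|%.6f", t$type, t$x, t$y, t$z, t$radius)
    sort(k)
  }
  expect_identical(key(t1), key(t2))
  unlink(c(f, f2))
})

test_that("SWC reader rejects malformed files and accepts a point soma", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 2", "2 2 0 -10 0 1 1"), f)  # parent cycle 1<->2
  expect_error(read_swc(f), "cycle")
  writeLines(c("1 9 0 0 0 5 -1"), f)
  expect_error(read_swc(f), "type code")
  writeLines(c("1 1 0 0 0 5 -1 9"), f)
  expect_error(read_swc(f), "7 columns")
  writeLines("1 1 0 0 0 5 -1", f)
  m <- read_swc(f)
  cc <- discretize(m, 25)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$kind, "soma")
  expect_equal(cc$len_um, 10, tolerance = 1e-9)  # 2 * radius
  unlink(f)
})
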