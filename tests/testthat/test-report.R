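# Reporting: region summaries, excited fractions, sensitivity, maps,
# initiation tables (on constructed record fixtures).

rec_fixture <- function() {
  r <- fx_records()
  # anodal L5: C lowest (7), lip 17, bank 23 (printed slab pattern)
  set_thr <- function(r, layer, pol, region, thr) {
    i <- r$layer == layer & r$polarity == pol & r$region == region
    r$threshold[i] <- thr
    r$excitable[i] <- !is.na(thr)
    r
  }
  r <- set_thr(r, "L5", "anodal", "C", 7)
  r <- set_thr(r, "L5", "anodal", "L", 17)
  r <- set_thr(r, "L5", "anodal", "B", 23)
  r <- set_thr(r, "L5", "cathodal", "C", 21)
  r <- set_thr(r, "L5", "cathodal", "B", 14)
  r <- set_thr(r, "L3", "anodal", "C", 3)
  r <- set_thr(r, "L3", "cathodal", "C", 12)
  r$init_category[r$excitable & r$layer == "L3"] <- "axon_terminal"
  r$init_category[r$excitable & r$layer == "L5"] <- "gmwm_boundary"
  r
}

test_that("region summary reports minima, argmin regions and 20 mA counts", {
  r <- rec_fixture()
  rs <- summarize_regions(r)
  g <- function(layer, pol, region)
    rs$min_threshold[rs$layer == layer & rs$polarity == pol &
                     rs$region == region]
  expect_equal(g("L5", "anodal", "C"), 7)
  expect_equal(g("L5", "anodal", "L"), 17)
  expect_equal(g("L5", "anodal", "B"), 23)
  expect_true(is.na(g("L5", "anodal", "BS")))
  ov <- attr(rs, "overall_min")
  expect_equal(ov$min_threshold[ov$layer == "L5" & ov$polarity == "anodal"], 7)
  expect_identical(ov$region[ov$layer == "L5" & ov$polarity == "anodal"], "C")
  # 20 mA marker counts only thresholds at or under the cap
  expect_equal(rs$n_under_cap[rs$layer == "L5" & rs$polarity == "anodal" &
                              rs$region == "L"], 1)
  expect_equal(rs$n_under_cap[rs$layer == "L5" & rs$polarity == "anodal" &
                              rs$region == "B"], 0)
  # single record group
  one <- r[r$layer == "L5" & r$polarity == "anodal" & r$region == "C", ]
  rs1 <- summarize_regions(one)
  expect_equal(rs1$min_threshold, 7)
})

test_that("excited fractions are monotone CDFs with correct counting", {
  r <- data.frame(layer = "L5", polarity = "anodal",
                  threshold = c(5, 10, NA), neuron = 1:3)
  ef <- excited_fraction(r, amplitudes = c(0, 5, 10, 100))
  expect_equal(ef$fraction, c(0, 1 / 3, 2 / 3, 2 / 3))
  # monotone and bounded by the excitable proportion
  expect_true(all(diff(ef$fraction) >= 0))
  expect_lte(max(ef$fraction), mean(!is.na(r$threshold)))
  # crossing detection on a constructed pair of curves
  r2 <- rbind(
    data.frame(layer = "L5", polarity = "anodal",
               threshold = c(5, 6, NA, NA), neuron = 1:4),
    data.frame(layer = "L5", polarity = "cathodal",
               threshold = c(20, 21, 22, 23), neuron = 1:4))
  # fractions first touch at 21 mA (anodal 0.5, cathodal reaches 0.5)
  cr <- attr(excited_fraction(r2, amplitudes = 0:40), "crossings")
  expect_equal(cr$amplitude, 21)
})

test_that("sensitivity comparison computes percent differences over co-excitable", {
  r <- rec_fixture()
  expect_equal(compare_sensitivity(r, r)$mean_pct, 0)
  expect_equal(compare_sensitivity(r, r)$max_pct, 0)
  r2 <- r
  i <- which(r2$layer == "L5" & r2$polarity == "anodal" & r2$region == "C")
  r2$threshold[i] <- 7.7  # 10% on a baseline of 7
  cmp <- compare_sensitivity(r, r2)
  expect_equal(cmp$max_pct, 10, tolerance = 1e-9)
  expect_equal(cmp$n_discordant, 0)
  # discordant excitability is counted, not averaged
  r3 <- r
  r3$threshold[i] <- NA
  cmp3 <- compare_sensitivity(r, r3)
  expect_equal(cmp3$n_discordant, 1)
  # empty intersection errors
  r4 <- r; r4$neuron <- paste0("x", r4$neuron)
  expect_error(compare_sensitivity(r, r4), "comparison error")
  # symmetric denominator option
  cmp_s <- compare_sensitivity(r, r2, symmetric = TRUE)
  expect_equal(cmp_s$max_pct, 0.7 / 7.35 * 100, tolerance = 1e-9)
})

test_that("spatial map flags the sub-20 mA contour and computes asymmetry", {
  r <- rec_fixture()
  map <- spatial_extent_map(r)
  expect_identical(map$under_cap, !is.na(map$threshold) & map$threshold <= 20)
  # without side information, index falls back to B vs OB (OB empty -> NA)
  ai <- attr(map, "asymmetry_index")
  expect_true(all(is.na(ai$index[ai$polarity == "anodal"])))
  # with sides: slab-like symmetric records give index 1
  r2 <- rbind(r, transform(r, side = -1, x = -x))
  r2 <- r2[r2$region == "B", ]
  map2 <- spatial_extent_map(r2)
  ai2 <- attr(map2, "asymmetry_index")
  i5 <- ai2$layer == "L5" & ai2$polarity == "anodal"
  expect_equal(ai2$index[i5], 1)
  # all-not-excitable records: empty contour
  r0 <- fx_records()
  expect_equal(nrow(attr(spatial_extent_map(r0), "contour")), 0)
})

test_that("initiation summary normalizes frequencies and flags dominants", {
  r <- rec_fixture()
  tab <- initiation_summary(r)
  l3 <- tab[tab$layer == "L3" & tab$polarity == "anodal", ]
  expect_equal(l3$init_category[l3$dominant], "axon_terminal")
  expect_equal(sum(l3$frequency), 1)
  l5 <- tab[tab$layer == "L5" & tab$polarity == "cathodal", ]
  expect_equal(l5$init_category[l5$dominant], "gmwm_boundary")
  # empty fired set -> empty table
  expect_equal(nrow(initiation_summary(fx_records())), 0)
})

test_that("placement and trace CSV exports round numbers through files", {
  g <- fx_slab()
  set <- distribute_neurons(g, "L5", planes = 25)
  f <- tempfile(fileext = ".csv")
  write_placement_csv(set, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 57)
  expect_true(all(c("qw", "qx", "qy", "qz") %in% names(tab)))
  # quaternions are unit and reproduce the frame for a crown soma
  expect_equal(tab$qw^2 + tab$qx^2 + tab$qy^2 + tab$qz^2, rep(1, 57),
               tolerance = 1e-9)
  unlink(f)
  comps <- discretize(build_morphology("L3"), 100)
  tr <- simulate_cable(comps, passive_membrane(cm = 0.05),
                       rep(0, nrow(comps)), amplitude = 0, duration_ms = 0.5)
  f2 <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f2)
  tab2 <- read.csv(f2)
  expect_equal(nrow(tab2), length(tr$t))
  expect_equal(ncol(tab2), nrow(comps) + 1)
  unlink(f2)
})

test_that("spatial map plotting runs without error", {
  r <- fx_records()
  r$threshold[1:3] <- c(7, 15, 30)
  map <- spatial_extent_map(r)
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(map))
  grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
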