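# Cable integrator: resting stability, passive oracle, AP detection and
# initiation classification, temporal convergence.

straight_cable <- function(L_um, d_um = 2, kind = "axon") {
  sec <- cortistim:::new_section(1L, kind, 0L, 0,
                                 rbind(c(0, 0, 0), c(L_um * 1e-3, 0, 0)), d_um)
  structure(list(layer = "fixture", sections = list(sec), placed = TRUE,
                 bend = NULL), class = "sucs_morphology")
}

test_that("zero-input simulations stay at rest for all section kinds", {
  mem <- membrane_parameters()
  for (layer in c("L5", "L3")) {
    comps <- discretize(build_morphology(layer), 50)
    tr <- simulate_cable(comps, mem, rep(0, nrow(comps)), amplitude = 0,
                         duration_ms = 5)
    expect_lt(max(abs(tr$v - mem$global$v_init)), 0.5)
  }
})

test_that("steady-state passive polarization matches the analytic cable solution", {
  # sealed-end cable of length L in a uniform axial field E:
  # Vm(x) = E * lambda * sinh(x/lambda) / cosh(L/(2 lambda))
  Rm <- 30000; Ra <- 150; d_um <- 2
  pm <- passive_membrane(g_pas = 1 / Rm, cm = 0.01)  # short tau -> steady state
  lambda_um <- sqrt(Rm * d_um * 1e-4 / (4 * Ra)) * 1e4
  for (L_um in c(3000, 5000)) {
    cc <- discretize(straight_cable(L_um), 25)
    E <- 1  # mV / mm
    ve <- -E * cc$x
    tr <- simulate_cable(cc, pm, ve, pulse = pulse_spec(width_us = 4000,
                                                       onset_ms = 0.05),
                         amplitude = 1, duration_ms = 3.5, coarse_factor = 1)
    vend <- tr$v[nrow(tr$v), ncol(tr$v)] - pm$global$v_init
    xe <- (cc$x[nrow(cc)] - mean(cc$x)) * 1e3
    pred <- E * 1e-3 * lambda_um * sinh(xe / lambda_um) /
      cosh(L_um / 2 / lambda_um)
    expect_lt(abs(vend - pred) / abs(pred), 0.03)
    # interior profile too
    mid <- which.min(abs(cc$x - mean(cc$x)))
    expect_lt(abs(tr$v[nrow(tr$v), mid] - pm$global$v_init), 0.05 * abs(pred))
  }
})

test_that("suprathreshold forcing evokes an action potential; zero does not", {
  mem <- membrane_parameters()
  comps <- discretize(build_morphology("L5"), 50)
  # steep gradient along the axon direction
  ve <- 100 * comps$y
  tr0 <- simulate_cable(comps, mem, ve, amplitude = 0)
  expect_false(detect_ap(tr0)$fired)
  amp <- 2^(0:8)
  fired <- vapply(amp, function(a) {
    detect_ap(simulate_cable(comps, mem, ve, amplitude = a))$fired
  }, TRUE)
  expect_true(any(fired))
  # all-or-none: firing is monotone over the sampled amplitude grid
  expect_true(all(diff(fired) >= 0))
})

test_that("detector finds the earliest crossing and is deterministic", {
  t <- seq(0, 1, by = 0.01)
  flat <- matrix(-70, length(t), 3)
  tr <- structure(list(v = flat, t = t), class = "sucs_trace")
  expect_false(detect_ap(tr)$fired)
  v <- flat
  v[t >= 0.40, 2] <- 20
  v[t >= 0.45, 3] <- 20
  ev <- detect_ap(structure(list(v = v, t = t), class = "sucs_trace"))
  expect_true(ev$fired)
  expect_equal(ev$init_comp, 2L)
  expect_equal(ev$init_time, 0.40)
  # tie: equal first-crossing times resolve to the lower compartment index
  v[t >= 0.40, 3] <- 20
  ev2 <- detect_ap(structure(list(v = v, t = t), class = "sucs_trace"))
  expect_equal(ev2$init_comp, 2L)
})

test_that("initiation classification follows the zone rules", {
  g <- fx_slab()
  set <- distribute_neurons(g, "L3", planes = 25)
  i <- which(set$region == "C")[1]
  comps <- discretize(instance_morphology(set, i), 50)
  fake <- function(comp) {
    structure(list(fired = TRUE, times = NA, init_comp = comp,
                   init_time = 0.4), class = "sucs_ap_event")
  }
  # last axonal compartment of an L3 cell -> axon terminal
  expect_identical(classify_initiation(fake(which(comps$terminal)), comps, g),
                   "axon_terminal")
  # initial-segment compartment -> initial segment
  expect_identical(classify_initiation(fake(which(comps$kind == "ais")[1]),
                                       comps, g), "initial_segment")
  # soma -> soma; apical dendrite -> other
  expect_identical(classify_initiation(fake(which(comps$kind == "soma")[1]),
                                       comps, g), "soma")
  expect_identical(classify_initiation(fake(which(comps$kind == "apical")[1]),
                                       comps, g), "other")
  # axonal compartment within tolerance of the GM/WM surface -> boundary
  dl <- gmwm_signed_distance(g, cbind(comps$x, comps$y))
  cand <- which(comps$kind %in% c("internode", "node") & abs(dl) <= 0.3 &
                !comps$terminal)
  if (length(cand))
    expect_identical(classify_initiation(fake(cand[1]), comps, g),
                     "gmwm_boundary")
  # bent-arc compartments of an L5 bank cell -> axon bend
  set5 <- distribute_neurons(g, "L5", planes = 25)
  ib <- which(set5$region == "B")[8]
  comps5 <- discretize(instance_morphology(set5, ib), 50)
  bend <- attr(comps5, "bend")
  inarc <- which(!is.na(comps5$axon_arc) &
                 comps5$axon_arc >= bend$s_cross &
                 comps5$axon_arc <= bend$s_cross + bend$arc_len &
                 abs(gmwm_signed_distance(g, cbind(comps5$x, comps5$y))) > 0.3)
  if (length(inarc))
    expect_identical(classify_initiation(fake(inarc[1]), comps5, g),
                     "axon_bend")
  expect_error(classify_initiation(structure(list(fired = FALSE),
                                             class = "sucs_ap_event"),
                                   comps, g), "did not fire")
})

test_that("polarity flip negates the extracellular forcing seen by the cable", {
  comps <- discretize(build_morphology("L3"), 50)
  pm <- passive_membrane(cm = 0.05)
  ve <- 10 * comps$y + 3 * comps$x
  tr_p <- simulate_cable(comps, pm, ve, amplitude = 2)
  tr_n <- simulate_cable(comps, pm, -ve, amplitude = 2)
  dev_p <- tr_p$v - pm$global$v_init
  dev_n <- tr_n$v - pm$global$v_init
  expect_equal(dev_p, -dev_n, tolerance = 1e-9)
})

test_that("halving dt changes subthreshold responses by less than 2 percent", {
  mem <- membrane_parameters()
  comps <- discretize(build_morphology("L3"), 50)
  ve <- 50 * comps$y
  v1 <- simulate_cable(comps, mem, ve, amplitude = 3, dt_us = 5,
                       coarse_factor = 1)
  v2 <- simulate_cable(comps, mem, ve, amplitude = 3, dt_us = 2.5,
                       coarse_factor = 1)
  peak1 <- max(v1$v) - mem$global$v_init
  peak2 <- max(v2$v) - mem$global$v_init
  expect_lt(abs(peak1 - peak2) / abs(peak2), 0.02)
})

test_that("input validation: mismatched lengths and bad dt", {
  comps <- discretize(build_morphology("L3"), 50)
  mem <- membrane_parameters()
  expect_error(simulate_cable(comps, mem, c(0, 1), amplitude = 1),
               "input error")
  expect_error(simulate_cable(comps, mem, rep(0, nrow(comps)), dt_us = 0),
               "dt")
})
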