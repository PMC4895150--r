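# Cable simulation under extracellular forcing, action-potential detection
# and initiation-site classification.

#' Specify the stimulus pulse
#'
#' The stimulation protocol is a monophasic rectangular pulse (100 us by
#' default); the amplitude is supplied separately as a multiplier of a
#' unit-amplitude (1 mA) potential field.
#'
#' @param width_us Pulse width in microseconds.
#' @param onset_ms Pulse onset time in ms.
#' @return Object of class `sucs_pulse`.
#' @export
pulse_spec <- function(width_us = 100, onset_ms = 0.1) {
  if (!is.finite(width_us) || width_us <= 0)
    stop("pulse error: width must be > 0")
  structure(list(shape = "monophasic_rectangular",
                 width_us = width_us, onset_ms = onset_ms),
            class = "sucs_pulse")
}

#' Simulate the compartmental cable equation
#'
#' Integrates the multi-compartment cable equations with active membrane
#' dynamics; the extracellular node of every compartment is driven by
#' `amplitude * phi_unit` during the pulse window and zero otherwise
#' (one-way coupling; no ephaptic feedback). Voltage uses backward Euler on
#' the tree (unconditionally stable); gating uses exponential Euler.
#'
#' @param comps A `sucs_compartments` from [discretize()].
#' @param mem A `sucs_membrane`.
#' @param phi_unit Extracellular potential (mV) at each compartment center
#'   for the unit-amplitude (1 mA) field solve.
#' @param pulse A [pulse_spec()].
#' @param amplitude Stimulus amplitude (mA); multiplies `phi_unit`.
#' @param dt_us Time step (microseconds) through the pulse window.
#' @param duration_ms Simulated duration (ms).
#' @param coarse_factor After the pulse (plus a 0.4 ms margin) the step is
#'   enlarged to `coarse_factor * dt_us` (backward Euler remains stable);
#'   set to 1 for a uniform step.
#' @param record_every Record every k-th step.
#' @return Object of class `sucs_trace`: list with matrix `v` (time x
#'   compartment, mV) and times `t` (ms).
#' @export
simulate_cable <- function(comps, mem, phi_unit, pulse = pulse_spec(),
                           amplitude = 0, dt_us = 5, duration_ms = 5,
                           coarse_factor = 5, record_every = 1L) {
  n <- nrow(comps)
  if (length(phi_unit) != n)
    stop(sprintf("input error: %d compartments but %d potential samples",
                 n, length(phi_unit)))
  if (!is.finite(dt_us) || dt_us <= 0) stop("input error: dt must be > 0")
  arr <- membrane_arrays(comps, mem)
  g <- mem$global
  t_switch <- pulse$onset_ms + pulse$width_us * 1e-3 + 0.4
  out <- .cable_sim_cpp(as.integer(comps$parent) - 1L, arr$area, arr$cm,
                        arr$g_pas, arr$e_pas, arr$gna, arr$gkv, arr$gkm,
                        arr$gca, arr$gkca, arr$g_ax, as.numeric(phi_unit),
                        amplitude, pulse$onset_ms, pulse$width_us * 1e-3,
                        dt_us * 1e-3, duration_ms,
                        max(coarse_factor, 1) * dt_us * 1e-3, t_switch,
                        g$v_init, g$celsius, g$q10, g$temp_base,
                        g$ena, g$ek, g$eca,
                        isTRUE(g$balance_at_init), as.integer(record_every))
  structure(list(v = out$v, t = out$t, dt_us = dt_us, comps = comps,
                 amplitude = amplitude, v_init = g$v_init),
            class = "sucs_trace")
}

#' Detect an action potential in a membrane trace
#'
#' Fires iff any compartment crosses the detection level with positive slope;
#' the initiation compartment is the earliest crossing (ties broken by lowest
#' compartment index). Deterministic.
#'
#' @param trace A `sucs_trace`.
#' @param criterion List with `level` (mV, default 0).
#' @return Object of class `sucs_ap_event`: `fired`, per-compartment first
#'   crossing times `times` (ms, NA if none), `init_comp`, `init_time`.
#' @export
detect_ap <- function(trace, criterion = list(level = 0)) {
  level <- criterion$level
  v <- trace$v
  above <- v >= level
  crossed <- above[-1, , drop = FALSE] & !above[-nrow(v), , drop = FALSE]
  first <- apply(crossed, 2, function(col) {
    i <- which(col)
    if (length(i)) i[1] + 1L else NA_integer_
  })
  times <- trace$t[first]
  fired <- any(!is.na(times))
  init_comp <- if (fired) which.min(replace(times, is.na(times), Inf)) else NA_integer_
  structure(list(fired = fired, times = times,
                 init_comp = init_comp,
                 init_time = if (fired) times[init_comp] else NA_real_),
            class = "sucs_ap_event")
}

#' Classify the initiation site of a detected action potential
#'
#' Categories: `axon_terminal` (a compartment of the unmyelinated terminal
#' segment, or the last axonal compartment), `gmwm_boundary` (axonal
#' compartment within `boundary_tol` of the GM/WM surface),
#' `initial_segment`, `axon_bend` (within the bent arc), `soma`, `other`.
#' The terminal is checked first so a terminal near the boundary keeps its
#' identity; among the rest, boundary proximity takes precedence. In a
#' discretized model the interface position is only known to about one mesh
#' cell, so campaigns default `boundary_tol` to
#' `max(0.3, mesh_resolution)` mm.
#'
#' @param event A fired `sucs_ap_event`.
#' @param comps The `sucs_compartments` the trace was simulated on.
#' @param geom The `sucs_geometry` (for the GM/WM surface).
#' @param boundary_tol Distance tolerance to the GM/WM surface (mm).
#' @return Character scalar.
#' @export
classify_initiation <- function(event, comps, geom, boundary_tol = 0.3) {
  if (!isTRUE(event$fired))
    stop("classification error: event did not fire")
  i <- event$init_comp
  kind <- comps$kind[i]
  axonal <- kind %in% c("ais", "internode", "node", "terminal", "axon")
  if (axonal && (comps$terminal[i] || kind == "terminal"))
    return("axon_terminal")
  if (axonal) {
    dist_b <- abs(gmwm_signed_distance(geom, cbind(comps$x[i], comps$y[i])))
    if (dist_b <= boundary_tol) return("gmwm_boundary")
  }
  if (kind == "ais") return("initial_segment")
  bend <- attr(comps, "bend")
  if (axonal && !is.null(bend) && !is.na(comps$axon_arc[i]) &&
      comps$axon_arc[i] >= bend$s_cross - 1e-9 &&
      comps$axon_arc[i] <= bend$s_cross + bend$arc_len + 1e-9)
    return("axon_bend")
  if (kind == "soma") return("soma")
  "other"
}
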