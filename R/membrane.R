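# Membrane parameter handling. The published models this work follows do not
# print their electrical constants, so all membrane parameters
# live in a versioned JSON configuration shipped with the package and can be
# overridden per call.

#' Load membrane parameters
#'
#' @param file JSON file following the schema of
#'   `system.file("extdata", "membrane_default.json", package = "cortistim")`;
#'   `NULL` loads the packaged defaults.
#' @param overrides Optional nested list merged over the file contents, e.g.
#'   `list(sections = list(soma = list(gna = 0)))`.
#' @return Object of class `sucs_membrane`.
#' @export
membrane_parameters <- function(file = NULL, overrides = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "membrane_default.json",
                        package = "cortistim")
  mem <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]]))
        merge_rec(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  if (!is.null(overrides)) mem <- merge_rec(mem, overrides)
  needed <- c("cm", "g_pas", "e_pas", "gna", "gkv", "gkm", "gca", "gkca")
  for (sec in names(mem$sections)) {
    miss <- setdiff(needed, names(mem$sections[[sec]]))
    if (length(miss))
      stop(sprintf("membrane configuration error: section '%s' missing %s",
                   sec, paste(miss, collapse = ", ")))
    if (any(unlist(mem$sections[[sec]][c("gna", "gkv", "gkm", "gca", "gkca",
                                          "g_pas")]) < 0))
      stop("membrane configuration error: conductances must be >= 0")
  }
  class(mem) <- "sucs_membrane"
  mem
}

#' A purely passive membrane (oracle use)
#'
#' All active conductances zero; optionally a reduced membrane capacitance to
#' shorten the membrane time constant for steady-state comparisons.
#'
#' @param g_pas Leak density (S/cm2).
#' @param cm Specific capacitance (uF/cm2).
#' @param e_pas Leak reversal (mV).
#' @return A `sucs_membrane`.
#' @export
passive_membrane <- function(g_pas = 1 / 30000, cm = 0.75, e_pas = -70) {
  mem <- membrane_parameters()
  for (sec in names(mem$sections)) {
    mem$sections[[sec]][c("gna", "gkv", "gkm", "gca", "gkca")] <- 0
    mem$sections[[sec]]$g_pas <- g_pas
    mem$sections[[sec]]$cm <- cm
    mem$sections[[sec]]$e_pas <- e_pas
  }
  mem$global$balance_at_init <- FALSE
  mem
}

# per-compartment electrical arrays for the integrator
membrane_arrays <- function(comps, mem) {
  kind <- comps$kind
  kind[!kind %in% names(mem$sections)] <- "axon"
  sec <- mem$sections[kind]
  get <- function(field) vapply(sec, `[[`, 0, field)
  area_cm2 <- pi * comps$diam_um * comps$len_um * 1e-8
  # axial resistance of each half-compartment (ohm); lengths/diams in cm
  ra <- mem$global$ra_ohm_cm
  l_cm <- comps$len_um * 1e-4
  d_cm <- comps$diam_um * 1e-4
  rhalf <- 4 * ra * (l_cm / 2) / (pi * d_cm^2)
  g_ax <- numeric(nrow(comps))
  has_par <- comps$parent > 0
  g_ax[has_par] <- 1e6 / (rhalf[has_par] + rhalf[comps$parent[has_par]])
  ps2scm <- 1e-4  # pS/um2 -> S/cm2
  list(area = area_cm2, cm = get("cm"), g_pas = get("g_pas"),
       e_pas = get("e_pas"),
       gna = get("gna") * ps2scm, gkv = get("gkv") * ps2scm,
       gkm = get("gkm") * ps2scm, gca = get("gca") * ps2scm,
       gkca = get("gkca") * ps2scm, g_ax = g_ax)
}
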