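# Summary products of a threshold campaign: minimum-threshold-by-region
# tables, excited-fraction curves, sensitivity comparisons, spatial maps and
# initiation-site frequency tables.

finite_thr <- function(records) records[!is.na(records$threshold), , drop = FALSE]

#' Minimum excitation threshold per region
#'
#' @param records A `sucs_records` data frame.
#' @param clinical_cap Amplitude (mA) for the "clinically excitable" count
#'   (20 mA marker, applied at reporting time only).
#' @return Object of class `sucs_region_summary`: data frame with per
#'   layer x polarity x region minimum thresholds (NA where no neuron is
#'   excitable) and counts excitable under `clinical_cap`, plus the region(s)
#'   of the overall minimum per layer x polarity in
#'   `attr(, "overall_min")` (ties all reported).
#' @export
summarize_regions <- function(records, clinical_cap = 20) {
  sp <- split(records, list(records$layer, records$polarity, records$region),
              drop = TRUE)
  tab <- do.call(rbind, lapply(sp, function(d) {
    f <- finite_thr(d)
    data.frame(layer = d$layer[1], polarity = d$polarity[1],
               region = d$region[1],
               min_threshold = if (nrow(f)) min(f$threshold) else NA_real_,
               n = nrow(d), n_excitable = nrow(f),
               n_under_cap = sum(f$threshold <= clinical_cap),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  ov <- do.call(rbind, lapply(split(tab, list(tab$layer, tab$polarity),
                                    drop = TRUE), function(d) {
    if (all(is.na(d$min_threshold)))
      return(data.frame(layer = d$layer[1], polarity = d$polarity[1],
                        min_threshold = NA_real_, region = NA_character_))
    mn <- min(d$min_threshold, na.rm = TRUE)
    data.frame(layer = d$layer[1], polarity = d$polarity[1],
               min_threshold = mn,
               region = paste(d$region[!is.na(d$min_threshold) &
                                       d$min_threshold == mn],
                              collapse = ","))
  }))
  rownames(ov) <- NULL
  attr(tab, "overall_min") <- ov
  class(tab) <- c("sucs_region_summary", class(tab))
  tab
}

#' Excited-neuron fraction versus stimulus amplitude
#'
#' Empirical CDF of thresholds per layer x polarity; where both anodal and
#' cathodal curves exist, the crossing amplitude (first amplitude at which
#' the cathodal fraction reaches the anodal fraction after starting below
#' it) is reported per layer.
#'
#' @param records A `sucs_records`.
#' @param amplitudes Amplitude grid (mA).
#' @return Data frame `layer, polarity, amplitude, fraction` of class
#'   `sucs_fraction_curve`, with `attr(, "crossings")`.
#' @export
excited_fraction <- function(records, amplitudes = seq(0, 100, by = 1)) {
  sp <- split(records, list(records$layer, records$polarity), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    thr <- d$threshold
    frac <- vapply(amplitudes,
                   function(a) mean(!is.na(thr) & thr <= a), 0)
    data.frame(layer = d$layer[1], polarity = d$polarity[1],
               amplitude = amplitudes, fraction = frac,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  crossings <- NULL
  for (layer in unique(out$layer)) {
    fa <- out[out$layer == layer & out$polarity == "anodal", ]
    fc <- out[out$layer == layer & out$polarity == "cathodal", ]
    if (!nrow(fa) || !nrow(fc)) next
    diffn <- fa$fraction - fc$fraction
    started <- which(diffn > 0)
    if (!length(started)) next
    after <- which(diffn <= 0 & seq_along(diffn) > started[1] & fc$fraction > 0)
    crossings <- rbind(crossings, data.frame(
      layer = layer,
      amplitude = if (length(after)) fa$amplitude[after[1]] else NA_real_))
  }
  attr(out, "crossings") <- crossings
  class(out) <- c("sucs_fraction_curve", class(out))
  out
}

#' Percent threshold differences between two matched campaigns
#'
#' Neurons are matched on `neuron` id and polarity; percent differences
#' `|t_a - t_b| / t_a * 100` are computed over neurons excitable in both
#' arms (arm A is the baseline denominator; set `symmetric = TRUE` for the
#' mean-denominator variant).
#'
#' @param records_a,records_b Two `sucs_records` sharing neuron ids.
#' @param symmetric Use `(t_a + t_b)/2` as denominator.
#' @return List of class `sucs_sensitivity`: `mean_pct`, `max_pct`,
#'   `n_matched`, `n_discordant` (excitability flags differing), `per_neuron`.
#' @export
compare_sensitivity <- function(records_a, records_b, symmetric = FALSE) {
  key <- function(d) paste(d$neuron, d$polarity)
  ka <- key(records_a); kb <- key(records_b)
  common <- intersect(ka, kb)
  if (!length(common)) stop("comparison error: no shared neuron/polarity pairs")
  a <- records_a[match(common, ka), ]
  b <- records_b[match(common, kb), ]
  both <- !is.na(a$threshold) & !is.na(b$threshold)
  discord <- sum(xor(is.na(a$threshold), is.na(b$threshold)))
  if (!any(both)) stop("comparison error: no co-excitable neurons")
  den <- if (symmetric) (a$threshold[both] + b$threshold[both]) / 2
         else a$threshold[both]
  pct <- abs(a$threshold[both] - b$threshold[both]) / den * 100
  per <- data.frame(neuron = a$neuron[both], polarity = a$polarity[both],
                    t_a = a$threshold[both], t_b = b$threshold[both],
                    pct = pct, stringsAsFactors = FALSE)
  structure(list(mean_pct = mean(pct), max_pct = max(pct),
                 n_matched = sum(both), n_discordant = discord,
                 per_neuron = per),
            class = "sucs_sensitivity")
}

#' Spatial threshold map along the cortical path
#'
#' Per-soma threshold surface with the sub-20 mA contour flag; for
#' fold geometries the left/right bank asymmetry index (ratio of the
#' central-sulcus bank minimum threshold to the precentral bank minimum) is
#' reported per layer x polarity.
#'
#' @param records A `sucs_records`.
#' @param clinical_cap Contour level (mA).
#' @return Data frame of soma positions and thresholds with
#'   `attr(, "asymmetry_index")` (NA where either bank has no excitable
#'   neuron) and `attr(, "contour")` (rows under the cap).
#' @export
spatial_extent_map <- function(records, clinical_cap = 20) {
  map <- records[, intersect(c("neuron", "id", "layer", "polarity", "region",
                               "side", "s", "sw", "x", "y", "z", "threshold"),
                             names(records))]
  map$under_cap <- !is.na(map$threshold) & map$threshold <= clinical_cap
  has_side <- "side" %in% names(records) && length(unique(records$side)) > 1
  asym <- do.call(rbind, lapply(
    split(records, list(records$layer, records$polarity), drop = TRUE),
    function(d) {
      if (has_side) {
        mb <- suppressWarnings(min(d$threshold[d$region == "B" & d$side > 0],
                                   na.rm = TRUE))
        mo <- suppressWarnings(min(d$threshold[d$region == "B" & d$side < 0],
                                   na.rm = TRUE))
      } else {
        mb <- suppressWarnings(min(d$threshold[d$region == "B"], na.rm = TRUE))
        mo <- suppressWarnings(min(d$threshold[d$region == "OB"], na.rm = TRUE))
      }
      data.frame(layer = d$layer[1], polarity = d$polarity[1],
                 min_central_bank = ifelse(is.finite(mb), mb, NA),
                 min_precentral_bank = ifelse(is.finite(mo), mo, NA),
                 index = ifelse(is.finite(mb) && is.finite(mo), mb / mo, NA))
    }))
  rownames(asym) <- NULL
  attr(map, "asymmetry_index") <- asym
  attr(map, "contour") <- map[map$under_cap, , drop = FALSE]
  class(map) <- c("sucs_spatial_map", class(map))
  map
}

#' Initiation-site frequency table
#'
#' Normalized frequencies of initiation categories per layer x polarity
#' (optionally x region); the dominant category is flagged.
#'
#' @param records A `sucs_records`.
#' @param by_region Also split by region.
#' @return Data frame with `frequency` and `dominant` columns (empty if no
#'   neuron fired).
#' @export
initiation_summary <- function(records, by_region = FALSE) {
  fired <- records[!is.na(records$init_category), , drop = FALSE]
  if (!nrow(fired)) {
    out <- data.frame(layer = character(), polarity = character(),
                      region = character(), init_category = character(),
                      n = integer(), frequency = numeric(),
                      dominant = logical())
    return(out)
  }
  keys <- if (by_region) list(fired$layer, fired$polarity, fired$region)
          else list(fired$layer, fired$polarity)
  out <- do.call(rbind, lapply(split(fired, keys, drop = TRUE), function(d) {
    tb <- table(d$init_category)
    res <- data.frame(layer = d$layer[1], polarity = d$polarity[1],
                      region = if (by_region) d$region[1] else NA_character_,
                      init_category = names(tb), n = as.integer(tb),
                      frequency = as.numeric(tb) / nrow(d),
                      stringsAsFactors = FALSE)
    res$dominant <- res$n == max(res$n)
    res
  }))
  rownames(out) <- NULL
  out
}
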