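#' Flow-cytometry gating configuration
#'
#' @param viability_max events with live/dead stain above this are dead.
#' @param scatter_box c(fsc_min, fsc_max, ssc_min, ssc_max) singlet gate.
#' @param sox2_threshold,tubb3_threshold rectangular-split thresholds for
#'   the progenitor/neuron discrimination.
#' @param target_progenitor_fraction fraction of progenitors allowed above
#'   the dynamic marker threshold (the 1-2% calibration rule; default the
#'   1.5% midpoint).
#' @param mode \code{"dynamic"} (per-sample threshold from progenitors) or
#'   \code{"global"} (one threshold for all samples).
#' @param global_threshold marker threshold used in global mode.
#' @return An object of class \code{gate_config}.
#' @export
gate_config <- function(viability_max = 2.5,
                        scatter_box = c(2.3, 3.7, 1.8, 3.2),
                        sox2_threshold = 2.4,
                        tubb3_threshold = 2.4,
                        target_progenitor_fraction = 0.015,
                        mode = c("dynamic", "global"),
                        global_threshold = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(length(scatter_box) == 4L,
            target_progenitor_fraction >= 0,
            target_progenitor_fraction <= 1)
  if (mode == "global" && !is.finite(global_threshold))
    stop("global mode needs a finite global_threshold")
  structure(list(viability_max = viability_max, scatter_box = scatter_box,
                 sox2_threshold = sox2_threshold,
                 tubb3_threshold = tubb3_threshold,
                 target_progenitor_fraction = target_progenitor_fraction,
                 mode = mode, global_threshold = global_threshold),
            class = "gate_config")
}

.require_channels <- function(events, chans) {
  miss <- setdiff(chans, names(events))
  if (length(miss))
    stop("event table is missing channel(s): ", paste(miss, collapse = ", "))
}

#' Live/single-cell gate
#'
#' Keeps events with viability stain below \code{viability_max} and
#' forward/side scatter inside the scatter box.
#'
#' @param events event table (one row per event).
#' @param cfg a [gate_config()].
#' @return The gated subset of \code{events}.
#' @export
gate_live_single <- function(events, cfg = gate_config()) {
  .require_channels(events, c("viability", "fsc", "ssc"))
  b <- cfg$scatter_box
  keep <- events$viability < cfg$viability_max &
    events$fsc >= b[1] & events$fsc <= b[2] &
    events$ssc >= b[3] & events$ssc <= b[4]
  events[keep, , drop = FALSE]
}

#' Split gated events into progenitors and neurons
#'
#' Rectangular Sox2/Tubb3 gates: Sox2-high & Tubb3-low events are
#' progenitors, Tubb3-high & Sox2-low are neurons; double-positive and
#' double-negative events are unassigned.
#'
#' @param events gated event table.
#' @param cfg a [gate_config()].
#' @return \code{events} with a \code{gate_class} column.
#' @export
split_progenitor_neuron <- function(events, cfg = gate_config()) {
  .require_channels(events, c("sox2", "tubb3"))
  s_hi <- events$sox2 > cfg$sox2_threshold
  t_hi <- events$tubb3 > cfg$tubb3_threshold
  events$gate_class <- ifelse(s_hi & !t_hi, "progenitor",
                       ifelse(t_hi & !s_hi, "neuron", "unassigned"))
  events
}

#' Per-sample dynamic marker threshold
#'
#' The threshold at which \code{target_fraction} of the sample's Sox2+
#' progenitors score positive: the \code{1 - target_fraction} empirical
#' quantile (linear interpolation between order statistics).
#'
#' @param progenitor_intensities marker intensities of the sample's
#'   progenitors.
#' @param target_fraction allowed positive fraction among progenitors.
#' @param min_events minimum progenitor count for a stable quantile.
#' @return The threshold intensity.
#' @export
dynamic_threshold <- function(progenitor_intensities,
                              target_fraction = 0.015,
                              min_events = 50L) {
  if (length(progenitor_intensities) < min_events)
    stop("only ", length(progenitor_intensities), " progenitor events ",
         "(need >= ", min_events, "); use a global threshold instead")
  unname(stats::quantile(progenitor_intensities, 1 - target_fraction,
                         type = 7, names = FALSE))
}

#' Percentage of events strictly above a threshold
#'
#' @param intensities marker intensities (typically neurons).
#' @param threshold marker threshold.
#' @return Percentage in [0, 100]; an empty vector gives 0 with an
#'   \code{undefined} attribute.
#' @export
percent_positive <- function(intensities, threshold) {
  stopifnot(is.finite(threshold))
  if (length(intensities) == 0)
    return(structure(0, undefined = TRUE))
  100 * mean(intensities > threshold)
}

#' Unpaired two-sample t test (Welch or pooled variance)
#'
#' Thin wrapper for the group comparisons of gated percentages. When both
#' groups are constant with equal means the test is degenerate and reports
#' t = 0, p = 1 with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance (classic unpaired) variant.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("both groups constant with equal means; reporting p = 1")
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    stop("both groups have zero variance but different means")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Significance stars
#'
#' @param p p-value.
#' @return \code{"***"} (p < 0.001), \code{"**"} (p < 0.01), \code{"*"}
#'   (p < 0.05) or \code{"ns"}.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Gate one flow sample and quantify marker positivity
#'
#' Runs the live/single gate, the Sox2/Tubb3 split, derives the marker
#' threshold (dynamic from the sample's progenitors, or the configured
#' global threshold) and reports percent-positive neurons and progenitors.
#'
#' @param events raw event table.
#' @param cfg a [gate_config()].
#' @param marker_channel channel holding the queried marker.
#' @return One-row data.frame: \code{threshold_used, pct_pos_neurons,
#'   pct_pos_progenitors, n_neurons, n_progenitors}.
#' @export
gate_sample <- function(events, cfg = gate_config(),
                        marker_channel = "marker") {
  .require_channels(events, marker_channel)
  ev <- split_progenitor_neuron(gate_live_single(events, cfg), cfg)
  prog <- ev[[marker_channel]][ev$gate_class == "progenitor"]
  neur <- ev[[marker_channel]][ev$gate_class == "neuron"]
  thr <- if (cfg$mode == "dynamic")
    dynamic_threshold(prog, cfg$target_progenitor_fraction)
  else cfg$global_threshold
  data.frame(threshold_used = thr,
             pct_pos_neurons = as.numeric(percent_positive(neur, thr)),
             pct_pos_progenitors = as.numeric(percent_positive(prog, thr)),
             n_neurons = length(neur),
             n_progenitors = length(prog))
}
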