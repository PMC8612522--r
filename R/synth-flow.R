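#' Specification of a synthetic flow-cytometry sample
#'
#' Events are drawn from per-subpopulation Gaussians on a log10-intensity
#' scale. Progenitors are Sox2-high/Tubb3-low, neurons the reverse; a
#' configurable fraction of each class carries the queried marker (a bright
#' positive mode well separated from the negative mode). A fraction of
#' events is dead (high viability stain) or falls outside the singlet
#' scatter box, so the live/single gate has work to do.
#'
#' @param n_events total events.
#' @param progenitor_fraction fraction of events that are progenitors.
#' @param dead_fraction fraction stained by the live/dead dye.
#' @param scatter_outlier_fraction fraction of debris/doublets thrown
#'   outside the scatter box.
#' @param marker_positive_fraction_neurons,marker_positive_fraction_progenitors
#'   fraction of each class in the marker-positive mode.
#' @param means,sds named lists of per-channel Gaussian parameters; see
#'   defaults for the expected names.
#' @return An object of class \code{flow_spec}.
#' @export
flow_spec <- function(n_events = 20000L,
                      progenitor_fraction = 0.5,
                      dead_fraction = 0.1,
                      scatter_outlier_fraction = 0.1,
                      marker_positive_fraction_neurons = 0.4,
                      marker_positive_fraction_progenitors = 0,
                      means = list(viability_live = 1.5, viability_dead = 3.5,
                                   fsc = 3.0, ssc = 2.5,
                                   sox2_hi = 3.2, sox2_lo = 1.5,
                                   tubb3_hi = 3.2, tubb3_lo = 1.5,
                                   marker_neg = 1.0, marker_pos = 3.0),
                      sds = list(viability = 0.3, fsc = 0.2, ssc = 0.2,
                                 sox2 = 0.25, tubb3 = 0.25, marker = 0.35)) {
  stopifnot(n_events >= 1,
            progenitor_fraction >= 0, progenitor_fraction <= 1,
            marker_positive_fraction_neurons >= 0,
            marker_positive_fraction_neurons <= 1,
            marker_positive_fraction_progenitors >= 0,
            marker_positive_fraction_progenitors <= 1,
            all(unlist(sds) > 0))
  structure(as.list(environment()), class = "flow_spec")
}

#' Generate a synthetic flow event table
#'
#' @param spec a [flow_spec()].
#' @param seed integer seed.
#' @return data.frame with channels \code{viability, fsc, ssc, sox2, tubb3,
#'   marker} and ground-truth columns \code{class} and \code{marker_true}.
#' @export
generate_flow_events <- function(spec = flow_spec(), seed = 1L) {
  stopifnot(inherits(spec, "flow_spec"))
  with_seed(seed, {
    n <- spec$n_events
    m <- spec$means; s <- spec$sds
    cls <- ifelse(stats::runif(n) < spec$progenitor_fraction,
                  "progenitor", "neuron")
    is_p <- cls == "progenitor"
    dead <- stats::runif(n) < spec$dead_fraction
    outl <- stats::runif(n) < spec$scatter_outlier_fraction
    marker_true <- ifelse(is_p,
                          stats::runif(n) <
                            spec$marker_positive_fraction_progenitors,
                          stats::runif(n) <
                            spec$marker_positive_fraction_neurons)
    ev <- data.frame(
      viability = stats::rnorm(n, ifelse(dead, m$viability_dead,
                                         m$viability_live), s$viability),
      fsc = stats::rnorm(n, m$fsc, s$fsc) +
        ifelse(outl, sample(c(-1.2, 1.2), n, replace = TRUE), 0),
      ssc = stats::rnorm(n, m$ssc, s$ssc) +
        ifelse(outl, sample(c(-1.2, 1.2), n, replace = TRUE), 0),
      sox2 = stats::rnorm(n, ifelse(is_p, m$sox2_hi, m$sox2_lo), s$sox2),
      tubb3 = stats::rnorm(n, ifelse(is_p, m$tubb3_lo, m$tubb3_hi), s$tubb3),
      marker = stats::rnorm(n, ifelse(marker_true, m$marker_pos,
                                      m$marker_neg), s$marker),
      class = cls,
      marker_true = marker_true,
      stringsAsFactors = FALSE)
    ev
  })
}
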