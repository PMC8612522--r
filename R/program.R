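#' Temporal transcription-factor program
#'
#' The temporal TF code assigns to each neuronal TF a half-open birthdate
#' window \code{[on, off)} (in embryonic days) during which neurons born at
#' that time switch the TF on and maintain it, and to each late progenitor
#' gene an embryonic-day onset after which cycling progenitors express it.
#'
#' Defaults encode the spinal-cord program: Onecut2 marks early-born neurons
#' (e9.0-e10.5), Zfhx3 neurons born before e11.5, Pou2f2 an intermediate
#' cohort (e10.5-e11.5), and Nfia/Nfib/Neurod2 late-born neurons (e11.5
#' onwards). Late progenitor genes (Sox9, Nfia, Nfib) mark the gliogenic
#' switch in progenitors.
#'
#' @param tf_windows named list of numeric length-2 vectors \code{c(on, off)};
#'   embryonic days, half-open \code{[on, off)}.
#' @param progenitor_onsets named numeric vector of embryonic-day onsets for
#'   late progenitor genes.
#' @return An object of class \code{temporal_program}.
#' @examples
#' prog <- temporal_program()
#' temporal_tf_state(12.5, "neuron", prog)
#' @export
temporal_program <- function(tf_windows = list(
                               Onecut2 = c(9.0, 10.5),
                               Zfhx3   = c(9.0, 11.5),
                               Pou2f2  = c(10.5, 11.5),
                               Nfia    = c(11.5, 13.5),
                               Nfib    = c(11.5, 13.5),
                               Neurod2 = c(11.5, 13.5)),
                             progenitor_onsets = c(Sox9 = 11.0,
                                                   Nfia = 11.5,
                                                   Nfib = 11.5)) {
  stopifnot(is.list(tf_windows), length(tf_windows) >= 1L)
  for (nm in names(tf_windows)) {
    w <- tf_windows[[nm]]
    if (length(w) != 2L || !is.numeric(w) || w[1] >= w[2])
      stop("tf_window for ", nm, " must be a non-empty interval c(on, off)")
  }
  stopifnot(is.numeric(progenitor_onsets), !is.null(names(progenitor_onsets)))
  structure(list(tf_windows = tf_windows,
                 progenitor_onsets = progenitor_onsets),
            class = "temporal_program")
}

#' @export
print.temporal_program <- function(x, ...) {
  cat("Temporal TF program\n  neuronal windows [on, off):\n")
  for (nm in names(x$tf_windows))
    cat(sprintf("    %-8s e%.1f - e%.1f\n", nm,
                x$tf_windows[[nm]][1], x$tf_windows[[nm]][2]))
  cat("  progenitor onsets:\n")
  for (nm in names(x$progenitor_onsets))
    cat(sprintf("    %-8s e%.1f\n", nm, x$progenitor_onsets[[nm]]))
  invisible(x)
}

#' TF expression state implied by a birthdate
#'
#' For a neuron, each TF with a neuronal window is on iff the birthdate lies
#' in its half-open window \code{[on, off)}; genes with only a progenitor
#' onset are off. For a progenitor (which has no birthdate), late progenitor
#' genes are on iff the collection day has reached their onset; purely
#' neuronal TFs are off.
#'
#' @param birthdate embryonic day a neuron was born (ignored for
#'   progenitors, may be \code{NA}).
#' @param cell_class \code{"neuron"} or \code{"progenitor"}.
#' @param program a [temporal_program()].
#' @param collection_day embryonic day the tissue is examined; required for
#'   progenitors.
#' @return Named logical vector over all genes in the program.
#' @export
temporal_tf_state <- function(birthdate, cell_class, program,
                              collection_day = NA_real_) {
  stopifnot(inherits(program, "temporal_program"))
  cell_class <- match.arg(cell_class, c("neuron", "progenitor"))
  genes <- union(names(program$tf_windows), names(program$progenitor_onsets))
  state <- stats::setNames(logical(length(genes)), genes)
  if (cell_class == "neuron") {
    if (is.na(birthdate)) stop("a neuron must have a birthdate")
    for (nm in names(program$tf_windows)) {
      w <- program$tf_windows[[nm]]
      state[nm] <- birthdate >= w[1] && birthdate < w[2]
    }
  } else {
    if (is.na(collection_day))
      stop("collection_day is required to evaluate progenitor gene onsets")
    for (nm in names(program$progenitor_onsets))
      state[nm] <- collection_day >= program$progenitor_onsets[[nm]]
  }
  state
}

#' Look up whether one TF is on
#'
#' Convenience wrapper around [temporal_tf_state()] for a single gene;
#' errors on a gene the program does not know.
#'
#' @inheritParams temporal_tf_state
#' @param tf gene symbol present in the program.
#' @return Logical scalar.
#' @export
tf_is_on <- function(tf, birthdate, cell_class, program,
                     collection_day = NA_real_) {
  genes <- union(names(program$tf_windows), names(program$progenitor_onsets))
  if (!tf %in% genes)
    stop("unknown TF '", tf, "'; program knows: ",
         paste(genes, collapse = ", "))
  unname(temporal_tf_state(birthdate, cell_class, program,
                           collection_day)[tf])
}
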