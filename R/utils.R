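#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to a known state, runs \code{code}, and restores whatever
#' state the session had before, so generators are pure functions of
#' (spec, seed) without clobbering the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage child seed from a run seed
#'
#' Counter-based derivation so each pipeline stage gets an independent,
#' reproducible stream from one user-facing seed. Kept below 2^31.
#'
#' @param seed integer run seed.
#' @param stage integer or character stage tag.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage))
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483629)
}

round_half_up <- function(x) floor(x + 0.5)
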