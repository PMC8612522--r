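#' Specification of a synthetic tissue section
#'
#' Describes one simulated transverse-section image used to benchmark the
#' EdU-birthdating quantification pipeline: elliptical nuclei scattered over
#' a dark background, imaged in four channels (DAPI, a class marker that
#' separates progenitors from neurons, one temporal TF, and EdU). Each
#' neuron's TF state is a deterministic function of its sampled birthdate
#' via the [temporal_program()]; EdU labels neurons born within
#' \code{edu_window_halfwidth} days of the pulse, and cycling progenitors
#' that happened to be in S phase at the pulse (independent Bernoulli).
#'
#' @param image_shape integer c(rows, cols) in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_range c(min, max) semi-major axis, pixels.
#' @param progenitor_fraction expected fraction of progenitor nuclei.
#' @param birthdate_grid embryonic-day grid neurons are born on.
#' @param birthdate_weights mixture weights over the grid (recycled/normalised).
#' @param edu_pulse_day embryonic day of the EdU pulse.
#' @param edu_window_halfwidth half-width (days) of the effective labeling
#'   window around the pulse.
#' @param edu_progenitor_rate probability a progenitor is in S phase at the
#'   pulse and therefore labeled.
#' @param collection_day embryonic day the section is collected.
#' @param tf_channel temporal TF imaged in channel 3.
#' @param class_marker \code{"HuC"} (present in neurons) or \code{"Sox2"}
#'   (present in progenitors).
#' @param snr guaranteed contrast-to-noise ratio: the rendered signal
#'   amplitude is at least \code{snr} noise standard deviations (a 40%%
#'   headroom absorbs edge attenuation of the flat-top profile).
#' @param background_level constant background intensity, [0,1] scale.
#' @return An object of class \code{section_spec}.
#' @export
section_spec <- function(image_shape = c(512L, 512L),
                         n_nuclei = 150L,
                         nucleus_radius_range = c(5, 8),
                         progenitor_fraction = 0.35,
                         birthdate_grid = seq(9.0, 13.25, by = 0.25),
                         birthdate_weights = NULL,
                         edu_pulse_day = 12.5,
                         edu_window_halfwidth = 0.25,
                         edu_progenitor_rate = 0.3,
                         collection_day = 13.5,
                         tf_channel = "Nfib",
                         class_marker = c("HuC", "Sox2"),
                         snr = 10,
                         background_level = 0.1) {
  class_marker <- match.arg(class_marker)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 32L),
            n_nuclei >= 0L,
            length(nucleus_radius_range) == 2L,
            all(nucleus_radius_range > 0),
            nucleus_radius_range[1] <= nucleus_radius_range[2],
            progenitor_fraction >= 0, progenitor_fraction <= 1,
            edu_pulse_day <= collection_day,
            edu_window_halfwidth >= 0,
            snr > 0, background_level >= 0, background_level < 1)
  if (is.null(birthdate_weights))
    birthdate_weights <- rep(1, length(birthdate_grid))
  birthdate_weights <- rep_len(birthdate_weights, length(birthdate_grid))
  birthdate_weights <- birthdate_weights / sum(birthdate_weights)
  structure(list(image_shape = as.integer(image_shape),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = nucleus_radius_range,
                 progenitor_fraction = progenitor_fraction,
                 birthdate_grid = birthdate_grid,
                 birthdate_weights = birthdate_weights,
                 edu_pulse_day = edu_pulse_day,
                 edu_window_halfwidth = edu_window_halfwidth,
                 edu_progenitor_rate = edu_progenitor_rate,
                 collection_day = collection_day,
                 tf_channel = tf_channel,
                 class_marker = class_marker,
                 snr = snr,
                 background_level = background_level),
            class = "section_spec")
}

# Rendered signal amplitude and the noise sd implied by the spec snr.
# Amplitude is fixed; noise scales so that amplitude = 1.4 * snr * sd,
# i.e. the flat-top signal clears snr noise-sd even after ~15% loss of
# mean intensity to the 1-px blurred ellipse edge.
.section_amp <- function(spec) 0.5
.section_noise_sd <- function(spec) .section_amp(spec) / (1.4 * spec$snr)

#' Generate one synthetic section and its ground truth
#'
#' Places \code{n_nuclei} non-overlapping elliptical nuclei (minimum centre
#' spacing 1.5 x the maximum semi-major axis, bounded rejection sampling),
#' samples each nucleus a class and (for neurons) a birthdate, derives its
#' TF and EdU states from the temporal program, and renders a 4-channel
#' image with additive Gaussian noise. Identical (spec, program, seed)
#' give bit-identical output.
#'
#' @param spec a [section_spec()].
#' @param program a [temporal_program()]; must contain \code{spec$tf_channel}.
#' @param seed integer seed.
#' @return A list with \code{image} (rows x cols x 4 array, channel names in
#'   \code{dimnames}), \code{truth} (data.frame, one row per nucleus:
#'   id, row, col, radius (semi-major), radius_minor, theta, cell_class,
#'   birthdate, edu_true and one \code{tf_<gene>} logical column per program
#'   gene), and \code{spec}.
#' @export
generate_section <- function(spec, program = temporal_program(), seed = 1L) {
  stopifnot(inherits(spec, "section_spec"),
            inherits(program, "temporal_program"))
  genes <- union(names(program$tf_windows), names(program$progenitor_onsets))
  if (!spec$tf_channel %in% genes)
    stop("tf_channel '", spec$tf_channel, "' is not in the temporal program")
  with_seed(seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    rmax <- spec$nucleus_radius_range[2]
    min_spacing <- 1.5 * rmax
    margin <- rmax + 2

    ## -- placement: dart throwing with a bounded retry budget.
    ## Radii are drawn first so spacing can enforce true non-overlap:
    ## centers must be at least 1.5 x rmax apart AND leave a 2-px gap
    ## between the two nuclei (semi-major axes, conservative for ellipses).
    radius_all <- stats::runif(spec$n_nuclei,
                               spec$nucleus_radius_range[1],
                               spec$nucleus_radius_range[2])
    centers <- matrix(numeric(0), ncol = 2)
    placed_r <- numeric(0)
    budget <- max(2000L, 300L * spec$n_nuclei)
    tries <- 0L
    while (nrow(centers) < spec$n_nuclei && tries < budget) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, nr - margin),
                stats::runif(1, margin, nc - margin))
      r_cand <- radius_all[nrow(centers) + 1L]
      if (nrow(centers) == 0L) {
        centers <- rbind(centers, cand); placed_r <- r_cand
        next
      }
      d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      need <- pmax(min_spacing, placed_r + r_cand + 2)
      if (all(d >= need)) {
        centers <- rbind(centers, cand)
        placed_r <- c(placed_r, r_cand)
      }
    }
    if (nrow(centers) < spec$n_nuclei) {
      achievable <- nrow(centers)
      stop("could not place ", spec$n_nuclei, " nuclei at spacing ",
           round(min_spacing, 1), " px in a ", nr, "x", nc,
           " image after ", budget, " tries; about ", achievable,
           " nuclei are achievable at this density")
    }

    n <- spec$n_nuclei
    radius <- radius_all
    axis_ratio <- stats::runif(n, 0.7, 1.0)
    theta <- stats::runif(n, 0, pi)
    cell_class <- ifelse(stats::runif(n) < spec$progenitor_fraction,
                         "progenitor", "neuron")
    birthdate <- rep(NA_real_, n)
    is_neu <- cell_class == "neuron"
    if (any(is_neu))
      birthdate[is_neu] <- sample(spec$birthdate_grid, sum(is_neu),
                                  replace = TRUE,
                                  prob = spec$birthdate_weights)
    edu_true <- logical(n)
    edu_true[is_neu] <- abs(birthdate[is_neu] - spec$edu_pulse_day) <=
      spec$edu_window_halfwidth
    edu_true[!is_neu] <- stats::runif(sum(!is_neu)) < spec$edu_progenitor_rate

    tf_state <- matrix(FALSE, n, length(genes),
                       dimnames = list(NULL, genes))
    for (i in seq_len(n))
      tf_state[i, ] <- temporal_tf_state(birthdate[i], cell_class[i],
                                         program, spec$collection_day)

    truth <- data.frame(id = seq_len(n),
                        row = centers[, 1], col = centers[, 2],
                        radius = radius,
                        radius_minor = radius * axis_ratio,
                        theta = theta,
                        cell_class = cell_class,
                        birthdate = birthdate,
                        edu_true = edu_true,
                        stringsAsFactors = FALSE)
    for (g in genes) truth[[paste0("tf_", g)]] <- tf_state[, g]

    ## -- channel amplitudes per nucleus
    amp <- .section_amp(spec)
    class_pos <- if (spec$class_marker == "HuC") is_neu else !is_neu
    ch_amp <- cbind(DAPI  = rep(amp * 1.2, n),
                    class = ifelse(class_pos, amp, 0),
                    tf    = ifelse(tf_state[, spec$tf_channel], amp, 0),
                    edu   = ifelse(edu_true, amp, 0))

    img <- array(spec$background_level, dim = c(nr, nc, 4L))
    for (i in seq_len(n)) {
      prof <- .ellipse_profile(nr, nc, centers[i, 1], centers[i, 2],
                               radius[i], radius[i] * axis_ratio[i],
                               theta[i])
      for (ch in 1:4) {
        if (ch_amp[i, ch] == 0) next
        idx <- prof$index
        img[, , ch][idx] <- img[, , ch][idx] + ch_amp[i, ch] * prof$value
      }
    }
    sd <- .section_noise_sd(spec)
    img <- img + stats::rnorm(length(img), 0, sd)
    img[img < 0] <- 0
    img[img > 1] <- 1
    dimnames(img) <- list(NULL, NULL,
                          c("DAPI", spec$class_marker, spec$tf_channel, "EdU"))
    list(image = img, truth = truth, spec = spec)
  })
}

# Flat-top elliptical intensity profile with a ~1-px Gaussian edge blur.
# Returns linear indices into an nr x nc matrix plus the profile value.
.ellipse_profile <- function(nr, nc, r0, c0, a, b, theta) {
  ext <- ceiling(a + 3)
  rows <- max(1L, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cols <- max(1L, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  dr <- rows - r0
  dc <- cols - c0
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dr, dc, function(x, y) x * ct + y * st) / a
  v <- outer(dr, dc, function(x, y) -x * st + y * ct) / b
  e <- sqrt(u^2 + v^2)
  edge_dist <- (1 - e) * b          # approx. signed distance to boundary, px
  val <- stats::pnorm(edge_dist / 0.7)
  keep <- val > 0.01
  idx <- which(keep)
  grid_idx <- cbind(rep(rows, times = length(cols))[idx],
                    rep(cols, each = length(rows))[idx])
  list(index = grid_idx[, 1] + (grid_idx[, 2] - 1L) * nr,
       value = val[idx])
}

#' Write a section to a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit page per channel; the sidecar records channel names, the spec
#' and the seed so a run can be reproduced from its outputs.
#'
#' @param section result of [generate_section()].
#' @param path output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @param seed seed recorded in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_section <- function(section, path, seed = NA_integer_) {
  img <- section$image
  pages <- lapply(seq_len(dim(img)[3]), function(ch) img[, , ch])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = dimnames(img)[[3]],
               pixel_size_um = 1.0,
               seed = seed,
               spec = unclass(section$spec))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a section TIFF and its sidecar
#'
#' @param path TIFF path written by [write_section()].
#' @return List with \code{image} (rows x cols x channels array with channel
#'   names) and \code{meta} (parsed sidecar).
#' @export
read_section <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (ch in seq_along(pages)) img[, , ch] <- pages[[ch]]
  dimnames(img) <- list(NULL, NULL, meta$channels)
  list(image = img, meta = meta)
}
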