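#' Segmentation configuration
#'
#' Parameters of the DAPI segmentation: adaptive local-mean threshold,
#' distance-transform watershed, and the area band that keeps objects of
#' plausible nuclear size.
#'
#' @param adaptive_block_size odd box side (pixels) for the local mean.
#' @param adaptive_offset threshold offset as a fraction of the image's
#'   dynamic range (a pixel is foreground when it exceeds its local mean by
#'   more than this).
#' @param min_seed_distance minimum separation (pixels) between watershed
#'   seeds (regional maxima of the distance transform).
#' @param area_min,area_max area band (pixels^2) for retained nuclei.
#' @param smooth_sigma Gaussian pre-smoothing sigma (pixels); 0 disables.
#' @return An object of class \code{seg_config}.
#' @export
seg_config <- function(adaptive_block_size = 51L,
                       adaptive_offset = 0.02,
                       min_seed_distance = 5,
                       area_min = 40,
                       area_max = 400,
                       smooth_sigma = 1.5) {
  if (adaptive_block_size < 3L || adaptive_block_size %% 2L == 0L)
    stop("adaptive_block_size must be odd and >= 3")
  stopifnot(area_min < area_max, min_seed_distance >= 1, smooth_sigma >= 0)
  structure(list(adaptive_block_size = as.integer(adaptive_block_size),
                 adaptive_offset = adaptive_offset,
                 min_seed_distance = min_seed_distance,
                 area_min = area_min, area_max = area_max,
                 smooth_sigma = smooth_sigma),
            class = "seg_config")
}

#' Segment nuclei from a DAPI channel
#'
#' Adaptive local-mean threshold (optionally after light Gaussian
#' smoothing), morphological opening to drop speckle, then watershed on the
#' Euclidean distance transform, seeded from regional maxima at least
#' \code{min_seed_distance} apart so touching nuclei are split. Labels are
#' relabelled contiguously from 1; 0 is background.
#'
#' @param dapi numeric matrix, single channel.
#' @param cfg a [seg_config()].
#' @return Integer label matrix of the same shape.
#' @export
segment_nuclei <- function(dapi, cfg = seg_config()) {
  stopifnot(is.matrix(dapi), inherits(cfg, "seg_config"))
  if (diff(range(dapi)) == 0)   # flat image: nothing to segment
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  img <- EBImage::Image(dapi)
  if (cfg$smooth_sigma > 0)
    img <- EBImage::gblur(img, sigma = cfg$smooth_sigma)
  halfw <- (cfg$adaptive_block_size - 1L) / 2L
  offset <- cfg$adaptive_offset * diff(range(img))
  mask <- EBImage::thresh(img, w = halfw, h = halfw, offset = offset)
  if (sum(mask) == 0) return(matrix(0L, nrow(dapi), ncol(dapi)))
  mask <- EBImage::opening(mask, EBImage::makeBrush(3L, shape = "disc"))
  d <- EBImage::distmap(mask)
  ws <- EBImage::watershed(d, tolerance = 1,
                           ext = max(1L, round(cfg$min_seed_distance)))
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(dapi), ncol(dapi))
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[] <- match(lab, ids, nomatch = 0L)
  lab
}

#' Extract per-nucleus records from a label map
#'
#' One record per label whose area lies in \code{[area_min, area_max]};
#' records carry the centroid, area and the arithmetic mean intensity of
#' every image channel over the member pixels. Class, normalisation, trim
#' and positivity columns are added by the downstream steps.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param image rows x cols x channels array with channel dimnames.
#' @param cfg a [seg_config()] (area band).
#' @return data.frame with columns \code{label,row,col,area,cell_class} and
#'   \code{mean_<channel>} per channel.
#' @export
extract_records <- function(labels, image, cfg = seg_config()) {
  stopifnot(all(dim(labels) == dim(image)[1:2]))
  channels <- dimnames(image)[[3]]
  if (is.null(channels)) stop("image must carry channel names")
  nlab <- max(labels)
  if (nlab == 0L)
    return(.empty_records(channels))
  flat <- as.vector(labels)
  keep_px <- flat > 0L
  fl <- flat[keep_px]
  area <- tabulate(fl, nbins = nlab)
  rows <- rep(seq_len(nrow(labels)), times = ncol(labels))[keep_px]
  cols <- rep(seq_len(ncol(labels)), each = nrow(labels))[keep_px]
  cr <- tapply(rows, fl, mean)
  cc <- tapply(cols, fl, mean)
  rec <- data.frame(label = seq_len(nlab),
                    row = as.numeric(cr) - 1,   # 0-based pixel coordinates
                    col = as.numeric(cc) - 1,
                    area = area,
                    cell_class = "unassigned",
                    stringsAsFactors = FALSE)
  for (ch in seq_along(channels)) {
    v <- as.vector(image[, , ch])[keep_px]
    rec[[paste0("mean_", channels[ch])]] <-
      as.numeric(tapply(v, fl, mean))
  }
  rec <- rec[rec$area >= cfg$area_min & rec$area <= cfg$area_max, ,
             drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "channels") <- channels
  rec
}

.empty_records <- function(channels) {
  rec <- data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                    area = numeric(0), cell_class = character(0),
                    stringsAsFactors = FALSE)
  for (ch in channels) rec[[paste0("mean_", ch)]] <- numeric(0)
  attr(rec, "channels") <- channels
  rec
}

#' Per-section intensity normalisation with outlier trimming
#'
#' Min-max rescales the channel's mean intensities over all nuclei of the
#' section to [0, 1] (progenitors and neurons together), then flags the
#' \code{round(trim_fraction * N)} brightest and equally many dimmest
#' objects (round half up, per tail) as trimmed on that channel. The
#' rescale uses all records, including those later trimmed.
#'
#' @param records record table from [extract_records()].
#' @param channel channel name.
#' @param trim_fraction fraction trimmed per tail (default 0.3%).
#' @return \code{records} with \code{norm_<channel>} and
#'   \code{trimmed_<channel>} columns.
#' @export
normalize_and_trim <- function(records, channel, trim_fraction = 0.003) {
  raw <- records[[paste0("mean_", channel)]]
  if (is.null(raw)) stop("no mean intensity for channel '", channel, "'")
  n <- length(raw)
  rng <- range(raw)
  if (n > 0 && rng[1] == rng[2]) {
    warning("channel '", channel, "' is constant over the section; ",
            "normalised intensities set to 0")
    norm <- rep(0, n)
  } else {
    norm <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  k <- round_half_up(trim_fraction * n)
  trimmed <- logical(n)
  if (k > 0) {
    ord <- order(raw)
    trimmed[ord[seq_len(k)]] <- TRUE
    trimmed[ord[n + 1 - seq_len(k)]] <- TRUE
  }
  records[[paste0("norm_", channel)]] <- norm
  records[[paste0("trimmed_", channel)]] <- trimmed
  records
}

#' Classify nuclei as progenitor or neuron
#'
#' Uses the normalised class-marker intensity: with \code{huc_presence} a
#' nucleus is a neuron when its normalised HuC exceeds the threshold
#' (strict); with \code{sox2_absence} it is a neuron when its normalised
#' Sox2 is at or below the threshold. All other nuclei are progenitors.
#'
#' @param records record table; the class channel must already be
#'   normalised (see [normalize_and_trim()]).
#' @param class_channel channel name (HuC or Sox2).
#' @param mode \code{"huc_presence"} or \code{"sox2_absence"}.
#' @param class_threshold threshold on the normalised intensity.
#' @return \code{records} with \code{cell_class} filled in.
#' @export
classify_cells <- function(records, class_channel,
                           mode = c("huc_presence", "sox2_absence"),
                           class_threshold = 0.25) {
  mode <- match.arg(mode)
  norm <- records[[paste0("norm_", class_channel)]]
  if (is.null(norm))
    stop("class channel '", class_channel, "' must be normalised first")
  neuron <- if (mode == "huc_presence") norm > class_threshold
            else norm <= class_threshold
  records$cell_class <- ifelse(neuron, "neuron", "progenitor")
  records
}

#' Call marker positivity on a normalised channel
#'
#' A nucleus is positive when its normalised intensity is strictly greater
#' than the threshold. Trimmed nuclei get \code{NA}: they are excluded from
#' every downstream count.
#'
#' @param records record table with the channel normalised and trimmed.
#' @param channel channel name.
#' @param threshold positivity cutoff on the normalised scale.
#' @return \code{records} with a \code{positive_<channel>} column.
#' @export
call_positive <- function(records, channel, threshold = 0.25) {
  norm <- records[[paste0("norm_", channel)]]
  trm <- records[[paste0("trimmed_", channel)]]
  if (is.null(norm) || is.null(trm))
    stop("channel '", channel, "' must be normalised and trimmed before ",
         "positivity can be called")
  pos <- norm > threshold
  pos[trm] <- NA
  records[[paste0("positive_", channel)]] <- pos
  records
}

#' EdU-TF colocalization percentage
#'
#' Fraction of EdU-positive neurons that also express the temporal TF,
#' counted over untrimmed neurons only. A section with no EdU-positive
#' neuron reports 0% with \code{undefined = TRUE}.
#'
#' @param records record table with positivity called on both channels and
#'   cells classified.
#' @param tf_channel temporal TF channel name.
#' @param edu_channel EdU channel name.
#' @return A one-row data.frame: \code{tf, n_edu_pos_neurons, n_double_pos,
#'   percent, undefined}.
#' @export
colocalization_fraction <- function(records, tf_channel,
                                    edu_channel = "EdU") {
  pos_tf <- records[[paste0("positive_", tf_channel)]]
  pos_edu <- records[[paste0("positive_", edu_channel)]]
  if (is.null(pos_tf) || is.null(pos_edu))
    stop("positivity must be called on both channels first")
  neu <- records$cell_class == "neuron" & !is.na(pos_tf) & !is.na(pos_edu)
  n_edu <- sum(neu & pos_edu)
  n_both <- sum(neu & pos_edu & pos_tf)
  data.frame(tf = tf_channel,
             n_edu_pos_neurons = n_edu,
             n_double_pos = n_both,
             percent = if (n_edu == 0) 0 else 100 * n_both / n_edu,
             undefined = n_edu == 0,
             stringsAsFactors = FALSE)
}

#' Run the full birthdating quantification on one section
#'
#' Convenience wrapper: segment the DAPI channel, extract area-filtered
#' records, normalise and trim every non-DAPI channel, classify cells from
#' the class marker, call positivity on the TF and EdU channels, and
#' compute the colocalization percentage.
#'
#' @param image rows x cols x 4 array with channel names
#'   (DAPI, class marker, TF, EdU).
#' @param cfg a [seg_config()].
#' @param class_marker \code{"HuC"} or \code{"Sox2"}; defaults to whichever
#'   is present among the channel names.
#' @param tf_channel TF channel name; defaults to channel 3.
#' @param positive_threshold positivity cutoff (normalised scale).
#' @param trim_fraction outlier trim fraction per tail.
#' @return List with \code{records} and \code{coloc}.
#' @export
quantify_section <- function(image, cfg = seg_config(),
                             class_marker = NULL, tf_channel = NULL,
                             positive_threshold = 0.25,
                             trim_fraction = 0.003) {
  channels <- dimnames(image)[[3]]
  if (is.null(class_marker))
    class_marker <- intersect(c("HuC", "Sox2"), channels)[1]
  if (is.null(tf_channel)) tf_channel <- channels[3]
  labels <- segment_nuclei(image[, , "DAPI"], cfg)
  rec <- extract_records(labels, image, cfg)
  for (ch in setdiff(channels, "DAPI"))
    rec <- normalize_and_trim(rec, ch, trim_fraction)
  mode <- if (class_marker == "HuC") "huc_presence" else "sox2_absence"
  rec <- classify_cells(rec, class_marker, mode,
                        class_threshold = positive_threshold)
  rec <- call_positive(rec, tf_channel, positive_threshold)
  rec <- call_positive(rec, "EdU", positive_threshold)
  list(records = rec,
       coloc = colocalization_fraction(rec, tf_channel, "EdU"))
}

#' Ground-truth colocalization percentage for a synthetic section
#'
#' Computes, from a [generate_section()] truth table, the percentage of
#' EdU-labeled neurons whose birthdate places them inside the TF's window —
#' the quantity the imaging pipeline estimates.
#'
#' @param truth truth table from [generate_section()].
#' @param tf TF gene symbol.
#' @return Percentage in [0, 100] (0 when no neuron is EdU-labeled).
#' @export
truth_coloc_percent <- function(truth, tf) {
  neu <- truth$cell_class == "neuron"
  denom <- sum(neu & truth$edu_true)
  if (denom == 0) return(0)
  100 * sum(neu & truth$edu_true & truth[[paste0("tf_", tf)]]) / denom
}
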