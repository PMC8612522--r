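test_that("segmentation handles empty images and rejects bad config", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
  expect_error(seg_config(adaptive_block_size = 50L), "odd")
})

test_that("segmentation count matches a flood-fill oracle on clean sections", {
  s <- generate_section(section_spec(image_shape = c(220L, 220L),
                                     n_nuclei = 5L, snr = Inf), seed = 3)
  lab <- segment_nuclei(s$image[, , "DAPI"])
  mask <- s$image[, , "DAPI"] > s$spec$background_level + 0.1
  expect_equal(max(lab), flood_fill_components(mask))
  expect_equal(max(lab), 5L)
  # labels are contiguous from 1
  expect_setequal(setdiff(unique(as.vector(lab)), 0L), seq_len(max(lab)))
})

test_that("watershed splits two touching ellipses into two labels", {
  img <- matrix(0, 80, 80)
  for (ctr in list(c(40, 32), c(40, 49))) {
    d <- outer(seq_len(80) - ctr[1], seq_len(80) - ctr[2],
               function(a, b) sqrt(a^2 + b^2))
    img[d <= 9] <- 0.8
  }
  expect_equal(flood_fill_components(img > 0.4), 1L)  # they do touch
  lab <- segment_nuclei(img, seg_config(min_seed_distance = 7,
                                        smooth_sigma = 0))
  expect_equal(max(lab), 2L)
})

test_that("record extraction filters by area and averages intensities exactly", {
  lab <- matrix(0L, 20, 20)
  lab[2:7, 2:7] <- 1L        # area 36 - kept
  lab[12, 12] <- 2L          # area 1 - filtered out
  lab[14:19, 10:19] <- 3L    # area 60 - filtered out by area_max
  img <- array(0, dim = c(20, 20, 2), dimnames = list(NULL, NULL,
                                                      c("DAPI", "EdU")))
  img[, , "DAPI"] <- 0.5
  img[2:7, 2:7, "EdU"] <- matrix(seq(0, 1, length.out = 36), 6, 6)
  rec <- extract_records(lab, img, seg_config(area_min = 10, area_max = 50))
  expect_equal(rec$label, 1L)
  expect_equal(rec$mean_DAPI, 0.5)
  expect_equal(rec$mean_EdU, mean(seq(0, 1, length.out = 36)))
  # 3-pixel object with values 1,2,3 averages to 2
  lab2 <- matrix(0L, 5, 5); lab2[2, 2:4] <- 1L
  img2 <- array(0, dim = c(5, 5, 1), dimnames = list(NULL, NULL, "X"))
  img2[2, 2:4, 1] <- c(1, 2, 3)
  rec2 <- extract_records(lab2, img2, seg_config(area_min = 1, area_max = 10))
  expect_equal(rec2$mean_X, 2)
})

make_records <- function(vals, channel = "TF") {
  rec <- data.frame(label = seq_along(vals), row = 0, col = 0,
                    area = 50, cell_class = "unassigned")
  rec[[paste0("mean_", channel)]] <- vals
  rec
}

test_that("min-max normalisation and round-half-up trimming", {
  rec <- normalize_and_trim(make_records(c(10, 20, 30)), "TF")
  expect_equal(rec$norm_TF, c(0, 0.5, 1))
  # N = 1000 at 0.3% trims 3 per tail
  rec <- normalize_and_trim(make_records(seq_len(1000)), "TF")
  expect_equal(sum(rec$trimmed_TF), 6)
  expect_true(all(which(rec$trimmed_TF) %in% c(1:3, 998:1000)))
  # N = 100: round(0.3) = 0 per tail
  rec <- normalize_and_trim(make_records(seq_len(100)), "TF")
  expect_equal(sum(rec$trimmed_TF), 0)
  # N = 167: round-half-up(0.501) = 1 per tail
  rec <- normalize_and_trim(make_records(seq_len(167)), "TF")
  expect_equal(sum(rec$trimmed_TF), 2)
  # constant channel: zeros with a warning
  expect_warning(rec <- normalize_and_trim(make_records(rep(5, 10)), "TF"),
                 "constant")
  expect_true(all(rec$norm_TF == 0))
})

test_that("normalisation is rank-preserving and affine-invariant", {
  vals <- c(3, 8, 1, 9, 4, 7)
  r1 <- normalize_and_trim(make_records(vals), "TF")
  r2 <- normalize_and_trim(make_records(5 + 3 * vals), "TF")
  expect_equal(r1$norm_TF, r2$norm_TF)
  expect_equal(order(r1$norm_TF), order(vals))
})

test_that("classification by marker presence/absence with a strict boundary", {
  rec <- make_records(c(0.1, 0.25, 0.9), channel = "HuC")
  rec$norm_HuC <- rec$mean_HuC
  out <- classify_cells(rec, "HuC", "huc_presence", 0.25)
  expect_equal(out$cell_class, c("progenitor", "progenitor", "neuron"))
  rec2 <- make_records(c(0.1, 0.25, 0.9), channel = "Sox2")
  rec2$norm_Sox2 <- rec2$mean_Sox2
  out2 <- classify_cells(rec2, "Sox2", "sox2_absence", 0.25)
  expect_equal(out2$cell_class, c("neuron", "neuron", "progenitor"))
  expect_error(classify_cells(make_records(1), "HuC"), "normalised")
})

test_that("positivity is strict at the threshold and excludes trimmed nuclei", {
  rec <- make_records(c(0.10, 0.25, 0.26, 0.80))
  rec$norm_TF <- rec$mean_TF
  rec$trimmed_TF <- c(FALSE, FALSE, FALSE, TRUE)
  out <- call_positive(rec, "TF", 0.25)
  expect_identical(out$positive_TF, c(FALSE, FALSE, TRUE, NA))
  expect_error(call_positive(make_records(1), "TF"), "normalised")
})

test_that("colocalization percentage counts untrimmed EdU-positive neurons", {
  rec <- data.frame(label = 1:7,
                    cell_class = c(rep("neuron", 6), "progenitor"),
                    positive_TF  = c(TRUE, TRUE, TRUE, TRUE, FALSE, NA, TRUE),
                    positive_EdU = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  # 5 untrimmed EdU+ neurons, 4 also TF+ (trimmed record 6 excluded,
  # progenitor 7 excluded)
  out <- colocalization_fraction(rec, "TF", "EdU")
  expect_equal(out$n_edu_pos_neurons, 5)
  expect_equal(out$n_double_pos, 4)
  expect_equal(out$percent, 80)
  expect_false(out$undefined)
  # no EdU+ neurons: flagged zero
  rec$positive_EdU <- FALSE
  out0 <- colocalization_fraction(rec, "TF", "EdU")
  expect_equal(out0$percent, 0)
  expect_true(out0$undefined)
})

test_that("adding a double-positive neuron never decreases the percentage", {
  base <- data.frame(cell_class = rep("neuron", 4),
                     positive_TF = c(TRUE, FALSE, TRUE, FALSE),
                     positive_EdU = c(TRUE, TRUE, TRUE, FALSE))
  p0 <- colocalization_fraction(base, "TF", "EdU")$percent
  more <- rbind(base, data.frame(cell_class = "neuron", positive_TF = TRUE,
                                 positive_EdU = TRUE))
  expect_gte(colocalization_fraction(more, "TF", "EdU")$percent, p0)
})

test_that("positivity calls are invariant to uniform affine rescaling of a section", {
  s <- generate_section(section_spec(image_shape = c(320L, 320L),
                                     n_nuclei = 50L), seed = 13)
  q1 <- quantify_section(s$image)
  img2 <- 0.1 + 0.6 * s$image   # same segmentation geometry, rescaled signal
  # rescale all channels except DAPI (segmentation input must stay valid)
  img2[, , "DAPI"] <- s$image[, , "DAPI"]
  q2 <- quantify_section(img2)
  expect_identical(q1$records$positive_Nfib, q2$records$positive_Nfib)
  expect_identical(q1$records$positive_EdU, q2$records$positive_EdU)
  expect_equal(q1$coloc$percent, q2$coloc$percent)
})

test_that("the full pipeline recovers ground-truth colocalization within 5 points", {
  diffs <- vapply(1:5, function(sd) {
    s <- generate_section(section_spec(edu_pulse_day = 11.5,
                                       tf_channel = "Zfhx3"), seed = sd)
    q <- quantify_section(s$image)
    q$coloc$percent - truth_coloc_percent(s$truth, "Zfhx3")
  }, numeric(1))
  expect_lte(abs(mean(diffs)), 5)
})
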