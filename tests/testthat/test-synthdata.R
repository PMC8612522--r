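spec_small <- function(...) {
  args <- utils::modifyList(list(image_shape = c(256L, 256L),
                                 n_nuclei = 12L), list(...))
  do.call(section_spec, args)
}

test_that("section generation is deterministic and self-consistent", {
  s1 <- generate_section(spec_small(), seed = 4)
  s2 <- generate_section(spec_small(), seed = 4)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  # re-deriving tf_true from birthdates reproduces the stored columns
  prog <- temporal_program()
  for (i in seq_len(nrow(s1$truth))) {
    st <- temporal_tf_state(s1$truth$birthdate[i], s1$truth$cell_class[i],
                            prog, collection_day = 13.5)
    for (g in names(st))
      expect_identical(unname(st[g]), s1$truth[[paste0("tf_", g)]][i])
  }
})

test_that("an empty spec yields a background-only image", {
  s <- generate_section(spec_small(n_nuclei = 0L, snr = Inf), seed = 1)
  expect_equal(nrow(s$truth), 0)
  expect_true(all(s$image == s$image[1, 1, 1]))
})

test_that("noise-free DAPI has exactly n_nuclei connected components", {
  s <- generate_section(section_spec(image_shape = c(200L, 200L),
                                     n_nuclei = 5L, snr = Inf), seed = 1)
  mask <- s$image[, , "DAPI"] > s$spec$background_level + 0.1
  expect_equal(flood_fill_components(mask), 5L)
})

test_that("EdU truth follows the labeling window definition", {
  s <- generate_section(spec_small(n_nuclei = 60L, image_shape = c(512L, 512L),
                                   edu_pulse_day = 12.5,
                                   edu_window_halfwidth = 0.25), seed = 2)
  neu <- s$truth$cell_class == "neuron"
  in_win <- abs(s$truth$birthdate - 12.5) <= 0.25
  expect_identical(s$truth$edu_true[neu], in_win[neu])
})

test_that("TF channel contrast between tf_true and tf_false nuclei is >= snr * noise sd", {
  sp <- section_spec(edu_pulse_day = 11.5, tf_channel = "Zfhx3")
  s <- generate_section(sp, seed = 6)
  tfcol <- s$truth$tf_Zfhx3
  skip_if(length(unique(tfcol)) < 2)  # needs both classes present
  fg_mean <- function(rows) {
    vals <- c()
    for (i in rows) {
      r0 <- s$truth$row[i]; c0 <- s$truth$col[i]; rad <- s$truth$radius_minor[i]
      rr <- round(seq(r0 - rad / 2, r0 + rad / 2))
      cc <- round(seq(c0 - rad / 2, c0 + rad / 2))
      vals <- c(vals, as.vector(s$image[rr, cc, "Zfhx3"]))
    }
    mean(vals)
  }
  noise_sd <- 0.5 / (1.4 * sp$snr)
  expect_gte(fg_mean(which(tfcol)) - fg_mean(which(!tfcol)),
             sp$snr * noise_sd)
})

test_that("overcrowded placement fails with an informative error", {
  expect_error(generate_section(section_spec(image_shape = c(64L, 64L),
                                             n_nuclei = 100L), seed = 1),
               "achievable")
})

test_that("section TIFF round-trips through the sidecar format", {
  s <- generate_section(spec_small(), seed = 9)
  path <- file.path(tempdir(), "sec.tiff")
  write_section(s, path, seed = 9)
  back <- read_section(path)
  expect_identical(dimnames(back$image)[[3]], dimnames(s$image)[[3]])
  # 16-bit quantisation: agreement to 1/65535
  expect_lt(max(abs(back$image - s$image)), 1 / 65534)
  expect_equal(back$meta$seed, 9)
})

test_that("count generation is deterministic with planted monotone programs", {
  cs <- counts_spec(n_genes = 60L, n_planted = 4L, cells_per_group = 15L)
  c1 <- generate_counts(cs, seed = 11)
  c2 <- generate_counts(cs, seed = 11)
  expect_identical(as.matrix(c1$counts), as.matrix(c2$counts))
  expect_equal(nrow(c1$planted), 4)
  # planted annotation records exactly planted_domain_count domains
  expect_true(all(lengths(strsplit(c1$planted$domains, ";")) == 9))
  # planted gene means are monotone across stages inside planted domains
  norm <- normalize_counts(c1)
  g <- c1$planted$gene[1]
  doms <- strsplit(c1$planted$domains[1], ";")[[1]]
  meta <- c1$cell_meta
  sel <- meta$domain %in% doms
  mns <- tapply(as.numeric(c1$counts[g, sel]),
                factor(meta$stage[sel], levels = cs$stages), mean)
  ord <- if (c1$planted$direction[1] == "up") diff(mns) else -diff(mns)
  expect_true(all(ord > 0))
})

test_that("unplanted genes have flat stage profiles", {
  cs <- counts_spec(n_genes = 40L, n_planted = 0L, cells_per_group = 60L,
                    nb_dispersion = 50, libsize_sdlog = 0)
  cm <- generate_counts(cs, seed = 5)
  meta <- cm$cell_meta
  mns <- sapply(cs$stages, function(st)
    Matrix::rowMeans(cm$counts[, meta$stage == st, drop = FALSE]))
  # stage means of each gene agree within sampling error (low dispersion)
  rel_spread <- apply(mns, 1, function(v) diff(range(v)) / (mean(v) + 0.1))
  expect_lt(median(rel_spread), 0.35)
})

test_that("counts must be able to hold the planted genes", {
  expect_error(counts_spec(n_genes = 3L, n_planted = 5L), "n_planted")
})

test_that("MatrixMarket round trip preserves counts and metadata", {
  cm <- generate_counts(counts_spec(n_genes = 30L, n_planted = 2L,
                                    cells_per_group = 5L, dp6_cells = 3L),
                        seed = 2)
  d <- file.path(tempdir(), "mtx")
  write_counts(cm, d)
  back <- read_counts(d)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_equal(back$cell_meta$domain, cm$cell_meta$domain)
})

test_that("flow event tables are deterministic with truthful class counts", {
  fs <- flow_spec(n_events = 10000L, progenitor_fraction = 0.4)
  e1 <- generate_flow_events(fs, seed = 7)
  e2 <- generate_flow_events(fs, seed = 7)
  expect_identical(e1, e2)
  # progenitor count within the binomial 99% interval around 4000
  ci <- qbinom(c(0.005, 0.995), 10000, 0.4)
  expect_gte(sum(e1$class == "progenitor"), ci[1])
  expect_lte(sum(e1$class == "progenitor"), ci[2])
})

test_that("marker_positive_fraction = 0 yields no marker-true neurons", {
  ev <- generate_flow_events(flow_spec(n_events = 2000L,
                                       marker_positive_fraction_neurons = 0),
                             seed = 3)
  expect_false(any(ev$marker_true[ev$class == "neuron"]))
})
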