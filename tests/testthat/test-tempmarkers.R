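toy_norm <- function(counts, domain, stage) {
  meta <- data.frame(cell_id = colnames(counts), domain = domain,
                     stage = stage, cell_type = "progenitor")
  normalize_counts(counts, meta)
}

test_that("normalisation scales every cell to exactly 10,000 counts", {
  cm <- generate_counts(counts_spec(n_genes = 40L, n_planted = 2L,
                                    cells_per_group = 6L), seed = 8)
  norm <- normalize_counts(cm)
  expect_equal(unname(Matrix::colSums(norm$scaled)),
               rep(10000, ncol(norm$scaled)), tolerance = 1e-9)
  # cell with total 5000 scales a count of 5 to 10
  m <- Matrix::Matrix(matrix(c(5, 4995, 3, 9997), 2,
                             dimnames = list(c("g1", "g2"), c("c1", "c2"))),
                      sparse = TRUE)
  n2 <- normalize_counts(m, data.frame(cell_id = c("c1", "c2"),
                                       domain = "d", stage = "s"))
  expect_equal(n2$scaled["g1", "c1"], 10)
  expect_equal(n2$lognorm["g1", "c1"], log1p(10))
  # totals already 10,000: identity
  m3 <- Matrix::Matrix(matrix(c(10000, 0, 2500, 7500), 2,
                              dimnames = list(c("g1", "g2"),
                                              c("c1", "c2"))), sparse = TRUE)
  n3 <- normalize_counts(m3, NULL)
  expect_equal(as.matrix(n3$scaled), as.matrix(m3))
  # all-zero cell is an error naming the cell
  m4 <- m3; m4[, 2] <- 0
  expect_error(normalize_counts(m4, NULL), "c2")
})

test_that("stage markers find a planted shift and match the exact rank-sum p", {
  # 16-cell toy: two stages, one gene shifted 8x, one flat, plus a large
  # ballast gene so the library-size normalisation leaves totals stable
  counts <- rbind(shifted = c(rep(1, 8), rep(8, 8)) * 100,
                  flat = rep(c(300, 400), 8),
                  ballast = rep(1e5, 16))
  colnames(counts) <- paste0("c", 1:16)
  norm <- toy_norm(Matrix::Matrix(counts, sparse = TRUE), "p0",
                   rep(c("e9.5", "e13.5"), each = 8))
  res <- stage_markers(norm, "p0", min_cells = 3L)
  expect_setequal(unique(res$gene), "shifted")
  # p equals the exact enumeration on the log-normalised values
  ln <- as.matrix(norm$lognorm)
  p_oracle <- enumerate_ranksum_p(ln["shifted", 1:8], ln["shifted", 9:16])
  expect_equal(res$p[1], p_oracle, tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p))
})

test_that("low-detection genes are excluded by the min.pct filter", {
  set.seed(41)
  # gene detected in 10% of cells on both sides, strongly shifted where seen
  counts <- rbind(rare = c(rep(0, 9), 50, rep(0, 9), 400),
                  anchor = rep(100, 20))
  colnames(counts) <- paste0("c", 1:20)
  norm <- toy_norm(Matrix::Matrix(counts, sparse = TRUE), "p0",
                   rep(c("e9.5", "e13.5"), each = 10))
  res <- stage_markers(norm, "p0")
  expect_false("rare" %in% res$gene)
})

test_that("identically expressed genes are never returned", {
  counts <- matrix(5, 3, 12, dimnames = list(paste0("g", 1:3),
                                             paste0("c", 1:12)))
  norm <- toy_norm(Matrix::Matrix(counts, sparse = TRUE), "p1",
                   rep(c("e9.5", "e11.5", "e13.5"), each = 4))
  expect_equal(nrow(stage_markers(norm, "p1")), 0)
})

test_that("stages with too few cells are skipped with a warning", {
  counts <- matrix(rpois(100, 5), 5, 20,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:20)))
  norm <- toy_norm(Matrix::Matrix(counts, sparse = TRUE), "p2",
                   c(rep("e9.5", 9), rep("e13.5", 9), rep("e11.5", 2)))
  expect_warning(stage_markers(norm, "p2", min_cells = 3L), "e11.5")
})

test_that("cross-domain filter keeps genes in strictly more than min_domains", {
  sets <- list(dp1 = c("a", "b"), dp2 = c("a", "b"), dp3 = c("a", "b"),
               dp4 = c("a", "b"), dp5 = c("a", "b"), p0 = c("a", "b"),
               p1 = c("a", "b"), p2 = c("a"), pMN = c("a"), p3 = c("a"),
               dp6 = c("b"))
  gs <- cross_domain_filter(sets, min_domains = 7, excluded_domains = "dp6")
  expect_equal(gs$genes, "a")              # a: 10 hits; b: 7 hits (dp6 dropped)
  expect_equal(unname(gs$domain_hit_counts["b"]), 7L)
  # brute-force recount over the retained map
  kept <- sets[names(sets) != "dp6"]
  brute <- sum(sapply(kept, function(s) "a" %in% s))
  expect_equal(unname(gs$domain_hit_counts["a"]), brute)
  expect_length(cross_domain_filter(list())$genes, 0)
})

test_that("TF subsetting is an order-preserving intersection", {
  genes <- c("g1", "Nfib", "g2", "Zfhx3", "Sox9", "g3")
  expect_equal(subset_tfs(genes, c("Sox9", "Zfhx3", "Nfib")),
               c("Nfib", "Zfhx3", "Sox9"))
  expect_length(subset_tfs(genes, character(0)), 0)
  expect_length(subset_tfs(c("x", "y"), c("Nfib")), 0)
  tf_file <- system.file("extdata", "mouse_tfs_mini.txt",
                         package = "tempocode")
  planted <- c("gene1", "Nfia", "Pou2f2", "gene2", "Atoh1")
  expect_equal(subset_tfs(planted, tf_file), c("Nfia", "Pou2f2", "Atoh1"))
})

test_that("z-score matrix rows have mean 0 and the two-group closed form", {
  counts <- matrix(rpois(60, 10), 6, 10,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  norm <- toy_norm(Matrix::Matrix(counts, sparse = TRUE), "p0",
                   rep(c("e9.5", "e13.5"), each = 5))
  z <- zscore_matrix(norm, rep(c("a", "b"), each = 5))
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  # two groups: with the n-1 sd the z-scores are exactly +/- 1/sqrt(2)
  nonflat <- apply(z, 1, function(v) any(v != 0))
  expect_equal(abs(z[nonflat, ]),
               matrix(1 / sqrt(2), sum(nonflat), 2,
                      dimnames = dimnames(z[nonflat, , drop = FALSE])),
               tolerance = 1e-12)
  # constant gene maps to a zero row
  cst <- matrix(7, 2, 6, dimnames = list(c("k1", "k2"), paste0("c", 1:6)))
  expect_message(z2 <- zscore_matrix(log1p(cst), rep(c("a", "b"), 3)),
                 "constant")
  expect_true(all(z2 == 0))
})

test_that("planted temporal genes are recovered with high sensitivity and low FDP", {
  sens <- fdp <- numeric(2)
  for (i in 1:2) {
    cm <- generate_counts(counts_spec(), seed = i)
    gs <- find_temporal_genes(normalize_counts(cm))
    planted <- cm$planted$gene
    sens[i] <- mean(planted %in% gs$genes)
    fdp[i] <- if (length(gs$genes)) mean(!gs$genes %in% planted) else 0
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdp), 0.1)
})
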