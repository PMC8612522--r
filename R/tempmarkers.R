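#' Library-size normalisation to 10,000 counts per cell
#'
#' Scales each cell to a total of 10,000 counts, and stores the
#' log-transformed values \code{log(1 + scaled)} alongside, the scale the
#' rank-sum tests and heatmaps operate on.
#'
#' @param x a \code{synth_counts} object, the list returned by
#'   [read_counts()], or a genes x cells matrix (sparse or dense); in the
#'   matrix case supply \code{cell_meta}.
#' @param cell_meta per-cell annotation (cell_id, domain, stage, cell_type);
#'   taken from \code{x} when present.
#' @return List of class \code{norm_counts}: \code{scaled} (counts per
#'   10,000), \code{lognorm} (log1p of scaled), \code{counts},
#'   \code{cell_meta}.
#' @export
normalize_counts <- function(x, cell_meta = NULL) {
  if (is.list(x) && !is.null(x$counts)) {
    if (is.null(cell_meta)) cell_meta <- x$cell_meta
    counts <- x$counts
  } else counts <- x
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    ids <- colnames(counts)[totals == 0]
    if (is.null(ids)) ids <- which(totals == 0)
    stop("cell(s) with zero total counts: ",
         paste(utils::head(ids, 10), collapse = ", "))
  }
  scaled <- counts %*% Matrix::Diagonal(x = 10000 / totals)
  dimnames(scaled) <- dimnames(counts)
  structure(list(scaled = scaled, lognorm = log1p(scaled),
                 counts = counts, cell_meta = cell_meta),
            class = "norm_counts")
}

#' Stage-wise marker discovery within one progenitor domain
#'
#' For each stage with at least \code{min_cells} cells in the domain, tests
#' every gene one-stage-versus-rest: detection fractions \code{pct_in} and
#' \code{pct_out} (nonzero counts) must reach \code{min_pct} in at least
#' one group; the natural-log fold change of group means of the
#' de-logged normalised expression (pseudocount 1) must reach
#' \code{lfc_threshold} in absolute value; surviving genes get a two-sided
#' Wilcoxon rank-sum test on the log-normalised values, Bonferroni-adjusted
#' over the genes tested in that comparison. Only significant markers
#' (\code{p_adj < alpha}) are returned.
#'
#' @param norm a [normalize_counts()] result.
#' @param domain domain label to analyse.
#' @param min_pct minimum detection fraction.
#' @param lfc_threshold minimum |ln fold change|.
#' @param alpha significance level on the adjusted p-value.
#' @param min_cells minimum cells per stage group (smaller stages are
#'   skipped with a warning).
#' @return data.frame with gene, domain, stage, ln_fold_change, pct_in,
#'   pct_out, p, p_adj.
#' @export
stage_markers <- function(norm, domain, min_pct = 0.25,
                          lfc_threshold = 0.25, alpha = 0.05,
                          min_cells = 3L) {
  stopifnot(inherits(norm, "norm_counts"))
  meta <- norm$cell_meta
  in_dom <- meta$domain == domain
  if (!any(in_dom)) stop("no cells in domain '", domain, "'")
  stages <- unique(meta$stage[in_dom])
  sizes <- table(meta$stage[in_dom])
  usable <- names(sizes)[sizes >= min_cells]
  skipped <- setdiff(stages, usable)
  if (length(skipped))
    warning("domain ", domain, ": skipping stage(s) with < ", min_cells,
            " cells: ", paste(skipped, collapse = ", "))
  if (length(usable) < 2)
    stop("domain '", domain, "' needs >= 2 stages with >= ", min_cells,
         " cells")
  scaled <- as.matrix(norm$scaled[, in_dom, drop = FALSE])
  lognorm <- as.matrix(norm$lognorm[, in_dom, drop = FALSE])
  counts <- as.matrix(norm$counts[, in_dom, drop = FALSE])
  stage_of <- meta$stage[in_dom]
  res <- list()
  for (st in usable) {
    grp_in <- stage_of == st
    grp_out <- stage_of %in% setdiff(usable, st)
    pct_in <- rowMeans(counts[, grp_in, drop = FALSE] > 0)
    pct_out <- rowMeans(counts[, grp_out, drop = FALSE] > 0)
    lnfc <- log((rowMeans(scaled[, grp_in, drop = FALSE]) + 1) /
                (rowMeans(scaled[, grp_out, drop = FALSE]) + 1))
    test_idx <- which(pmax(pct_in, pct_out) >= min_pct &
                      abs(lnfc) >= lfc_threshold)
    if (!length(test_idx)) next
    p <- vapply(test_idx, function(g)
      rank_sum_test(lognorm[g, grp_in], lognorm[g, grp_out])$p.value,
      numeric(1))
    p_adj <- pmin(1, p * length(test_idx))
    sig <- p_adj < alpha
    if (!any(sig)) next
    res[[st]] <- data.frame(gene = rownames(counts)[test_idx][sig],
                            domain = domain, stage = st,
                            ln_fold_change = lnfc[test_idx][sig],
                            pct_in = pct_in[test_idx][sig],
                            pct_out = pct_out[test_idx][sig],
                            p = p[sig], p_adj = p_adj[sig],
                            stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res)
  else data.frame(gene = character(0), domain = character(0),
                  stage = character(0), ln_fold_change = numeric(0),
                  pct_in = numeric(0), pct_out = numeric(0),
                  p = numeric(0), p_adj = numeric(0))
  rownames(out) <- NULL
  out
}

#' Cross-domain consistency filter
#'
#' Keeps genes returned as a significant stage marker (any stage) in
#' strictly more than \code{min_domains} progenitor domains, after dropping
#' the excluded domains (dp6 by default, which has too few cells).
#'
#' @param per_domain_markers named list (domain -> character vector of
#'   marker genes) or a [stage_markers()] data.frame covering several
#'   domains.
#' @param min_domains a gene must be a marker in more than this many
#'   domains.
#' @param excluded_domains domains dropped before counting.
#' @return List of class \code{temporal_gene_set}: \code{genes},
#'   \code{domain_hit_counts}, \code{tf_subset} (NULL until
#'   [subset_tfs()]).
#' @export
cross_domain_filter <- function(per_domain_markers, min_domains = 7L,
                                excluded_domains = "dp6") {
  if (is.data.frame(per_domain_markers))
    per_domain_markers <- lapply(
      split(per_domain_markers$gene, per_domain_markers$domain), unique)
  sets <- per_domain_markers[!names(per_domain_markers) %in%
                               excluded_domains]
  hits <- table(unlist(lapply(sets, unique)))
  genes <- names(hits)[hits > min_domains]
  structure(list(genes = genes,
                 domain_hit_counts = stats::setNames(as.integer(hits),
                                                     names(hits)),
                 tf_subset = NULL),
            class = "temporal_gene_set")
}

#' Intersect a gene set with a transcription-factor list
#'
#' @param genes character vector or a \code{temporal_gene_set}.
#' @param tf_list path to a one-symbol-per-line text file, or a character
#'   vector of TF symbols. The package bundles a miniature mouse TF list at
#'   \code{system.file("extdata", "mouse_tfs_mini.txt", package =
#'   "tempocode")}.
#' @return For a gene-set input, the set with \code{tf_subset} filled in;
#'   otherwise the intersection (input order preserved).
#' @export
subset_tfs <- function(genes, tf_list) {
  if (is.character(tf_list) && length(tf_list) == 1 && file.exists(tf_list))
    tf_list <- readLines(tf_list)
  tf_list <- trimws(tf_list)
  tf_list <- tf_list[nzchar(tf_list)]
  if (inherits(genes, "temporal_gene_set")) {
    genes$tf_subset <- genes$genes[genes$genes %in% tf_list]
    return(genes)
  }
  genes[genes %in% tf_list]
}

#' Group-mean z-score matrix for heatmaps
#'
#' Mean log-normalised expression per group, then z-scored per gene across
#' groups (row mean 0, sd 1). Zero-variance rows become rows of zeros.
#'
#' @param norm a [normalize_counts()] result, or a genes x cells matrix of
#'   log-scale values.
#' @param groups grouping vector over cells (e.g. interaction of domain
#'   and stage); its factor-level order fixes the column order.
#' @param genes optional gene subset.
#' @return genes x groups matrix.
#' @export
zscore_matrix <- function(norm, groups, genes = NULL) {
  mat <- if (inherits(norm, "norm_counts")) norm$lognorm else norm
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  means <- sapply(levels(groups), function(g)
    Matrix::rowMeans(mat[, groups == g, drop = FALSE]))
  mu <- rowMeans(means)
  sd <- apply(means, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    message(sum(flat), " constant gene(s) set to zero rows")
    sd[flat] <- 1
  }
  z <- (means - mu) / sd
  z[flat, ] <- 0
  z
}

#' Discover temporal genes across progenitor domains
#'
#' Full marker workflow: per-domain stage-wise DE, the cross-domain filter,
#' and the TF subset.
#'
#' @param norm a [normalize_counts()] result.
#' @param tf_list TF symbols (vector or file); NULL skips the TF subset.
#' @param min_domains,excluded_domains see [cross_domain_filter()].
#' @param ... passed to [stage_markers()].
#' @return A \code{temporal_gene_set} with an additional
#'   \code{marker_table} element (all per-domain significant markers).
#' @export
find_temporal_genes <- function(norm, tf_list = NULL, min_domains = 7L,
                                excluded_domains = "dp6", ...) {
  domains <- setdiff(unique(norm$cell_meta$domain), excluded_domains)
  tabs <- lapply(domains, function(d) stage_markers(norm, d, ...))
  marker_table <- do.call(rbind, tabs)
  gs <- cross_domain_filter(marker_table, min_domains, excluded_domains)
  if (!is.null(tf_list)) gs <- subset_tfs(gs, tf_list)
  gs$marker_table <- marker_table
  gs
}
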