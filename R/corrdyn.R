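#' Pairwise Spearman correlation matrix over cells
#'
#' @param expr genes x cells matrix of expression values (any monotone
#'   transform of counts gives the same result).
#' @param genes optional gene subset.
#' @return Symmetric genes x genes Spearman matrix with unit diagonal.
#' @export
spearman_matrix <- function(expr, genes = NULL) {
  if (!is.null(genes)) expr <- expr[genes, , drop = FALSE]
  if (ncol(expr) < 3) stop("need >= 3 cells")
  m <- stats::cor(t(as.matrix(expr)), method = "spearman")
  diag(m) <- 1
  m
}

#' Rank all genes by Spearman correlation to a reference gene
#'
#' The reference ranks first with r = 1; remaining genes are ordered by
#' descending correlation. Genes in \code{highlight} are flagged so
#' rank plots can mark, e.g., the temporal TFs.
#'
#' @param expr genes x cells expression matrix.
#' @param reference_gene row name of the reference.
#' @param highlight gene symbols to flag.
#' @return data.frame gene, r, rank, highlighted (sorted by rank).
#' @export
correlation_rank <- function(expr, reference_gene,
                             highlight = character()) {
  if (!reference_gene %in% rownames(expr))
    stop("reference gene '", reference_gene, "' not in matrix")
  ref <- as.numeric(expr[reference_gene, ])
  if (sum(ref != 0) < 3)
    stop("reference gene must be expressed in >= 3 cells")
  r <- apply(as.matrix(expr), 1, function(v)
    suppressWarnings(stats::cor(ref, v, method = "spearman")))
  r[reference_gene] <- 1
  ord <- order(-r, names(r) != reference_gene)
  out <- data.frame(gene = names(r)[ord], r = unname(r[ord]),
                    rank = seq_along(r),
                    highlighted = names(r)[ord] %in% highlight,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-gene stage profiles: log-scale stage means, z-scored across stages
#'
#' @param expr genes x samples matrix; values are log1p-transformed first
#'   when \code{log1p_transform} is TRUE (use for linear-scale input).
#' @param stages stage label per sample column; profile columns follow the
#'   order of \code{unique(stages)} (or the factor levels).
#' @param log1p_transform log the values before averaging.
#' @return genes x stages matrix of z-scored profiles (constant genes
#'   become zero rows, with a message).
#' @export
stage_profiles <- function(expr, stages, log1p_transform = FALSE) {
  stopifnot(ncol(expr) == length(stages))
  mat <- as.matrix(expr)
  if (log1p_transform) mat <- log1p(mat)
  stages <- if (is.factor(stages)) droplevels(stages)
            else factor(stages, levels = unique(stages))
  means <- sapply(levels(stages), function(s)
    rowMeans(mat[, stages == s, drop = FALSE]))
  mu <- rowMeans(means)
  sd <- apply(means, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) message(sum(flat), " constant gene(s) set to zero rows")
  sd[flat] <- 1
  z <- (means - mu) / sd
  z[flat, ] <- 0
  z
}

#' Partition genes by in-vivo / in-vitro correlation
#'
#' Pairs the stage columns of the two profile matrices positionally
#' (default: 5 in-vivo stages e9.5-e13.5 against 5 in-vitro days D5-D9),
#' intersects the gene universes, computes the Pearson correlation per
#' gene, and classes each gene as correlated (r > 0.5), anticorrelated
#' (r < -0.5) or uncorrelated (everything else, including genes whose
#' correlation is undefined because a profile is constant; those are
#' flagged).
#'
#' @param in_vivo,in_vitro genes x stages profile matrices (same number of
#'   columns; see [stage_profiles()]).
#' @param tf_list optional TF symbols for per-class TF counts.
#' @return data.frame gene, r, class, flagged, with a \code{summary}
#'   attribute (class counts and, if \code{tf_list} given, TF counts).
#' @export
partition_by_correlation <- function(in_vivo, in_vitro, tf_list = NULL) {
  if (ncol(in_vivo) != ncol(in_vitro))
    stop("profiles must cover the same number of paired stages")
  genes <- intersect(rownames(in_vivo), rownames(in_vitro))
  if (!length(genes)) stop("no genes in common")
  r <- vapply(genes, function(g) {
    a <- in_vivo[g, ]; b <- in_vitro[g, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  cls <- ifelse(is.na(r), "uncorrelated",
         ifelse(r > 0.5, "correlated",
         ifelse(r < -0.5, "anticorrelated", "uncorrelated")))
  out <- data.frame(gene = genes, r = unname(r), class = unname(cls),
                    flagged = is.na(r), stringsAsFactors = FALSE)
  counts <- c(n_correlated = sum(cls == "correlated"),
              n_uncorrelated = sum(cls == "uncorrelated"),
              n_anticorrelated = sum(cls == "anticorrelated"))
  if (!is.null(tf_list)) {
    if (length(tf_list) == 1 && file.exists(tf_list))
      tf_list <- readLines(tf_list)
    tf <- out$gene %in% trimws(tf_list)
    counts <- c(counts,
                n_tf_correlated = sum(tf & cls == "correlated"),
                n_tf_uncorrelated = sum(tf & cls == "uncorrelated"),
                n_tf_anticorrelated = sum(tf & cls == "anticorrelated"))
  }
  attr(out, "summary") <- counts
  out
}
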