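#' Order cells along a lineage path in a 2D embedding
#'
#' Minimal lineage ordering on a provided embedding and clustering: builds
#' the minimum spanning tree over cluster centroids (Euclidean distance in
#' the embedding), takes the unique MST path from the start to the end
#' cluster, projects every cell of the path's clusters onto the
#' piecewise-linear centroid path, and rescales arc-length position to
#' [0, 1]. When no end cluster is given, the centroid farthest from the
#' start centroid is used. Paths named in \code{exclusion_list} are marked
#' excluded and skipped downstream (mirroring manual curation of
#' trajectories that curve back or cross); an advisory self-intersection
#' check warns but never auto-excludes.
#'
#' @param embedding cells x 2 numeric matrix with cell ids as rownames.
#' @param clusters cluster label per cell.
#' @param start_cluster,end_cluster cluster ids; \code{end_cluster = NULL}
#'   picks the centroid farthest from the start.
#' @param exclusion_list path names ("start->end") to exclude.
#' @return List of class \code{lineage_path}: \code{cluster_sequence},
#'   \code{pseudotime} (named vector over path cells), \code{path_name},
#'   \code{excluded}, \code{reason}.
#' @export
order_cells <- function(embedding, clusters, start_cluster,
                        end_cluster = NULL, exclusion_list = character()) {
  stopifnot(ncol(embedding) == 2, nrow(embedding) == length(clusters))
  clusters <- as.character(clusters)
  if (!start_cluster %in% clusters) stop("unknown start cluster")
  cents <- do.call(rbind, lapply(split(seq_along(clusters), clusters),
                                 function(i) colMeans(embedding[i, ,
                                                                drop = FALSE])))
  if (is.null(end_cluster)) {
    d0 <- sqrt(rowSums((cents - matrix(cents[start_cluster, ],
                                       nrow(cents), 2,
                                       byrow = TRUE))^2))
    end_cluster <- names(which.max(d0))
  }
  if (!end_cluster %in% rownames(cents)) stop("unknown end cluster")
  if (identical(start_cluster, end_cluster))
    stop("start and end cluster must differ")
  path_name <- paste0(start_cluster, "->", end_cluster)
  if (path_name %in% exclusion_list)
    return(structure(list(cluster_sequence = character(0),
                          pseudotime = numeric(0),
                          path_name = path_name, excluded = TRUE,
                          reason = "listed in exclusion_list"),
                     class = "lineage_path"))
  dmat <- as.matrix(stats::dist(cents))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  vp <- igraph::shortest_paths(tree,
                               from = which(rownames(cents) ==
                                              start_cluster),
                               to = which(rownames(cents) == end_cluster))
  seqn <- rownames(cents)[as.integer(vp$vpath[[1]])]
  poly <- cents[seqn, , drop = FALSE]
  if (.polyline_self_intersects(poly))
    warning("centroid path '", path_name, "' intersects itself; ",
            "consider excluding it")
  seg_len <- sqrt(rowSums(diff(poly)^2))
  cum0 <- c(0, cumsum(seg_len))
  total <- cum0[length(cum0)]
  on_path <- clusters %in% seqn
  pts <- embedding[on_path, , drop = FALSE]
  arc <- vapply(seq_len(nrow(pts)), function(i) {
    best <- Inf; pos <- 0
    for (s in seq_len(nrow(poly) - 1)) {
      a <- poly[s, ]; b <- poly[s + 1, ]
      ab <- b - a
      t <- sum((pts[i, ] - a) * ab) / sum(ab^2)
      t <- min(1, max(0, t))
      proj <- a + t * ab
      d2 <- sum((pts[i, ] - proj)^2)
      if (d2 < best) { best <- d2; pos <- cum0[s] + t * seg_len[s] }
    }
    pos
  }, numeric(1))
  pt <- if (total > 0) arc / total else arc
  names(pt) <- rownames(embedding)[on_path]
  structure(list(cluster_sequence = seqn, pseudotime = pt,
                 path_name = path_name, excluded = FALSE,
                 reason = NA_character_),
            class = "lineage_path")
}

# advisory check: do any two non-adjacent segments of the polyline cross?
.polyline_self_intersects <- function(poly) {
  ns <- nrow(poly) - 1
  if (ns < 3) return(FALSE)
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(ns - 2)) for (j in (i + 2):ns) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    c <- poly[j, ]; d <- poly[j + 1, ]
    if (ccw(a, c, d) != ccw(b, c, d) && ccw(a, b, c) != ccw(a, b, d))
      return(TRUE)
  }
  FALSE
}

#' LOESS smoothing of expression along pseudotime, evaluated at bin midpoints
#'
#' Local linear regression (tricube weights over the span fraction of
#' nearest neighbours) fitted to (pseudotime, expression) and evaluated at
#' the midpoints of \code{n_bins} equal pseudotime bins. With fewer than
#' 10 points the local window is unstable and a global linear fit is used
#' instead (with a message).
#'
#' @param x pseudotime vector.
#' @param y expression vector.
#' @param span LOESS span in (0, 1].
#' @param n_bins number of bins over [0, 1].
#' @return Numeric vector of \code{n_bins} fitted values.
#' @export
loess_smooth <- function(x, y, span = 0.75, n_bins = 30L) {
  stopifnot(length(x) == length(y), span > 0, span <= 1)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  # evaluate within the observed pseudotime range to avoid extrapolation
  mids_eval <- pmin(pmax(mids, min(x)), max(x))
  if (length(x) < 10) {
    message("fewer than 10 points; falling back to a global linear fit")
    fit <- stats::lm(y ~ x)
    return(unname(stats::predict(fit,
                                 newdata = data.frame(x = mids_eval))))
  }
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  unname(stats::predict(fit, newdata = data.frame(x = mids_eval)))
}

#' Bin pseudotime expression and normalise each gene across all stages
#'
#' For each stage's lineage path, fits LOESS curves of log-normalised
#' expression against pseudotime and evaluates them at the midpoints of
#' \code{n_bins} bins (negative fits are clamped to 0); then divides each
#' gene by its maximum over the bins of ALL stages, so the global per-gene
#' maximum is exactly 1 (all-zero genes stay 0 and are flagged).
#'
#' @param paths named list (stage -> [order_cells()] result); excluded
#'   paths are dropped.
#' @param expr genes x cells matrix (e.g. \code{lognorm} from
#'   [normalize_counts()]); columns must cover the path cells.
#' @param genes optional gene subset.
#' @param n_bins number of pseudotime bins.
#' @param span LOESS span.
#' @return List of class \code{binned_expression}: \code{stages} (named
#'   list of gene x n_bins matrices), \code{flagged_zero} (all-zero
#'   genes), \code{n_bins}.
#' @export
bin_and_normalize <- function(paths, expr, genes = NULL, n_bins = 30L,
                              span = 0.75) {
  paths <- Filter(function(p) !p$excluded, paths)
  if (!length(paths)) stop("no non-excluded path available")
  if (is.null(genes)) genes <- rownames(expr)
  raw <- lapply(paths, function(p) {
    cells <- names(p$pseudotime)
    m <- t(vapply(genes, function(g)
      loess_smooth(p$pseudotime, as.numeric(expr[g, cells]),
                   span = span, n_bins = n_bins),
      numeric(n_bins)))
    m[m < 0] <- 0
    rownames(m) <- genes
    m
  })
  gmax <- Reduce(pmax, lapply(raw, function(m) apply(m, 1, max)))
  flagged <- genes[gmax == 0]
  gmax[gmax == 0] <- 1
  out <- lapply(raw, function(m) m / gmax)
  structure(list(stages = out, flagged_zero = flagged, n_bins = n_bins),
            class = "binned_expression")
}

#' Expression-wave order statistic
#'
#' Tests whether the early, intermediate and late TF groups peak in that
#' order along pseudotime. Per stage, a group's peak is the median argmax
#' bin over its expressed genes (groups whose genes are all zero make the
#' stage's verdict undefined and flag it); the stage passes when
#' early < intermediate < late strictly, and the overall verdict is TRUE
#' when every defined stage passes (and at least one is defined).
#'
#' @param binned a [bin_and_normalize()] result.
#' @param gene_groups ordered named list (early, intermediate, late) of
#'   gene symbols.
#' @return List: \code{verdict}, \code{peak_table} (stage x group median
#'   peak bins), \code{per_stage} (logical, NA when undefined).
#' @export
wave_order <- function(binned, gene_groups) {
  stopifnot(inherits(binned, "binned_expression"),
            length(gene_groups) == 3L, all(lengths(gene_groups) >= 1L))
  stages <- names(binned$stages)
  peak_table <- matrix(NA_real_, length(stages), 3,
                       dimnames = list(stages, names(gene_groups)))
  per_stage <- stats::setNames(rep(NA, length(stages)), stages)
  for (st in stages) {
    m <- binned$stages[[st]]
    peaks <- vapply(gene_groups, function(gg) {
      gg <- intersect(gg, rownames(m))
      expressed <- gg[apply(m[gg, , drop = FALSE], 1, max) > 0]
      if (!length(expressed)) return(NA_real_)
      stats::median(apply(m[expressed, , drop = FALSE], 1, which.max))
    }, numeric(1))
    peak_table[st, ] <- peaks
    if (anyNA(peaks)) next
    per_stage[st] <- peaks[1] < peaks[2] && peaks[2] < peaks[3]
  }
  defined <- !is.na(per_stage)
  list(verdict = any(defined) && all(per_stage[defined]),
       peak_table = peak_table,
       per_stage = per_stage)
}
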