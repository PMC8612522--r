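#' Specification of a synthetic progenitor count matrix
#'
#' Describes a genes x cells negative-binomial count matrix with cells
#' annotated by progenitor domain, developmental stage and cell type, and a
#' planted set of temporal genes whose mean expression changes monotonically
#' (up or down, \code{planted_fold} between first and last stage) in a fixed
#' number of domains and stays flat elsewhere. dp6 is deliberately sparse
#' (few cells), emulating its low abundance in real spinal-cord data, and
#' planted programs live in the well-populated domains.
#'
#' @param n_genes total genes (planted included).
#' @param domains progenitor domain labels.
#' @param stages ordered stage labels.
#' @param cells_per_group cells per domain x stage (except dp6).
#' @param dp6_cells cells per stage in dp6.
#' @param n_planted number of planted temporal genes.
#' @param planted_domain_count number of domains each planted gene is
#'   temporal in (drawn from the non-dp6 domains).
#' @param planted_fold fold change between first and last stage.
#' @param nb_dispersion NB size parameter (smaller = more overdispersed).
#' @param libsize_meanlog,libsize_sdlog log-normal cell size-factor
#'   parameters.
#' @param planted_symbols gene symbols given to the planted genes (real
#'   temporal-gene names, so the TF-subset step has something to find);
#'   padded with \code{tgene###} when \code{n_planted} exceeds them.
#' @return An object of class \code{counts_spec}.
#' @export
counts_spec <- function(n_genes = 315L,
                        domains = c("dp1", "dp2", "dp3", "dp4", "dp5", "dp6",
                                    "p0", "p1", "p2", "pMN", "p3"),
                        stages = c("e9.5", "e10.5", "e11.5", "e12.5", "e13.5"),
                        cells_per_group = 40L,
                        dp6_cells = 5L,
                        n_planted = 15L,
                        planted_domain_count = 9L,
                        planted_fold = 4,
                        nb_dispersion = 2,
                        libsize_meanlog = 0,
                        libsize_sdlog = 0.3,
                        planted_symbols = c("Nfia", "Nfib", "Nfix", "Sox9",
                                            "Zbtb20", "Npas3", "Tcf4",
                                            "Thra", "Lin28a", "Lin28b",
                                            "Hmga1", "Hmga2", "Nr6a1",
                                            "Dnajc2", "Tcf7l2")) {
  stopifnot(n_genes >= n_planted, n_planted >= 0,
            planted_domain_count >= 1,
            planted_domain_count <= sum(domains != "dp6"),
            planted_fold > 0, nb_dispersion > 0,
            cells_per_group >= 1, length(stages) >= 2)
  if (n_genes < n_planted) stop("n_genes must be at least n_planted")
  structure(as.list(environment()), class = "counts_spec")
}

#' Generate a synthetic count matrix with planted temporal genes
#'
#' @param spec a [counts_spec()].
#' @param seed integer seed.
#' @return A list of class \code{synth_counts}: \code{counts} (sparse
#'   dgCMatrix, genes x cells), \code{cell_meta} (cell_id, domain, stage,
#'   cell_type), and \code{planted} (gene, direction, domains as a
#'   semicolon-joined string) for the ground truth.
#' @export
generate_counts <- function(spec = counts_spec(), seed = 1L) {
  stopifnot(inherits(spec, "counts_spec"))
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(spec$n_genes))
    planted_idx <- seq_len(spec$n_planted)
    if (spec$n_planted > 0) {
      syms <- c(spec$planted_symbols,
                sprintf("tgene%03d", seq_len(spec$n_planted)))
      genes[planted_idx] <- syms[planted_idx]
    }

    meta <- do.call(rbind, lapply(spec$domains, function(d) {
      nper <- if (d == "dp6") spec$dp6_cells else spec$cells_per_group
      do.call(rbind, lapply(spec$stages, function(s)
        data.frame(domain = d, stage = s,
                   cell_type = "progenitor",
                   n = seq_len(nper), stringsAsFactors = FALSE)))
    }))
    meta$cell_id <- sprintf("cell%05d", seq_len(nrow(meta)))
    meta <- meta[, c("cell_id", "domain", "stage", "cell_type")]
    ncell <- nrow(meta)

    baseline <- stats::rlnorm(spec$n_genes, log(0.5), 0.8)
    if (spec$n_planted > 0)
      baseline[planted_idx] <- stats::rlnorm(spec$n_planted, log(2), 0.3)
    sizef <- stats::rlnorm(ncell, spec$libsize_meanlog, spec$libsize_sdlog)

    nondp6 <- setdiff(spec$domains, "dp6")
    planted <- NULL
    stage_idx <- match(meta$stage, spec$stages)
    nstage <- length(spec$stages)
    # per-stage multiplier on a log-linear ramp from 1 to fold (or down)
    ramp <- spec$planted_fold^((seq_len(nstage) - 1) / (nstage - 1))

    mu <- matrix(baseline, spec$n_genes, ncell) *
      matrix(sizef, spec$n_genes, ncell, byrow = TRUE)
    if (spec$n_planted > 0) {
      planted <- data.frame(gene = genes[planted_idx],
                            direction = rep(c("up", "down"),
                                            length.out = spec$n_planted),
                            domains = NA_character_,
                            stringsAsFactors = FALSE)
      for (j in seq_len(spec$n_planted)) {
        doms <- sort(sample(nondp6, spec$planted_domain_count))
        planted$domains[j] <- paste(doms, collapse = ";")
        mult <- if (planted$direction[j] == "up") ramp else rev(ramp)
        in_dom <- meta$domain %in% doms
        mu[planted_idx[j], in_dom] <-
          mu[planted_idx[j], in_dom] * mult[stage_idx[in_dom]]
      }
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = spec$nb_dispersion),
                     spec$n_genes, ncell,
                     dimnames = list(genes, meta$cell_id))
    list(counts = methods::as(methods::as(Matrix::Matrix(counts,
                                                         sparse = TRUE),
                                          "CsparseMatrix"), "dMatrix"),
         cell_meta = meta,
         planted = planted,
         spec = spec) |>
      structure(class = "synth_counts")
  })
}

#' Write a count matrix as MatrixMarket + metadata TSVs
#'
#' Writes \code{matrix.mtx} (genes x cells), \code{genes.tsv} (one symbol
#' per line) and \code{cells.tsv} (cell_id, domain, stage, cell_type) into
#' a directory.
#'
#' @param x a \code{synth_counts} object or a list with \code{counts} and
#'   \code{cell_meta}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_counts <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param dir directory containing matrix.mtx, genes.tsv, cells.tsv.
#' @return A list with \code{counts} (dgCMatrix with dimnames) and
#'   \code{cell_meta}.
#' @export
read_counts <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, meta$cell_id)
  list(counts = counts, cell_meta = meta)
}
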