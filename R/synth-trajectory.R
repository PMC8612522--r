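#' Generate a synthetic neuronal differentiation trajectory
#'
#' Emulates a single neuronal lineage captured at one or more developmental
#' stages: each cell has a latent maturation in [0, 1] (0 = just born),
#' a 2D embedding position along a noisy arc, a cluster label from
#' contiguous maturation segments, and NB counts for three sequential
#' waves of temporal TFs (early Onecut, intermediate Zfhx/Pou2f2, late
#' Nfi/Neurod) whose mean expression is a Gaussian bump over maturation
#' peaked at pseudotime bins 5, 15 and 25 of 30, plus flat background
#' genes. Birthdates are back-computed from maturation so that, at a fixed
#' collection stage, later-born neurons sit earlier on the trajectory.
#'
#' @param stages character vector of stage labels (one trajectory each).
#' @param cells_per_stage cells per stage.
#' @param n_clusters clusters per trajectory (contiguous maturation bands).
#' @param gene_groups named list of gene symbols for the early,
#'   intermediate and late waves, in that order.
#' @param n_background flat non-temporal genes.
#' @param peak_positions maturation positions of the three wave peaks
#'   (defaults are the midpoints of bins 5, 15, 25 of 30).
#' @param peak_width Gaussian bump width (maturation units).
#' @param amplitude peak mean count of wave genes.
#' @param nb_dispersion NB size parameter.
#' @param embedding_noise_sd Gaussian noise on the embedding arc.
#' @param seed integer seed.
#' @return List of class \code{synth_trajectory}: \code{counts} (genes x
#'   cells), \code{cell_meta} (cell_id, stage, maturation, birthdate,
#'   cluster), \code{embedding} (cells x 2), \code{gene_groups},
#'   \code{start_cluster}, \code{end_cluster}.
#' @export
generate_trajectory <- function(stages = c("e11.5", "e12.5", "e13.5"),
                                cells_per_stage = 400L,
                                n_clusters = 6L,
                                gene_groups = list(
                                  early = c("Onecut1", "Onecut2"),
                                  intermediate = c("Zfhx3", "Pou2f2"),
                                  late = c("Nfia", "Nfib", "Neurod2")),
                                n_background = 30L,
                                peak_positions = c(4.5, 14.5, 24.5) / 30,
                                peak_width = 0.12,
                                amplitude = 8,
                                nb_dispersion = 3,
                                embedding_noise_sd = 0.35,
                                seed = 1L) {
  stopifnot(length(gene_groups) == 3L, all(lengths(gene_groups) >= 1L),
            length(peak_positions) == 3L, cells_per_stage >= 30L,
            n_clusters >= 2L)
  with_seed(seed, {
    wave_genes <- unlist(gene_groups, use.names = FALSE)
    genes <- c(wave_genes, sprintf("bg%03d", seq_len(n_background)))
    peaks <- rep(peak_positions, times = lengths(gene_groups))

    meta_list <- list(); emb_list <- list(); cnt_list <- list()
    for (st in stages) {
      n <- cells_per_stage
      mat <- stats::runif(n)
      stage_day <- suppressWarnings(as.numeric(sub("^e", "", st)))
      if (is.na(stage_day)) stage_day <- 13.5
      birthdate <- stage_day - mat * (stage_day - 9.0)
      cl <- paste0(st, "_c", pmin(n_clusters, floor(mat * n_clusters) + 1L))
      ang <- mat * pi
      emb <- cbind(x = 10 * cos(ang), y = 10 * sin(ang)) +
        matrix(stats::rnorm(2 * n, 0, embedding_noise_sd), n, 2)
      mu <- matrix(0.5, length(genes), n,
                   dimnames = list(genes, NULL))
      for (g in seq_along(wave_genes))
        mu[g, ] <- 0.2 + amplitude *
          exp(-(mat - peaks[g])^2 / (2 * peak_width^2))
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = nb_dispersion),
                    nrow(mu), ncol(mu), dimnames = dimnames(mu))
      meta_list[[st]] <- data.frame(stage = st, maturation = mat,
                                    birthdate = birthdate, cluster = cl,
                                    stringsAsFactors = FALSE)
      emb_list[[st]] <- emb
      cnt_list[[st]] <- cnt
    }
    meta <- do.call(rbind, meta_list)
    meta$cell_id <- sprintf("tcell%05d", seq_len(nrow(meta)))
    rownames(meta) <- NULL
    meta <- meta[, c("cell_id", "stage", "maturation", "birthdate",
                     "cluster")]
    embedding <- do.call(rbind, emb_list)
    rownames(embedding) <- meta$cell_id
    counts <- do.call(cbind, cnt_list)
    colnames(counts) <- meta$cell_id
    structure(list(counts = counts, cell_meta = meta,
                   embedding = embedding, gene_groups = gene_groups,
                   start_suffix = "_c1",
                   end_suffix = paste0("_c", n_clusters)),
              class = "synth_trajectory")
  })
}

#' Generate paired in-vivo / in-vitro stage profiles with planted classes
#'
#' For benchmarking the correlation partition: a fraction of genes share
#' their stage dynamics between the two conditions (up to additive Gaussian
#' noise), a fraction has independent dynamics, and a fraction has
#' sign-flipped dynamics. Profiles are z-scored across stages on each side,
#' as in the partition's input contract.
#'
#' @param n_genes number of genes.
#' @param fractions named numeric (correlated, uncorrelated, anticorrelated)
#'   mixture; normalised to sum 1.
#' @param n_stages number of paired stages.
#' @param noise_sd additive Gaussian noise sd (profiles have unit sd).
#' @param seed integer seed.
#' @return List with \code{vivo}, \code{vitro} (genes x stages matrices)
#'   and \code{truth} (planted class per gene).
#' @export
generate_profile_pairs <- function(n_genes = 1000L,
                                   fractions = c(correlated = 0.8,
                                                 uncorrelated = 0.1,
                                                 anticorrelated = 0.1),
                                   n_stages = 5L,
                                   noise_sd = 0.2,
                                   seed = 1L) {
  stopifnot(n_genes >= 1, n_stages >= 3, all(fractions >= 0))
  fractions <- fractions / sum(fractions)
  with_seed(seed, {
    truth <- sample(names(fractions), n_genes, replace = TRUE,
                    prob = fractions)
    zrow <- function(m) {
      mu <- rowMeans(m); sd <- apply(m, 1, stats::sd)
      sd[sd == 0] <- 1
      (m - mu) / sd
    }
    base <- zrow(matrix(stats::rnorm(n_genes * n_stages), n_genes))
    other <- zrow(matrix(stats::rnorm(n_genes * n_stages), n_genes))
    noise <- function() matrix(stats::rnorm(n_genes * n_stages, 0,
                                            noise_sd), n_genes)
    vivo <- base + noise()
    vitro_core <- base
    vitro_core[truth == "anticorrelated", ] <-
      -base[truth == "anticorrelated", ]
    vitro_core[truth == "uncorrelated", ] <- other[truth == "uncorrelated", ]
    vitro <- vitro_core + noise()
    gn <- sprintf("pgene%04d", seq_len(n_genes))
    dimnames(vivo) <- dimnames(vitro) <-
      list(gn, paste0("stage", seq_len(n_stages)))
    list(vivo = zrow(vivo), vitro = zrow(vitro),
         truth = stats::setNames(truth, gn))
  })
}
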