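#' Configuration for the synthetic multiome generator
#'
#' Collects every parameter of the paired RNA/ATAC simulator into a validated
#' list. The generator plants a known regulatory architecture on a single
#' synthetic chromosome: each gene receives a block of candidate peaks inside
#' the +/- `link_window_bp` window around its TSS, a subset of which are true
#' enhancers whose accessibility drives the gene's expression, and each true
#' enhancer carries the binding motif of an assigned transcription factor.
#'
#' Accessibility follows a logistic model: each peak has a per-state baseline
#' open probability plus a smooth gradient along the embedding, so cells that
#' are neighbours in the embedding have similar accessibility. True enhancers
#' are open with probability `atac_open_prob_high` in the gene's designated
#' high state and `atac_open_prob_low` elsewhere. RNA counts are negative
#' binomial with log-mean equal to a gene baseline plus `link_effect` times the
#' z-scored accessibility probability of each true enhancer, so `link_effect`
#' is the planted standardized effect per enhancer.
#'
#' @param n_states Number of cell states.
#' @param cells_per_state_per_modality Cells per state for each of the RNA and
#'   ATAC modalities.
#' @param n_patients Number of patients (metacell grouping labels).
#' @param n_genes,n_peaks,n_tfs Numbers of genes, accessibility peaks and
#'   transcription factors. The first `n_tfs` genes act as the TFs and the
#'   motif set is named after them. Requires `n_tfs >= n_states`.
#' @param genome_length_bp Length of the single synthetic chromosome.
#' @param link_window_bp Enhancer-promoter window half-width (bp).
#' @param n_true_links_per_gene Planted enhancers per gene.
#' @param link_effect Standardized effect of a true enhancer on its gene's
#'   log-mean expression. `0` plants no signal.
#' @param rna_noise_dispersion Negative-binomial dispersion of RNA counts.
#' @param atac_open_prob_high,atac_open_prob_low Open probability of a true
#'   enhancer in the gene's high state / other states.
#' @param motif_density Probability of a background motif hit per peak x motif.
#' @param ptx_logfc Planted log fold-change added to a random 10% of genes in
#'   post-therapy (PTX) cells; `0` disables the timepoint shift.
#' @param embedding_dims,state_separation,accessibility_gradient Embedding
#'   dimensionality, the spread of state centroids, and the scale of the
#'   within-state accessibility gradient along the embedding.
#' @param baseline_mean Median baseline mean RNA count per gene (low by
#'   default, as in sparse single-nucleus data).
#' @param rng_seed Integer seed; generation is a pure function of the seed.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_states = 3,
                         cells_per_state_per_modality = 1000,
                         n_patients = 4,
                         n_genes = 200,
                         n_peaks = 2000,
                         n_tfs = 10,
                         genome_length_bp = 250e6,
                         link_window_bp = 500000,
                         n_true_links_per_gene = 2,
                         link_effect = 0.5,
                         rna_noise_dispersion = 0.3,
                         atac_open_prob_high = 0.65,
                         atac_open_prob_low = 0.08,
                         motif_density = 0.05,
                         ptx_logfc = 0.5,
                         embedding_dims = 10,
                         state_separation = 4,
                         accessibility_gradient = 1.75,
                         baseline_mean = 2,
                         rng_seed = 1L) {
  cfg <- list(
    n_states = as.integer(n_states),
    cells_per_state_per_modality = as.integer(cells_per_state_per_modality),
    n_patients = as.integer(n_patients),
    n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks),
    n_tfs = as.integer(n_tfs),
    genome_length_bp = as.numeric(genome_length_bp),
    link_window_bp = as.numeric(link_window_bp),
    n_true_links_per_gene = as.integer(n_true_links_per_gene),
    link_effect = as.numeric(link_effect),
    rna_noise_dispersion = as.numeric(rna_noise_dispersion),
    atac_open_prob_high = as.numeric(atac_open_prob_high),
    atac_open_prob_low = as.numeric(atac_open_prob_low),
    motif_density = as.numeric(motif_density),
    ptx_logfc = as.numeric(ptx_logfc),
    embedding_dims = as.integer(embedding_dims),
    state_separation = as.numeric(state_separation),
    accessibility_gradient = as.numeric(accessibility_gradient),
    baseline_mean = as.numeric(baseline_mean),
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("n_states", "cells_per_state_per_modality", "n_patients",
              "n_genes", "n_peaks", "n_tfs", "n_true_links_per_gene",
              "embedding_dims")
  stop_if(any(vapply(cfg[counts], function(x) x < 1L, logical(1))),
          "all count parameters must be positive integers")
  probs <- c("atac_open_prob_high", "atac_open_prob_low", "motif_density")
  stop_if(any(vapply(cfg[probs], function(x) x <= 0 || x >= 1, logical(1))),
          "probabilities must lie strictly in (0, 1)")
  stop_if(cfg$link_window_bp <= 0, "link_window_bp must be > 0")
  stop_if(!is.finite(cfg$link_effect) || !is.finite(cfg$ptx_logfc),
          "effect sizes must be finite")
  stop_if(cfg$rna_noise_dispersion <= 0, "rna_noise_dispersion must be > 0")
  stop_if(cfg$n_tfs < cfg$n_states,
          "n_tfs must be >= n_states so every state has a regulator")
  peaks_per_gene <- cfg$n_peaks %/% cfg$n_genes
  stop_if(peaks_per_gene < cfg$n_true_links_per_gene + 1L,
          paste0("n_peaks too small to place in-window candidate peaks for ",
                 "every gene: need at least (n_true_links_per_gene + 1) * ",
                 "n_genes = ",
                 (cfg$n_true_links_per_gene + 1L) * cfg$n_genes))
  structure(cfg, class = "synth_config")
}

#' Generate a paired RNA/ATAC multiome with planted ground truth
#'
#' Simulates RNA and ATAC cells for each state, a low-dimensional embedding
#' with state structure, peak and promoter coordinates on one synthetic
#' chromosome, a peak-by-motif hit matrix, and a truth object recording the
#' planted enhancer-gene links, TF-target pairs, state marker genes and
#' state-specific peaks. Identical seeds give identical output.
#'
#' @param config A [synth_config()].
#'
#' @return A list of class `multiome_sim` with elements `rna` and `atac`
#'   (sparse counts, features x cells), `cell_meta` (tibble: cell, patient,
#'   timepoint, state, modality), `peaks` (tibble: peak, chrom, start, end in
#'   0-based half-open coordinates), `promoters` (tibble: gene, chrom, tss,
#'   strand), `motifs` (sparse 0/1 peak x motif matrix), `embedding` (cells x
#'   dims matrix) and `truth` (class `synth_truth`).
#' @export
generate_multiome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$rng_seed, generate_multiome_impl(config))
}

generate_multiome_impl <- function(cfg) {
  n_states <- cfg$n_states
  cps <- cfg$cells_per_state_per_modality
  n_cells <- n_states * cps * 2L
  n_genes <- cfg$n_genes
  n_peaks <- cfg$n_peaks
  ndim <- cfg$embedding_dims

  genes <- sprintf("gene%04d", seq_len(n_genes))
  tfs <- genes[seq_len(cfg$n_tfs)]
  states <- sprintf("state%d", seq_len(n_states))
  cells <- sprintf("cell%06d", seq_len(n_cells))

  state_idx <- rep(rep(seq_len(n_states), each = cps), 2L)
  modality <- rep(c("RNA", "ATAC"), each = n_states * cps)
  patient <- sample(sprintf("P%02d", seq_len(cfg$n_patients)), n_cells,
                    replace = TRUE)
  timepoint <- sample(c("DX", "PTX"), n_cells, replace = TRUE)

  # embedding: state centroids + isotropic jitter
  centroids <- matrix(rnorm(n_states * ndim, sd = cfg$state_separation),
                      n_states, ndim)
  jitter <- matrix(rnorm(n_cells * ndim), n_cells, ndim)
  embedding <- centroids[state_idx, , drop = FALSE] + jitter
  rownames(embedding) <- cells

  # genome layout: evenly spaced TSSs, candidate peak blocks around each TSS
  spacing <- floor(cfg$genome_length_bp / (n_genes + 1L))
  tss <- spacing * seq_len(n_genes)
  peaks_per_gene <- n_peaks %/% n_genes
  n_extra <- n_peaks - peaks_per_gene * n_genes
  peak_w <- 500
  half <- peak_w / 2
  block_gene <- rep(seq_len(n_genes), each = peaks_per_gene)
  mid <- tss[block_gene] +
    round(runif(length(block_gene), -cfg$link_window_bp + half,
                cfg$link_window_bp - half))
  if (n_extra > 0) {
    mid <- c(mid, round(runif(n_extra, half, cfg$genome_length_bp - half)))
    block_gene <- c(block_gene, rep(NA_integer_, n_extra))
  }
  mid <- pmin(pmax(mid, half), cfg$genome_length_bp - half)
  ord <- order(mid, seq_along(mid))
  mid <- mid[ord]
  block_gene <- block_gene[ord]
  peak_ids <- sprintf("peak%05d", seq_len(n_peaks))
  peaks <- tibble::tibble(peak = peak_ids, chrom = "chrS",
                          start = as.integer(mid - half),
                          end = as.integer(mid + half))

  # planted architecture: per-gene high state; true enhancers = first
  # n_true peaks of the gene's block (in sorted order)
  gene_hi <- sample(rep_len(seq_len(n_states), n_genes))
  tf_state <- rep_len(seq_len(n_states), cfg$n_tfs)
  gene_hi[seq_len(cfg$n_tfs)] <- tf_state  # TF genes peak in their own state
  n_true <- cfg$n_true_links_per_gene
  true_rows <- unlist(lapply(seq_len(n_genes), function(g) {
    which(block_gene == g)[seq_len(n_true)]
  }))
  true_gene_idx <- rep(seq_len(n_genes), each = n_true)

  # accessibility model: logit pi = a[peak, state] + gradient . jitter
  a <- matrix(rnorm(n_peaks * n_states, mean = -1, sd = 1), n_peaks, n_states)
  a[true_rows, ] <- qlogis(cfg$atac_open_prob_low)
  a[cbind(true_rows, gene_hi[true_gene_idx])] <- qlogis(cfg$atac_open_prob_high)
  grad <- matrix(rnorm(n_peaks * ndim), n_peaks, ndim)
  grad <- grad / sqrt(rowSums(grad^2)) * cfg$accessibility_gradient

  pi_for <- function(cell_rows, peak_rows = seq_len(n_peaks)) {
    plogis(a[peak_rows, state_idx[cell_rows], drop = FALSE] +
             grad[peak_rows, , drop = FALSE] %*%
             t(jitter[cell_rows, , drop = FALSE]))
  }

  atac_cols <- which(modality == "ATAC")
  rna_cols <- which(modality == "RNA")

  pi_atac <- pi_for(atac_cols)
  open <- matrix(rbinom(length(pi_atac), 1L, pi_atac), nrow = n_peaks)
  atac <- open * (1L + matrix(rpois(length(open), 0.5), nrow = n_peaks))
  dimnames(atac) <- list(peak_ids, cells[atac_cols])

  # RNA: log-mean = baseline + link_effect * z(pi) per true enhancer (+ PTX)
  log_base <- rnorm(n_genes, mean = log(cfg$baseline_mean), sd = 0.5)
  pi_rna_true <- pi_for(rna_cols, true_rows)
  pi_z <- t(apply(pi_rna_true, 1, zscore))
  eff <- rowsum(pi_z, true_gene_idx)
  ptx_up <- sort(sample(genes, max(1L, round(0.1 * n_genes))))
  log_mu <- log_base + cfg$link_effect * eff
  log_mu[match(ptx_up, genes), timepoint[rna_cols] == "PTX"] <-
    log_mu[match(ptx_up, genes), timepoint[rna_cols] == "PTX"] + cfg$ptx_logfc
  size <- 1 / cfg$rna_noise_dispersion
  rna <- matrix(rnbinom(n_genes * length(rna_cols), mu = exp(log_mu),
                        size = size), nrow = n_genes)
  dimnames(rna) <- list(genes, cells[rna_cols])

  # motifs: background Bernoulli hits on non-enhancer peaks; planted
  # enhancers carry exactly their designated regulator's motif so the
  # planted TF-target truth stays identifiable
  hits <- matrix(rbinom(n_peaks * cfg$n_tfs, 1L, cfg$motif_density),
                 n_peaks, cfg$n_tfs, dimnames = list(peak_ids, tfs))
  hits[true_rows, ] <- 0L
  regulator <- integer(length(true_rows))
  for (i in seq_along(true_rows)) {
    pool <- which(tf_state == gene_hi[true_gene_idx[i]])
    regulator[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    hits[true_rows[i], regulator[i]] <- 1L
  }

  true_links <- tibble::tibble(
    gene = genes[true_gene_idx],
    peak = peak_ids[true_rows],
    effect = cfg$link_effect,
    state = states[gene_hi[true_gene_idx]],
    tf = tfs[regulator]
  )
  if (cfg$link_effect > 0) {
    de_genes_by_state <- lapply(seq_len(n_states),
                                function(s) genes[gene_hi == s])
    da_peaks_by_state <- lapply(seq_len(n_states), function(s) {
      unique(true_links$peak[true_links$state == states[s]])
    })
    tf_targets <- dplyr::distinct(true_links[, c("tf", "gene", "state")])
    names(tf_targets) <- c("tf", "target", "state")
  } else {
    de_genes_by_state <- rep(list(character(0)), n_states)
    da_peaks_by_state <- rep(list(character(0)), n_states)
    tf_targets <- tibble::tibble(tf = character(0), target = character(0),
                                 state = character(0))
  }
  names(de_genes_by_state) <- states
  names(da_peaks_by_state) <- states

  truth <- structure(list(
    true_links = true_links,
    true_tf_targets = tf_targets,
    de_genes_by_state = de_genes_by_state,
    da_peaks_by_state = da_peaks_by_state,
    ptx_up_genes = if (cfg$ptx_logfc != 0) ptx_up else character(0),
    tf_state = setNames(states[tf_state], tfs)
  ), class = "synth_truth")

  structure(list(
    rna = as_dgc(rna),
    atac = as_dgc(atac),
    cell_meta = tibble::tibble(cell = cells, patient = patient,
                               timepoint = timepoint,
                               state = states[state_idx],
                               modality = modality),
    peaks = peaks,
    promoters = tibble::tibble(gene = genes, chrom = "chrS",
                               tss = as.integer(tss), strand = "+"),
    motifs = as_dgc(hits),
    embedding = embedding,
    truth = truth,
    config = cfg
  ), class = "multiome_sim")
}

#' @export
print.multiome_sim <- function(x, ...) {
  cat("<multiome_sim> ", nrow(x$rna), " genes x ", ncol(x$rna),
      " RNA cells; ", nrow(x$atac), " peaks x ", ncol(x$atac),
      " ATAC cells; ", nrow(x$truth$true_links), " planted links\n", sep = "")
  invisible(x)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth> ", nrow(x$true_links), " planted links; ",
      nrow(x$true_tf_targets), " TF-target pairs\n", sep = "")
  invisible(x)
}
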