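#' Quality-control thresholds for RNA and ATAC cells
#'
#' Bounds written as ranges are inclusive; bounds written as strict
#' inequalities (`<`, `>`) are strict. Defaults: UMI in \[2,000, 40,000\],
#' detected genes in \[1,000, 10,000\], mitochondrial fraction < 0.10 for RNA;
#' fragments in \[5,000, 100,000\], mitochondrial fraction < 0.15 and fraction
#' of reads in peaks (FRiP) > 0.25 for ATAC.
#'
#' @param rna_umi_min,rna_umi_max,rna_genes_min,rna_genes_max,rna_mito_max_frac
#'   RNA cell thresholds.
#' @param atac_frag_min,atac_frag_max,atac_mito_max_frac,atac_frip_min
#'   ATAC cell thresholds.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(rna_umi_min = 2000, rna_umi_max = 40000,
                          rna_genes_min = 1000, rna_genes_max = 10000,
                          rna_mito_max_frac = 0.10,
                          atac_frag_min = 5000, atac_frag_max = 100000,
                          atac_mito_max_frac = 0.15, atac_frip_min = 0.25) {
  th <- list(rna_umi_min = rna_umi_min, rna_umi_max = rna_umi_max,
             rna_genes_min = rna_genes_min, rna_genes_max = rna_genes_max,
             rna_mito_max_frac = rna_mito_max_frac,
             atac_frag_min = atac_frag_min, atac_frag_max = atac_frag_max,
             atac_mito_max_frac = atac_mito_max_frac,
             atac_frip_min = atac_frip_min)
  stop_if(th$rna_umi_min >= th$rna_umi_max ||
            th$rna_genes_min >= th$rna_genes_max ||
            th$atac_frag_min >= th$atac_frag_max,
          "each lower bound must be below its upper bound")
  fr <- c(th$rna_mito_max_frac, th$atac_mito_max_frac, th$atac_frip_min)
  stop_if(any(fr < 0 | fr > 1), "fractions must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Filter RNA cells on UMI count, detected genes and mitochondrial fraction
#'
#' Retains cells whose total UMI count and number of detected genes fall
#' inside the inclusive ranges and whose mitochondrial fraction is strictly
#' below the threshold. Column order is preserved.
#'
#' @param counts Gene-by-cell count matrix (sparse or dense, named columns).
#' @param mito_fraction Per-cell mitochondrial fraction in \[0, 1\], in column
#'   order or named by cell.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered count matrix, with a `qc` attribute holding the
#'   per-cell QC tibble (cell, umi, genes, mito_fraction, keep).
#' @export
filter_rna_cells <- function(counts, mito_fraction,
                             thresholds = qc_thresholds()) {
  stop_if(missing(mito_fraction) || is.null(mito_fraction),
          "per-cell mitochondrial fractions are required")
  if (!is.null(names(mito_fraction)) && !is.null(colnames(counts))) {
    stop_if(!all(colnames(counts) %in% names(mito_fraction)),
            "mito_fraction is missing some cells")
    mito_fraction <- mito_fraction[colnames(counts)]
  }
  stop_if(length(mito_fraction) != ncol(counts),
          "mito_fraction must have one value per cell")
  stop_if(any(mito_fraction < 0 | mito_fraction > 1),
          "mito_fraction must lie in [0, 1]")
  umi <- Matrix::colSums(counts)
  genes <- Matrix::colSums(counts > 0)
  th <- thresholds
  keep <- umi >= th$rna_umi_min & umi <= th$rna_umi_max &
    genes >= th$rna_genes_min & genes <= th$rna_genes_max &
    mito_fraction < th$rna_mito_max_frac
  out <- counts[, keep, drop = FALSE]
  attr(out, "qc") <- tibble::tibble(
    cell = colnames(counts) %||% as.character(seq_len(ncol(counts))),
    umi = as.numeric(umi), genes = as.numeric(genes),
    mito_fraction = as.numeric(mito_fraction), keep = keep)
  out
}

#' Filter ATAC cells on fragment count, mitochondrial fraction and FRiP
#'
#' Fragment bounds are inclusive; the mitochondrial bound is strict (`<`) and
#' the FRiP bound is strict (`>`).
#'
#' @param fragments Per-cell total fragment counts (named by cell).
#' @param mito_fraction Per-cell mitochondrial read fraction.
#' @param frip Per-cell fraction of reads in peaks, in \[0, 1\].
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of retained cell names (or integer indices when
#'   `fragments` is unnamed), in input order.
#' @export
filter_atac_cells <- function(fragments, mito_fraction, frip,
                              thresholds = qc_thresholds()) {
  n <- length(fragments)
  stop_if(length(mito_fraction) != n || length(frip) != n,
          "fragments, mito_fraction and frip must have equal length")
  if (n == 0) return(character(0))
  stop_if(any(fragments < 0), "negative fragment counts")
  stop_if(any(frip < 0 | frip > 1), "frip must lie in [0, 1]")
  th <- thresholds
  keep <- fragments >= th$atac_frag_min & fragments <= th$atac_frag_max &
    mito_fraction < th$atac_mito_max_frac & frip > th$atac_frip_min
  ids <- names(fragments) %||% seq_len(n)
  ids[keep]
}

#' Log-normalize a count matrix
#'
#' Each entry becomes `log(1 + count * scale_factor / cell_total)`, the
#' standard library-size log normalization. Zero counts map to zero, so
#' sparsity is preserved, and the result is invariant to multiplying all
#' counts of a cell by a constant.
#'
#' @param counts Feature-by-cell count matrix (sparse or dense).
#' @param scale_factor Scale factor; default 10,000.
#' @return A sparse normalized matrix of the same dimensions.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  stop_if(any(counts < 0), "counts must be non-negative")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    bad <- (colnames(counts) %||% as.character(seq_len(ncol(counts))))[tot == 0]
    rlang::abort(paste0("cells with zero total counts: ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  m <- as_dgc(counts)
  out <- m %*% Matrix::Diagonal(x = scale_factor / tot)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  as_dgc(out)
}

#' Merge peak sets across samples
#'
#' Two peaks are merged when they overlap or when the gap between them is at
#' most `max_gap` base pairs; merging is the transitive closure of this
#' relation within each chromosome. Coordinates are 0-based half-open and the
#' gap between adjacent intervals is `next_start - prev_end`. The operation is
#' idempotent and its output is sorted and non-redundant.
#'
#' @param peak_sets A peak data frame (`chrom`, `start`, `end`) or a list of
#'   such data frames from different samples.
#' @param max_gap Maximum gap (bp) still merged; default 500.
#' @return A tibble (chrom, start, end) of merged peaks, sorted by chromosome
#'   and start.
#' @export
merge_peaks <- function(peak_sets, max_gap = 500) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  all_pk <- dplyr::bind_rows(lapply(peak_sets, function(p) {
    tibble::tibble(chrom = as.character(p$chrom), start = as.numeric(p$start),
                   end = as.numeric(p$end))
  }))
  bad <- which(all_pk$start >= all_pk$end)
  stop_if(length(bad) > 0,
          paste0("malformed interval (start >= end) at record ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  merged <- lapply(split(all_pk, all_pk$chrom), function(p) {
    ir <- IRanges::IRanges(start = p$start + 1, end = p$end)  # 1-based closed
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1)
    tibble::tibble(chrom = p$chrom[[1]],
                   start = as.numeric(IRanges::start(red) - 1),
                   end = as.numeric(IRanges::end(red)))
  })
  out <- dplyr::bind_rows(merged)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Gini index of a non-negative vector
#'
#' The population form `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, without
#' small-sample correction; 0 for a constant vector, approaching 1 as the mass
#' concentrates on one entry.
#'
#' @param values Non-negative numeric vector of length >= 2, not all zero.
#' @return The Gini index in \[0, 1).
#' @export
gini_index <- function(values) {
  stop_if(length(values) < 2, "need at least 2 values")
  stop_if(any(values < 0), "values must be non-negative")
  stop_if(all(values == 0), "all-zero vector has no Gini index")
  n <- length(values)
  x <- sort(values)
  # equivalent to the double sum: sum_i (2i - n - 1) x_(i) / (n^2 mean)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Filter genes on patient specificity and minimum expression
#'
#' Removes genes whose patient pseudo-bulk profile has a Gini index above
#' `gini_max` (highly patient-specific genes) and genes whose expressed-cell
#' fraction is below `min_frac` in every patient. A gene survives the second
#' filter if any single patient expresses it in at least `min_frac` of cells.
#'
#' @param pseudobulk Gene-by-patient matrix of summed raw counts.
#' @param expressed_frac Gene-by-patient matrix of expressed-cell fractions
#'   (expressed = count > 0).
#' @param gini_max Maximum allowed Gini index; default 0.8.
#' @param min_frac Minimum expressed-cell fraction; default 0.002.
#' @return A tibble (gene, gini, max_expressed_frac, keep) in input gene
#'   order; `keep` marks genes passing both filters.
#' @export
filter_genes <- function(pseudobulk, expressed_frac, gini_max = 0.8,
                         min_frac = 0.002) {
  stop_if(!all(dim(pseudobulk) == dim(expressed_frac)),
          "pseudobulk and expressed_frac must have matching dimensions")
  genes <- rownames(pseudobulk) %||% as.character(seq_len(nrow(pseudobulk)))
  if (ncol(pseudobulk) < 2) {
    rlang::warn("single patient: Gini filter skipped")
    gini <- rep(NA_real_, nrow(pseudobulk))
    keep_gini <- rep(TRUE, nrow(pseudobulk))
  } else {
    gini <- apply(pseudobulk, 1, function(v) {
      if (all(v == 0)) NA_real_ else gini_index(v)
    })
    keep_gini <- is.na(gini) | gini <= gini_max
  }
  max_frac <- apply(expressed_frac, 1, max)
  keep_expr <- max_frac >= min_frac
  tibble::tibble(gene = genes, gini = as.numeric(gini),
                 max_expressed_frac = as.numeric(max_frac),
                 keep = keep_gini & keep_expr)
}

#' Rank genes by normalized-expression variance
#'
#' A simple highly-variable-gene utility: ranks features by their variance in
#' the normalized layer and returns the top `n`. This is a deliberately plain
#' stand-in for integration-based feature selection, which is outside the
#' scope of this package.
#'
#' @param norm Feature-by-cell normalized matrix.
#' @param n Number of features to return.
#' @return Character vector of feature names, highest variance first.
#' @export
hvg_select <- function(norm, n = 2000) {
  m <- as_dgc(norm)
  mu <- Matrix::rowMeans(m)
  v <- Matrix::rowSums(m^2) / ncol(m) - mu^2
  ord <- order(-v, seq_len(nrow(m)))
  (rownames(m) %||% as.character(seq_len(nrow(m))))[utils::head(ord, n)]
}
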