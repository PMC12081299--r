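#' Parameters for one-vs-rest differential expression
#'
#' @param max_cells_per_ident Per-group subsampling cap; default 500.
#' @param min_pct Minimum expressed-cell fraction in either group; default
#'   0.05.
#' @param min_diff_pct Minimum absolute difference in expressed fractions;
#'   default 0.05.
#' @return A list of class `de_params`.
#' @export
de_params <- function(max_cells_per_ident = 500, min_pct = 0.05,
                      min_diff_pct = 0.05) {
  stop_if(min_pct < 0 || min_pct > 1 || min_diff_pct < 0 || min_diff_pct > 1,
          "fractions must lie in [0, 1]")
  stop_if(max_cells_per_ident < 1, "max_cells_per_ident must be >= 1")
  structure(list(max_cells_per_ident = as.integer(max_cells_per_ident),
                 min_pct = min_pct, min_diff_pct = min_diff_pct),
            class = "de_params")
}

#' One-vs-rest differential expression with fraction filters
#'
#' For each state, both the state and the rest are subsampled to at most
#' `max_cells_per_ident` cells (seeded), genes are kept when expressed in at
#' least `min_pct` of either group and when the absolute difference of
#' expressed fractions is at least `min_diff_pct`, and surviving genes are
#' tested with a two-sided Wilcoxon rank-sum test on normalized values. The
#' log fold-change is the difference of group means on the log scale
#' (natural-log normalized data). BH adjustment is per state.
#'
#' @param norm Gene-by-cell normalized matrix.
#' @param state_labels Per-cell state labels (column order or named).
#' @param params A [de_params()].
#' @param states States to test; all observed states by default.
#' @param rng_seed Integer seed for the subsampling.
#' @return A tibble (gene, state, log_fc, pct_in, pct_out, p_value, q_value),
#'   one row per tested gene and state.
#' @export
de_genes <- function(norm, state_labels, params = de_params(), states = NULL,
                     rng_seed = 1L) {
  if (!is.null(names(state_labels)) && !is.null(colnames(norm)))
    state_labels <- state_labels[colnames(norm)]
  stop_if(length(state_labels) != ncol(norm),
          "state_labels must have one label per cell")
  stop_if(length(unique(state_labels)) < 2, "need at least two states")
  states <- states %||% sort(unique(state_labels))
  norm <- as_dgc(norm)
  genes <- rownames(norm) %||% as.character(seq_len(nrow(norm)))

  res <- withr::with_seed(rng_seed, lapply(states, function(s) {
    inside <- which(state_labels == s)
    outside <- which(state_labels != s)
    if (length(inside) < 3) {
      rlang::warn(paste0("state ", s, " has < 3 cells; skipped"))
      return(NULL)
    }
    if (length(inside) > params$max_cells_per_ident)
      inside <- sort(sample(inside, params$max_cells_per_ident))
    if (length(outside) > params$max_cells_per_ident)
      outside <- sort(sample(outside, params$max_cells_per_ident))
    min_ <- norm[, inside, drop = FALSE]
    mout <- norm[, outside, drop = FALSE]
    pct_in <- as.numeric(Matrix::rowSums(min_ != 0)) / length(inside)
    pct_out <- as.numeric(Matrix::rowSums(mout != 0)) / length(outside)
    test <- which((pct_in >= params$min_pct | pct_out >= params$min_pct) &
                    abs(pct_in - pct_out) >= params$min_diff_pct)
    if (length(test) == 0) return(NULL)
    p <- vapply(test, function(g) {
      stats::wilcox.test(min_[g, ], mout[g, ], exact = FALSE,
                         correct = TRUE)$p.value
    }, numeric(1))
    tibble::tibble(gene = genes[test], state = s,
                   log_fc = as.numeric(Matrix::rowMeans(min_[test, ,
                                                             drop = FALSE]) -
                                         Matrix::rowMeans(mout[test, ,
                                                               drop = FALSE])),
                   pct_in = pct_in[test], pct_out = pct_out[test],
                   p_value = as.numeric(p),
                   q_value = bh_adjust(as.numeric(p)))
  }))
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0)
    out <- tibble::tibble(gene = character(0), state = character(0),
                          log_fc = numeric(0), pct_in = numeric(0),
                          pct_out = numeric(0), p_value = numeric(0),
                          q_value = numeric(0))
  out
}

#' Pseudo-bulk differential accessibility
#'
#' Counts are summed to sample-by-state pseudo-bulk profiles and the given
#' state is tested against the rest with edgeR's quasi-likelihood negative
#' binomial framework on library-size-normalized pseudo-bulks (TMM). At least
#' two pseudo-bulk replicates are required on each side. All-zero peaks are
#' excluded and reported via the `dropped` attribute.
#'
#' @param atac Peak-by-cell count matrix.
#' @param state_labels Per-cell state labels.
#' @param sample_labels Per-cell sample (replicate) labels.
#' @param state State tested against the rest.
#' @return A tibble (peak, state, log_fc, p_value, q_value); `log_fc` is
#'   edgeR's log2 fold-change of the state versus the rest. Attribute
#'   `dropped` lists excluded peaks with reasons.
#' @export
da_peaks_pseudobulk <- function(atac, state_labels, sample_labels, state) {
  if (!is.null(names(state_labels)) && !is.null(colnames(atac)))
    state_labels <- state_labels[colnames(atac)]
  if (!is.null(names(sample_labels)) && !is.null(colnames(atac)))
    sample_labels <- sample_labels[colnames(atac)]
  stop_if(length(state_labels) != ncol(atac) ||
            length(sample_labels) != ncol(atac),
          "labels must have one value per cell")
  stop_if(!state %in% state_labels, paste0("state not present: ", state))
  grp <- factor(paste(sample_labels, state_labels, sep = "||"))
  atac <- as_dgc(atac)
  # pseudo-bulk: sum counts per sample x state
  agg <- atac %*% sparseMatrix(i = seq_along(grp), j = as.integer(grp),
                               x = 1, dims = c(length(grp), nlevels(grp)))
  pb <- as.matrix(agg)
  colnames(pb) <- levels(grp)
  pb_state <- sub("^.*\\|\\|", "", levels(grp))
  side <- factor(ifelse(pb_state == state, "state", "rest"),
                 levels = c("rest", "state"))
  stop_if(min(table(side)) < 2,
          "need at least two pseudo-bulk replicates per side")
  nonzero <- rowSums(pb) > 0
  dropped <- tibble::tibble(
    peak = (rownames(pb) %||% as.character(seq_len(nrow(pb))))[!nonzero],
    reason = "all-zero peak")
  pb <- pb[nonzero, , drop = FALSE]
  design <- stats::model.matrix(~side)
  y <- edgeR::DGEList(counts = pb)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  qlf <- edgeR::glmQLFTest(fit, coef = 2)
  tt <- edgeR::topTags(qlf, n = Inf, sort.by = "none")$table
  out <- tibble::tibble(peak = rownames(tt), state = state,
                        log_fc = tt$logFC, p_value = tt$PValue,
                        q_value = tt$FDR)
  attr(out, "dropped") <- dropped
  out
}

#' Fraction of cells in which a peak is accessible
#'
#' "Accessible" means a non-zero count. The downstream sparse-state rule
#' passes peaks whose fraction strictly exceeds 0.20.
#'
#' @param atac Peak-by-cell count matrix.
#' @param cells Cell subset (names or indices); must be non-empty.
#' @param peaks Peaks to report (names or indices); all by default.
#' @return Named numeric vector of accessible fractions in \[0, 1\].
#' @export
peak_accessible_fraction <- function(atac, cells, peaks = NULL) {
  stop_if(length(cells) == 0, "cell subset must be non-empty")
  sub <- atac[, cells, drop = FALSE]
  if (!is.null(peaks)) sub <- sub[peaks, , drop = FALSE]
  out <- as.numeric(Matrix::rowSums(sub != 0)) / ncol(sub)
  names(out) <- rownames(sub)
  out
}
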