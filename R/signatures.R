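#' Signature (module) score with expression-matched control genes
#'
#' Scores each cell as the mean normalized expression of the signature genes
#' minus the mean over a control gene pool. Control candidates (all
#' non-signature genes) are binned by average expression into `n_bins`
#' equal-frequency bins; each signature gene draws `n_controls` control genes
#' (with replacement, seeded) from the candidate bin whose mean average
#' expression is nearest to the gene's own. The score is invariant to adding
#' a constant to every gene in every cell.
#'
#' @param norm Gene-by-cell normalized matrix.
#' @param genes Character vector of signature genes (intersected with the
#'   matrix; the intersection must be non-empty).
#' @param n_bins Number of expression bins; default 24.
#' @param n_controls Control genes drawn per signature gene; default 100.
#' @param rng_seed Integer seed for control sampling.
#' @return A tibble (cell, score).
#' @export
module_score <- function(norm, genes, n_bins = 24, n_controls = 100,
                         rng_seed = 1L) {
  all_genes <- rownames(norm)
  stop_if(is.null(all_genes), "norm must have gene rownames")
  sig <- intersect(genes, all_genes)
  stop_if(length(sig) == 0, "no signature genes present in the matrix")
  candidates <- setdiff(all_genes, sig)
  stop_if(length(candidates) == 0, "no non-signature genes to draw controls from")
  avg <- Matrix::rowMeans(norm)
  cand_bin <- rank_bins(avg[candidates], n_bins)
  bin_means <- tapply(avg[candidates], cand_bin, mean)
  by_bin <- split(candidates, cand_bin)
  controls <- withr::with_seed(rng_seed, {
    unlist(lapply(sig, function(g) {
      b <- which.min(abs(bin_means - avg[[g]]))
      pool <- by_bin[[names(bin_means)[b]]]
      pool[sample.int(length(pool), n_controls, replace = TRUE)]
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::colMeans(norm[sig, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[controls, , drop = FALSE])
  tibble::tibble(cell = colnames(norm) %||%
                   as.character(seq_len(ncol(norm))),
                 score = as.numeric(sig_mean - ctrl_mean))
}

#' Mesenchymal minus adrenergic signature score difference
#'
#' @param scores_mes,scores_adrn Tibbles from [module_score()] (or named
#'   numeric vectors) over the same cells.
#' @return A tibble (cell, diff) with the elementwise MES - ADRN difference.
#' @export
mes_adrn_diff <- function(scores_mes, scores_adrn) {
  to_vec <- function(s) {
    if (is.data.frame(s)) stats::setNames(s$score, s$cell) else s
  }
  a <- to_vec(scores_mes); b <- to_vec(scores_adrn)
  stop_if(length(a) != length(b) || !identical(names(a), names(b)),
          "cell ids of the two score sets do not align")
  tibble::tibble(cell = names(a) %||% as.character(seq_along(a)),
                 diff = as.numeric(a - b))
}

#' Assign each sample to its maximum-scoring state
#'
#' @param scores A sample-by-state data frame or matrix of signature scores;
#'   a `sample` column (or rownames) identifies samples.
#' @return A tibble (sample, state). Exact ties go to the first state in
#'   column order, with a warning; rows that are entirely missing are an
#'   error.
#' @export
assign_max_state <- function(scores) {
  df <- as.data.frame(scores)
  if ("sample" %in% names(df)) {
    samples <- as.character(df$sample)
    df$sample <- NULL
  } else {
    samples <- rownames(df) %||% as.character(seq_len(nrow(df)))
  }
  stop_if(ncol(df) < 1, "need at least one state column")
  m <- as.matrix(df)
  stop_if(any(rowSums(!is.na(m)) == 0), "some samples have no scores at all")
  had_tie <- FALSE
  pick <- apply(m, 1, function(v) {
    w <- which(v == max(v, na.rm = TRUE))
    if (length(w) > 1) had_tie <<- TRUE
    w[[1]]
  })
  if (had_tie)
    rlang::warn("ties in maximum score resolved by state column order")
  tibble::tibble(sample = samples, state = colnames(m)[pick])
}

#' Dichotomize values at the median
#'
#' `"high"` strictly above the median; values equal to the median are
#' `"low"`.
#'
#' @param values Numeric vector of length >= 2.
#' @return Character vector of `"high"` / `"low"` in input order.
#' @export
dichotomize_median <- function(values) {
  stop_if(length(values) < 2, "need at least 2 values")
  med <- stats::median(values)
  if (all(values == values[[1]]))
    rlang::warn("constant values: everything is 'low'")
  ifelse(values > med, "high", "low")
}

#' Rescale scores to the unit interval
#'
#' `(x - min) / (max - min)` along the requested margin; constant slices map
#' to zero with a warning.
#'
#' @param x Numeric matrix (or data frame of numerics).
#' @param margin 1 to normalize within rows (default), 2 within columns.
#' @return A matrix with values in \[0, 1\].
#' @export
normalize_01 <- function(x, margin = 1) {
  m <- as.matrix(x)
  check_finite(m, "scores")
  stop_if(!margin %in% c(1, 2), "margin must be 1 or 2")
  f <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      rlang::warn("constant slice rescaled to zeros")
      return(rep(0, length(v)))
    }
    (v - rng[1]) / (rng[2] - rng[1])
  }
  out <- if (margin == 1) t(apply(m, 1, f)) else apply(m, 2, f)
  dimnames(out) <- dimnames(m)
  out
}

#' Build the design table for a delegated Cox proportional-hazards fit
#'
#' Emits the model-ready exposure and covariates; the survival fit itself is
#' performed by a standard survival library (e.g. `survival::coxph`), not by
#' this package. In `"median"` mode the exposure is the median-dichotomized
#' signature score; in `"maxstate"` mode it is the maximum-score state
#' assignment with `baseline` as the reference level.
#'
#' @param scores In `"median"` mode a tibble (sample, score); in `"maxstate"`
#'   mode a sample-by-state score table as for [assign_max_state()].
#' @param covariates Tibble (sample, age, sex, mycn_status); must be complete
#'   for every sample.
#' @param mode `"median"` or `"maxstate"`.
#' @param baseline Reference state for `"maxstate"` mode; defaults to the
#'   first state column.
#' @return A tibble (sample, exposure, age, sex, mycn_status) with `exposure`
#'   a factor (`low` reference in median mode; `baseline` reference in
#'   maxstate mode).
#' @export
survival_inputs <- function(scores, covariates,
                            mode = c("median", "maxstate"), baseline = NULL) {
  mode <- match.arg(mode)
  need <- c("sample", "age", "sex", "mycn_status")
  stop_if(!all(need %in% names(covariates)),
          "covariates needs columns sample, age, sex, mycn_status")
  if (mode == "median") {
    stop_if(!all(c("sample", "score") %in% names(scores)),
            "median mode needs a (sample, score) table")
    exposure <- factor(dichotomize_median(scores$score),
                       levels = c("low", "high"))
    out <- tibble::tibble(sample = as.character(scores$sample),
                          exposure = exposure)
  } else {
    assigned <- assign_max_state(scores)
    lev <- unique(assigned$state)
    baseline <- baseline %||% setdiff(colnames(scores), "sample")[[1]]
    stop_if(!baseline %in% c(lev, colnames(scores)),
            paste0("baseline state not found: ", baseline))
    lev <- union(baseline, sort(lev))
    out <- tibble::tibble(sample = assigned$sample,
                          exposure = factor(assigned$state, levels = lev))
  }
  merged <- dplyr::left_join(out, tibble::as_tibble(covariates),
                             by = "sample")
  bad <- merged$sample[!stats::complete.cases(
    merged[, c("age", "sex", "mycn_status")])]
  stop_if(length(bad) > 0,
          paste0("missing covariates for sample(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  merged[, c("sample", "exposure", "age", "sex", "mycn_status")]
}
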