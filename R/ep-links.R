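#' Thresholds for enhancer-promoter link calling
#'
#' @param coef_min Minimum (strict) regression coefficient; default 0.2.
#' @param q_max Maximum (strict) Benjamini-Hochberg adjusted p; default 0.01.
#' @param window_bp Window half-width around the TSS; default 500,000.
#' @param min_peak_frac Candidate peaks must be non-zero in at least this
#'   fraction of metacells before entering the regression; default 0.05.
#' @param bh_scope `"global"` pools all gene-peak p-values into one BH family
#'   (default); `"per_gene"` adjusts within each gene.
#' @param standardize Fit on z-scored expression and accessibility (default
#'   `TRUE`), making `coef_min` a scale-free threshold.
#' @return A list of class `link_thresholds`.
#' @export
link_thresholds <- function(coef_min = 0.2, q_max = 0.01, window_bp = 500000,
                            min_peak_frac = 0.05,
                            bh_scope = c("global", "per_gene"),
                            standardize = TRUE) {
  stop_if(coef_min <= 0, "coef_min must be > 0")
  stop_if(q_max <= 0 || q_max >= 1, "q_max must lie in (0, 1)")
  stop_if(window_bp <= 0, "window_bp must be > 0")
  structure(list(coef_min = coef_min, q_max = q_max, window_bp = window_bp,
                 min_peak_frac = min_peak_frac,
                 bh_scope = match.arg(bh_scope),
                 standardize = isTRUE(standardize)),
            class = "link_thresholds")
}

#' Candidate peaks within the promoter window of a gene
#'
#' A peak is a candidate when its midpoint lies within `window_bp` of the
#' gene's TSS on the same chromosome (inclusive at both ends,
#' strand-agnostic).
#'
#' @param gene Gene identifier present in `promoters`.
#' @param promoters Tibble (gene, chrom, tss, strand).
#' @param peaks Tibble (peak, chrom, start, end), 0-based half-open.
#' @param window_bp Window half-width in bp.
#' @return The candidate rows of `peaks`, with a `midpoint` column.
#' @export
candidate_peaks <- function(gene, promoters, peaks, window_bp = 500000) {
  row <- promoters[promoters$gene == gene, , drop = FALSE]
  stop_if(nrow(row) == 0, paste0("gene not found in promoters: ", gene))
  mid <- (peaks$start + peaks$end) / 2
  keep <- peaks$chrom == row$chrom[[1]] &
    abs(mid - row$tss[[1]]) <= window_bp
  out <- peaks[keep, , drop = FALSE]
  out$midpoint <- mid[keep]
  tibble::as_tibble(out)
}

#' Per-gene ordinary least squares of expression on peak accessibility
#'
#' Fits `y ~ X` with an intercept by ordinary least squares; by default both
#' the response and each accessibility column are z-scored first so the
#' coefficients are standardized. Zero-variance columns are excluded from the
#' fit and reported with a reason. P-values are two-sided t-tests on
#' `n - p - 1` degrees of freedom.
#'
#' @param y Numeric expression vector over metacells.
#' @param X Metacell-by-peak accessibility matrix (named columns).
#' @param standardize Z-score `y` and the columns of `X` before fitting.
#' @return A tibble (peak, coefficient, std_error, p_value, dropped_reason);
#'   fitted peaks carry `NA` in `dropped_reason`, dropped peaks carry the
#'   reason and `NA` estimates.
#' @export
fit_gene_model <- function(y, X, standardize = TRUE) {
  X <- as.matrix(X)
  stop_if(length(y) != nrow(X), "y and X must agree on metacells")
  check_finite(y, "y"); check_finite(X, "X")
  peak_ids <- colnames(X) %||% sprintf("x%d", seq_len(ncol(X)))
  sds <- unname(apply(X, 2, stats::sd))
  usable <- sds > 0
  out <- tibble::tibble(peak = peak_ids, coefficient = NA_real_,
                        std_error = NA_real_, p_value = NA_real_,
                        dropped_reason = ifelse(usable, NA_character_,
                                                "zero variance"))
  p <- sum(usable)
  stop_if(length(y) <= p + 1,
          "under-determined fit: need more metacells than peaks + 1")
  if (p == 0) return(out)
  Xf <- X[, usable, drop = FALSE]
  if (standardize) {
    y <- zscore(y)
    Xf <- apply(Xf, 2, zscore)
  }
  fit <- stats::lm(y ~ Xf)
  cf_all <- unname(stats::coef(fit)[-1])      # column order; NA if aliased
  sm <- summary(fit)$coefficients             # estimated terms only
  est <- which(!is.na(cf_all))
  se <- pv <- rep(NA_real_, length(cf_all))
  se[est] <- sm[-1, 2]
  pv[est] <- sm[-1, 4]
  out$coefficient[usable] <- cf_all
  out$std_error[usable] <- se
  out$p_value[usable] <- pv
  # columns made collinear by lm's pivoting come back NA and stay dropped
  aliased <- usable & is.na(out$coefficient)
  out$dropped_reason[aliased] <- "collinear"
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_(j >= i) p_(j) * m / j` on the sorted p-values, mapped back to
#' input order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stop_if(any(is.na(p_values)) || any(p_values < 0 | p_values > 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Flag significant enhancer-promoter links
#'
#' A link is significant when its coefficient strictly exceeds `coef_min`
#' and its BH-adjusted p-value is strictly below `q_max`.
#'
#' @param table Link tibble with `coefficient` and `q_value` columns.
#' @param thresholds A [link_thresholds()].
#' @return The table with a logical `significant` column.
#' @export
call_links <- function(table, thresholds = link_thresholds()) {
  stop_if(!all(c("coefficient", "q_value") %in% names(table)),
          "table needs coefficient and q_value columns")
  dplyr::mutate(tibble::as_tibble(table),
                significant = !is.na(.data$coefficient) &
                  !is.na(.data$q_value) &
                  .data$coefficient > thresholds$coef_min &
                  .data$q_value < thresholds$q_max)
}

#' Predict enhancer-promoter links by per-gene metacell regression
#'
#' For each gene, regresses metacell expression on the accessibility of
#' candidate peaks within `window_bp` of the TSS (midpoint rule), after
#' dropping candidates that are non-zero in fewer than `min_peak_frac` of
#' metacells. P-values are BH-adjusted (globally by default) and links are
#' called at `coefficient > coef_min` and `q < q_max`. Genes whose surviving
#' candidate count reaches the number of metacells minus one are skipped with
#' a warning rather than regularized.
#'
#' @param expr_mc Gene-by-metacell expression matrix (aggregated normalized
#'   expression).
#' @param acc_mc Peak-by-metacell accessibility matrix (aggregated normalized
#'   accessibility), columns aligned with `expr_mc`.
#' @param promoters Tibble (gene, chrom, tss, strand).
#' @param peaks Tibble (peak, chrom, start, end).
#' @param thresholds A [link_thresholds()].
#' @return An object of class `ep_links`: a tibble (gene, peak, chrom, start,
#'   end, coefficient, std_error, p_value, q_value, n_metacells, significant)
#'   with attributes `thresholds`, `skipped` (tibble of skipped genes with
#'   reasons) and `dropped` (per-gene dropped candidate peaks).
#' @export
link_enhancers <- function(expr_mc, acc_mc, promoters, peaks,
                           thresholds = link_thresholds()) {
  stop_if(ncol(expr_mc) != ncol(acc_mc),
          "expression and accessibility must cover the same metacells")
  n_mc <- ncol(expr_mc)
  genes <- intersect(rownames(expr_mc), promoters$gene)
  prevalence <- row_nonzero_frac(acc_mc)
  res <- vector("list", length(genes))
  skipped <- list(); dropped <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    cand <- candidate_peaks(g, promoters, peaks, thresholds$window_bp)
    cand <- cand[cand$peak %in% rownames(acc_mc), , drop = FALSE]
    cand <- cand[prevalence[cand$peak] >= thresholds$min_peak_frac, ,
                 drop = FALSE]
    if (nrow(cand) == 0) next
    if (n_mc <= nrow(cand) + 1) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        gene = g, reason = "more candidate peaks than metacells - 1")
      rlang::warn(paste0("skipping gene ", g,
                         ": under-determined fit (", nrow(cand),
                         " candidates, ", n_mc, " metacells)"))
      next
    }
    X <- Matrix::t(acc_mc[cand$peak, , drop = FALSE])
    fit <- fit_gene_model(as.numeric(expr_mc[g, ]), as.matrix(X),
                          standardize = thresholds$standardize)
    drp <- fit[!is.na(fit$dropped_reason), c("peak", "dropped_reason")]
    if (nrow(drp) > 0) dropped[[length(dropped) + 1]] <-
        dplyr::mutate(drp, gene = g, .before = 1)
    fit <- fit[is.na(fit$dropped_reason), , drop = FALSE]
    if (nrow(fit) == 0) next
    res[[i]] <- dplyr::mutate(
      dplyr::left_join(fit[, c("peak", "coefficient", "std_error", "p_value")],
                       cand[, c("peak", "chrom", "start", "end")],
                       by = "peak"),
      gene = g, n_metacells = n_mc, .before = 1)
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene = character(0), peak = character(0),
                          chrom = character(0), start = numeric(0),
                          end = numeric(0), coefficient = numeric(0),
                          std_error = numeric(0), p_value = numeric(0),
                          q_value = numeric(0), n_metacells = integer(0),
                          significant = logical(0))
  } else {
    if (thresholds$bh_scope == "global") {
      out$q_value <- bh_adjust(out$p_value)
    } else {
      out <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(out, .data$gene),
                                          q_value = bh_adjust(.data$p_value)))
    }
    out <- call_links(out, thresholds)
  }
  structure(out, class = c("ep_links", class(out)),
            thresholds = thresholds,
            skipped = dplyr::bind_rows(skipped),
            dropped = dplyr::bind_rows(dropped))
}

#' @export
tidy.ep_links <- function(x, ...) {
  tibble::as_tibble(unclass_links(x))
}

#' @export
glance.ep_links <- function(x, ...) {
  tibble::tibble(n_genes = length(unique(x$gene)), n_tests = nrow(x),
                 n_significant = sum(x$significant),
                 n_skipped_genes = nrow(attr(x, "skipped") %||% tibble()),
                 coef_min = attr(x, "thresholds")$coef_min,
                 q_max = attr(x, "thresholds")$q_max)
}

unclass_links <- function(x) {
  class(x) <- setdiff(class(x), "ep_links")
  x
}

#' Volcano-style plot of enhancer-promoter link tests
#'
#' @param object An `ep_links` object.
#' @param ... Unused.
#' @return A ggplot: coefficient against -log10 q, significant links
#'   highlighted.
#' @export
autoplot.ep_links <- function(object, ...) {
  df <- tidy(object)
  th <- attr(object, "thresholds")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient,
                                   y = -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = th$coef_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(th$q_max), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "standardized coefficient",
                  y = expression(-log[10] ~ q),
                  colour = "significant")
}
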