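#' Paired Wilcoxon signed-rank test
#'
#' Tests the paired differences `ptx - dx`. Zero differences are dropped
#' (the standard convention). The exact distribution is used for up to 12
#' tie-free non-zero differences; otherwise the normal approximation with
#' tie and continuity correction. The direction of the one-sided alternative
#' is a required, explicit argument: `"greater"` tests whether PTX exceeds
#' DX.
#'
#' @param dx,ptx Paired numeric vectors of equal length.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`; no default.
#' @return A tibble (statistic, p_value, n_effective, method), where
#'   `statistic` is the positive-rank sum V of `ptx - dx` and `n_effective`
#'   the number of non-zero differences.
#' @export
paired_signed_rank <- function(dx, ptx,
                               alternative = c("greater", "less",
                                               "two.sided")) {
  stop_if(missing(alternative),
          "alternative must be given explicitly ('greater'/'less'/'two.sided')")
  alternative <- match.arg(alternative)
  stop_if(length(dx) != length(ptx), "dx and ptx must be paired")
  d <- ptx - dx
  d <- d[d != 0]
  stop_if(length(d) == 0, "all paired differences are zero")
  stop_if(length(d) < 3, "need at least 3 non-zero differences")
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 12 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_effective = length(d),
                 method = if (exact) "exact" else "normal approximation")
}

#' Two-sample proportion test
#'
#' Chi-squared / z test of two proportions with continuity correction.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (first sample versus second).
#' @return A tibble (statistic, p_value, p1, p2, alternative); `statistic`
#'   is the chi-squared statistic with continuity correction.
#' @export
proportion_test <- function(k1, n1, k2, n2,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stop_if(n1 < 1 || n2 < 1, "sample sizes must be >= 1")
  stop_if(k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2,
          "successes must satisfy 0 <= k <= n")
  ht <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                          alternative = alternative,
                                          correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 p1 = k1 / n1, p2 = k2 / n2, alternative = alternative)
}

#' Paired composition-shift table across cell types
#'
#' For each cell type, applies the paired signed-rank test to the per-patient
#' DX and PTX proportions, then BH-adjusts across cell types. Patients
#' missing either timepoint are excluded with a warning.
#'
#' @param composition Tibble (patient, timepoint, cell_type, proportion) with
#'   `timepoint` in `{"DX", "PTX"}`.
#' @param alternative One-sided direction for [paired_signed_rank()];
#'   required.
#' @return A tibble (cell_type, n_patients, median_dx, median_ptx, p_value,
#'   q_value).
#' @export
shift_table <- function(composition,
                        alternative = c("greater", "less", "two.sided")) {
  stop_if(missing(alternative), "alternative must be given explicitly")
  alternative <- match.arg(alternative)
  need <- c("patient", "timepoint", "cell_type", "proportion")
  stop_if(!all(need %in% names(composition)),
          "composition needs patient, timepoint, cell_type, proportion")
  wide <- tidyr::pivot_wider(composition, names_from = "timepoint",
                             values_from = "proportion")
  paired <- tapply(!is.na(wide$DX) & !is.na(wide$PTX), wide$patient, all)
  unpaired <- names(paired)[!paired]
  if (length(unpaired) > 0) {
    rlang::warn(paste0("excluding unpaired patient(s): ",
                       paste(unpaired, collapse = ", ")))
    wide <- wide[!wide$patient %in% unpaired, , drop = FALSE]
  }
  res <- lapply(split(wide, wide$cell_type), function(w) {
    sr <- paired_signed_rank(w$DX, w$PTX, alternative = alternative)
    tibble::tibble(cell_type = w$cell_type[[1]], n_patients = nrow(w),
                   median_dx = stats::median(w$DX),
                   median_ptx = stats::median(w$PTX),
                   p_value = sr$p_value)
  })
  out <- dplyr::bind_rows(res)
  out$q_value <- bh_adjust(out$p_value)
  out
}
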