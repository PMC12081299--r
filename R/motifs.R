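#' Per-motif accessibility deviation z-scores
#'
#' For motif m and cell i, the raw deviation is
#' `d(m, i) = (obs - exp) / exp`, where `obs` is the summed counts of cell i
#' in the motif's peaks and `exp` is the cell's total count times the motif
#' peaks' share of the grand total. The z-score standardizes `d` against
#' `n_background` random background peak sets matched to the motif's peaks by
#' mean-accessibility bin. Deviations are invariant to rescaling all counts
#' by a common constant (the expectation's peak shares are weighted by the
#' observed totals, so rescaling one cell alone perturbs every expectation by
#' that cell's weight, as in the reference deviation method), and a motif
#' annotating every peak deviates by exactly zero. A background with zero standard deviation maps the z-score
#' to zero with a warning. GC-content matching is deliberately absent: the
#' backgrounds are matched on accessibility only.
#'
#' @param atac Peak-by-cell count matrix; no all-zero cells.
#' @param hits Peak-by-motif 0/1 hit matrix; every motif needs >= 1 hit.
#' @param n_background Number of background peak sets; default 50.
#' @param bins Number of equal-frequency mean-accessibility bins; default 20.
#' @param rng_seed Integer seed for background sampling.
#' @return An object of class `deviation_scores`: list with `z` (motif-by-cell
#'   z-score matrix), `raw` (raw deviations) and `params`.
#' @export
motif_deviation_z <- function(atac, hits, n_background = 50, bins = 20,
                              rng_seed = 1L) {
  atac <- as_dgc(atac)
  hits <- as_dgc(hits)
  stop_if(nrow(atac) != nrow(hits), "atac and hits must agree on peaks")
  cell_tot <- Matrix::colSums(atac)
  stop_if(any(cell_tot == 0), "all-zero cells are not allowed")
  motif_n <- Matrix::colSums(hits)
  stop_if(any(motif_n == 0), "every motif needs at least one peak hit")
  peak_tot <- Matrix::rowSums(atac)
  grand <- sum(peak_tot)
  stop_if(grand == 0, "expectation is zero: empty count matrix")

  dev_for <- function(h) {
    obs <- Matrix::t(h) %*% atac                       # motif x cell
    share <- as.numeric(Matrix::t(h) %*% peak_tot) / grand
    stop_if(any(share == 0), "expectation is zero for some motif")
    expd <- outer(share, cell_tot)
    as.matrix(obs) / expd - 1
  }
  d <- dev_for(hits)

  bin_id <- rank_bins(peak_tot, bins)
  by_bin <- split(seq_len(nrow(atac)), bin_id)
  bg <- withr::with_seed(rng_seed, {
    lapply(seq_len(n_background), function(b) {
      # per-iteration map: each peak replaced by a random peak of its bin
      map <- integer(nrow(atac))
      for (ids in by_bin) map[ids] <- ids[sample.int(length(ids),
                                                     length(ids),
                                                     replace = TRUE)]
      dev_for(hits[map, , drop = FALSE])
    })
  })
  s1 <- Reduce(`+`, bg)
  s2 <- Reduce(`+`, lapply(bg, function(m) m^2))
  mu <- s1 / n_background
  sdv <- sqrt(pmax(s2 / n_background - mu^2, 0) *
                n_background / (n_background - 1))
  z <- (d - mu) / sdv
  degenerate <- !is.finite(z)
  if (any(degenerate)) {
    rlang::warn("zero-variance background for some motif/cell; z set to 0")
    z[degenerate] <- 0
  }
  dimnames(z) <- list(colnames(hits), colnames(atac))
  dimnames(d) <- dimnames(z)
  structure(list(z = z, raw = d,
                 params = list(n_background = n_background, bins = bins,
                               rng_seed = rng_seed)),
            class = "deviation_scores")
}

#' @export
print.deviation_scores <- function(x, ...) {
  cat("<deviation_scores> ", nrow(x$z), " motifs x ", ncol(x$z), " cells (",
      x$params$n_background, " background sets)\n", sep = "")
  invisible(x)
}

#' @export
tidy.deviation_scores <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$z, stringsAsFactors = FALSE,
                                        responseName = "z")) |>
    stats::setNames(c("motif", "cell", "z"))
}

#' Mean motif-activity difference between a state and the rest
#'
#' @param dev A [motif_deviation_z()] result.
#' @param state_labels Per-cell state labels (in column order of `dev$z` or
#'   named by cell).
#' @param state State of interest.
#' @return A tibble (motif, activity_diff): mean z within the state minus
#'   mean z over all other cells.
#' @export
motif_activity_diff <- function(dev, state_labels, state) {
  stopifnot(inherits(dev, "deviation_scores"))
  if (!is.null(names(state_labels)))
    state_labels <- state_labels[colnames(dev$z)]
  stop_if(length(state_labels) != ncol(dev$z),
          "state_labels must have one label per cell")
  stop_if(length(unique(state_labels)) < 2,
          "need at least two states to compare")
  inside <- state_labels == state
  stop_if(!any(inside) || all(inside),
          "state must have cells both inside and outside")
  tibble::tibble(motif = rownames(dev$z),
                 activity_diff = as.numeric(
                   rowMeans(dev$z[, inside, drop = FALSE]) -
                     rowMeans(dev$z[, !inside, drop = FALSE])))
}

#' Differentially active motifs per state
#'
#' For each state, performs a two-sided Wilcoxon rank-sum test of the
#' per-cell z-scores inside the state against the rest, BH-adjusted across
#' motifs within each state.
#'
#' @param dev A [motif_deviation_z()] result.
#' @param state_labels Per-cell state labels.
#' @param states States to test; all observed states by default.
#' @return A tibble (motif, state, activity_diff, p_value, q_value).
#' @export
differential_motifs <- function(dev, state_labels, states = NULL) {
  stopifnot(inherits(dev, "deviation_scores"))
  if (!is.null(names(state_labels)))
    state_labels <- state_labels[colnames(dev$z)]
  stop_if(length(state_labels) != ncol(dev$z),
          "state_labels must have one label per cell")
  stop_if(length(unique(state_labels)) < 2, "need at least two states")
  if (nrow(dev$z) == 0) {
    return(tibble::tibble(motif = character(0), state = character(0),
                          activity_diff = numeric(0), p_value = numeric(0),
                          q_value = numeric(0)))
  }
  states <- states %||% sort(unique(state_labels))
  res <- lapply(states, function(s) {
    inside <- state_labels == s
    stop_if(!any(inside) || all(inside),
            paste0("degenerate grouping for state ", s))
    p <- apply(dev$z, 1, function(v) {
      if (all(v[inside] == v[inside][1]) && all(v == v[1])) return(1)
      stats::wilcox.test(v[inside], v[!inside], exact = FALSE,
                         correct = TRUE)$p.value
    })
    tibble::tibble(motif = rownames(dev$z), state = s,
                   activity_diff = as.numeric(
                     rowMeans(dev$z[, inside, drop = FALSE]) -
                       rowMeans(dev$z[, !inside, drop = FALSE])),
                   p_value = as.numeric(p),
                   q_value = bh_adjust(as.numeric(p)))
  })
  dplyr::bind_rows(res)
}
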