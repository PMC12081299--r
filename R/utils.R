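# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if <- function(cond, msg, class = "trnlink_error") {
  if (cond) rlang::abort(msg, class = class)
  invisible(TRUE)
}

check_finite <- function(x, what) {
  stop_if(any(!is.finite(x)), paste0("non-finite values in ", what))
}

# z-score a vector; zero-variance vectors map to all zeros
zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

# equal-frequency bin assignment by rank (1..n_bins), stable under ties
rank_bins <- function(x, n_bins) {
  n_bins <- min(n_bins, length(x))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / length(x) * n_bins))
}

# fraction of non-zero entries per row of a sparse/dense matrix
row_nonzero_frac <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    Matrix::rowSums(m != 0) / ncol(m)
  } else {
    rowSums(m != 0) / ncol(m)
  }
}

as_dgc <- function(m) methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
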