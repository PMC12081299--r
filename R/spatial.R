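#' Centered log-ratio normalization of marker intensities
#'
#' Per cell: `ln(x + pseudocount)` minus the mean of `ln(x + pseudocount)`
#' across that cell's features, so each cell's transformed markers sum to
#' zero.
#'
#' @param markers Cell-by-feature matrix or data frame of non-negative
#'   intensities.
#' @param pseudocount Added before the log; default 1.
#' @return A matrix of the same shape; rows sum to zero.
#' @export
normalize_clr <- function(markers, pseudocount = 1) {
  m <- as.matrix(markers)
  stop_if(any(m < 0), "intensities must be non-negative")
  if (pseudocount == 0)
    stop_if(any(rowSums(m > 0) == 0),
            "all-zero cell with pseudocount 0 has no CLR")
  lg <- log(m + pseudocount)
  out <- lg - rowMeans(lg)
  dimnames(out) <- dimnames(m)
  out
}

#' Mean marker level in a radius window around index cells
#'
#' For each index cell, the mean of `marker` over all other cells within
#' Euclidean distance `radius` (boundary inclusive); the index cell's own
#' marker value is excluded. Index cells without neighbours are omitted from
#' the output and counted in the `n_omitted` attribute.
#'
#' @param data Cell table with `x`, `y` and the marker column.
#' @param marker Name of the marker column.
#' @param radius Window radius in the coordinate units; default 40.
#' @param index Logical vector, cell indices, or values of `id_col` selecting
#'   the index cells; all cells by default.
#' @param id_col Name of the cell id column (used when `index` is character);
#'   default `"cell"`.
#' @return A tibble (cell, n_neighbors, density) for index cells with at
#'   least one neighbour.
#' @export
neighborhood_density <- function(data, marker, radius = 40, index = NULL,
                                 id_col = "cell") {
  stop_if(radius <= 0, "radius must be > 0")
  stop_if(!marker %in% names(data),
          paste0("marker column not found: ", marker))
  n <- nrow(data)
  ids <- if (id_col %in% names(data)) as.character(data[[id_col]]) else
    as.character(seq_len(n))
  idx <- if (is.null(index)) seq_len(n)
  else if (is.logical(index)) which(index)
  else if (is.character(index)) match(index, ids)
  else as.integer(index)
  stop_if(any(is.na(idx)), "unknown index cells")
  x <- data$x; y <- data$y; mk <- data[[marker]]
  out <- lapply(idx, function(i) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    nb <- which(d2 <= radius^2)
    nb <- nb[nb != i]
    if (length(nb) == 0) return(NULL)
    tibble::tibble(cell = ids[i], n_neighbors = length(nb),
                   density = mean(mk[nb]))
  })
  keep <- !vapply(out, is.null, logical(1))
  res <- if (any(keep)) dplyr::bind_rows(out[keep]) else
    tibble::tibble(cell = character(0), n_neighbors = integer(0),
                   density = numeric(0))
  attr(res, "n_omitted") <- sum(!keep)
  res
}

#' Distance from each cell of one type to the nearest cell of another
#'
#' Euclidean nearest distance, computed within each sample independently
#' when `sample_col` is given. Samples without any `to_type` cell are skipped
#' with a warning.
#'
#' @param data Cell table with `x`, `y` and a cell-type column.
#' @param from_type,to_type Cell types (values of `type_col`).
#' @param type_col Name of the cell-type column; default `"cell_type"`.
#' @param sample_col Optional name of a sample column.
#' @param id_col Cell id column; default `"cell"`.
#' @return A tibble (cell, sample, distance) over `from_type` cells.
#' @export
nearest_distance <- function(data, from_type, to_type,
                             type_col = "cell_type", sample_col = NULL,
                             id_col = "cell") {
  stop_if(!type_col %in% names(data), "cell-type column not found")
  ids <- if (id_col %in% names(data)) as.character(data[[id_col]]) else
    as.character(seq_len(nrow(data)))
  samples <- if (is.null(sample_col)) rep("all", nrow(data)) else
    as.character(data[[sample_col]])
  out <- lapply(unique(samples), function(s) {
    rows <- samples == s
    from <- which(rows & data[[type_col]] == from_type)
    to <- which(rows & data[[type_col]] == to_type)
    if (length(from) == 0) return(NULL)
    if (length(to) == 0) {
      rlang::warn(paste0("sample ", s, " has no ", to_type,
                         " cells; skipped"))
      return(NULL)
    }
    d <- vapply(from, function(i) {
      sqrt(min((data$x[to] - data$x[i])^2 + (data$y[to] - data$y[i])^2))
    }, numeric(1))
    tibble::tibble(cell = ids[from], sample = s, distance = d)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble::tibble(cell = character(0), sample = character(0),
                          distance = numeric(0))
  res
}

#' Ligand-receptor colocalization score with a permutation null
#'
#' The score is the fraction of receptor-positive cells having at least one
#' ligand-positive cell within `radius`. The null distribution permutes the
#' ligand flags over cells (positions fixed) `n_permutations` times; the
#' one-sided p-value is `(1 + #(null >= observed)) / (n_permutations + 1)`.
#'
#' @param data Cell table with `x`, `y` and two logical flag columns.
#' @param ligand,receptor Names of the logical flag columns.
#' @param radius Colocalization radius; default 40.
#' @param n_permutations Number of permutations; default 999.
#' @param rng_seed Integer seed.
#' @return A tibble (score, p_value, n_receptor, n_ligand, n_permutations).
#' @export
colocalization_score <- function(data, ligand = "ligand_pos",
                                 receptor = "receptor_pos", radius = 40,
                                 n_permutations = 999, rng_seed = 1L) {
  stop_if(!all(c(ligand, receptor) %in% names(data)),
          "flag columns not found")
  lig <- as.logical(data[[ligand]]); rec <- as.logical(data[[receptor]])
  stop_if(!any(lig) || !any(rec), "both flag sets must be non-empty")
  ri <- which(rec)
  # neighbour lists of receptor cells (excluding the cell itself)
  nbrs <- lapply(ri, function(i) {
    d2 <- (data$x - data$x[i])^2 + (data$y - data$y[i])^2
    setdiff(which(d2 <= radius^2), i)
  })
  score_of <- function(flags) {
    mean(vapply(nbrs, function(nb) any(flags[nb]), logical(1)))
  }
  obs <- score_of(lig)
  null <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_permutations),
           function(b) score_of(sample(lig)), numeric(1))
  })
  tibble::tibble(score = obs,
                 p_value = (1 + sum(null >= obs)) / (n_permutations + 1),
                 n_receptor = sum(rec), n_ligand = sum(lig),
                 n_permutations = n_permutations)
}

#' Compare two groups with a rank-sum or Welch t test
#'
#' The rank-sum test uses the exact distribution for small tie-free samples
#' and the normal approximation with tie and continuity correction
#' otherwise; the t test is Welch's (unequal variances).
#'
#' @param values Numeric vector.
#' @param groups Grouping vector with exactly two levels; the alternative is
#'   oriented as first level versus second (levels in order of appearance,
#'   or factor levels).
#' @param test `"ranksum"` or `"t"`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A tibble (statistic, p_value, test, alternative, n1, n2).
#' @export
compare_groups <- function(values, groups, test = c("ranksum", "t"),
                           alternative = c("two.sided", "greater", "less")) {
  test <- match.arg(test); alternative <- match.arg(alternative)
  g <- if (is.factor(groups)) groups else factor(groups,
                                                 levels = unique(groups))
  stop_if(nlevels(g) != 2, "exactly two groups are required")
  x <- values[g == levels(g)[1]]; y <- values[g == levels(g)[2]]
  stop_if(length(x) == 0 || length(y) == 0, "a group is empty")
  ht <- if (test == "ranksum") {
    suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                        correct = TRUE))
  } else {
    stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
  }
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 test = test, alternative = alternative,
                 n1 = length(x), n2 = length(y))
}

#' Scatter plot of a spatial cell table
#'
#' @param data Cell table with `x`, `y` and a cell-type column.
#' @param colour Column mapped to colour; default `"cell_type"`.
#' @return A ggplot with fixed aspect ratio.
#' @export
plot_spatial <- function(data, colour = "cell_type") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}
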