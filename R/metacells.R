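#' Metacell construction parameters
#'
#' @param k Metacell size: each metacell is the seed cell plus its `k - 1`
#'   nearest neighbours (the seed counts among its own k neighbours).
#' @param max_shared Maximum number of cells a candidate metacell may share
#'   with any previously accepted metacell.
#' @param min_cells Groups with fewer cells produce no metacells.
#' @param retain_rna_min,retain_rna_max Inclusive bounds on the number of RNA
#'   cells a metacell must contain to be retained.
#' @return A list of class `metacell_params`.
#' @export
metacell_params <- function(k = 25, max_shared = 3, min_cells = 100,
                            retain_rna_min = 5, retain_rna_max = 15) {
  stop_if(k < 2, "k must be >= 2")
  stop_if(max_shared >= k, "max_shared must be < k")
  stop_if(retain_rna_min <= 0 || retain_rna_max < retain_rna_min,
          "retention bounds must be positive and ordered")
  structure(list(k = as.integer(k), max_shared = as.integer(max_shared),
                 min_cells = as.integer(min_cells),
                 retain_rna_min = as.integer(retain_rna_min),
                 retain_rna_max = as.integer(retain_rna_max)),
            class = "metacell_params")
}

#' Build metacells by greedy k-nearest-neighbour aggregation
#'
#' Within each group (typically one sample), every cell is visited in input
#' order as a candidate seed. The candidate metacell is the seed's `k` nearest
#' neighbours in the embedding (Euclidean distance, seed included, distance
#' ties broken by cell index). It is accepted if it shares at most
#' `max_shared` members with every previously accepted metacell. Accepted
#' metacells are then filtered to those containing between `retain_rna_min`
#' and `retain_rna_max` RNA cells (inclusive). Groups with fewer than
#' `min_cells` cells are skipped. The procedure is deterministic.
#'
#' @param embedding Cells-by-dimensions numeric matrix with unique rownames.
#' @param modality Per-cell modality label (`"RNA"` or `"ATAC"`), in row order
#'   or named by cell. With RNA-only data, pass all-`"RNA"`.
#' @param groups Per-cell group label (e.g. sample); a single group when
#'   `NULL`.
#' @param params A [metacell_params()].
#' @return A list of class `metacell_map`: `metacells` (tibble: metacell,
#'   group, n_cells, n_rna, retained) and `membership` (tibble: metacell,
#'   cell), covering accepted metacells; retained ones satisfy the RNA-count
#'   rule.
#' @export
build_metacells <- function(embedding, modality, groups = NULL,
                            params = metacell_params()) {
  stop_if(is.null(dim(embedding)) || ncol(embedding) == 0,
          "embedding must be a matrix with at least one dimension")
  check_finite(embedding, "embedding")
  ids <- rownames(embedding)
  stop_if(is.null(ids), "embedding must have cell ids as rownames")
  stop_if(anyDuplicated(ids) > 0, "duplicate cell ids in embedding")
  if (!is.null(names(modality))) modality <- modality[ids]
  stop_if(length(modality) != nrow(embedding),
          "modality must have one label per cell")
  if (is.null(groups)) groups <- rep("all", nrow(embedding))
  if (!is.null(names(groups))) groups <- groups[ids]
  stop_if(length(groups) != nrow(embedding),
          "groups must have one label per cell")

  meta <- list(); members <- list(); mc_id <- 0L
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < params$min_cells) next
    sub <- embedding[rows, , drop = FALSE]
    acc <- greedy_metacells(sub, params$k, params$max_shared)
    for (m in acc) {
      mc_id <- mc_id + 1L
      id <- sprintf("mc%05d", mc_id)
      cells_m <- ids[rows[m]]
      n_rna <- sum(modality[rows[m]] == "RNA")
      meta[[mc_id]] <- tibble::tibble(
        metacell = id, group = g, n_cells = length(m), n_rna = n_rna,
        retained = n_rna >= params$retain_rna_min &
          n_rna <= params$retain_rna_max)
      members[[mc_id]] <- tibble::tibble(metacell = id, cell = cells_m)
    }
  }
  structure(list(
    metacells = if (length(meta)) dplyr::bind_rows(meta) else
      tibble::tibble(metacell = character(0), group = character(0),
                     n_cells = integer(0), n_rna = integer(0),
                     retained = logical(0)),
    membership = if (length(members)) dplyr::bind_rows(members) else
      tibble::tibble(metacell = character(0), cell = character(0)),
    params = params
  ), class = "metacell_map")
}

# greedy acceptance over seeds in row order; returns list of member index sets
greedy_metacells <- function(emb, k, max_shared) {
  n <- nrow(emb)
  k <- min(k, n)
  accepted <- list()
  cell_mc <- vector("list", n)  # accepted metacell ids touching each cell
  # distances computed seed-by-seed to bound memory on large groups
  for (s in seq_len(n)) {
    d <- sqrt(colSums((t(emb) - emb[s, ])^2))
    nb <- order(d, seq_len(n))[seq_len(k)]
    shared <- unlist(cell_mc[nb], use.names = FALSE)
    ok <- length(shared) == 0 ||
      max(tabulate(shared, nbins = length(accepted))) <= max_shared
    if (ok) {
      id <- length(accepted) + 1L
      accepted[[id]] <- sort(nb)
      for (j in nb) cell_mc[[j]] <- c(cell_mc[[j]], id)
    }
  }
  accepted
}

#' @export
print.metacell_map <- function(x, ...) {
  cat("<metacell_map> ", nrow(x$metacells), " accepted metacells (",
      sum(x$metacells$retained), " retained) in ",
      length(unique(x$metacells$group)), " group(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.metacell_map <- function(x, ...) {
  dplyr::left_join(x$membership, x$metacells, by = "metacell")
}

#' @export
glance.metacell_map <- function(x, ...) {
  tibble::tibble(n_metacells = nrow(x$metacells),
                 n_retained = sum(x$metacells$retained),
                 n_groups = length(unique(x$metacells$group)),
                 k = x$params$k, max_shared = x$params$max_shared)
}

#' Aggregate a normalized matrix over metacells
#'
#' Each retained metacell's profile is the arithmetic mean of the normalized
#' profiles of its member cells present in the matrix. Pass the RNA matrix to
#' obtain expression metacell profiles and the ATAC matrix for accessibility;
#' members of the other modality are simply absent from the matrix.
#'
#' @param norm Feature-by-cell normalized matrix (columns named by cell).
#' @param map A [build_metacells()] result.
#' @param retained_only Aggregate only retained metacells (default `TRUE`).
#' @return A dense feature-by-metacell matrix.
#' @export
aggregate_metacells <- function(norm, map, retained_only = TRUE) {
  stopifnot(inherits(map, "metacell_map"))
  stop_if(is.null(colnames(norm)), "norm must have cell ids as colnames")
  mcs <- map$metacells
  if (retained_only) mcs <- mcs[mcs$retained, , drop = FALSE]
  members <- split(map$membership$cell, map$membership$metacell)
  out <- matrix(0, nrow(norm), nrow(mcs),
                dimnames = list(rownames(norm), mcs$metacell))
  for (i in seq_len(nrow(mcs))) {
    cells_m <- intersect(members[[mcs$metacell[i]]], colnames(norm))
    stop_if(length(cells_m) == 0,
            paste0("metacell ", mcs$metacell[i],
                   " has no member cells in the matrix"))
    out[, i] <- Matrix::rowMeans(norm[, cells_m, drop = FALSE])
  }
  out
}
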