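#' Configuration for the synthetic spatial generator
#'
#' Describes a rectangular tissue field populated by a homogeneous Poisson
#' background of cells of several types, optionally with planted proximity
#' structure: for each row of `pairs`, every index-type cell receives (with
#' probability `partner_prob`) one partner-type cell placed uniformly within
#' `radius` micrometres, and a marker is additively elevated on cells lying
#' within `radius` of an index cell.
#'
#' @param field_um Side length of the square field in micrometres.
#' @param cell_types Character vector of background cell types.
#' @param cells_per_type Expected background count per type (Poisson).
#' @param pairs Data frame with columns `index_type`, `partner_type`,
#'   `radius` (micrometres); one row per planted proximity pair. Use
#'   `NULL` for a fully unstructured field.
#' @param partner_prob Probability that an index cell receives a planted
#'   partner.
#' @param marker_effect Additive elevation of the marker on neighbours of
#'   index cells.
#' @param rng_seed Integer seed.
#'
#' @return A list of class `spatial_config`.
#' @export
spatial_config <- function(field_um = 1000,
                           cell_types = c("tumor", "macrophage",
                                          "fibroblast", "tcell"),
                           cells_per_type = 250,
                           pairs = data.frame(index_type = "tumor",
                                              partner_type = "macrophage",
                                              radius = 20),
                           partner_prob = 0.5,
                           marker_effect = 2,
                           rng_seed = 1L) {
  if (!is.null(pairs)) {
    pairs <- tibble::as_tibble(pairs)
    stop_if(!all(c("index_type", "partner_type", "radius") %in% names(pairs)),
            "pairs needs columns index_type, partner_type, radius")
    stop_if(any(pairs$radius <= 0), "planted radius must be > 0")
    stop_if(!all(c(pairs$index_type, pairs$partner_type) %in% cell_types),
            "pair cell types must appear in cell_types")
  }
  stop_if(field_um <= 0 || cells_per_type <= 0, "field and counts must be > 0")
  stop_if(partner_prob < 0 || partner_prob > 1, "partner_prob must be in [0,1]")
  structure(list(field_um = as.numeric(field_um), cell_types = cell_types,
                 cells_per_type = as.numeric(cells_per_type), pairs = pairs,
                 partner_prob = as.numeric(partner_prob),
                 marker_effect = as.numeric(marker_effect),
                 rng_seed = as.integer(rng_seed)),
            class = "spatial_config")
}

#' Generate a segmented-cell spatial table with planted proximity structure
#'
#' @param config A [spatial_config()].
#'
#' @return A list of class `spatial_sim` with `cells` (tibble: cell, x, y,
#'   cell_type, marker, ligand_pos, receptor_pos) and `truth` (tibble of
#'   planted index/partner pairs with their radii). Receptor positivity marks
#'   index-type cells and ligand positivity marks partner-type cells, so the
#'   planted structure is recoverable by proximity statistics.
#' @export
generate_spatial <- function(config = spatial_config()) {
  stopifnot(inherits(config, "spatial_config"))
  withr::with_seed(config$rng_seed, generate_spatial_impl(config))
}

generate_spatial_impl <- function(cfg) {
  counts <- rpois(length(cfg$cell_types), cfg$cells_per_type)
  n_bg <- sum(counts)
  cells <- tibble::tibble(
    x = runif(n_bg, 0, cfg$field_um),
    y = runif(n_bg, 0, cfg$field_um),
    cell_type = rep(cfg$cell_types, counts)
  )
  if (!is.null(cfg$pairs) && nrow(cfg$pairs) > 0) {
    for (i in seq_len(nrow(cfg$pairs))) {
      pr <- cfg$pairs[i, ]
      idx <- cells[cells$cell_type == pr$index_type, ]
      take <- runif(nrow(idx)) < cfg$partner_prob
      if (!any(take)) next
      theta <- runif(sum(take), 0, 2 * pi)
      rad <- pr$radius * sqrt(runif(sum(take)))  # uniform over the disc
      cells <- dplyr::bind_rows(cells, tibble::tibble(
        x = pmin(pmax(idx$x[take] + rad * cos(theta), 0), cfg$field_um),
        y = pmin(pmax(idx$y[take] + rad * sin(theta), 0), cfg$field_um),
        cell_type = pr$partner_type
      ))
    }
  }
  n <- nrow(cells)
  cells$cell <- sprintf("sp%05d", seq_len(n))
  cells$marker <- rgamma(n, shape = 2, scale = 1)
  index_types <- if (is.null(cfg$pairs)) character(0) else cfg$pairs$index_type
  partner_types <- if (is.null(cfg$pairs)) character(0) else cfg$pairs$partner_type
  if (length(index_types) > 0) {
    # elevate the marker on neighbours of index cells
    is_idx <- cells$cell_type %in% index_types
    if (any(is_idx)) {
      d2 <- outer(cells$x, cells$x[is_idx], "-")^2 +
        outer(cells$y, cells$y[is_idx], "-")^2
      rmax <- max(cfg$pairs$radius)
      near <- rowSums(d2 <= rmax^2) > 0
      near[is_idx] <- FALSE
      cells$marker[near] <- cells$marker[near] + cfg$marker_effect
    }
  }
  cells$receptor_pos <- cells$cell_type %in% index_types
  cells$ligand_pos <- cells$cell_type %in% partner_types
  truth <- if (is.null(cfg$pairs)) {
    tibble::tibble(index_cell_type = character(0),
                   partner_cell_type = character(0),
                   planted_radius = numeric(0))
  } else {
    tibble::tibble(index_cell_type = cfg$pairs$index_type,
                   partner_cell_type = cfg$pairs$partner_type,
                   planted_radius = cfg$pairs$radius)
  }
  structure(list(cells = cells[, c("cell", "x", "y", "cell_type", "marker",
                                   "ligand_pos", "receptor_pos")],
                 truth = truth, config = cfg),
            class = "spatial_sim")
}

#' @export
print.spatial_sim <- function(x, ...) {
  cat("<spatial_sim> ", nrow(x$cells), " cells; ", nrow(x$truth),
      " planted proximity pair(s)\n", sep = "")
  invisible(x)
}

#' Configuration for the paired-cohort composition generator
#'
#' @param n_patients Number of patients, each sampled at diagnosis (DX) and
#'   post-therapy (PTX). At least 3.
#' @param cell_types Cell-type labels.
#' @param base_props Baseline expected proportions (recycled/normalized).
#' @param composition_shift_delta Planted DX to PTX proportion change applied
#'   to `shift_type`; the remaining types are scaled down proportionally.
#' @param shift_type Cell type receiving the planted shift.
#' @param patient_concentration,sample_concentration Dirichlet concentrations
#'   for between-patient and within-sample variation (larger = less noise).
#' @param rng_seed Integer seed.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 22,
                          cell_types = sprintf("type%d", 1:6),
                          base_props = NULL,
                          composition_shift_delta = 0.1,
                          shift_type = cell_types[[1]],
                          patient_concentration = 200,
                          sample_concentration = 500,
                          rng_seed = 1L) {
  stop_if(n_patients < 3, "n_patients must be >= 3 for paired tests")
  if (is.null(base_props)) base_props <- rev(seq_along(cell_types))
  base_props <- base_props / sum(base_props)
  stop_if(length(base_props) != length(cell_types),
          "base_props must match cell_types")
  stop_if(!shift_type %in% cell_types, "shift_type must be a cell type")
  structure(list(n_patients = as.integer(n_patients), cell_types = cell_types,
                 base_props = base_props,
                 composition_shift_delta = as.numeric(composition_shift_delta),
                 shift_type = shift_type,
                 patient_concentration = as.numeric(patient_concentration),
                 sample_concentration = as.numeric(sample_concentration),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  g / sum(g)
}

#' Generate paired DX/PTX cell-type compositions with a planted shift
#'
#' Per patient, a baseline composition is drawn around `base_props`; the DX
#' sample is Dirichlet noise around it, and the PTX sample is Dirichlet noise
#' around the baseline with `composition_shift_delta` added to the shifted
#' type (other types scaled down proportionally).
#'
#' @param config A [cohort_config()].
#'
#' @return A tibble (patient, timepoint, cell_type, proportion); proportions
#'   sum to 1 within each (patient, timepoint). The planted shift is attached
#'   as attribute `planted_shifts` (tibble: cell_type, delta).
#' @export
generate_paired_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$rng_seed, generate_paired_cohort_impl(config))
}

generate_paired_cohort_impl <- function(cfg) {
  k <- length(cfg$cell_types)
  shift_i <- match(cfg$shift_type, cfg$cell_types)
  out <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    p0 <- rdirichlet1(cfg$base_props * cfg$patient_concentration)
    p_ptx <- p0
    p_ptx[shift_i] <- p0[shift_i] + cfg$composition_shift_delta
    stop_if(p_ptx[shift_i] < 0 || p_ptx[shift_i] > 1,
            "planted shift pushes a proportion outside [0, 1]")
    p_ptx[-shift_i] <- p0[-shift_i] * (1 - p_ptx[shift_i]) / (1 - p0[shift_i])
    dx <- rdirichlet1(p0 * cfg$sample_concentration)
    ptx <- rdirichlet1(p_ptx * cfg$sample_concentration)
    out[[i]] <- tibble::tibble(
      patient = sprintf("P%02d", i),
      timepoint = rep(c("DX", "PTX"), each = k),
      cell_type = rep(cfg$cell_types, 2L),
      proportion = c(dx, ptx)
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "planted_shifts") <- tibble::tibble(
    cell_type = cfg$shift_type, delta = cfg$composition_shift_delta)
  res
}
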