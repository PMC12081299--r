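#' Configuration for the end-to-end pipeline
#'
#' Bundles every stage's parameters with a single seed. Defaults are the
#' pipeline's reference values: +/-500 kb window, coefficient > 0.2,
#' q < 0.01, k = 25, max_shared = 3, min_cells = 100, 5-15 RNA cells
#' retained, DE filters 0.05/0.05/500.
#'
#' @param link [link_thresholds()].
#' @param metacell [metacell_params()].
#' @param de [de_params()].
#' @param de_q_max,da_q_max,motif_q_max Significance gates used by network
#'   assembly.
#' @param n_background,bins Motif-deviation background parameters.
#' @param sparse_states States assembled with the >20%-accessible rule
#'   instead of the differential-accessibility gate.
#' @param scale_factor Log-normalization scale factor.
#' @param rng_seed Integer seed driving every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(link = link_thresholds(),
                       metacell = metacell_params(),
                       de = de_params(),
                       de_q_max = 0.05, da_q_max = 0.05, motif_q_max = 0.05,
                       n_background = 50, bins = 20,
                       sparse_states = character(0),
                       scale_factor = 1e4,
                       rng_seed = 1L) {
  structure(list(link = link, metacell = metacell, de = de,
                 de_q_max = de_q_max, da_q_max = da_q_max,
                 motif_q_max = motif_q_max, n_background = n_background,
                 bins = bins, sparse_states = sparse_states,
                 scale_factor = scale_factor,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("pipeline stage '", stage, "' failed: ",
                        conditionMessage(e)), parent = e)
  })
}

#' Run the multiome pipeline end to end
#'
#' Normalizes the RNA and ATAC matrices, builds and aggregates metacells,
#' predicts enhancer-promoter links, computes motif deviation z-scores and
#' per-state differential expression/accessibility/motif activity, assembles
#' one regulatory network per state, and records a manifest (seed, parameter
#' hash, per-stage row counts). Re-running with the same inputs and
#' configuration reproduces the manifest byte for byte.
#'
#' @param sim A [generate_multiome()] result (or a list with the same
#'   components: rna, atac, cell_meta, peaks, promoters, motifs, embedding).
#' @param config A [run_config()].
#' @return A list of class `trn_pipeline`: normalized layers, metacell map,
#'   `links` (class `ep_links`), `deviations`, `de`, `da`, `motifs_diff`,
#'   `networks` (one `trn_network` per state), `manifest` and
#'   `manifest_json`.
#' @export
run_pipeline <- function(sim, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  meta <- sim$cell_meta
  rna_meta <- meta[meta$modality == "RNA", , drop = FALSE]
  atac_meta <- meta[meta$modality == "ATAC", , drop = FALSE]
  states <- sort(unique(meta$state))

  rna_n <- run_stage("normalize_rna",
                     log_normalize(sim$rna, config$scale_factor))
  atac_n <- run_stage("normalize_atac",
                      log_normalize(sim$atac, config$scale_factor))

  map <- run_stage("metacells", build_metacells(
    sim$embedding,
    modality = stats::setNames(meta$modality, meta$cell),
    groups = stats::setNames(meta$patient, meta$cell),
    params = config$metacell))
  expr_mc <- run_stage("aggregate_rna", aggregate_metacells(rna_n, map))
  acc_mc <- run_stage("aggregate_atac", aggregate_metacells(atac_n, map))

  links <- run_stage("links", link_enhancers(expr_mc, acc_mc, sim$promoters,
                                             sim$peaks, config$link))

  dev <- run_stage("motif_deviations", motif_deviation_z(
    sim$atac, sim$motifs, n_background = config$n_background,
    bins = config$bins, rng_seed = config$rng_seed))
  atac_states <- stats::setNames(atac_meta$state, atac_meta$cell)
  motifs_diff <- run_stage("differential_motifs",
                           differential_motifs(dev, atac_states))

  rna_states <- stats::setNames(rna_meta$state, rna_meta$cell)
  de <- run_stage("de_genes", de_genes(rna_n, rna_states, config$de,
                                       rng_seed = config$rng_seed))
  da <- run_stage("da_peaks", dplyr::bind_rows(lapply(states, function(s) {
    da_peaks_pseudobulk(sim$atac, atac_states,
                        stats::setNames(atac_meta$patient, atac_meta$cell),
                        state = s)
  })))

  networks <- run_stage("trn", lapply(stats::setNames(states, states),
                                      function(s) {
    atac_cells_s <- atac_meta$cell[atac_meta$state == s]
    rna_cells_s <- rna_meta$cell[rna_meta$state == s]
    expr_frac <- as.numeric(Matrix::rowSums(
      rna_n[, rna_cells_s, drop = FALSE] != 0)) / length(rna_cells_s)
    names(expr_frac) <- rownames(rna_n)
    acc_frac <- peak_accessible_fraction(sim$atac, atac_cells_s)
    assemble_network(links, sim$motifs, de, da, motifs_diff,
                     expressed_fraction = expr_frac,
                     accessible_fraction = acc_frac, state = s,
                     sparse_state_mode = s %in% config$sparse_states,
                     de_q_max = config$de_q_max, da_q_max = config$da_q_max,
                     motif_q_max = config$motif_q_max)
  }))

  manifest <- list(
    package = "trnlink",
    version = as.character(utils::packageVersion("trnlink")),
    rng_seed = config$rng_seed,
    parameter_hash = rlang::hash(unclass_config(config)),
    stages = list(
      n_rna_cells = ncol(sim$rna), n_atac_cells = ncol(sim$atac),
      n_genes = nrow(sim$rna), n_peaks = nrow(sim$atac),
      n_metacells_accepted = nrow(map$metacells),
      n_metacells_retained = sum(map$metacells$retained),
      n_link_tests = nrow(links),
      n_links_significant = sum(links$significant),
      n_de_calls = sum(de$q_value < config$de_q_max),
      n_da_calls = sum(da$q_value < config$da_q_max),
      n_motif_calls = sum(motifs_diff$q_value < config$motif_q_max),
      edges_per_state = lapply(networks, function(nw) nrow(nw$edges))
    )
  )
  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)

  structure(list(rna_norm = rna_n, atac_norm = atac_n, metacells = map,
                 expr_mc = expr_mc, acc_mc = acc_mc, links = links,
                 deviations = dev, motifs_diff = motifs_diff, de = de,
                 da = da, networks = networks, manifest = manifest,
                 manifest_json = as.character(manifest_json),
                 config = config),
            class = "trn_pipeline")
}

unclass_config <- function(cfg) {
  rapply(unclass(cfg), unclass, how = "replace")
}

#' @export
print.trn_pipeline <- function(x, ...) {
  st <- x$manifest$stages
  cat("<trn_pipeline> ", st$n_metacells_retained, " metacells; ",
      st$n_links_significant, "/", st$n_link_tests, " significant links; ",
      "edges per state: ",
      paste(names(x$networks), unlist(st$edges_per_state), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
glance.trn_pipeline <- function(x, ...) {
  st <- x$manifest$stages
  tibble::tibble(n_metacells = st$n_metacells_retained,
                 n_link_tests = st$n_link_tests,
                 n_links_significant = st$n_links_significant,
                 n_de_calls = st$n_de_calls, n_da_calls = st$n_da_calls,
                 n_edges = sum(unlist(st$edges_per_state)))
}
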