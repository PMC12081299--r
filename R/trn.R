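#' Assemble the state-specific transcriptional regulatory network
#'
#' Applies the network rules in order: (1) significant enhancer-promoter
#' links are restricted to those whose enhancer peak is differentially
#' accessible for the state (q below `da_q_max` and more accessible in the
#' state, since positive-coefficient links describe activating enhancers), or
#' - in
#' `sparse_state_mode`, meant for states with too few differential peaks - to
#' peaks accessible in strictly more than 20% of the state's cells; (2) a
#' transcription factor enters the network when it is differentially
#' expressed (up) or shows positive differential motif activity for the
#' state, and is
#' expressed in at least 20% of the state's cells (inclusive); (3) target
#' genes are restricted to the state's differentially expressed genes; (4) an
#' edge (tf, target, peak) exists when the TF's motif is present at the
#' enhancer peak of a surviving link. Differential calls are gated on the
#' state-positive direction throughout: a state's network is built from its
#' own up-regulated genes and open enhancers, not from markers of other
#' states. Edge weight is the regression
#' coefficient times the fraction of state cells accessible at the enhancer.
#'
#' @param links An [link_enhancers()] result (or any tibble with gene, peak,
#'   coefficient and significant columns).
#' @param motif_hits Peak-by-motif 0/1 matrix; motif names are TF gene names.
#' @param de_table [de_genes()] output covering the state (uses q < `de_q_max`
#'   as the differential-expression call).
#' @param da_table [da_peaks_pseudobulk()] output for the state; may be
#'   `NULL` in `sparse_state_mode`.
#' @param motif_table [differential_motifs()] output covering the state.
#' @param expressed_fraction Named per-gene fraction of state cells with
#'   non-zero expression (for TF inclusion).
#' @param accessible_fraction Named per-peak fraction of state cells with
#'   non-zero accessibility (for edge weights and the sparse-state rule).
#' @param state State label.
#' @param sparse_state_mode Replace the differential-accessibility gate by
#'   the >20% accessible-fraction gate; default `FALSE`.
#' @param de_q_max,da_q_max,motif_q_max Significance cutoffs for the
#'   differential expression, accessibility and motif-activity gates
#'   (defaults 0.05).
#' @param expr_min_frac TF expressed-fraction floor (inclusive); default 0.20.
#' @param accessible_min_frac Sparse-state accessible-fraction floor
#'   (strict); default 0.20.
#' @return An object of class `trn_network`: list with `state`, `tf_nodes`
#'   (tf, activity_diff, expressed_fraction, included_by), `target_nodes`
#'   (gene, log_fc) and `edges` (tf, target, peak, coefficient,
#'   accessible_fraction, weight).
#' @export
assemble_network <- function(links, motif_hits, de_table, da_table,
                             motif_table, expressed_fraction,
                             accessible_fraction, state,
                             sparse_state_mode = FALSE,
                             de_q_max = 0.05, da_q_max = 0.05,
                             motif_q_max = 0.05, expr_min_frac = 0.20,
                             accessible_min_frac = 0.20) {
  missing_in <- c(links = missing(links) || is.null(links),
                  motif_hits = missing(motif_hits) || is.null(motif_hits),
                  de_table = missing(de_table) || is.null(de_table),
                  motif_table = missing(motif_table) || is.null(motif_table),
                  expressed_fraction = missing(expressed_fraction) ||
                    is.null(expressed_fraction),
                  accessible_fraction = missing(accessible_fraction) ||
                    is.null(accessible_fraction))
  if (!sparse_state_mode)
    missing_in <- c(missing_in, da_table = is.null(da_table))
  stop_if(any(missing_in),
          paste0("missing inputs: ",
                 paste(names(missing_in)[missing_in], collapse = ", ")))

  links <- tibble::as_tibble(links)
  sig <- links[links$significant, , drop = FALSE]

  # (1) enhancer gate: DA peaks, or accessible fraction in sparse-state mode
  if (sparse_state_mode) {
    ok_peaks <- names(accessible_fraction)[accessible_fraction >
                                             accessible_min_frac]
  } else {
    da_s <- da_table[da_table$state == state & da_table$q_value < da_q_max &
                       da_table$log_fc > 0, , drop = FALSE]
    ok_peaks <- da_s$peak
  }
  sig <- sig[sig$peak %in% ok_peaks, , drop = FALSE]

  # (3) targets restricted to the state's DE genes
  de_s <- de_table[de_table$state == state & de_table$q_value < de_q_max &
                     de_table$log_fc > 0, , drop = FALSE]
  sig <- sig[sig$gene %in% de_s$gene, , drop = FALSE]

  # (2) TF inclusion
  motif_s <- motif_table[motif_table$state == state, , drop = FALSE]
  tf_universe <- colnames(motif_hits)
  de_tfs <- intersect(tf_universe, de_s$gene)
  active_tfs <- motif_s$motif[motif_s$q_value < motif_q_max &
                                motif_s$activity_diff > 0]
  expr_ok <- tf_universe[tf_universe %in% names(expressed_fraction) &
                           expressed_fraction[tf_universe] >= expr_min_frac]
  included <- intersect(union(de_tfs, active_tfs), expr_ok)
  included_by <- vapply(included, function(tf) {
    paste(c(if (tf %in% de_tfs) "DE",
            if (tf %in% active_tfs) "motif_activity"), collapse = "+")
  }, character(1))

  # (4) edges where the TF motif is present at the link's enhancer
  edges <- list()
  if (nrow(sig) > 0 && length(included) > 0) {
    hm <- as.matrix(motif_hits[, included, drop = FALSE]) > 0
    for (i in seq_len(nrow(sig))) {
      pk <- sig$peak[[i]]
      if (!pk %in% rownames(hm)) next
      tfs_here <- included[hm[pk, ]]
      if (length(tfs_here) == 0) next
      af <- unname(accessible_fraction[pk])
      edges[[length(edges) + 1]] <- tibble::tibble(
        tf = tfs_here, target = sig$gene[[i]], peak = pk,
        coefficient = sig$coefficient[[i]],
        accessible_fraction = af,
        weight = edge_weight(sig$coefficient[[i]], af))
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(tf = character(0), target = character(0),
                   peak = character(0), coefficient = numeric(0),
                   accessible_fraction = numeric(0), weight = numeric(0))
  act <- stats::setNames(motif_s$activity_diff, motif_s$motif)
  tf_nodes <- tibble::tibble(
    tf = included,
    activity_diff = as.numeric(act[included]),
    expressed_fraction = as.numeric(expressed_fraction[included]),
    included_by = unname(included_by))
  tf_nodes <- tf_nodes[tf_nodes$tf %in% edges$tf, , drop = FALSE]
  target_nodes <- de_s[de_s$gene %in% edges$target, c("gene", "log_fc")]
  target_nodes <- dplyr::distinct(target_nodes)

  structure(list(state = state, tf_nodes = tf_nodes,
                 target_nodes = target_nodes, edges = edges),
            class = "trn_network")
}

#' Edge weight of a regulatory interaction
#'
#' The product of the enhancer-promoter regression coefficient and the
#' fraction of state cells accessible at the enhancer peak.
#'
#' @param coefficient Regression coefficient(s).
#' @param accessible_fraction Accessible fraction(s) in \[0, 1\].
#' @return Numeric weight(s).
#' @export
edge_weight <- function(coefficient, accessible_fraction) {
  stop_if(any(accessible_fraction < 0 | accessible_fraction > 1),
          "accessible_fraction must lie in [0, 1]")
  coefficient * accessible_fraction
}

#' Rank transcription factors by the fraction of targets they regulate
#'
#' @param network A [assemble_network()] result.
#' @param n Number of top regulators to return; default 15.
#' @return A tibble (tf, n_targets, fraction_targets) sorted by descending
#'   fraction, ties broken lexicographically by TF name.
#' @export
top_regulators <- function(network, n = 15) {
  stopifnot(inherits(network, "trn_network"))
  if (nrow(network$edges) == 0)
    return(tibble::tibble(tf = character(0), n_targets = integer(0),
                          fraction_targets = numeric(0)))
  n_targets_total <- nrow(network$target_nodes)
  per_tf <- dplyr::summarise(dplyr::group_by(network$edges, .data$tf),
                             n_targets = dplyr::n_distinct(.data$target),
                             .groups = "drop")
  per_tf$fraction_targets <- per_tf$n_targets / n_targets_total
  per_tf <- per_tf[order(-per_tf$fraction_targets, per_tf$tf), , drop = FALSE]
  utils::head(per_tf, n)
}

#' Direction of expression change between diagnosis and post-therapy
#'
#' Mean log-normalized expression difference (PTX minus DX) among the given
#' cells, thresholded into up / down / unchanged.
#'
#' @param norm Gene-by-cell normalized matrix restricted to (or indexed by)
#'   the cells of one state.
#' @param timepoints Per-cell timepoint labels (`"DX"` / `"PTX"`), column
#'   order or named.
#' @param genes Genes to classify; all rows by default.
#' @param logfc_threshold Absolute difference below which a gene is
#'   `"unchanged"`; default 0.1.
#' @return A tibble (gene, mean_dx, mean_ptx, diff, direction).
#' @export
dx_ptx_direction <- function(norm, timepoints, genes = NULL,
                             logfc_threshold = 0.1) {
  if (!is.null(names(timepoints)) && !is.null(colnames(norm)))
    timepoints <- timepoints[colnames(norm)]
  stop_if(length(timepoints) != ncol(norm),
          "timepoints must have one label per cell")
  genes <- genes %||% rownames(norm)
  sub <- norm[genes, , drop = FALSE]
  has_dx <- any(timepoints == "DX"); has_ptx <- any(timepoints == "PTX")
  if (!has_dx || !has_ptx) {
    rlang::warn("a timepoint is absent; directions set to 'unchanged'")
    return(tibble::tibble(gene = genes, mean_dx = NA_real_,
                          mean_ptx = NA_real_, diff = NA_real_,
                          direction = "unchanged"))
  }
  m_dx <- Matrix::rowMeans(sub[, timepoints == "DX", drop = FALSE])
  m_ptx <- Matrix::rowMeans(sub[, timepoints == "PTX", drop = FALSE])
  d <- as.numeric(m_ptx - m_dx)
  tibble::tibble(gene = genes, mean_dx = as.numeric(m_dx),
                 mean_ptx = as.numeric(m_ptx), diff = d,
                 direction = ifelse(abs(d) < logfc_threshold, "unchanged",
                                    ifelse(d > 0, "up", "down")))
}

#' Validate the structural invariants of a regulatory network
#'
#' Checks that every edge's TF and target exist as nodes, that every edge's
#' (target, peak) is a significant link in the supplied link table, that the
#' TF's motif is present at the edge peak, and that each weight equals the
#' coefficient times the accessible fraction.
#'
#' @param network A [assemble_network()] result.
#' @param links The link table the network was assembled from.
#' @param motif_hits The peak-by-motif hit matrix.
#' @return `TRUE` invisibly; aborts with the violated invariant otherwise.
#' @export
validate_trn <- function(network, links, motif_hits) {
  stopifnot(inherits(network, "trn_network"))
  e <- network$edges
  if (nrow(e) == 0) return(invisible(TRUE))
  stop_if(!all(e$tf %in% network$tf_nodes$tf),
          "edge TF missing from tf_nodes")
  stop_if(!all(e$target %in% network$target_nodes$gene),
          "edge target missing from target_nodes")
  links <- tibble::as_tibble(links)
  sig_keys <- paste(links$gene[links$significant],
                    links$peak[links$significant])
  stop_if(!all(paste(e$target, e$peak) %in% sig_keys),
          "edge (target, peak) is not a significant link")
  hm <- as.matrix(motif_hits) > 0
  stop_if(!all(hm[cbind(e$peak, e$tf)]),
          "edge TF motif absent at the enhancer peak")
  stop_if(!isTRUE(all.equal(e$weight,
                            e$coefficient * e$accessible_fraction)),
          "edge weight != coefficient x accessible_fraction")
  invisible(TRUE)
}

#' @export
print.trn_network <- function(x, ...) {
  cat("<trn_network> state ", x$state, ": ", nrow(x$tf_nodes), " TFs, ",
      nrow(x$target_nodes), " targets, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
tidy.trn_network <- function(x, ...) x$edges

#' @export
glance.trn_network <- function(x, ...) {
  tibble::tibble(state = x$state, n_tfs = nrow(x$tf_nodes),
                 n_targets = nrow(x$target_nodes), n_edges = nrow(x$edges))
}

#' Convert a regulatory network to an igraph object
#'
#' @param network A [assemble_network()] result.
#' @return An igraph directed graph with node and edge attributes.
#' @export
trn_igraph <- function(network) {
  stopifnot(inherits(network, "trn_network"))
  rlang::check_installed("igraph")
  nodes <- dplyr::bind_rows(
    tibble::tibble(name = network$tf_nodes$tf, kind = "tf",
                   size_attr = network$tf_nodes$activity_diff),
    tibble::tibble(name = setdiff(network$target_nodes$gene,
                                  network$tf_nodes$tf),
                   kind = "target",
                   size_attr = network$target_nodes$log_fc[
                     match(setdiff(network$target_nodes$gene,
                                   network$tf_nodes$tf),
                           network$target_nodes$gene)]))
  igraph::graph_from_data_frame(
    network$edges[, c("tf", "target", "peak", "coefficient", "weight")],
    directed = TRUE, vertices = nodes)
}

#' Plot a regulatory network
#'
#' @param object A `trn_network`.
#' @param ... Unused.
#' @return A ggplot of the network with TFs as diamonds and targets as
#'   circles, edge width proportional to weight.
#' @export
autoplot.trn_network <- function(object, ...) {
  rlang::check_installed("igraph")
  g <- trn_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name, kind = igraph::V(g)$kind,
                          x = lay[, 1], y = lay[, 2])
  ed <- object$edges
  ed$x <- nodes$x[match(ed$tf, nodes$name)]
  ed$y <- nodes$y[match(ed$tf, nodes$name)]
  ed$xend <- nodes$x[match(ed$target, nodes$name)]
  ed$yend <- nodes$y[match(ed$target, nodes$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = abs(.data$weight)),
                          colour = "grey70", alpha = 0.7) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$kind,
                                     colour = .data$kind), size = 3) +
    ggplot2::scale_shape_manual(values = c(tf = 18, target = 16)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste("Regulatory network:", object$state))
}
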