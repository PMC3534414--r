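# The two-step module search: (1) enrichment of the reference network to an
# organism-specific subnetwork from presence evidence, (2) functional-module
# extraction on the enriched subnetwork from trend-derived node scores and
# differential-EST edge scores.

#' Enrichment step: reduce the network to an organism-specific subnetwork
#'
#' Nodes of measured metabolites score \code{+1}; unmeasured nodes score a
#' small negative value so that connector metabolites are admitted only when
#' needed. Edges carry the enzyme-presence scores (+0.01 / -0.01). The
#' maximum-scoring connected subnetwork under these scores is the enriched
#' network used by [find_functional_module()].
#'
#' @param net metabolite network.
#' @param measured_nodes character vector of measured metabolite IDs;
#'   IDs absent from the network are dropped with a message.
#' @param presence [score_edges_presence()] table for \code{net}.
#' @param unmeasured_score node score for unmeasured metabolites
#'   (default \code{-0.001}).
#' @param method solver backend, see [solve_mwcs()].
#' @param edge_semantics \code{"induced"} (default: the enriched network is
#'   the subgraph induced by the selected nodes) or \code{"selected"} (only
#'   the solver-chosen edges are kept).
#' @param ... passed to [solve_mwcs()].
#' @return List with \code{scored_network}, \code{module} and
#'   \code{enriched} (the enriched subnetwork as an \code{igraph}).
#' @export
enrich_network <- function(net, measured_nodes, presence,
                           unmeasured_score = -0.001,
                           method = "exact",
                           edge_semantics = c("induced", "selected"), ...) {
  edge_semantics <- match.arg(edge_semantics)
  if (length(measured_nodes) == 0)
    stop_usage("measured_nodes must not be empty")
  known <- intersect(measured_nodes, igraph::V(net)$name)
  if (length(known) < length(measured_nodes))
    message(length(measured_nodes) - length(known),
            " measured IDs not in the network were ignored")
  if (length(known) == 0)
    stop_usage("none of the measured metabolites occur in the network")
  ns <- stats::setNames(rep(unmeasured_score, igraph::vcount(net)),
                        igraph::V(net)$name)
  ns[known] <- 1
  sn <- scored_network(net, ns, presence)
  module <- solve_mwcs(sn, method = method, ...)
  enriched <- if (edge_semantics == "induced") {
    igraph::induced_subgraph(net, module$nodes)
  } else {
    keep <- igraph::get_edge_ids(net, t(as.matrix(module$edges[, c("from", "to")])))
    igraph::subgraph_from_edges(net, keep[keep > 0], delete.vertices = FALSE)
  }
  if (edge_semantics == "selected")
    enriched <- igraph::induced_subgraph(
      enriched, igraph::V(enriched)$name[igraph::V(enriched)$name %in% module$nodes])
  list(scored_network = sn, module = module, enriched = enriched)
}

#' Module step: extract the functional module from the enriched network
#'
#' Attaches the BUM-derived node scores and the differential-EST edge scores
#' to the enriched subnetwork and solves for the maximum-scoring connected
#' subgraph. Nodes absent from the score table receive the unmeasured-node
#' score; edges without a score fall back to \code{-0.01}.
#'
#' @param enriched enriched subnetwork (from [enrich_network()]).
#' @param node_scores a [score_nodes()] table.
#' @param edge_scores an edge-score table ([score_edges_dest()]).
#' @param trend optional [umbrella_test_profiles()] result; when given, the
#'   module nodes are annotated with the signed Z statistic (positive =
#'   umbrella, negative = inverse umbrella).
#' @param method solver backend, see [solve_mwcs()].
#' @param ... passed to [solve_mwcs()].
#' @return A \code{module_result} with an extra \code{annotation} element
#'   (per-node score, p-value, z, direction, measured flag).
#' @export
find_functional_module <- function(enriched, node_scores, edge_scores,
                                   trend = NULL, method = "exact", ...) {
  sn <- scored_network(enriched, node_scores, edge_scores,
                       default_node = attr(node_scores, "unmeasured_score"),
                       default_edge = -0.01)
  module <- solve_mwcs(sn, method = method, ...)
  first <- if (is.list(module) && !inherits(module, "module_result"))
    module[[1]] else module
  idx <- match(first$nodes, node_scores$node)
  ann <- data.frame(node = first$nodes,
                    score = stats::setNames(igraph::V(sn)$score,
                                            igraph::V(sn)$name)[first$nodes],
                    p_value = node_scores$p_value[idx],
                    measured = !is.na(idx) & node_scores$measured[idx],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(trend)) {
    ti <- match(first$nodes, trend$metabolite_id)
    ann$z <- trend$z[ti]
    ann$direction <- ifelse(is.na(ann$z), NA_character_,
                            ifelse(ann$z >= 0, "umbrella", "inverse-umbrella"))
  }
  first$annotation <- ann
  if (is.list(module) && !inherits(module, "module_result")) {
    module[[1]] <- first
    return(module)
  }
  first
}

#' Run the full integrated analysis
#'
#' Orchestrates the complete workflow: umbrella trend tests on the profiles,
#' BUM fitting and node scoring, enzyme-presence and differential-EST edge
#' scoring, the enrichment step, and the functional-module step.
#'
#' @param net metabolite network.
#' @param profiles a [profile_matrix()]; its metabolite IDs must be network
#'   node IDs (use \code{name_map} otherwise).
#' @param ec_map EST-to-EC mapping data frame (\code{est_id}, \code{ec}).
#' @param dest_counts differential-EST count table (\code{cluster_id},
#'   \code{ko}, \code{n_active}, \code{n_inactive}).
#' @param name_map optional two-column data frame (\code{name}, \code{id})
#'   resolving measured metabolite names to compound IDs.
#' @param peak umbrella peak time point (default 10).
#' @param fdr false discovery rate for node scoring (default 0.2).
#' @param t differential-EST threshold (default 1).
#' @param pseudocount for the dEST log-ratio (default 1).
#' @param method solver backend.
#' @param ... passed to [solve_mwcs()].
#' @return List with elements \code{trend}, \code{bum}, \code{node_scores},
#'   \code{presence}, \code{edge_scores}, \code{enrichment}, \code{module}.
#' @export
run_pipeline <- function(net, profiles, ec_map, dest_counts,
                         name_map = NULL, peak = 10, fdr = 0.2, t = 1,
                         pseudocount = 1, method = "exact", ...) {
  if (!is.null(name_map)) {
    idx <- match(profiles$metabolites, name_map$name)
    mapped <- !is.na(idx)
    profiles$metabolites[mapped] <- name_map$id[idx[mapped]]
    dimnames(profiles$values)[[1]] <- profiles$metabolites
  }
  trend <- umbrella_test_profiles(profiles, peak = peak)
  usable <- trend[trend$ok & !is.na(trend$p_value), ]
  bum <- fit_bum(usable$p_value)
  node_scores <- score_nodes(bum,
                             stats::setNames(usable$p_value,
                                             usable$metabolite_id),
                             fdr = fdr, nodes = igraph::V(net)$name)
  presence <- score_edges_presence(net, ec_map)
  enrichment <- enrich_network(net, usable$metabolite_id, presence,
                               method = method, ...)
  edge_scores <- score_edges_dest(net, dest_counts, t = t,
                                  pseudocount = pseudocount,
                                  presence = presence)
  module <- find_functional_module(enrichment$enriched, node_scores,
                                   edge_scores, trend = trend,
                                   method = method, ...)
  list(trend = trend, bum = bum, node_scores = node_scores,
       presence = presence, edge_scores = edge_scores,
       enrichment = enrichment, module = module)
}

#' Summary statistics of the profile-scoring stage
#'
#' Convenience wrapper reproducing the headline statistics of a
#' dehydration/rehydration profile analysis: umbrella-test p-values, the BUM
#' fit (pi-upper, the estimated noise fraction, and its complement, the
#' signal fraction), the node-score range, the unmeasured-node score, and
#' the inertia explained by the first two correspondence-analysis axes (for
#' all profiles and for a top-variance subset).
#'
#' @param pm a [profile_matrix()].
#' @param peak umbrella peak time point (default 10).
#' @param fdr false discovery rate (default 0.2).
#' @param top_fraction variance fraction for the CA subset (default 0.1).
#' @return List: \code{trend}, \code{bum}, \code{pi_upper},
#'   \code{signal_fraction_pct}, \code{tau}, \code{score_range},
#'   \code{unmeasured_score}, \code{ca_inertia_first2_all},
#'   \code{ca_inertia_first2_top}.
#' @export
profile_scoring_summary <- function(pm, peak = 10, fdr = 0.2,
                                    top_fraction = 0.1) {
  trend <- umbrella_test_profiles(pm, peak = peak)
  usable <- trend[trend$ok & !is.na(trend$p_value), ]
  bum <- fit_bum(usable$p_value)
  scores <- score_nodes(bum, stats::setNames(usable$p_value,
                                             usable$metabolite_id),
                        fdr = fdr)
  ca_all <- correspondence_analysis(pm)
  ca_top <- correspondence_analysis(top_variance(pm, top_fraction))
  list(trend = trend, bum = bum, pi_upper = bum$pi_upper,
       signal_fraction_pct = 100 * (1 - bum$pi_upper),
       tau = attr(scores, "tau"),
       score_range = range(scores$score[scores$measured]),
       unmeasured_score = attr(scores, "unmeasured_score"),
       ca_inertia_first2_all = sum(ca_all$inertia_fractions[1:2]),
       ca_inertia_first2_top = sum(ca_top$inertia_fractions[1:2]))
}
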