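# Plain-text interchange: GraphML / SIF network export, TSV tables.

#' Write a metabolite network as GraphML
#'
#' Node attributes: compound ID (\code{name}) and display name; edge
#' attributes: semicolon-joined reaction IDs and enzymes. Non-atomic
#' bookkeeping graph attributes (fusion log etc.) are dropped from the file.
#'
#' @param net metabolite network (optionally scored).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  for (at in igraph::graph_attr_names(net))
    if (!is.atomic(igraph::graph_attr(net, at)) ||
        length(igraph::graph_attr(net, at)) != 1)
      net <- igraph::delete_graph_attr(net, at)
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a metabolite network in SIF format
#'
#' One line per edge: \code{node TAB rxn TAB node}.
#'
#' @param net metabolite network.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_network_sif <- function(net, path) {
  ends <- igraph::as_edgelist(net)
  lines <- if (nrow(ends)) paste(ends[, 1], "rxn", ends[, 2], sep = "\t")
           else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a network written by [write_network_graphml()]
#'
#' @param path GraphML file.
#' @return Undirected \code{igraph}.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read auxiliary two-column tables
#'
#' \code{read_pool_list}: TSV with column \code{id} (optionally \code{name});
#' \code{read_fusion_table}: TSV with columns \code{anomer},
#' \code{canonical}; \code{read_name_map}: TSV with columns \code{name},
#' \code{id}; \code{read_ec_map}: TSV with columns \code{est_id}, \code{ec};
#' \code{read_dest_counts}: TSV with columns \code{cluster_id}, \code{ko},
#' \code{n_active}, \code{n_inactive}.
#'
#' @param path TSV file.
#' @return Data frame (character vector of IDs for \code{read_pool_list}).
#' @name read_tables
NULL

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_usage(path, " lacks required columns: ",
               paste(missing, collapse = ", "))
  df
}

#' @rdname read_tables
#' @export
read_pool_list <- function(path) read_tsv_checked(path, "id")$id

#' @rdname read_tables
#' @export
read_fusion_table <- function(path)
  read_tsv_checked(path, c("anomer", "canonical"))

#' @rdname read_tables
#' @export
read_name_map <- function(path) read_tsv_checked(path, c("name", "id"))

#' @rdname read_tables
#' @export
read_ec_map <- function(path) read_tsv_checked(path, c("est_id", "ec"))

#' @rdname read_tables
#' @export
read_dest_counts <- function(path)
  read_tsv_checked(path, c("cluster_id", "ko", "n_active", "n_inactive"))

#' Read a p-value table (node_id, p_value)
#'
#' @param path TSV file.
#' @return Named numeric vector.
#' @export
read_pvalues <- function(path) {
  df <- read_tsv_checked(path, c("node_id", "p_value"))
  stats::setNames(df$p_value, df$node_id)
}

#' Write a module result as TSV files and GraphML
#'
#' Writes \code{<prefix>_nodes.tsv}, \code{<prefix>_edges.tsv},
#' \code{<prefix>.graphml} and a plain-text solve report
#' \code{<prefix>_report.txt}.
#'
#' @param module a \code{module_result}.
#' @param prefix output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_module <- function(module, prefix) {
  nodes <- if (!is.null(module$annotation)) module$annotation
           else data.frame(node = module$nodes)
  np <- paste0(prefix, "_nodes.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  gp <- paste0(prefix, ".graphml")
  rp <- paste0(prefix, "_report.txt")
  utils::write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(module$edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(module$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, gp, format = "graphml")
  writeLines(c(sprintf("status: %s", module$status),
               sprintf("solver: %s", module$solver),
               sprintf("score: %.6f", module$score),
               sprintf("gap: %s", format(module$gap)),
               sprintf("nodes: %d", length(module$nodes)),
               sprintf("edges: %d", nrow(module$edges))), rp)
  invisible(c(np, ep, gp, rp))
}
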