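#' Parse a KGML pathway document into a directed compound graph
#'
#' Reads a KEGG Markup Language (KGML v0.7.1) pathway description and converts
#' it into a directed graph with compounds as nodes and reactions as edges.
#' Every reaction contributes one directed edge per (substrate, product) pair,
#' annotated with the reaction identifier(s), reversibility, and the enzymes
#' (EC numbers and/or KO identifiers) of the entries linked to the reaction.
#' Compound entries not touched by any reaction are dropped.
#'
#' @param document path to a KGML XML file, or a single string of KGML XML.
#' @return A directed \code{igraph} with vertex attributes \code{name}
#'   (compound ID, e.g. \code{"C00031"}) and \code{display}, edge attributes
#'   \code{reactions}, \code{enzymes} (semicolon-joined sets) and
#'   \code{reversible}; graph attributes \code{pathway_id} and
#'   \code{provenance}.
#' @export
parse_kgml <- function(document) {
  doc <- tryCatch(
    {
      if (length(document) == 1L && !grepl("<", document, fixed = TRUE) &&
          file.exists(document)) {
        xml2::read_xml(document)
      } else {
        xml2::read_xml(paste(document, collapse = "\n"))
      }
    },
    error = function(e) {
      stop_usage("malformed KGML XML: ", conditionMessage(e))
    })
  root <- xml2::xml_name(doc)
  if (!identical(root, "pathway"))
    stop_usage("malformed KGML: root element is <", root, ">, expected <pathway>")
  pathway_id <- xml2::xml_attr(doc, "name")
  if (is.na(pathway_id)) pathway_id <- "unknown"
  pathway_id <- strip_kegg_prefix(pathway_id)

  entries <- xml2::xml_find_all(doc, "./entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  entry_name <- xml2::xml_attr(entries, "name")
  entry_reaction <- xml2::xml_attr(entries, "reaction")

  # display names come from the graphics child, first alternative only
  entry_display <- vapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "./graphics")
    nm <- if (inherits(g, "xml_missing")) NA_character_ else xml2::xml_attr(g, "name")
    if (is.na(nm)) NA_character_ else sub(",.*$", "", nm)
  }, character(1))

  is_cpd <- !is.na(entry_type) & entry_type == "compound"
  cpd_by_entry <- stats::setNames(strip_kegg_prefix(first_token(entry_name[is_cpd])),
                                  entry_id[is_cpd])
  display_by_cpd <- stats::setNames(entry_display[is_cpd], cpd_by_entry)

  # enzymes: entries of type enzyme/ortholog/gene that declare a reaction
  is_enz <- !is.na(entry_type) & entry_type %in% c("enzyme", "ortholog", "gene") &
    !is.na(entry_reaction)
  enzyme_map <- list()
  for (i in which(is_enz)) {
    rns <- strip_kegg_prefix(strsplit(entry_reaction[i], "\\s+")[[1]])
    enz <- strip_kegg_prefix(strsplit(entry_name[i], "\\s+")[[1]])
    for (rn in rns)
      enzyme_map[[rn]] <- union(enzyme_map[[rn]] %||% character(0), enz)
  }

  reactions <- xml2::xml_find_all(doc, "./reaction")
  ef <- et <- er <- ee <- character(0)
  erev <- logical(0)
  for (rx in reactions) {
    rn_names <- xml2::xml_attr(rx, "name")
    if (is.na(rn_names))
      stop_usage("malformed KGML: <reaction> element without name attribute")
    rids <- strip_kegg_prefix(strsplit(rn_names, "\\s+")[[1]])
    rev <- identical(xml2::xml_attr(rx, "type"), "reversible")
    subs <- xml2::xml_find_all(rx, "./substrate")
    prods <- xml2::xml_find_all(rx, "./product")
    sub_cpd <- kgml_side_compounds(subs, cpd_by_entry)
    prod_cpd <- kgml_side_compounds(prods, cpd_by_entry)
    if (length(sub_cpd) == 0 || length(prod_cpd) == 0) next
    enz <- join_semi(unlist(lapply(rids, function(r) enzyme_map[[r]] %||% character(0))))
    for (s in sub_cpd) for (p in prod_cpd) {
      if (s == p) next  # no self-loop edges
      ef <- c(ef, s); et <- c(et, p)
      er <- c(er, join_semi(rids)); ee <- c(ee, enz); erev <- c(erev, rev)
    }
  }

  nodes <- unique(c(ef, et))
  if (length(nodes) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    edf <- data.frame(from = ef, to = et, reactions = er, enzymes = ee,
                      reversible = erev, stringsAsFactors = FALSE)
    vdf <- data.frame(name = nodes,
                      display = unname(display_by_cpd[nodes]),
                      stringsAsFactors = FALSE)
    vdf$display[is.na(vdf$display)] <- vdf$name[is.na(vdf$display)]
    g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
    # merge parallel edges for the same ordered pair
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = edge_attr_comb())
  }
  g <- igraph::set_graph_attr(g, "pathway_id", pathway_id)
  igraph::set_graph_attr(g, "provenance", pathway_id)
}

strip_kegg_prefix <- function(x) sub("^[a-z]{2,4}:", "", x)
first_token <- function(x) vapply(strsplit(x, "\\s+"), `[`, character(1), 1L)

kgml_side_compounds <- function(nodes, cpd_by_entry) {
  if (length(nodes) == 0) return(character(0))
  ids <- xml2::xml_attr(nodes, "id")
  nms <- strip_kegg_prefix(first_token(xml2::xml_attr(nodes, "name")))
  # prefer resolution through the entry id; fall back to the name attribute
  out <- ifelse(!is.na(ids) & ids %in% names(cpd_by_entry),
                unname(cpd_by_entry[ids]), nms)
  unique(out[!is.na(out) & nzchar(out)])
}

#' Combine pathway graphs into one supergraph
#'
#' Takes the union of nodes and edges over a collection of directed pathway
#' graphs sharing the KEGG compound-ID namespace. Edges with identical ordered
#' endpoints are merged, with union semantics for reaction identifiers and
#' enzymes; provenance records every contributing pathway.
#'
#' @param graphs list of graphs as returned by [parse_kgml()].
#' @return A directed \code{igraph} supergraph.
#' @export
merge_pathways <- function(graphs) {
  graphs <- Filter(Negate(is.null), graphs)
  if (length(graphs) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
    return(igraph::set_graph_attr(g, "provenance", character(0)))
  }
  vdfs <- lapply(graphs, function(g) igraph::as_data_frame(g, what = "vertices"))
  edfs <- lapply(graphs, function(g) igraph::as_data_frame(g, what = "edges"))
  vdf <- do.call(rbind, vdfs)
  vdf <- vdf[!duplicated(vdf$name), , drop = FALSE]
  edf <- do.call(rbind, edfs)
  prov <- unique(unlist(lapply(graphs, function(g)
    igraph::graph_attr(g, "provenance") %||% character(0))))
  if (nrow(edf) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(vdf$name, display = vdf$display)
  } else {
    g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = edge_attr_comb())
  }
  igraph::set_graph_attr(g, "provenance", prov)
}

#' Convert a directed pathway (super)graph to an undirected metabolite network
#'
#' Antiparallel edge pairs collapse to a single undirected edge with merged
#' annotations. Reversibility is retained as an annotation but plays no
#' further role once the graph is undirected.
#'
#' @param g directed graph from [parse_kgml()] or [merge_pathways()].
#' @return Undirected \code{igraph} metabolite network with graph attributes
#'   \code{provenance}, \code{fusion_log} and \code{removed_pool}.
#' @export
to_undirected <- function(g) {
  net <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = edge_attr_comb())
  net <- igraph::simplify(net, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = edge_attr_comb())
  if (is.null(igraph::graph_attr(net, "provenance")))
    net <- igraph::set_graph_attr(net, "provenance", character(0))
  net <- igraph::set_graph_attr(net, "fusion_log",
                                data.frame(anomer = character(0),
                                           canonical = character(0),
                                           stringsAsFactors = FALSE))
  igraph::set_graph_attr(net, "removed_pool", character(0))
}

#' Fuse carbohydrate anomers to a single canonical node
#'
#' Replaces each anomer node by its canonical node (e.g. alpha- and
#' beta-D-glucose to D-glucose), re-attaching all incident edges. Duplicate
#' edges created by the fusion are merged and self-loops are dropped; applied
#' merges are recorded in the \code{fusion_log} graph attribute.
#'
#' @param net undirected metabolite network.
#' @param fusion_table data frame with columns \code{anomer} and
#'   \code{canonical} (KEGG compound IDs). See [default_fusion_table()].
#' @return The fused network.
#' @export
fuse_anomers <- function(net, fusion_table = default_fusion_table()) {
  if (is.null(fusion_table) || nrow(fusion_table) == 0) return(net)
  ft <- fusion_table
  if (!all(c("anomer", "canonical") %in% names(ft)))
    stop_usage("fusion_table needs columns 'anomer' and 'canonical'")
  if (anyDuplicated(ft$anomer))
    stop_usage("fusion_table anomer IDs must be pairwise distinct")
  if (any(ft$canonical %in% ft$anomer))
    stop_usage("fusion target appears as a fusion source in fusion_table")
  nms <- igraph::V(net)$name
  hit <- nms %in% ft$anomer
  if (!any(hit)) return(net)
  new_names <- nms
  new_names[hit] <- ft$canonical[match(nms[hit], ft$anomer)]
  applied <- data.frame(anomer = nms[hit],
                        canonical = new_names[hit], stringsAsFactors = FALSE)
  mapping <- match(new_names, unique(new_names))
  disp <- igraph::V(net)$display %||% nms
  # display of the canonical compound wins where it already exists
  g2 <- igraph::contract(net, mapping,
                         vertex.attr.comb = list(name = function(x) x[1],
                                                 display = function(x) x[1],
                                                 "first"))
  igraph::V(g2)$name <- unique(new_names)
  keep_disp <- vapply(split(seq_along(nms),
                            factor(mapping, levels = seq_len(max(mapping)))),
                      function(ix) {
    canon <- which(!hit[ix])
    disp[if (length(canon)) ix[canon[1]] else ix[1]]
  }, character(1))
  igraph::V(g2)$display <- unname(keep_disp)
  g2 <- igraph::simplify(g2, remove.multiple = TRUE, remove.loops = TRUE,
                         edge.attr.comb = edge_attr_comb())
  log_old <- igraph::graph_attr(net, "fusion_log")
  g2 <- igraph::set_graph_attr(g2, "fusion_log", rbind(log_old, applied))
  for (at in c("provenance", "removed_pool"))
    g2 <- igraph::set_graph_attr(g2, at, igraph::graph_attr(net, at))
  g2
}

#' Remove pool ("currency") metabolites from the network
#'
#' Pool metabolites such as ATP, water or NADH connect otherwise unrelated
#' parts of metabolism and create biologically non-specific shortcuts; they
#' are removed together with all incident edges. The default list holds the
#' 13 standard cofactor-like compounds (see [default_pool_metabolites()]).
#'
#' @param net undirected metabolite network.
#' @param pool character vector of KEGG compound IDs to remove.
#' @return Network without the pool nodes; removed IDs are recorded in the
#'   \code{removed_pool} graph attribute. IDs absent from the network are
#'   silently skipped.
#' @export
remove_pool_metabolites <- function(net, pool = default_pool_metabolites()) {
  pool <- unique(pool)
  present <- intersect(pool, igraph::V(net)$name)
  out <- igraph::delete_vertices(net, present)
  igraph::set_graph_attr(out, "removed_pool",
                         union(igraph::graph_attr(net, "removed_pool") %||%
                                 character(0), present))
}

#' Default pool-metabolite list
#'
#' The 13 cofactor-like compounds excluded from the reference network:
#' H+, H2O, orthophosphate, ATP, NAD+, NADH, ADP, CO2, CoA, NADP+, NADPH,
#' NH3 and diphosphate, given as KEGG compound IDs.
#'
#' @return Named character vector of 13 compound IDs (names are the
#'   conventional compound names).
#' @export
default_pool_metabolites <- function() {
  c("H+" = "C00080", "H2O" = "C00001", "Orthophosphate" = "C00009",
    "ATP" = "C00002", "NAD+" = "C00003", "NADH" = "C00004",
    "ADP" = "C00008", "CO2" = "C00011", "CoA" = "C00010",
    "NADP+" = "C00006", "NADPH" = "C00005", "NH3" = "C00014",
    "Diphosphate" = "C00013")
}

#' Default anomer fusion table
#'
#' Editable configuration mapping anomeric carbohydrate IDs to a canonical
#' compound. The shipped table covers the common hexoses; extend it via a
#' two-column TSV (\code{anomer}, \code{canonical}) and [read_fusion_table()].
#'
#' @return Data frame with columns \code{anomer} and \code{canonical}.
#' @export
default_fusion_table <- function() {
  data.frame(
    anomer    = c("C00267", "C00221", "C00984", "C00962", "C02336", "C00936"),
    canonical = c("C00031", "C00031", "C00124", "C00124", "C00095", "C00159"),
    stringsAsFactors = FALSE)
}

#' Build the reference metabolite network from KGML sources
#'
#' Deterministic pipeline: parse each KGML document, combine into one
#' supergraph, convert to an undirected graph, fuse anomers, and remove pool
#' metabolites.
#'
#' @param kgml_sources character vector of KGML file paths (or XML strings).
#' @param fusion_table anomer fusion table, or \code{NULL} to skip fusion.
#' @param pool pool-metabolite IDs, or \code{character(0)} to skip removal.
#' @param verbose print summary counts per stage.
#' @return Undirected metabolite network (\code{igraph}).
#' @export
build_reference_network <- function(kgml_sources,
                                    fusion_table = default_fusion_table(),
                                    pool = default_pool_metabolites(),
                                    verbose = FALSE) {
  if (length(kgml_sources) < 1) stop_usage("at least one KGML source required")
  graphs <- lapply(kgml_sources, parse_kgml)
  super <- merge_pathways(graphs)
  net <- to_undirected(super)
  net <- fuse_anomers(net, fusion_table)
  net <- remove_pool_metabolites(net, pool)
  if (verbose) {
    message(sprintf("reference network: %d pathways -> %d nodes, %d edges",
                    length(graphs), igraph::vcount(net), igraph::ecount(net)))
  }
  net
}
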