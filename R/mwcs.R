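# Maximum-weight connected subgraph (MWCS) with node and edge scores.
#
# A module is a connected subgraph (V', E') with E' a subset of the edges
# induced by V'; its score is the sum of selected node and edge scores.
# Positive induced edges always belong to an optimal edge set; negative
# edges are only taken when needed for connectivity, via a maximum-weight
# spanning connection over the components formed by the positive edges.

#' Attach node and edge scores to a metabolite network
#'
#' @param net undirected \code{igraph} network.
#' @param node_scores named numeric vector, or a [score_nodes()] table.
#' @param edge_scores numeric vector in edge order, or an
#'   [score_edges_presence()] / [score_edges_dest()] table.
#' @param default_node,default_edge fallback scores for nodes/edges not
#'   covered by the tables.
#' @return The network with \code{score} vertex and edge attributes
#'   (a "scored network").
#' @export
scored_network <- function(net, node_scores, edge_scores,
                           default_node = NULL, default_edge = NULL) {
  nms <- igraph::V(net)$name
  if (inherits(node_scores, "node_score_table")) {
    ns <- stats::setNames(node_scores$score, node_scores$node)
    if (is.null(default_node))
      default_node <- attr(node_scores, "unmeasured_score")
  } else ns <- node_scores
  v_score <- unname(ns[nms])
  if (anyNA(v_score)) {
    if (is.null(default_node))
      stop_usage("missing node scores for: ",
                 paste(utils::head(nms[is.na(v_score)], 5), collapse = ", "))
    v_score[is.na(v_score)] <- default_node
  }
  m <- igraph::ecount(net)
  if (inherits(edge_scores, "edge_score_table")) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    tab <- stats::setNames(edge_scores$score,
                           key(edge_scores$from, edge_scores$to))
    ends <- igraph::as_edgelist(net)
    e_score <- unname(tab[key(ends[, 1], ends[, 2])])
    if (!is.null(edge_scores$evidence)) {
      ev <- stats::setNames(edge_scores$evidence,
                            key(edge_scores$from, edge_scores$to))
      net <- igraph::set_edge_attr(net, "evidence",
                                   value = unname(ev[key(ends[, 1], ends[, 2])]))
    }
  } else e_score <- rep_len(edge_scores, m)
  if (anyNA(e_score)) {
    if (is.null(default_edge))
      stop_usage("missing edge scores for ", sum(is.na(e_score)), " edges")
    e_score[is.na(e_score)] <- default_edge
  }
  if (any(!is.finite(v_score)) || any(!is.finite(e_score)))
    stop_usage("all node and edge scores must be finite")
  net <- igraph::set_vertex_attr(net, "score", value = v_score)
  igraph::set_edge_attr(net, "score", value = e_score)
}

# internal solver data
mwcs_data <- function(sn) {
  n <- igraph::vcount(sn)
  ends <- igraph::as_edgelist(sn, names = FALSE)
  list(n = n,
       names = igraph::V(sn)$name %||% as.character(seq_len(n)),
       s = igraph::V(sn)$score,
       ef = as.integer(ends[, 1]), et = as.integer(ends[, 2]),
       w = if (igraph::ecount(sn)) igraph::E(sn)$score else numeric(0),
       adj = lapply(seq_len(n), function(v) {
         eids <- which(ends[, 1] == v | ends[, 2] == v)
         cbind(nbr = as.integer(ifelse(ends[eids, 1] == v,
                                       ends[eids, 2], ends[eids, 1])),
               eid = as.integer(eids))
       }))
}

# Optimal edge set for a fixed connected node set: all positive induced
# edges, plus a maximum-weight spanning connection (Kruskal over the
# components formed by the positive edges) using negative edges.
subset_edge_selection <- function(nd, sel) {
  in_sel <- logical(nd$n); in_sel[sel] <- TRUE
  eids <- which(in_sel[nd$ef] & in_sel[nd$et])
  pos <- eids[nd$w[eids] > 0]
  neg <- eids[nd$w[eids] <= 0]
  comp <- as.integer(seq_len(nd$n))  # union-find
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in pos) {
    a <- find(nd$ef[e]); b <- find(nd$et[e])
    if (a != b) comp[a] <- b
  }
  chosen <- pos
  n_comp <- length(unique(vapply(sel, find, integer(1))))
  if (n_comp > 1) {
    neg <- neg[order(nd$w[neg], decreasing = TRUE)]
    for (e in neg) {
      a <- find(nd$ef[e]); b <- find(nd$et[e])
      if (a != b) {
        comp[a] <- b
        chosen <- c(chosen, e)
        n_comp <- n_comp - 1
        if (n_comp == 1) break
      }
    }
    if (n_comp > 1) return(NULL)  # node set not connectable
  }
  chosen
}

subset_score <- function(nd, sel) {
  if (length(sel) == 0) return(list(score = 0, edges = integer(0)))
  chosen <- subset_edge_selection(nd, sel)
  if (is.null(chosen)) return(NULL)
  list(score = sum(nd$s[sel]) + sum(nd$w[chosen]), edges = chosen)
}

new_module_result <- function(sn, nd, sel, status, solver, gap = NA_real_) {
  if (length(sel) == 0) {
    return(structure(list(nodes = character(0),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             score = numeric(0)),
                          score = 0, status = status, gap = gap,
                          solver = solver),
                     class = "module_result"))
  }
  res <- subset_score(nd, sel)
  edges <- data.frame(from = nd$names[nd$ef[res$edges]],
                      to = nd$names[nd$et[res$edges]],
                      score = nd$w[res$edges], stringsAsFactors = FALSE)
  ev <- igraph::edge_attr(sn, "evidence")
  if (!is.null(ev)) edges$evidence <- ev[res$edges]
  structure(list(nodes = sort(nd$names[sel]), edges = edges,
                 score = res$score, status = status, gap = gap,
                 solver = solver),
            class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat(sprintf("module: %d nodes, %d edges, score %.4f (%s, %s)\n",
              length(x$nodes), nrow(x$edges), x$score, x$status, x$solver))
  invisible(x)
}

# deterministic tie-break: tiny penalty increasing with node-ID rank prefers
# lexicographically small node sets among equal-score optima
perturbed_scores <- function(nd) {
  nd$s - 1e-9 * (rank(nd$names, ties.method = "first") / max(nd$n, 1))
}

#' Brute-force maximum-scoring connected subgraph (testing oracle)
#'
#' Enumerates every connected induced node subset (bitmask enumeration,
#' hence restricted to small networks) and selects the optimal edge set per
#' subset. Serves as the exactness oracle for the branch-and-bound solver.
#'
#' @param sn scored network from [scored_network()].
#' @param max_nodes refusal threshold (default 15).
#' @param allow_empty return the empty module when nothing scores positive.
#' @return A \code{module_result} with status \code{"optimal"}.
#' @export
brute_force_mwcs <- function(sn, max_nodes = 15, allow_empty = TRUE) {
  nd <- mwcs_data(sn)
  n <- nd$n
  if (n > max_nodes)
    stop_usage("network too large for brute force: ", n, " > ", max_nodes)
  sp <- perturbed_scores(nd)
  best_score <- if (allow_empty) 0 else -Inf
  best_sel <- integer(0)
  if (n > 0) {
    adj_mask <- integer(n)
    for (e in seq_along(nd$ef)) {
      adj_mask[nd$ef[e]] <- bitwOr(adj_mask[nd$ef[e]],
                                   bitwShiftL(1L, nd$et[e] - 1L))
      adj_mask[nd$et[e]] <- bitwOr(adj_mask[nd$et[e]],
                                   bitwShiftL(1L, nd$ef[e] - 1L))
    }
    bit_of <- bitwShiftL(1L, seq_len(n) - 1L)
    for (mask in seq_len(bitwShiftL(1L, n) - 1L)) {
      sel <- which(bitwAnd(mask, bit_of) != 0L)
      # connectivity by bitmask flood fill from the lowest member
      reached <- bit_of[sel[1]]
      repeat {
        grow <- reached
        for (v in sel)
          if (bitwAnd(reached, bit_of[v]) != 0L)
            grow <- bitwOr(grow, bitwAnd(adj_mask[v], mask))
        if (grow == reached) break
        reached <- grow
      }
      if (reached != mask) next
      res <- subset_score(nd, sel)
      if (is.null(res)) next
      pscore <- res$score + sum(sp[sel] - nd$s[sel])
      if (pscore > best_score + 1e-15) {
        best_score <- pscore; best_sel <- sel
      }
    }
  }
  new_module_result(sn, nd, best_sel, status = "optimal",
                    solver = "brute-force", gap = 0)
}

#' Exact maximum-scoring connected subgraph by branch and bound
#'
#' Depth-first search over connected node subsets with an admissible bound:
#' the committed score of the current subset (node scores plus positive
#' induced edges) plus all remaining positive node and edge mass still
#' reachable. Each connected subset is visited at most once (minimum-index
#' rooting); subsets whose bound cannot beat the incumbent are pruned. The
#' returned module is provably optimal unless the time limit is hit, in
#' which case the best feasible solution is returned with status
#' \code{"time-limit"}.
#'
#' @param sn scored network from [scored_network()].
#' @param allow_empty return the empty module when nothing scores positive.
#' @param time_limit wall-clock seconds (default \code{Inf}).
#' @param exclude list of character vectors (node sets) that may not be
#'   returned; used for top-K enumeration via solution exclusion.
#' @return A \code{module_result} with status \code{"optimal"} or
#'   \code{"time-limit"}.
#' @export
exact_mwcs <- function(sn, allow_empty = TRUE, time_limit = Inf,
                       exclude = list()) {
  nd <- mwcs_data(sn)
  n <- nd$n
  if (n == 0)
    return(new_module_result(sn, nd, integer(0), "optimal", "branch-and-bound", 0))
  sp <- perturbed_scores(nd)
  excl_keys <- vapply(exclude, function(x) paste(sort(x), collapse = "|"),
                      character(1))
  # search in decreasing-score vertex order so strong roots come first
  ord <- order(sp, decreasing = TRUE)
  env <- new.env(parent = emptyenv())
  env$best_score <- if (allow_empty && length(excl_keys) == 0) 0 else -Inf
  env$best_sel <- integer(0)
  # warm start: the heuristic's feasible module tightens pruning from the
  # first branch on
  inc <- heuristic_mwcs(sn, allow_empty = allow_empty)
  if (length(inc$nodes) > 0 &&
      !(length(excl_keys) &&
          paste(sort(inc$nodes), collapse = "|") %in% excl_keys)) {
    inc_sel <- match(inc$nodes, nd$names)
    inc_p <- inc$score + sum(sp[inc_sel] - nd$s[inc_sel])
    if (inc_p > env$best_score) {
      env$best_score <- inc_p
      env$best_sel <- inc_sel
    }
  }
  env$timed_out <- FALSE
  env$status <- integer(n)      # 0 free, 1 in, 2 banned
  env$edge_alive <- rep(TRUE, length(nd$w))  # counted in remaining mass
  t0 <- Sys.time()
  tol <- 1e-12
  check_time <- function() {
    if (is.finite(time_limit) &&
        as.numeric(Sys.time() - t0, units = "secs") > time_limit)
      env$timed_out <- TRUE
    env$timed_out
  }
  record <- function(sel, committed_real) {
    if (length(excl_keys) &&
        paste(sort(nd$names[sel]), collapse = "|") %in% excl_keys) return()
    if (committed_real > env$best_score + tol) {
      env$best_score <- committed_real
      env$best_sel <- sel
    }
  }
  ban_edges <- function(v) {
    eids <- nd$adj[[v]][, "eid"]
    dead <- eids[env$edge_alive[eids]]
    env$edge_alive[dead] <- FALSE
    dead
  }
  rec <- function(sel, frontier, committed, rem_pos) {
    if (check_time()) return()
    if (committed + rem_pos <= env$best_score + tol) return()
    v <- 0L
    for (f in frontier) if (env$status[f] == 0L) { v <- f; break }
    if (v == 0L) return()
    # branch A: include v
    env$status[v] <- 1L
    av <- nd$adj[[v]]
    in_eids <- av[env$status[av[, "nbr"]] == 1L & av[, "eid"] != 0L, "eid"]
    in_eids <- in_eids[env$edge_alive[in_eids]]
    # edges now internal leave the remaining mass and join the committed part
    env$edge_alive[in_eids] <- FALSE
    d_comm <- sp[v] + sum(pmax(nd$w[in_eids], 0))
    d_rem <- -max(sp[v], 0) - sum(pmax(nd$w[in_eids], 0))
    sel2 <- c(sel, v)
    res <- subset_score(nd, sel2)
    if (!is.null(res)) record(sel2, res$score + sum(sp[sel2] - nd$s[sel2]))
    new_front <- c(frontier[frontier != v],
                   av[env$status[av[, "nbr"]] == 0L, "nbr"])
    rec(sel2, new_front, committed + d_comm, rem_pos + d_rem)
    env$status[v] <- 0L
    env$edge_alive[in_eids] <- TRUE
    if (env$timed_out) return()
    # branch B: ban v for this subtree
    env$status[v] <- 2L
    dead <- ban_edges(v)
    d_rem_b <- -max(sp[v], 0) - sum(pmax(nd$w[dead], 0))
    rec(sel, frontier[frontier != v], committed, rem_pos + d_rem_b)
    env$status[v] <- 0L
    env$edge_alive[dead] <- TRUE
  }
  for (r_i in seq_len(n)) {
    if (env$timed_out) break
    r <- ord[r_i]
    # nodes already used as roots are banned permanently for this root
    env$status[] <- 0L
    if (r_i > 1) env$status[ord[seq_len(r_i - 1)]] <- 2L
    alive0 <- env$status[nd$ef] == 0L & env$status[nd$et] == 0L
    env$edge_alive <- alive0
    # only positive mass reachable from the root without crossing banned
    # nodes can ever join this root's subsets
    reach <- logical(n); reach[r] <- TRUE
    queue <- r
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- nd$adj[[v]][, "nbr"]
      nb <- nb[env$status[nb] == 0L & !reach[nb]]
      reach[nb] <- TRUE
      queue <- c(queue, nb)
    }
    rem0 <- sum(pmax(sp[reach], 0)) - max(sp[r], 0) +
      sum(pmax(nd$w[env$edge_alive & reach[nd$ef] & reach[nd$et]], 0))
    if (sp[r] + rem0 <= env$best_score + tol) next
    env$status[r] <- 1L
    record(r, sp[r])
    frontier <- nd$adj[[r]][env$status[nd$adj[[r]][, "nbr"]] == 0L, "nbr"]
    rec(r, frontier, sp[r], rem0)
  }
  sel <- env$best_sel
  status <- if (env$timed_out) "time-limit" else "optimal"
  new_module_result(sn, nd, sel, status, "branch-and-bound",
                    gap = if (env$timed_out) NA_real_ else 0)
}

#' Fast heuristic maximum-scoring connected subgraph
#'
#' Feasible (not necessarily optimal) module: positive-score nodes are
#' grouped into seed components, seeds are connected along cheapest paths
#' (transit cost of an edge is its negative part plus half the negative part
#' of its endpoints' node scores) while the attachment gain is positive, and
#' score-decreasing leaves are pruned. Intended for networks too large for
#' the exact solver.
#'
#' @param sn scored network.
#' @param allow_empty return the empty module when nothing scores positive.
#' @return A \code{module_result} with status \code{"feasible-heuristic"}.
#' @export
heuristic_mwcs <- function(sn, allow_empty = TRUE) {
  nd <- mwcs_data(sn)
  n <- nd$n
  finish <- function(sel) {
    res <- new_module_result(sn, nd, sel, "feasible-heuristic", "heuristic")
    if (!allow_empty && length(res$nodes) == 0 && n > 0) {
      res <- new_module_result(sn, nd, which.max(nd$s),
                               "feasible-heuristic", "heuristic")
    }
    res
  }
  pos_nodes <- which(nd$s > 0)
  if (length(pos_nodes) == 0) return(finish(integer(0)))
  sub <- igraph::induced_subgraph(sn, pos_nodes)
  comp <- igraph::components(sub)
  seeds <- split(pos_nodes, comp$membership)
  seed_value <- vapply(seeds, function(sel) {
    r <- subset_score(nd, sel)
    if (is.null(r)) sum(nd$s[sel]) else r$score
  }, numeric(1))
  # transit costs for connecting seeds through negative territory
  ecost <- pmax(-nd$w, 0) +
    (pmax(-nd$s[nd$ef], 0) + pmax(-nd$s[nd$et], 0)) / 2
  wg <- igraph::set_edge_attr(sn, "hcost", value = ecost + 1e-12)
  current <- seeds[[which.max(seed_value)]]
  remaining <- setdiff(seq_along(seeds), which.max(seed_value))
  repeat {
    if (length(remaining) == 0) break
    best_gain <- 0; best_i <- NA; best_path <- NULL
    for (i in remaining) {
      d <- igraph::distances(wg, v = current, to = seeds[[i]],
                             weights = igraph::E(wg)$hcost)
      mi <- which(d == min(d), arr.ind = TRUE)[1, ]
      gain <- seed_value[i] - min(d)
      if (gain > best_gain + 1e-12) {
        best_gain <- gain; best_i <- i
        sp <- igraph::shortest_paths(wg, from = current[mi[1]],
                                     to = seeds[[i]][mi[2]],
                                     weights = igraph::E(wg)$hcost)
        best_path <- as.integer(sp$vpath[[1]])
      }
    }
    if (is.na(best_i)) break
    current <- union(current, union(best_path, seeds[[best_i]]))
    remaining <- setdiff(remaining, best_i)
  }
  # prune score-decreasing leaves
  repeat {
    base <- subset_score(nd, current)
    if (is.null(base)) break
    improved <- FALSE
    if (length(current) > 1) {
      for (v in current) {
        rest <- setdiff(current, v)
        r <- subset_score(nd, rest)
        if (!is.null(r) && r$score > base$score + 1e-12) {
          current <- rest; improved <- TRUE; break
        }
      }
    }
    if (!improved) break
  }
  base <- subset_score(nd, current)
  if (!is.null(base) && base$score <= 0 && allow_empty)
    return(finish(integer(0)))
  finish(current)
}

#' Solve the MWCS problem with a selectable backend
#'
#' @param sn scored network.
#' @param method \code{"exact"} (branch and bound), \code{"heuristic"}, or
#'   \code{"brute"} (enumeration oracle, small networks only).
#' @param top_k number of solutions to return; solutions after the first are
#'   obtained by excluding previously found node sets.
#' @param ... passed to the backend.
#' @return A \code{module_result}, or a list of them when \code{top_k > 1}.
#' @export
solve_mwcs <- function(sn, method = c("exact", "heuristic", "brute"),
                       top_k = 1, ...) {
  method <- match.arg(method)
  solve1 <- function(exclude) {
    switch(method,
           exact = exact_mwcs(sn, exclude = exclude, ...),
           heuristic = {
             if (length(exclude))
               stop_solver("top-k enumeration requires the exact solver")
             heuristic_mwcs(sn, ...)
           },
           brute = {
             if (length(exclude))
               stop_solver("top-k enumeration requires the exact solver")
             brute_force_mwcs(sn, ...)
           })
  }
  if (top_k <= 1) return(solve1(list()))
  out <- list()
  exclude <- list()
  for (i in seq_len(top_k)) {
    res <- solve1(exclude)
    out[[i]] <- res
    if (length(res$nodes) == 0) break
    exclude <- c(exclude, list(res$nodes))
  }
  out
}

#' Verify that a module result is internally consistent
#'
#' Checks that selected edges have both endpoints selected, that the module
#' is connected, and that the reported score equals the recomputed sum.
#'
#' @param module a \code{module_result}.
#' @param sn the scored network it was computed on.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validate_module <- function(module, sn) {
  if (length(module$nodes) == 0) {
    stopifnot(nrow(module$edges) == 0, module$score == 0)
    return(invisible(TRUE))
  }
  stopifnot(all(module$edges$from %in% module$nodes),
            all(module$edges$to %in% module$nodes))
  g <- igraph::graph_from_data_frame(module$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = module$nodes)
  stopifnot(igraph::is_connected(g))
  ns <- stats::setNames(igraph::V(sn)$score, igraph::V(sn)$name)
  recomputed <- sum(ns[module$nodes]) + sum(module$edges$score)
  stopifnot(abs(recomputed - module$score) < 1e-9)
  invisible(TRUE)
}
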