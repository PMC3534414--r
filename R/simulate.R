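# Synthetic data generators. They emulate the statistical structure the
# method assumes -- tent-shaped (umbrella) time courses with replicate
# noise, beta-uniform p-value mixtures, sparse connected reaction networks
# and state-specific EST counts with planted fold changes -- so that every
# pipeline stage is testable without external downloads. All generators are
# deterministic under a fixed seed.

#' Simulate metabolite time-course profiles
#'
#' Trend classes: \code{null} (constant), \code{monotone_up} /
#' \code{monotone_down} (linear), \code{umbrella} (piecewise-linear rise to
#' the peak time point, then fall) and \code{inverse_umbrella} (mirrored).
#' Gaussian replicate noise is added on top of the noise-free shape.
#'
#' @param n_metabolites number of profiles.
#' @param k number of time points (default 20: 10 dehydration +
#'   10 rehydration).
#' @param replicates technical replicates per time point (default 4).
#' @param class_mix named fractions over the trend classes; must sum to 1.
#' @param peak peak time point of the umbrella classes (default 10, the
#'   turning point between dehydration and rehydration).
#' @param effect peak height of the noise-free shape (default 1).
#' @param noise_sd replicate noise standard deviation (default 0.3).
#' @param seed RNG seed.
#' @return List: \code{profiles} (a [profile_matrix()]) and \code{truth}
#'   (data frame with the per-metabolite class and parameters).
#' @export
simulate_profiles <- function(n_metabolites = 84, k = 20, replicates = 4,
                              class_mix = c(null = 0.5, monotone_up = 0.1,
                                            monotone_down = 0.1,
                                            umbrella = 0.2,
                                            inverse_umbrella = 0.1),
                              peak = 10, effect = 1, noise_sd = 0.3,
                              seed = 1) {
  classes <- c("null", "monotone_up", "monotone_down", "umbrella",
               "inverse_umbrella")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% classes))
    stop_usage("class_mix must be named with classes: ",
               paste(classes, collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop_usage("class_mix must sum to 1")
  mix <- stats::setNames(rep(0, length(classes)), classes)
  mix[names(class_mix)] <- class_mix
  counts <- diff(c(0, round(cumsum(mix) * n_metabolites)))
  cls <- rep(classes, times = counts)
  withr::with_seed(seed, {
    cls <- sample(cls)
    shapes <- vapply(cls, function(cl) trend_shape(cl, k, peak, effect),
                     numeric(k))  # k x n
    arr <- array(rep(t(shapes), times = replicates),
                 dim = c(n_metabolites, k, replicates),
                 dimnames = list(sprintf("M%03d", seq_len(n_metabolites)),
                                 NULL, NULL))
    arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
  })
  pm <- profile_matrix(arr, phase_split = min(peak, k - 1),
                       minutes = if (k == 20) default_sampling_minutes())
  truth <- data.frame(metabolite_id = pm$metabolites, class = cls,
                      peak = peak, effect = effect, noise_sd = noise_sd,
                      seed = seed, stringsAsFactors = FALSE)
  list(profiles = pm, truth = truth)
}

trend_shape <- function(class, k, peak, effect) {
  t <- seq_len(k)
  switch(class,
         null = rep(0, k),
         monotone_up = effect * (t - 1) / (k - 1),
         monotone_down = -effect * (t - 1) / (k - 1),
         umbrella = ifelse(t <= peak,
                           effect * (t - 1) / max(peak - 1, 1),
                           effect * (k - t) / max(k - peak, 1)),
         inverse_umbrella = -ifelse(t <= peak,
                                    effect * (t - 1) / max(peak - 1, 1),
                                    effect * (k - t) / max(k - peak, 1)),
         stop_usage("unknown trend class: ", class))
}

#' Simulate p-values from a beta-uniform mixture
#'
#' @param lambda uniform (noise) weight in [0, 1].
#' @param a beta shape in (0, 1).
#' @param n sample size.
#' @param seed RNG seed.
#' @return Numeric vector of p-values in (0, 1].
#' @export
simulate_pvalues <- function(lambda, a, n, seed = 1) {
  if (lambda < 0 || lambda > 1) stop_usage("lambda must lie in [0, 1]")
  if (a <= 0 || a >= 1) stop_usage("a must lie in (0, 1)")
  withr::with_seed(seed, {
    noise <- stats::runif(n) < lambda
    p <- ifelse(noise, stats::runif(n), stats::rbeta(n, a, 1))
  })
  pmax(p, .Machine$double.xmin)
}

#' Simulate a connected metabolite-like network
#'
#' Random spanning tree plus extra random edges up to the target mean
#' degree. Nodes get compound-like IDs, edges get synthetic reaction IDs and
#' dummy EC/KO enzyme annotations.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param mean_degree target mean degree (default 3).
#' @param seed RNG seed.
#' @return Undirected \code{igraph} metabolite network.
#' @export
simulate_network <- function(n_nodes, mean_degree = 3, seed = 1) {
  if (n_nodes < 2) stop_usage("n_nodes must be >= 2")
  withr::with_seed(seed, {
    ef <- integer(0); et <- integer(0)
    for (v in 2:n_nodes) {
      u <- if (v == 2) 1L else sample.int(v - 1L, 1)
      ef <- c(ef, u); et <- c(et, v)
    }
    target <- max(n_nodes - 1, ceiling(n_nodes * mean_degree / 2))
    key <- paste(pmin(ef, et), pmax(ef, et))
    tries <- 0
    while (length(ef) < target && tries < 20 * target) {
      uv <- sample.int(n_nodes, 2)
      kk <- paste(min(uv), max(uv))
      tries <- tries + 1
      if (kk %in% key) next
      ef <- c(ef, uv[1]); et <- c(et, uv[2]); key <- c(key, kk)
    }
  })
  ids <- sprintf("C9%04d", seq_len(n_nodes))
  m <- length(ef)
  edf <- data.frame(from = ids[ef], to = ids[et],
                    reactions = sprintf("R9%04d", seq_len(m)),
                    enzymes = paste(sprintf("K9%04d", seq_len(m)),
                                    sprintf("7.%d.%d.1", 1 + (seq_len(m) - 1) %/% 100,
                                            1 + (seq_len(m) - 1) %% 100),
                                    sep = ";"),
                    reversible = TRUE, stringsAsFactors = FALSE)
  vdf <- data.frame(name = ids, display = ids, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "provenance", "synthetic")
  g <- igraph::set_graph_attr(g, "fusion_log",
                              data.frame(anomer = character(0),
                                         canonical = character(0)))
  igraph::set_graph_attr(g, "removed_pool", character(0))
}

#' Plant a functional module in a synthetic network
#'
#' Selects a random connected node subset as the true module: its nodes get
#' umbrella or inverse-umbrella time courses (all other nodes are null), its
#' edges get differential-EST counts with the stated fold change between the
#' active and inactive state (active mean = fold x baseline), and the
#' EST-to-EC map marks the module edges as enzyme-present. This is the
#' end-to-end recovery benchmark for the two-step pipeline.
#'
#' @param net network from [simulate_network()].
#' @param module_size number of module nodes (< number of network nodes).
#' @param profile_params list: \code{k}, \code{replicates}, \code{peak},
#'   \code{effect}, \code{noise_sd}, \code{inverse_frac} (fraction of module
#'   nodes with an inverse umbrella).
#' @param est_params list: \code{baseline} (Poisson mean of the inactive
#'   count), \code{fold} (active/inactive fold change on module edges).
#' @param seed RNG seed.
#' @return List: \code{profiles}, \code{ec_map}, \code{dest_counts},
#'   \code{truth} (list with \code{nodes}, \code{edges}, \code{classes},
#'   \code{seed}).
#' @export
plant_module <- function(net, module_size = 8,
                         profile_params = list(), est_params = list(),
                         seed = 1) {
  pp <- utils::modifyList(list(k = 20, replicates = 4, peak = 10, effect = 1,
                               noise_sd = 0.3, inverse_frac = 0.3),
                          profile_params)
  ep <- utils::modifyList(list(baseline = 5, fold = 4), est_params)
  n <- igraph::vcount(net)
  if (module_size >= n)
    stop_usage("module_size must be smaller than the network (", n, " nodes)")
  ids <- igraph::V(net)$name
  withr::with_seed(seed, {
    start <- sample.int(n, 1)
    sel <- start
    while (length(sel) < module_size) {
      nbrs <- setdiff(unique(unlist(igraph::adjacent_vertices(net, sel))), sel)
      if (length(nbrs) == 0) break
      sel <- c(sel, nbrs[sample.int(length(nbrs), 1)])
    }
    module_nodes <- sort(ids[sel])
    n_inv <- round(pp$inverse_frac * length(sel))
    cls <- rep("null", n)
    cls[sel] <- "umbrella"
    cls[sample(sel, n_inv)] <- "inverse_umbrella"
    # profiles: planted classes with replicate noise
    shapes <- vapply(cls, function(cl) trend_shape(cl, pp$k, pp$peak,
                                                   pp$effect),
                     numeric(pp$k))
    arr <- array(rep(t(shapes), times = pp$replicates),
                 dim = c(n, pp$k, pp$replicates), dimnames = list(ids, NULL, NULL))
    arr <- arr + stats::rnorm(length(arr), sd = pp$noise_sd)
    # dEST counts on module edges, with random direction of change
    ends <- igraph::as_edgelist(net)
    on_module <- ends[, 1] %in% module_nodes & ends[, 2] %in% module_nodes
    eids <- which(on_module)
    kos <- vapply(igraph::E(net)$enzymes[eids],
                  function(x) split_semi(x)[grepl(KO_PATTERN, split_semi(x))][1],
                  character(1))
    up <- stats::runif(length(eids)) < 0.5
    hi <- stats::rpois(length(eids), ep$baseline * ep$fold)
    lo <- stats::rpois(length(eids), ep$baseline)
    dest <- data.frame(cluster_id = sprintf("CL%04d", seq_along(eids)),
                       ko = unname(kos),
                       n_active = ifelse(up, hi, lo),
                       n_inactive = ifelse(up, lo, hi),
                       stringsAsFactors = FALSE)
  })
  pm <- profile_matrix(arr, phase_split = min(pp$peak, pp$k - 1))
  ecs <- unlist(lapply(igraph::E(net)$enzymes[eids], function(x) {
    tk <- split_semi(x)
    tk[grepl(EC_PATTERN, tk)]
  }))
  ec_map <- data.frame(est_id = sprintf("EST%04d", seq_along(ecs)), ec = ecs,
                       stringsAsFactors = FALSE)
  truth <- list(nodes = module_nodes,
                edges = data.frame(from = pmin(ends[eids, 1], ends[eids, 2]),
                                   to = pmax(ends[eids, 1], ends[eids, 2]),
                                   stringsAsFactors = FALSE),
                classes = stats::setNames(cls, ids), seed = seed)
  list(profiles = pm, ec_map = ec_map, dest_counts = dest, truth = truth)
}

#' Write a pathway graph as a KGML-like XML document
#'
#' Emits a minimal KGML v0.7.1 pathway (compound entries, ortholog entries
#' carrying the enzyme annotations, and reaction elements) that round-trips
#' through [parse_kgml()]. Used to generate self-contained pathway fixtures.
#'
#' @param g directed pathway graph (as from [parse_kgml()]), or an
#'   undirected network whose edges become reversible reactions.
#' @param path output file; when \code{NULL} the XML text is returned.
#' @param pathway_id pathway identifier for the document.
#' @return The file path (invisibly) or the XML text.
#' @export
write_kgml <- function(g, path = NULL, pathway_id = "synthetic00001") {
  ids <- igraph::V(g)$name
  disp <- igraph::V(g)$display %||% ids
  ends <- igraph::as_edgelist(g)
  reactions <- if (igraph::ecount(g)) igraph::E(g)$reactions
               else character(0)
  enzymes <- igraph::edge_attr(g, "enzymes") %||% rep("", nrow(ends))
  reversible <- igraph::edge_attr(g, "reversible") %||%
    rep(!igraph::is_directed(g), nrow(ends))
  entry_id <- stats::setNames(seq_along(ids), ids)
  lines <- c(sprintf('<?xml version="1.0"?>'),
             sprintf('<pathway name="path:%s" org="syn" number="1" title="synthetic pathway">',
                     pathway_id))
  for (i in seq_along(ids))
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="cpd:%s" type="compound"><graphics name="%s"/></entry>',
      entry_id[i], ids[i], disp[i]))
  next_id <- length(ids)
  for (e in seq_len(nrow(ends))) {
    enz <- split_semi(enzymes[e])
    if (length(enz) > 0) {
      next_id <- next_id + 1
      enz_names <- paste(ifelse(grepl(KO_PATTERN, enz),
                                paste0("ko:", enz), paste0("ec:", enz)),
                         collapse = " ")
      lines <- c(lines, sprintf(
        '  <entry id="%d" name="%s" type="ortholog" reaction="rn:%s"/>',
        next_id, enz_names, strsplit(reactions[e], ";")[[1]][1]))
    }
  }
  for (e in seq_len(nrow(ends))) {
    rn <- strsplit(reactions[e], ";")[[1]][1]
    lines <- c(lines, sprintf(
      '  <reaction id="%d" name="rn:%s" type="%s">', e, rn,
      if (isTRUE(reversible[e])) "reversible" else "irreversible"),
      sprintf('    <substrate id="%d" name="cpd:%s"/>',
              entry_id[ends[e, 1]], ends[e, 1]),
      sprintf('    <product id="%d" name="cpd:%s"/>',
              entry_id[ends[e, 2]], ends[e, 2]),
      '  </reaction>')
  }
  lines <- c(lines, "</pathway>")
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}
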