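# Edge scoring from transcript evidence.
#
# Two evidence layers: presence/absence of an enzyme (EC number mapped from
# EST data) gives a small +/-0.01 weight; differential EST counts between
# the active and inactive state give |log2(n_a / n_i)| - t, a score in
# [-t, Inf) that dominates the presence weights.

EC_PATTERN <- "^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9-]+$"
KO_PATTERN <- "^K[0-9]{5}$"

normalize_ec <- function(x) {
  x <- trimws(sub("^(ec|EC):", "", x))
  ifelse(grepl(EC_PATTERN, x), x, NA_character_)
}

# field-wise EC comparison; "-" is a wildcard on either side, so the partial
# class "2.2.1.-" matches the full number "2.2.1.2"
ec_match <- function(e1, e2) {
  f1 <- strsplit(e1, ".", fixed = TRUE)[[1]]
  f2 <- strsplit(e2, ".", fixed = TRUE)[[1]]
  len <- max(length(f1), length(f2))
  f1 <- c(f1, rep("-", len - length(f1)))
  f2 <- c(f2, rep("-", len - length(f2)))
  all(f1 == f2 | f1 == "-" | f2 == "-")
}

edge_enzyme_tokens <- function(net) {
  enz <- igraph::E(net)$enzymes %||% rep("", igraph::ecount(net))
  lapply(enz, split_semi)
}

new_edge_score_table <- function(net, score, evidence, extra = NULL) {
  ends <- igraph::as_edgelist(net)
  out <- data.frame(from = ends[, 1], to = ends[, 2], score = score,
                    evidence = evidence, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  structure(out, class = c("edge_score_table", "data.frame"))
}

#' Score edges by enzyme presence
#'
#' An edge whose enzyme annotation (EC numbers) matches any EC number in the
#' EST-to-EC mapping receives \code{+0.01}; edges without an identified
#' enzyme mapping receive \code{-0.01}. Matching is field-wise with \code{-}
#' as a wildcard, so partial EC classes match their full members. Malformed
#' EC strings in the mapping are skipped (counted in the
#' \code{n_skipped} attribute).
#'
#' @param net metabolite network with an \code{enzymes} edge attribute.
#' @param ec_map data frame with columns \code{est_id} and \code{ec}.
#' @return Data frame of class \code{edge_score_table}: \code{from},
#'   \code{to}, \code{score}, \code{evidence} (\code{"enzyme-present"} or
#'   \code{"enzyme-absent"}).
#' @export
score_edges_presence <- function(net, ec_map) {
  if (!"ec" %in% names(ec_map)) stop_usage("ec_map needs an 'ec' column")
  mapped <- normalize_ec(ec_map$ec)
  n_skipped <- sum(is.na(mapped) & !is.na(ec_map$ec))
  mapped <- unique(mapped[!is.na(mapped)])
  tokens <- edge_enzyme_tokens(net)
  present <- vapply(tokens, function(tk) {
    ecs <- tk[grepl(EC_PATTERN, tk)]
    if (length(ecs) == 0 || length(mapped) == 0) return(FALSE)
    any(vapply(ecs, function(e) any(vapply(mapped, ec_match, logical(1), e)),
               logical(1)))
  }, logical(1))
  out <- new_edge_score_table(net,
                              score = ifelse(present, 0.01, -0.01),
                              evidence = ifelse(present, "enzyme-present",
                                                "enzyme-absent"))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Score edges from differential EST counts
#'
#' For every edge with at least one KO-mapped differential-EST cluster, the
#' score is \eqn{\max |\log_2((n_a + c)/(n_i + c))| - t} over its clusters,
#' where \eqn{n_a} and \eqn{n_i} are the active- and inactive-state counts,
#' \eqn{c} a pseudocount and \eqn{t \ge 0} the sensitivity threshold. The
#' score is bounded below by \eqn{-t}, attained when the counts are equal.
#' Edges without differential-EST evidence fall back to the presence scores
#' (or \code{-0.01} when none are supplied).
#'
#' @param net metabolite network with KO identifiers in the \code{enzymes}
#'   edge attribute.
#' @param dest_counts data frame with columns \code{cluster_id}, \code{ko},
#'   \code{n_active}, \code{n_inactive} (nonnegative integers).
#' @param t threshold, \code{t >= 0} (the module search default is 1).
#' @param pseudocount added to both counts (default 1); with
#'   \code{pseudocount = 0}, zero counts are an error.
#' @param presence optional [score_edges_presence()] table used as fallback.
#' @param clamp optional symmetric clamp: scores are truncated to
#'   \code{[-clamp, clamp]} when given.
#' @return Data frame of class \code{edge_score_table} with columns
#'   \code{from}, \code{to}, \code{score}, \code{evidence}
#'   (\code{"differential-EST"} or the fallback evidence), \code{n_active},
#'   \code{n_inactive}.
#' @export
score_edges_dest <- function(net, dest_counts, t = 1, pseudocount = 1,
                             presence = NULL, clamp = NULL) {
  assert_scalar_number(t, "t")
  if (t < 0) stop_usage("threshold t must be >= 0")
  assert_scalar_number(pseudocount, "pseudocount")
  if (pseudocount < 0) stop_usage("pseudocount must be >= 0")
  need <- c("ko", "n_active", "n_inactive")
  if (!all(need %in% names(dest_counts)))
    stop_usage("dest_counts needs columns ", paste(need, collapse = ", "))
  if (any(dest_counts$n_active < 0 | dest_counts$n_inactive < 0,
          na.rm = TRUE))
    stop_usage("dEST counts must be nonnegative")
  tokens <- edge_enzyme_tokens(net)
  m <- igraph::ecount(net)
  score <- numeric(m); evid <- character(m)
  na_col <- ni_col <- rep(NA_real_, m)
  fallback_score <- presence$score %||% rep(-0.01, m)
  fallback_evid <- presence$evidence %||% rep("enzyme-absent", m)
  for (e in seq_len(m)) {
    kos <- tokens[[e]][grepl(KO_PATTERN, tokens[[e]])]
    rows <- which(dest_counts$ko %in% kos)
    if (length(rows) == 0) {
      score[e] <- fallback_score[e]; evid[e] <- fallback_evid[e]
      next
    }
    na_ <- dest_counts$n_active[rows] + pseudocount
    ni_ <- dest_counts$n_inactive[rows] + pseudocount
    if (pseudocount == 0 && any(na_ == 0 | ni_ == 0))
      stop_usage("zero dEST count with pseudocount 0 gives an infinite ",
                 "log-ratio; use a positive pseudocount")
    s <- abs(log2(na_ / ni_)) - t
    best <- which.max(s)
    score[e] <- s[best]; evid[e] <- "differential-EST"
    na_col[e] <- dest_counts$n_active[rows[best]]
    ni_col[e] <- dest_counts$n_inactive[rows[best]]
  }
  if (!is.null(clamp)) score <- pmin(pmax(score, -clamp), clamp)
  out <- new_edge_score_table(net, score, evid,
                              extra = data.frame(n_active = na_col,
                                                 n_inactive = ni_col))
  attr(out, "t") <- t
  attr(out, "pseudocount") <- pseudocount
  out
}
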