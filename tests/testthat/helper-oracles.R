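# Independent oracles, deliberately written without reusing package
# internals: naive pairwise counting for the trend statistics, full N!
# permutation enumeration for exact p-values, chi-square SVD for CA, and a
# subset-enumeration scorer for small MWCS instances.

oracle_jt_stat <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (x in groups[[i]]) for (y in groups[[j]])
      s <- s + (x < y) + 0.5 * (x == y)
  s
}

oracle_umbrella_stat <- function(groups, peak) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && j <= peak) {
      for (x in groups[[i]]) for (y in groups[[j]])
        s <- s + (x < y) + 0.5 * (x == y)
    } else if (peak <= i && i < j) {
      for (x in groups[[j]]) for (y in groups[[i]])
        s <- s + (x < y) + 0.5 * (x == y)
    }
  }
  s
}

# all N! orderings (feasible for N <= 7); p-values from the full
# permutation distribution
oracle_perm_pvalue <- function(groups, stat_fun,
                               alternative = "two.sided") {
  values <- unlist(groups)
  sizes <- lengths(groups)
  N <- length(values)
  perms <- all_permutations(N)
  obs <- stat_fun(groups)
  stats <- apply(perms, 1, function(ix) {
    regroup <- split(values[ix], rep(seq_along(sizes), sizes))
    stat_fun(regroup)
  })
  eps <- 1e-9
  p_up <- mean(stats >= obs - eps)
  p_dn <- mean(stats <= obs + eps)
  switch(alternative,
         greater = p_up, less = p_dn,
         two.sided = min(1, 2 * min(p_up, p_dn)))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# classical CA by direct SVD of the chi-square standardized residuals
oracle_ca <- function(X) {
  P <- X / sum(X)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %*% t(cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  d <- sv$d[sv$d > 1e-12]
  list(inertia_fractions = d^2 / sum(d^2),
       row_pc = diag(1 / sqrt(r)) %*% sv$u[, seq_along(d)] %*% diag(d, length(d)))
}

# exhaustive MWCS scorer over all node subsets, using igraph for
# connectivity and a greedy maximum spanning connection for negative edges
oracle_mwcs_score <- function(sn) {
  n <- igraph::vcount(sn)
  s <- igraph::V(sn)$score
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- igraph::induced_subgraph(sn, sel)
    if (!igraph::is_connected(sub)) next
    w <- igraph::E(sub)$score
    pos <- which(w > 0)
    keep <- igraph::subgraph_from_edges(sub, pos, delete.vertices = FALSE)
    score <- sum(s[sel]) + sum(w[pos])
    comp <- igraph::components(keep)$membership
    if (max(comp) > 1) {
      # connect components greedily with the least negative edges (Kruskal)
      ord <- order(w, decreasing = TRUE)
      ends <- igraph::as_edgelist(sub, names = FALSE)
      for (e in ord) {
        if (w[e] > 0) next
        a <- comp[ends[e, 1]]; b <- comp[ends[e, 2]]
        if (a != b) {
          comp[comp == a] <- b
          score <- score + w[e]
        }
      }
      if (length(unique(comp)) > 1) next
    }
    if (score > best) best <- score
  }
  best
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

toy_kgml <- function(body, name = "path:rn99999") {
  paste0('<?xml version="1.0"?>\n<pathway name="', name, '">\n', body,
         "\n</pathway>")
}

compound_entry <- function(id, cpd, display = cpd) {
  sprintf('<entry id="%d" name="cpd:%s" type="compound"><graphics name="%s"/></entry>',
          id, cpd, display)
}

toy_profile_matrix <- function(values_by_metabolite, replicates = 1,
                               phase_split = NULL) {
  m <- length(values_by_metabolite)
  k <- length(values_by_metabolite[[1]])
  arr <- array(NA_real_, c(m, k, replicates),
               dimnames = list(names(values_by_metabolite), NULL, NULL))
  for (i in seq_len(m))
    for (r in seq_len(replicates))
      arr[i, , r] <- values_by_metabolite[[i]]
  profile_matrix(arr, phase_split = phase_split %||% floor(k / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
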