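# Rank-based trend tests for ordered groups (time points).
#
# Mann-Whitney counts use midranks: a tie between samples contributes 0.5.
# The normal approximation uses the closed-form null moments (tie-corrected
# for the Jonckheere-Terpstra statistic); with heavily tied data the exact or
# Monte-Carlo permutation methods are the reference.

mw_count <- function(x, y) {
  sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
}

jt_statistic <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    s <- s + mw_count(groups[[i]], groups[[j]])
  s
}

umbrella_statistic <- function(groups, peak) {
  k <- length(groups)
  s <- 0
  if (peak >= 2)
    for (i in 1:(peak - 1)) for (j in (i + 1):peak)
      s <- s + mw_count(groups[[i]], groups[[j]])
  if (peak <= k - 1)
    for (i in peak:(k - 1)) for (j in (i + 1):k)
      s <- s + mw_count(groups[[j]], groups[[i]])
  s
}

# Null moments of the JT statistic, with tie correction in the variance
jt_null_moments <- function(groups) {
  n <- lengths(groups)
  N <- sum(n)
  pooled <- unlist(groups)
  t_j <- table(pooled)
  mu <- (N^2 - sum(n^2)) / 4
  A <- N * (N - 1) * (2 * N + 5) -
    sum(n * (n - 1) * (2 * n + 5)) -
    sum(t_j * (t_j - 1) * (2 * t_j + 5))
  B <- sum(n * (n - 1) * (n - 2)) * sum(t_j * (t_j - 1) * (t_j - 2))
  C <- sum(n * (n - 1)) * sum(t_j * (t_j - 1))
  v <- A / 72 +
    (if (B != 0) B / (36 * N * (N - 1) * (N - 2)) else 0) +
    (if (C != 0) C / (8 * N * (N - 1)) else 0)
  list(mean = mu, var = max(v, 0))
}

# Mack-Wolfe null moments for the known-peak umbrella statistic (no tie
# correction exists in closed form; validated against permutation in tests)
umbrella_null_moments <- function(groups, peak) {
  n <- lengths(groups)
  N <- sum(n)
  N1 <- sum(n[1:peak])
  N2 <- sum(n[peak:length(n)])
  np <- n[peak]
  mu <- (N1^2 + N2^2 - sum(n^2) - np^2) / 4
  v <- (2 * (N1^3 + N2^3) + 3 * (N1^2 + N2^2) -
          sum(n^2 * (2 * n + 3)) - np^2 * (2 * np + 3) +
          12 * np * N1 * N2 - 12 * np^2 * N) / 72
  list(mean = mu, var = max(v, 0))
}

# enumerate all distinct assignments of pooled values into groups of the
# given sizes and return the statistic for each assignment
permutation_distribution <- function(values, sizes, stat_fun,
                                     max_assignments = 2e5) {
  total <- prod(choose(cumsum(rev(sizes)), rev(sizes)))
  if (total > max_assignments)
    stop_usage("exact enumeration infeasible: ", format(total),
               " assignments (limit ", format(max_assignments), ")")
  out <- numeric(0)
  recurse <- function(remaining_idx, groups_so_far) {
    g <- length(groups_so_far) + 1L
    if (g > length(sizes)) {
      out[[length(out) + 1L]] <<- stat_fun(groups_so_far)
      return(invisible())
    }
    if (g == length(sizes)) {
      recurse(integer(0), c(groups_so_far, list(values[remaining_idx])))
      return(invisible())
    }
    picks <- utils::combn(remaining_idx, sizes[g], simplify = FALSE)
    for (p in picks)
      recurse(setdiff(remaining_idx, p), c(groups_so_far, list(values[p])))
    invisible()
  }
  recurse(seq_along(values), list())
  unlist(out)
}

monte_carlo_distribution <- function(values, sizes, stat_fun, n_perm) {
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  vapply(seq_len(n_perm), function(b) {
    perm <- sample(values)
    stat_fun(lapply(seq_along(sizes),
                    function(g) perm[starts[g]:ends[g]]))
  }, numeric(1))
}

trend_pvalue <- function(stat, mu, sigma, alternative, perm = NULL) {
  if (!is.null(perm)) {
    eps <- 1e-9
    p_up <- mean(perm >= stat - eps)
    p_dn <- mean(perm <= stat + eps)
  } else if (sigma > 0) {
    # continuity correction: the statistic moves on a half-integer lattice
    cc <- min(0.5, abs(stat - mu))
    p_up <- stats::pnorm((stat - cc - mu) / sigma, lower.tail = FALSE)
    p_dn <- stats::pnorm((stat + cc - mu) / sigma)
  } else {
    p_up <- p_dn <- 1
  }
  switch(alternative,
         greater = p_up,
         less = p_dn,
         two.sided = min(1, 2 * min(p_up, p_dn)))
}

new_trend_result <- function(metabolite_id = NA_character_, statistic, z,
                             p_value, peak, method, alternative, k, n) {
  structure(list(metabolite_id = metabolite_id, statistic = statistic, z = z,
                 p_value = p_value, peak = peak, method = method,
                 alternative = alternative, k = k, n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("%s trend test (%s): statistic = %g, z = %.4f, p = %.4g\n",
              if (is.na(x$peak)) "Jonckheere-Terpstra"
              else sprintf("Umbrella (peak = %d)", x$peak),
              x$method, x$statistic, x$z, x$p_value))
  invisible(x)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_usage("need at least 2 ordered groups")
  n <- lengths(groups)
  if (any(n == 0))
    stop_usage("group ", which(n == 0)[1], " has zero observations")
  lapply(groups, as.numeric)
}

#' Jonckheere-Terpstra trend test
#'
#' Non-parametric, rank-based test for a monotone trend across \code{k}
#' ordered samples: the statistic is the sum of Mann-Whitney counts over all
#' ordered group pairs. Under the null of identical distributions it is
#' approximately normal; exact and Monte-Carlo permutation p-values are
#' available for small samples or tied data.
#'
#' @param groups list of numeric vectors, one per ordered group.
#' @param alternative \code{"two.sided"} (default), \code{"increasing"} or
#'   \code{"decreasing"}.
#' @param method \code{"normal"} (tie-corrected normal approximation),
#'   \code{"exact"} (full enumeration of group assignments) or
#'   \code{"montecarlo"}.
#' @param n_perm Monte-Carlo permutation count.
#' @return A \code{trend_result}: statistic, standardized \code{z},
#'   \code{p_value}, method.
#' @export
jt_test <- function(groups, alternative = c("two.sided", "increasing",
                                            "decreasing"),
                    method = c("normal", "exact", "montecarlo"),
                    n_perm = 10000) {
  groups <- check_groups(groups)
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  alt <- c(two.sided = "two.sided", increasing = "greater",
           decreasing = "less")[[alternative]]
  stat <- jt_statistic(groups)
  mom <- jt_null_moments(groups)
  perm <- switch(method,
                 normal = NULL,
                 exact = permutation_distribution(unlist(groups),
                                                 lengths(groups),
                                                 jt_statistic),
                 montecarlo = monte_carlo_distribution(unlist(groups),
                                                      lengths(groups),
                                                      jt_statistic, n_perm))
  if (is.null(perm)) {
    mu <- mom$mean; sigma <- sqrt(mom$var)
  } else {
    mu <- mean(perm); sigma <- stats::sd(perm)
    if (is.na(sigma)) sigma <- 0
  }
  z <- if (sigma > 0) (stat - mu) / sigma else 0
  p <- trend_pvalue(stat, mu, sigma, alt, perm)
  new_trend_result(statistic = stat, z = z, p_value = p, peak = NA_integer_,
                   method = method, alternative = alternative,
                   k = length(groups), n = sum(lengths(groups)))
}

#' Mack-Wolfe umbrella trend test with known peak
#'
#' Tests for a trend that rises to a peak group \code{l} and falls
#' afterwards (umbrella alternative
#' \eqn{G_1 \le \dots \le G_l \ge \dots \ge G_k}). The statistic
#' \eqn{A_l} sums Mann-Whitney counts forward up to the peak and backward
#' after it; with \code{peak = k} it reduces exactly to the
#' Jonckheere-Terpstra statistic. Positive standardized \code{z} indicates an
#' umbrella shape, negative \code{z} an inverse umbrella.
#'
#' @param groups list of numeric vectors, one per ordered group.
#' @param peak peak group index \code{l} in \code{1..k}.
#' @param alternative \code{"two.sided"} (default; umbrella or inverse
#'   umbrella), \code{"umbrella"} or \code{"inverse"}.
#' @param method,n_perm see [jt_test()].
#' @return A \code{trend_result}.
#' @export
umbrella_test <- function(groups, peak,
                          alternative = c("two.sided", "umbrella", "inverse"),
                          method = c("normal", "exact", "montecarlo"),
                          n_perm = 10000) {
  groups <- check_groups(groups)
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  k <- length(groups)
  if (!is.numeric(peak) || length(peak) != 1 || peak < 1 || peak > k)
    stop_usage("peak must be a group index in 1..", k)
  peak <- as.integer(peak)
  alt <- c(two.sided = "two.sided", umbrella = "greater",
           inverse = "less")[[alternative]]
  stat <- umbrella_statistic(groups, peak)
  mom <- umbrella_null_moments(groups, peak)
  perm <- switch(method,
                 normal = NULL,
                 exact = permutation_distribution(
                   unlist(groups), lengths(groups),
                   function(g) umbrella_statistic(g, peak)),
                 montecarlo = monte_carlo_distribution(
                   unlist(groups), lengths(groups),
                   function(g) umbrella_statistic(g, peak), n_perm))
  if (is.null(perm)) {
    mu <- mom$mean; sigma <- sqrt(mom$var)
  } else {
    mu <- mean(perm); sigma <- stats::sd(perm)
    if (is.na(sigma)) sigma <- 0
  }
  z <- if (sigma > 0) (stat - mu) / sigma else 0
  p <- trend_pvalue(stat, mu, sigma, alt, perm)
  new_trend_result(statistic = stat, z = z, p_value = p, peak = peak,
                   method = method, alternative = alternative,
                   k = k, n = sum(lengths(groups)))
}

#' Umbrella tests over all metabolite profiles
#'
#' Applies [umbrella_test()] to every metabolite of a profile matrix, with
#' the time points as ordered groups and the replicate measurements as the
#' group observations. Metabolites with fewer than three time points carrying
#' data are flagged (\code{ok = FALSE}) and get \code{NA} results; they are
#' excluded from downstream scoring.
#'
#' @param pm a [profile_matrix()].
#' @param peak peak time-point index (default 10, the end of dehydration).
#' @param ... passed to [umbrella_test()].
#' @return Data frame: \code{metabolite_id}, \code{statistic}, \code{z},
#'   \code{p_value}, \code{peak}, \code{method}, \code{ok}.
#' @export
umbrella_test_profiles <- function(pm, peak = 10, ...) {
  res <- lapply(pm$metabolites, function(m) {
    groups <- profile_groups(pm, m)
    nonempty <- lengths(groups) > 0
    if (sum(nonempty) < 3) return(NULL)
    groups <- groups[nonempty]
    pk <- sum(nonempty[seq_len(peak)])  # peak index among nonempty groups
    pk <- max(1L, pk)
    umbrella_test(groups, peak = pk, ...)
  })
  data.frame(
    metabolite_id = pm$metabolites,
    statistic = vapply(res, function(r) r$statistic %||% NA_real_, numeric(1)),
    z = vapply(res, function(r) r$z %||% NA_real_, numeric(1)),
    p_value = vapply(res, function(r) r$p_value %||% NA_real_, numeric(1)),
    peak = vapply(res, function(r) as.integer(r$peak %||% NA), integer(1)),
    method = vapply(res, function(r) r$method %||% NA_character_, character(1)),
    ok = !vapply(res, is.null, logical(1)),
    stringsAsFactors = FALSE)
}

#' Wilcoxon comparison of the dehydration and rehydration phases
#'
#' For each metabolite, pools all measurements of the first phase (time
#' points up to \code{split}) and of the second phase and compares them with
#' an unpaired two-sided Wilcoxon rank-sum test (normal approximation with
#' tie correction).
#'
#' @param pm a [profile_matrix()].
#' @param split last time point of the first phase (defaults to the profile
#'   matrix's phase split).
#' @return Data frame: \code{metabolite_id}, \code{n1}, \code{n2},
#'   \code{p_value}.
#' @export
wilcoxon_phase_test <- function(pm, split = pm$phase_split) {
  k <- dim(pm$values)[2]
  if (split < 1 || split >= k)
    stop_usage("split must leave both phases nonempty (1 <= split < ", k, ")")
  res <- lapply(pm$metabolites, function(m) {
    x <- as.vector(pm$values[m, seq_len(split), ])
    y <- as.vector(pm$values[m, (split + 1):k, ])
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0)
      return(list(n1 = length(x), n2 = length(y), p = NA_real_))
    if (stats::sd(c(x, y)) == 0)
      return(list(n1 = length(x), n2 = length(y), p = 1))
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    list(n1 = length(x), n2 = length(y), p = p)
  })
  data.frame(metabolite_id = pm$metabolites,
             n1 = vapply(res, `[[`, numeric(1), "n1"),
             n2 = vapply(res, `[[`, numeric(1), "n2"),
             p_value = vapply(res, `[[`, numeric(1), "p"),
             stringsAsFactors = FALSE)
}
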