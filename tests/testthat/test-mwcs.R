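path_network <- function(node_scores, edge_scores) {
  n <- length(node_scores)
  g <- igraph::graph_from_data_frame(
    data.frame(from = LETTERS[1:(n - 1)], to = LETTERS[2:n]),
    directed = FALSE)
  scored_network(g, stats::setNames(node_scores, LETTERS[1:n]), edge_scores)
}

test_that("brute force solves the hand-enumerable toy instances", {
  # path A(+2)-B(-1)-C(+2), zero edge scores: whole path, score 3
  m <- brute_force_mwcs(path_network(c(2, -1, 2), c(0, 0)))
  expect_setequal(m$nodes, c("A", "B", "C"))
  expect_equal(m$score, 3)

  # two positive nodes joined by a -5 edge: single node wins
  m2 <- brute_force_mwcs(path_network(c(1, 1), -5))
  expect_length(m2$nodes, 1)
  expect_equal(m2$score, 1)

  # all scores negative: empty module, or the least negative node on demand
  sn <- path_network(c(-1, -3, -0.2), c(-1, -1))
  expect_length(brute_force_mwcs(sn)$nodes, 0)
  expect_equal(brute_force_mwcs(sn)$score, 0)
  m3 <- brute_force_mwcs(sn, allow_empty = FALSE)
  expect_equal(m3$nodes, "C")
  expect_equal(m3$score, -0.2)

  big <- simulate_network(20, seed = 1)
  expect_error(brute_force_mwcs(scored_network(
    big, stats::setNames(rep(1, 20), igraph::V(big)$name), 0.01)),
    "too large")
})

test_that("exact solver equals brute force and the independent oracle", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(4:11, 1)
    net <- simulate_network(n, mean_degree = 2.5, seed = s)
    sn <- scored_network(
      net, stats::setNames(rnorm(n, -0.5, 1), igraph::V(net)$name),
      sample(c(-0.01, 0.01, round(runif(1, -1, 1), 3)),
             igraph::ecount(net), replace = TRUE))
    b <- brute_force_mwcs(sn)
    e <- exact_mwcs(sn)
    expect_equal(e$score, b$score, tolerance = 1e-9)
    expect_equal(e$status, "optimal")
    validate_module(e, sn)
    validate_module(b, sn)
    if (s <= 8)
      expect_equal(b$score, oracle_mwcs_score(sn), tolerance = 1e-9)
  }
})

test_that("single positive node among negatives is returned alone", {
  net <- simulate_network(9, seed = 4)
  ns <- stats::setNames(rep(-1, 9), igraph::V(net)$name)
  ns[5] <- 2
  sn <- scored_network(net, ns, -0.01)
  for (solver in list(exact_mwcs, heuristic_mwcs, brute_force_mwcs)) {
    m <- solver(sn)
    expect_equal(m$nodes, igraph::V(net)$name[5])
    expect_equal(m$score, 2)
  }
})

test_that("a strongly negative bridge separates two positive clusters", {
  # heavier cluster A-B (score 3) vs C (score 1), bridge edge -10
  edf <- data.frame(from = c("A", "B"), to = c("B", "C"))
  g <- igraph::graph_from_data_frame(edf, directed = FALSE)
  sn <- scored_network(g, c(A = 1, B = 2, C = 1), c(0.5, -10))
  for (m in list(exact_mwcs(sn), brute_force_mwcs(sn))) {
    expect_setequal(m$nodes, c("A", "B"))
    expect_equal(m$score, 3.5)
  }
})

test_that("positive induced edges are always part of the optimum", {
  for (s in 1:10) {
    net <- simulate_network(10, seed = 100 + s)
    set.seed(s)
    sn <- scored_network(
      net, stats::setNames(rnorm(10, 0, 1), igraph::V(net)$name),
      rnorm(igraph::ecount(net), 0, 0.5))
    m <- exact_mwcs(sn)
    if (length(m$nodes) < 2) next
    ends <- igraph::as_edgelist(net)
    w <- igraph::E(net)$score
    induced_pos <- which(ends[, 1] %in% m$nodes & ends[, 2] %in% m$nodes &
                           w > 0)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    expect_true(all(key(ends[induced_pos, 1], ends[induced_pos, 2]) %in%
                      key(m$edges$from, m$edges$to)))
  }
})

test_that("heuristic is feasible and never beats the exact optimum", {
  for (s in 1:15) {
    net <- simulate_network(12, mean_degree = 3, seed = 200 + s)
    set.seed(s)
    sn <- scored_network(
      net, stats::setNames(rnorm(12, -0.4, 1), igraph::V(net)$name),
      rnorm(igraph::ecount(net), 0, 0.4))
    h <- heuristic_mwcs(sn)
    e <- exact_mwcs(sn)
    expect_lte(h$score, e$score + 1e-9)
    expect_equal(h$status, "feasible-heuristic")
    validate_module(h, sn)
  }
})

test_that("top-k enumeration returns distinct, score-ordered solutions", {
  net <- simulate_network(8, seed = 31)
  set.seed(31)
  sn <- scored_network(net,
                       stats::setNames(rnorm(8, 0.2, 1), igraph::V(net)$name),
                       rnorm(igraph::ecount(net), 0, 0.2))
  sols <- solve_mwcs(sn, method = "exact", top_k = 3)
  expect_length(sols, 3)
  keys <- vapply(sols, function(m) paste(m$nodes, collapse = "|"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  scores <- vapply(sols, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 1e-9))
})

test_that("the solver is deterministic and respects the time limit status", {
  net <- simulate_network(10, seed = 77)
  set.seed(77)
  sn <- scored_network(net,
                       stats::setNames(rnorm(10), igraph::V(net)$name),
                       rnorm(igraph::ecount(net), 0, 0.3))
  m1 <- exact_mwcs(sn); m2 <- exact_mwcs(sn)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$score, m2$score)
})
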