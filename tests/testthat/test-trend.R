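test_that("JT statistic and p-values match the brute-force oracle", {
  # perfectly increasing data attains the maximum statistic
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- jt_test(g)
  expect_equal(r$statistic, 12)
  expect_equal(r$statistic, oracle_jt_stat(g))

  # exact permutation p equals full-enumeration oracle on random inputs
  for (seed in 1:5) {
    set.seed(seed)
    g <- split(rnorm(6), rep(1:3, each = 2))
    for (alt in c("two.sided", "increasing", "decreasing")) {
      alt_o <- c(two.sided = "two.sided", increasing = "greater",
                 decreasing = "less")[[alt]]
      expect_equal(jt_test(g, alternative = alt, method = "exact")$p_value,
                   oracle_perm_pvalue(g, oracle_jt_stat, alt_o))
    }
    # normal approximation close to exact at this size
    expect_lt(abs(jt_test(g, method = "normal")$p_value -
                    jt_test(g, method = "exact")$p_value), 0.05)
  }

  # tied data: oracle still agrees (midrank convention)
  g <- list(c(1, 1), c(1, 2), c(2, 2))
  expect_equal(jt_test(g, method = "exact")$p_value,
               oracle_perm_pvalue(g, oracle_jt_stat))
  expect_equal(jt_test(g)$statistic, oracle_jt_stat(g))
})

test_that("constant data gives z = 0 and p = 1", {
  g <- list(c(2, 2), c(2, 2), c(2, 2))
  for (m in c("normal", "exact")) {
    r <- jt_test(g, method = m)
    expect_equal(r$z, 0)
    expect_equal(r$p_value, 1)
    ru <- umbrella_test(g, peak = 2, method = m)
    expect_equal(ru$z, 0)
    expect_equal(ru$p_value, 1)
  }
})

test_that("umbrella statistic matches hand counts and the oracle", {
  # all of group 1 below group 2; all of group 3 below group 2 -> A_2 = 8
  g <- list(c(1, 2), c(5, 6), c(3, 4))
  r <- umbrella_test(g, peak = 2)
  expect_equal(r$statistic, 8)
  expect_equal(r$statistic, oracle_umbrella_stat(g, 2))
  expect_gt(r$z, 0)

  for (seed in 1:5) {
    set.seed(seed)
    g <- split(rnorm(6), rep(1:3, each = 2))
    for (pk in 1:3) {
      expect_equal(umbrella_test(g, peak = pk)$statistic,
                   oracle_umbrella_stat(g, pk))
      expect_equal(umbrella_test(g, peak = pk, method = "exact")$p_value,
                   oracle_perm_pvalue(g, function(x)
                     oracle_umbrella_stat(x, pk)))
    }
  }
  expect_error(umbrella_test(g, peak = 7), "peak")
  expect_error(jt_test(list(numeric(0), 1:3)), "zero observations")
})

test_that("umbrella with peak = k reduces to the JT statistic", {
  for (seed in 1:20) {
    set.seed(seed)
    sizes <- sample(2:4, sample(3:5, 1), replace = TRUE)
    g <- lapply(sizes, function(n) rnorm(n))
    k <- length(g)
    expect_equal(umbrella_test(g, peak = k)$statistic, jt_test(g)$statistic)
    # and the null moments coincide, so z does as well
    expect_equal(umbrella_test(g, peak = k)$z, jt_test(g)$z)
  }
})

test_that("negating the data flips z and keeps the two-sided p", {
  set.seed(9)
  g <- lapply(1:5, function(i) rnorm(3, mean = c(0, 1, 2, 1, 0)[i]))
  r1 <- umbrella_test(g, peak = 3)
  r2 <- umbrella_test(lapply(g, function(x) -x), peak = 3)
  expect_equal(r1$z, -r2$z, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("p-values are invariant under strictly monotone transforms", {
  set.seed(4)
  g <- lapply(1:4, function(i) runif(3, 0.1, 2))
  tr <- function(x) exp(3 * x) + 1
  expect_equal(umbrella_test(g, peak = 2)$p_value,
               umbrella_test(lapply(g, tr), peak = 2)$p_value)
  expect_equal(jt_test(g)$p_value, jt_test(lapply(g, tr))$p_value)
})

test_that("Monte-Carlo permutation approximates the exact p-value", {
  set.seed(12)
  g <- split(rnorm(6), rep(1:3, each = 2))
  pe <- umbrella_test(g, peak = 2, method = "exact")$p_value
  set.seed(1)
  pm <- umbrella_test(g, peak = 2, method = "montecarlo",
                      n_perm = 4000)$p_value
  expect_lt(abs(pe - pm), 0.05)
})

test_that("umbrella_test_profiles scores each metabolite and flags gaps", {
  sim <- simulate_profiles(n_metabolites = 12, seed = 5)
  res <- umbrella_test_profiles(sim$profiles, peak = 10)
  expect_equal(nrow(res), 12)
  expect_identical(res$metabolite_id, sim$profiles$metabolites)
  expect_true(all(res$ok))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # a clean umbrella profile is the most significant against null background
  shapes <- c(list(umb = metamod:::trend_shape("umbrella", 20, 10, 2)),
              stats::setNames(lapply(1:9, function(i) {
                set.seed(100 + i); rnorm(20, sd = 0.3)
              }), sprintf("null%d", 1:9)))
  pm <- toy_profile_matrix(shapes, replicates = 2)
  pm$values <- pm$values + array(withr::with_seed(42,
    rnorm(length(pm$values), sd = 0.05)), dim(pm$values))
  res <- umbrella_test_profiles(pm, peak = 10)
  expect_equal(which.min(res$p_value), 1L)

  # metabolites with data at fewer than 3 time points are flagged
  arr <- array(NA_real_, c(2, 5, 2), dimnames = list(c("a", "b"), NULL, NULL))
  arr[1, , ] <- rnorm(10)
  arr[2, 1:2, 1] <- c(1, 2)
  res2 <- umbrella_test_profiles(profile_matrix(arr, phase_split = 3),
                                 peak = 3)
  expect_true(res2$ok[1])
  expect_false(res2$ok[2])
  expect_true(is.na(res2$p_value[2]))
})

test_that("wilcoxon phase comparison behaves at the boundaries", {
  # identical phases: p = 1
  vals <- rep(c(1, 2, 3, 4, 5), 2)
  pm <- toy_profile_matrix(list(m1 = vals), replicates = 1, phase_split = 5)
  expect_equal(wilcoxon_phase_test(pm)$p_value, 1, tolerance = 1e-6)

  # fully separated phases with n = 40 each: p below 1e-6
  arr <- array(NA_real_, c(1, 20, 4), dimnames = list("m1", NULL, NULL))
  arr[1, 1:10, ] <- withr::with_seed(1, runif(40))
  arr[1, 11:20, ] <- withr::with_seed(2, runif(40) + 10)
  pm <- profile_matrix(arr, phase_split = 10)
  p_sep <- wilcoxon_phase_test(pm)$p_value
  expect_lt(p_sep, 1e-6)

  # swapping the phases leaves the two-sided p unchanged
  arr2 <- arr[, c(11:20, 1:10), , drop = FALSE]
  pm2 <- profile_matrix(arr2, phase_split = 10)
  expect_equal(wilcoxon_phase_test(pm2)$p_value, p_sep)

  expect_error(wilcoxon_phase_test(pm, split = 20), "phases")
})

test_that("top_variance keeps ceil(f*m) profiles with deterministic ties", {
  sim <- simulate_profiles(n_metabolites = 84, seed = 3)
  expect_equal(top_variance(sim$profiles, 1)$metabolites,
               sim$profiles$metabolites)
  expect_length(top_variance(sim$profiles, 0.1)$metabolites, 9)  # ceiling
  # constant-variance ties resolve by metabolite ID
  pm <- toy_profile_matrix(list(z2 = c(1, 2, 3), a1 = c(2, 3, 4),
                                b1 = c(0, 0, 0)), replicates = 1)
  expect_setequal(top_variance(pm, 2 / 3)$metabolites, c("a1", "z2"))
  expect_error(top_variance(pm, 0), "fraction")
})
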