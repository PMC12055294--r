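# taxonomic Hill numbers: observed, asymptotic, size- and
# coverage-standardized

test_that("observed Hill numbers match closed forms", {
  for (q in c(0, 1, 2)) expect_equal(hill_observed(rep(3, 7), q), 7)
  expect_equal(hill_observed(c(0.8, 0.2), 2), 1 / 0.68)
  expect_equal(hill_observed(c(0.8, 0.2), 1),
               exp(-(0.8 * log(0.8) + 0.2 * log(0.2))))
  expect_error(hill_observed(numeric(0), 0), "empty")
  expect_error(hill_observed(c(1, 1), 3), "q must be")
})

test_that("asymptotic estimators match closed forms and edge cases", {
  expect_equal(hill_asymptotic(c(5, 3, 2), 0), 3)        # f1 = 0 -> S_obs
  expect_equal(hill_asymptotic(c(4, 4, 4, 4), 2), 5)     # 1/(48/240)
  expect_warning(v <- hill_asymptotic(rep(1, 6), 2), "unavailable")
  expect_true(is.na(v))
  # Chao1 with doubletons: S_obs + ((n-1)/n) f1^2/(2 f2)
  x <- c(4, 2, 2, 1, 1, 1)
  expect_equal(hill_asymptotic(x, 0), 6 + (10 / 11) * 9 / 4)
})

test_that("q = 0 asymptote sits between observed and true richness (median)", {
  meds <- vapply(1:40, function(r) {
    x <- random_counts(S = 300, n = 4000, seed = 3000 + r, sigma = 1.5)
    c(S_obs = length(x), est = hill_asymptotic(x, 0))
  }, numeric(2))
  expect_gte(median(meds["est", ]), median(meds["S_obs", ]))
  expect_lte(median(meds["est", ]), 300 * 1.2)
})

test_that("size standardization is consistent at the boundaries", {
  x <- c(8, 4, 2, 1, 1)
  n <- sum(x)
  for (q in c(0, 1, 2)) {
    expect_equal(as.numeric(hill_at_size(x, q, n, seed = 1)),
                 hill_observed(x, q), tolerance = 1e-12)
    expect_equal(as.numeric(hill_at_size(x, q, 1, seed = 1)), 1,
                 tolerance = 1e-9)
  }
})

test_that("q = 0 rarefaction agrees with the subsampling oracle", {
  x <- c(8, 4, 2, 1, 1)
  n <- sum(x); m <- 8
  reads <- rep(seq_along(x), x)
  rich <- with_seed_local(21, replicate(1000, length(unique(reads[sample.int(n, m)]))))
  analytic <- as.numeric(hill_at_size(x, 0, m))
  se <- sd(rich) / sqrt(length(rich))
  expect_lt(abs(analytic - mean(rich)), 3 * se)
})

test_that("q = 2 size standardization equals full enumeration for tiny n", {
  # expected Simpson concentration over all read subsamples of size m,
  # enumerated exhaustively; the estimator must invert that expectation
  enum_simpson_hill <- function(x, m) {
    reads <- rep(seq_along(x), x)
    subs <- combn(length(reads), m)
    conc <- apply(subs, 2, function(idx) {
      t <- tabulate(reads[idx], nbins = length(x))
      sum((t / m)^2)
    })
    1 / mean(conc)
  }
  cases <- list(list(x = c(5, 4, 3), m = 4), list(x = c(6, 3, 2, 1), m = 6),
                list(x = c(2, 2, 1, 1), m = 3))
  for (cs in cases) {
    expect_equal(as.numeric(hill_at_size(cs$x, 2, cs$m)),
                 enum_simpson_hill(cs$x, cs$m), tolerance = 1e-9)
  }
})

test_that("Hill numbers are non-increasing in q", {
  for (seed in 1:6) {
    x <- random_counts(S = 50, n = 700, seed = 4000 + seed)
    obs <- vapply(c(0, 1, 2), function(q) hill_observed(x, q), numeric(1))
    expect_true(all(diff(obs) <= 1e-9))
    std <- vapply(c(0, 1, 2), function(q)
      as.numeric(hill_at_size(x, q, floor(sum(x) / 2), seed = 9)), numeric(1))
    expect_true(all(diff(std) <= 0.05 * std[1]))  # q = 1 is Monte-Carlo
  }
})

test_that("coverage standardization is monotone and consistent", {
  x <- random_counts(S = 80, n = 1200, seed = 77)
  Cobs <- estimate_coverage(x)
  v <- hill_at_coverage(x, 0, Cobs - 1e-13)
  expect_equal(as.numeric(v), hill_observed(x, 0), tolerance = 1e-6)
  lo <- as.numeric(hill_at_coverage(x, 0, Cobs - 0.1))
  hi <- as.numeric(hill_at_coverage(x, 0, Cobs - 0.02))
  expect_lte(lo, hi)
})

test_that("standardized values agree across sequencing depths of one community", {
  # one community sequenced at 2000 vs 8000 reads: raw richness differs, but
  # coverage-standardized means agree within combined Monte-Carlo error
  props <- simulate_community(300, "lognormal", sigma = 1.5, seed = 11)
  x1 <- simulate_reads(props, 2000, seed = 1)
  x2 <- simulate_reads(props, 8000, seed = 2)
  expect_gt(sum(x2 > 0) - sum(x1 > 0), 10)   # raw S_obs differs materially
  std <- function(n, q, r) {
    x <- simulate_reads(props, n, seed = 1000 * n + r)
    as.numeric(hill_at_coverage(x[x > 0], q, 0.96, seed = r, B = 100))
  }
  for (q in c(0, 1, 2)) {
    v1 <- vapply(1:10, function(r) std(2000, q, r), numeric(1))
    v2 <- vapply(1:10, function(r) std(8000, q, r), numeric(1))
    se <- sqrt(var(v1) / 10 + var(v2) / 10)
    expect_lt(abs(mean(v1) - mean(v2)), 3 * se)
  }
})

test_that("fixed seeds give bit-identical standardized estimates", {
  x <- random_counts(S = 60, n = 900, seed = 13)
  a <- hill_at_coverage(x, 1, 0.9, seed = 123, B = 50)
  b <- hill_at_coverage(x, 1, 0.9, seed = 123, B = 50)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("alpha_diversity tabulates every sample and order", {
  tab <- build_table(list(
    a = simulate_reads(simulate_community(40, "lognormal", sigma = 1, seed = 1), 800, 2),
    b = simulate_reads(simulate_community(40, "lognormal", sigma = 1, seed = 1), 1200, 3)))
  out <- alpha_diversity(tab, coverage = 0.95, seed = 5)
  expect_equal(nrow(out), 6)
  expect_true(all(out$value >= 1))
  expect_setequal(unique(out$sample_id), c("a", "b"))
})
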