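# Good-Turing singleton estimation and seeded surplus removal

test_that("the singleton estimator follows its closed forms", {
  expect_equal(good_turing_singletons(30, 20), 30)          # 2*30^2 / (3*20)
  expect_equal(good_turing_singletons(0, 5), 0)             # no doubletons
  expect_equal(good_turing_singletons(0, 0), 0)
  expect_equal(good_turing_singletons(6, 0), 2 * 6 * 5 / 3) # f3 = 0 fallback
  fc <- frequency_counts(c(2, 2, 2, 3, 3))                  # f2 = 3, f3 = 2
  expect_equal(estimate_true_singletons(fc), 2 * 9 / 6)
  # the estimator is injectable
  expect_equal(estimate_true_singletons(fc, estimator = function(f2, f3, f4) 7), 7)
})

test_that("surplus removal zeroes the right number of singleton cells only", {
  # 10 singletons; force f1_hat = 4.2 -> surplus = 6
  x <- c(rep(1L, 10), 5L, 4L, 3L)
  names(x) <- paste0("o", seq_along(x))
  tab <- matrix(x, nrow = 1, dimnames = list("s1", names(x)))
  res <- apply_singleton_filter(tab, seed = 11,
                                estimator = function(f2, f3, f4) 4.2,
                                drop_empty = FALSE)
  expect_equal(res$corrections$surplus, 6)
  expect_equal(sum(res$table["s1", ] == 0), 6)
  removed <- attr(res$corrections, "removed")[["s1"]]
  expect_length(removed, 6)
  expect_true(all(tab[1, removed] == 1L))          # removed cells held count 1
  expect_equal(res$table[1, c("o11", "o12", "o13")], tab[1, c("o11", "o12", "o13")])
  # column sums decrease by exactly the number of removals
  expect_equal(sum(tab) - sum(res$table), 6)

  # clamping: f1_hat >= f1_obs leaves the sample untouched
  res2 <- apply_singleton_filter(tab, seed = 11,
                                 estimator = function(f2, f3, f4) 99,
                                 drop_empty = FALSE)
  expect_identical(res2$table, tab)
  expect_equal(res2$corrections$surplus, 0)

  # determinism
  resA <- apply_singleton_filter(tab, seed = 5, estimator = function(...) 0,
                                 drop_empty = FALSE)
  resB <- apply_singleton_filter(tab, seed = 5, estimator = function(...) 0,
                                 drop_empty = FALSE)
  expect_identical(resA$table, resB$table)
})

test_that("filtering never increases a count and never touches counts >= 2", {
  for (seed in 1:5) {
    p <- simulate_community(80, "lognormal", sigma = 1.5, seed = seed)
    tab <- build_table(list(a = simulate_reads(p, 600, seed + 10),
                            b = simulate_reads(p, 900, seed + 20)))
    res <- apply_singleton_filter(tab, seed = seed, drop_empty = FALSE)
    expect_true(all(res$table <= tab))
    big <- tab >= 2L
    expect_identical(res$table[big], tab[big])
    changed <- which(res$table != tab)
    expect_true(all(tab[changed] == 1L))
  }
})

test_that("repeat_filter returns one table per seed, identical when surplus is 0", {
  tab <- toy_table()
  reps <- repeat_filter(tab, seeds = 1:5, estimator = function(...) 99,
                        drop_empty = FALSE)
  expect_length(reps, 5)
  for (r in reps) expect_identical(r$table, tab)

  # with genuine removal, replicates differ only in which singletons went
  x <- setNames(c(rep(1L, 12), 6L, 4L), paste0("o", 1:14))
  tab2 <- matrix(x, nrow = 1, dimnames = list("s1", names(x)))
  reps2 <- repeat_filter(tab2, seeds = 1:5, estimator = function(...) 2,
                         drop_empty = FALSE)
  for (r in reps2) {
    expect_equal(sum(r$table), sum(tab2) - 10)
    expect_identical(r$table[1, c("o13", "o14")], tab2[1, c("o13", "o14")])
  }
  expect_gt(length(unique(lapply(reps2, function(r) unname(r$table[1, ])))), 1)
})

test_that("injected spurious singletons are recovered by the surplus estimate", {
  # homogeneous community: injected pseudo-singletons dominate f1, so the
  # mean estimated surplus should sit within 20% of the injected k
  k <- 50
  m <- mean_recovered_surplus(k, reps = 100, S = 200, n = 5000, seed = 42)
  expect_lt(abs(m - k) / k, 0.2)
})

test_that("estimated f1 tracks observed f1 on clean homogeneous samples", {
  # at these sizes the community yields essentially no natural singletons or
  # doubletons, so both quantities are pinned near zero; the band uses a
  # small absolute floor to stay meaningful there
  vals <- vapply(1:100, function(r) {
    x <- simulate_reads(simulate_community(200, "equal"), 5000, seed = 500 + r)
    fc <- frequency_counts(x[x > 0])
    c(f1 = sum(x == 1), f1_hat = estimate_true_singletons(fc))
  }, numeric(2))
  mean_f1 <- mean(vals["f1", ]); mean_hat <- mean(vals["f1_hat", ])
  expect_lte(abs(mean_hat - mean_f1), max(0.15 * mean_f1, 0.5))
})

test_that("the estimator is well-behaved on skewed communities with rich tails", {
  vals <- vapply(1:50, function(r) {
    x <- random_counts(S = 400, n = 3000, seed = 900 + r, sigma = 1.5)
    fc <- frequency_counts(x)
    c(f1 = sum(x == 1), hat = estimate_true_singletons(fc))
  }, numeric(2))
  expect_true(all(is.finite(vals["hat", ])))
  expect_true(all(vals["hat", ] >= 0))
  # on clean (error-free) samples the estimate is on the scale of observed f1
  expect_lt(abs(mean(vals["hat", ]) - mean(vals["f1", ])) / mean(vals["f1", ]), 0.5)
})
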