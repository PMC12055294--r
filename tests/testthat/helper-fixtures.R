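# shared fixtures, all built in code

# evaluate expr under a local seed without disturbing the suite RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# 2-sample toy community matrix
toy_table <- function() {
  m <- matrix(c(3L, 1L, 0L,
                0L, 5L, 2L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  m
}

# cherry tree: tips A, B at depth 2, internal node at age 1
cherry_tree <- function() ape::read.tree(text = "((A:1,B:1):1);")

# star ultrametric tree with k unit branches
star_tree <- function(k = 4) {
  tips <- paste0("t", seq_len(k))
  ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), ");"))
}

# random sample counts from a seeded lognormal community
random_counts <- function(S = 60, n = 1000, seed = 1, sigma = 1.2) {
  p <- simulate_community(S, "lognormal", sigma = sigma, seed = seed)
  x <- simulate_reads(p, n, seed = seed + 1)
  x[x > 0]
}

# mean of the worked singleton-filter surplus over replicate error-injected
# homogeneous samples
mean_recovered_surplus <- function(k, reps, S = 200, n = 5000, seed = 1) {
  vals <- vapply(seq_len(reps), function(r) {
    x <- simulate_reads(simulate_community(S, "equal"), n, seed = seed + r)
    x <- inject_errors(x[x > 0], k)
    fc <- frequency_counts(x)
    f1 <- unname(fc$f["1"])
    f1_hat <- estimate_true_singletons(fc)
    max(0, min(f1, round(f1 - f1_hat)))
  }, numeric(1))
  mean(vals)
}
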