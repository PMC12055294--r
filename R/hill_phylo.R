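# Phylogenetic Hill numbers on the ultrametric mega-tree.
#
# Every branch b carries a length L_b (time units) and a relative read
# abundance a_b, the summed relative abundance of the tips descending from it.
# The mean phylogenetic diversity of order q generalizes the taxonomic Hill
# number by replacing species with lineages; multiplying by the reference
# time T (the tree depth) gives qPD in branch-length units.

#' Branch abundance profile of a sample on an ultrametric tree
#'
#' Aggregates tip relative abundances onto every branch by post-order
#' accumulation. Branches with zero abundance are retained (they simply do
#' not contribute to any sum), so a per-sample profile on the shared
#' mega-tree keeps the global reference time T and qPD values remain
#' comparable across samples. The ultrametric identity
#' `sum_b L_b a_b = T` is checked on construction.
#'
#' @param tree ultrametric [ape::phylo] (within `tol`).
#' @param x named count (or relative abundance) vector; every name with a
#'   positive value must be a tip of `tree`.
#' @param tol ultrametricity tolerance on root-to-tip depth differences.
#' @return list of class `branch_profile`: `lengths` (L_b), `abund` (a_b),
#'   `T` (tree depth), `n` (total reads when `x` are counts).
#' @export
branch_profile <- function(tree, x, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  x <- x[x > 0]
  if (!length(x)) stop_metadiv("empty abundance profile")
  if (is.null(names(x))) stop_metadiv("abundances must be named by tip label")
  missing <- setdiff(names(x), tree$tip.label)
  if (length(missing)) {
    stop_metadiv("OTU(s) not present in the tree: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ...")
  }
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  tipd <- depths[seq_len(ntip)]
  if (max(tipd) - min(tipd) > tol) {
    stop_metadiv("tree is not ultrametric (max depth spread ",
                 signif(max(tipd) - min(tipd), 4), ")")
  }
  T_ref <- max(tipd)
  p_tip <- rep(0, ntip)
  p_tip[match(names(x), tree$tip.label)] <- x / sum(x)

  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  acc <- c(p_tip, rep(0, tree$Nnode))
  for (e in seq_len(nrow(edge))) {
    acc[edge[e, 1]] <- acc[edge[e, 1]] + acc[edge[e, 2]]
  }
  a_b <- acc[edge[, 2]]
  L_b <- tree$edge.length
  if (abs(sum(L_b * a_b) - T_ref) > max(1e-9, 1e-12 * T_ref) * 10) {
    stop_metadiv("ultrametric identity sum(L_b a_b) = T violated")
  }
  structure(list(lengths = L_b, abund = a_b, T = T_ref, n = sum(x)),
            class = "branch_profile")
}

#' Observed phylogenetic Hill numbers
#'
#' Mean diversity of order q over the branch profile,
#' `qDbar = (sum_b (L_b/T) a_b^q)^(1/(1-q))` (limit form at q = 1), and the
#' phylogenetic diversity `qPD = T * qDbar`. At q = 0 with all tips present,
#' qPD is the Faith-type total branch length.
#'
#' @param bp a [branch_profile()].
#' @param q Hill order (0, 1 or 2).
#' @return list: `pd`, `mean_pd` (= pd / T), `q`, `T`.
#' @export
pd_observed <- function(bp, q) {
  check_q(q)
  stopifnot(inherits(bp, "branch_profile"))
  keep <- bp$abund > 0
  L <- bp$lengths[keep]; a <- bp$abund[keep]; T_ref <- bp$T
  meanD <- if (q == 1) {
    exp(-sum((L / T_ref) * a * log(a)))
  } else {
    sum((L / T_ref) * a^q)^(1 / (1 - q))
  }
  list(pd = T_ref * meanD, mean_pd = meanD, q = q, T = T_ref)
}

# asymptotic qPD treating branches as pseudo-species with integer read counts
# n * a_b and weights L_b/T (the q-matched analogues of the taxonomic
# asymptotic estimators)
pd_asymptotic <- function(bp, q) {
  check_q(q)
  keep <- bp$abund > 0
  L <- bp$lengths[keep]; a <- bp$abund[keep]
  T_ref <- bp$T; n <- bp$n
  y <- round(n * a)
  g1 <- sum(L[y == 1]); g2 <- sum(L[y == 2])
  if (q == 0) {
    pd_obs <- sum(L)
    f0L <- if (g2 > 0) ((n - 1) / n) * g1^2 / (2 * g2)
           else ((n - 1) / n) * g1 * (g1 - 1) / 2
    return(list(pd = pd_obs + max(0, f0L), mean_pd = (pd_obs + max(0, f0L)) / T_ref,
                q = q, T = T_ref))
  }
  if (q == 1) {
    part1 <- sum(vapply(seq_along(y), function(b) {
      if (y[b] > n - 1) return(0)
      L[b] * (y[b] / n) * sum(1 / (y[b]:(n - 1)))
    }, numeric(1)))
    A <- if (g2 > 0) 2 * g2 / ((n - 1) * g1 + 2 * g2)
         else if (g1 > 0) 2 / ((n - 1) * (g1 - 1) + 2) else 1
    part2 <- if (g1 > 0 && A < 1) {
      r <- seq_len(n - 1)
      (g1 / n) * (1 - A)^(1 - n) * (-log(A) - sum((1 / r) * (1 - A)^r))
    } else 0
    Hp <- part1 + part2
    meanD <- exp(Hp / T_ref)
    return(list(pd = T_ref * meanD, mean_pd = meanD, q = q, T = T_ref))
  }
  denom <- sum((L / T_ref) * y * (y - 1) / (n * (n - 1)))
  if (denom == 0) {
    warning("q = 2 phylogenetic asymptote unavailable", call. = FALSE)
    return(list(pd = NA_real_, mean_pd = NA_real_, q = q, T = T_ref))
  }
  meanD <- 1 / denom
  list(pd = T_ref * meanD, mean_pd = meanD, q = q, T = T_ref)
}

# mean observed qPD over B seeded subsamples of m reads
pd_rarefied <- function(tree, x, q, m, seed = NULL, B = 200) {
  x <- x[x > 0]
  n <- sum(x)
  m <- max(1L, as.integer(round(m)))
  if (m >= n) {
    bp <- branch_profile(tree, x)
    o <- pd_observed(bp, q)
    return(c(pd = o$pd, mean_pd = o$mean_pd))
  }
  reads <- rep(names(x), x)
  with_seed(seed, {
    vals <- vapply(seq_len(B), function(b) {
      sub <- table(sample(reads, m))
      sx <- setNames(as.integer(sub), names(sub))
      bp <- branch_profile(tree, sx)
      o <- pd_observed(bp, q)
      c(o$pd, o$mean_pd)
    }, numeric(2))
    c(pd = mean(vals[1, ]), mean_pd = mean(vals[2, ]))
  })
}

#' Coverage-standardized phylogenetic diversity
#'
#' The coverage target is solved on the sample's taxonomic (tip-level) read
#' distribution -- coverage is a property of the sample, the tree only enters
#' the diversity value. On the rarefaction side the estimate is the mean
#' observed qPD over `B` seeded read subsamples of the matching size; on the
#' extrapolation side the asymptotic branch-analogue estimate is approached
#' with the same completion term as the taxonomic q = 0 extrapolation.
#'
#' @param tree ultrametric [ape::phylo].
#' @param x named count vector (reads per OTU).
#' @param q Hill order (0, 1, 2).
#' @param C_target coverage target in (0, 1).
#' @param seed RNG seed for the subsampling.
#' @param B number of subsamples (default 200).
#' @param extrap_cap see [size_for_coverage()].
#' @return list: `pd`, `mean_pd`, `q`, `T`, `m`, `side`, `achieved_coverage`.
#' @export
pd_at_coverage <- function(tree, x, q, C_target, seed = NULL, B = 200,
                           extrap_cap = 2) {
  check_q(q)
  x <- x[x > 0]
  fc <- frequency_counts(x)
  m <- size_for_coverage(fc, C_target, extrap_cap = extrap_cap)
  side <- attr(m, "side")
  bp <- branch_profile(tree, x)
  if (side != "extrapolated") {
    est <- pd_rarefied(tree, x, q, as.numeric(m), seed = seed, B = B)
    pd <- est[["pd"]]; meanpd <- est[["mean_pd"]]
  } else {
    obs <- pd_observed(bp, q)
    asym <- pd_asymptotic(bp, q)
    f1 <- f_r(fc, 1)
    if (f1 == 0 || is.na(asym$pd)) {
      pd <- obs$pd
    } else {
      f0 <- max(chao_f0(fc), .Machine$double.eps)
      mstar <- as.numeric(m) - fc$n
      comp <- 1 - (1 - f1 / (fc$n * f0 + f1))^mstar
      pd <- obs$pd + (asym$pd - obs$pd) * comp
    }
    meanpd <- pd / bp$T
  }
  list(pd = pd, mean_pd = meanpd, q = q, T = bp$T, m = as.numeric(m),
       side = side, achieved_coverage = attr(m, "achieved_coverage"))
}

#' Per-sample phylogenetic diversity table
#'
#' @param table community matrix (rows = samples; columns must be tips of
#'   `tree`).
#' @param tree ultrametric [ape::phylo].
#' @param q Hill orders.
#' @param coverage coverage target, or `NULL` for observed qPD.
#' @param seed,B,extrap_cap see [pd_at_coverage()].
#' @return data.frame: sample_id, q, method, m, achieved_coverage, pd,
#'   mean_pd, T.
#' @export
pd_diversity <- function(table, tree, q = c(0, 1, 2), coverage = 0.996,
                         seed = NULL, B = 200, extrap_cap = 2) {
  table <- validate_otu_table(table)
  rows <- list(); k <- 0L
  for (s in rownames(table)) {
    x <- table[s, ]
    if (sum(x) == 0) next
    for (qq in q) {
      k <- k + 1L
      if (is.null(coverage)) {
        bp <- branch_profile(tree, x)
        o <- pd_observed(bp, qq)
        rows[[k]] <- data.frame(sample_id = s, q = qq, method = "observed",
                                m = sum(x), achieved_coverage = NA_real_,
                                pd = o$pd, mean_pd = o$mean_pd, T = o$T,
                                stringsAsFactors = FALSE)
      } else {
        o <- pd_at_coverage(tree, x, qq, coverage,
                            seed = if (is.null(seed)) NULL else seed + k,
                            B = B, extrap_cap = extrap_cap)
        rows[[k]] <- data.frame(sample_id = s, q = qq, method = o$side,
                                m = o$m, achieved_coverage = o$achieved_coverage,
                                pd = o$pd, mean_pd = o$mean_pd, T = o$T,
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
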