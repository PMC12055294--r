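# Coverage-standardized pairwise beta diversity.
#
# For a pair of samples (equal weights), gamma is the Hill diversity of the
# pooled mean relative abundances, alpha the within-assemblage Hill diversity,
# and beta = gamma/alpha lies in [1, 2]. The Jaccard (q = 0), Horn (q = 1) and
# Morisita-Horn (q = 2) dissimilarities are monotone transforms of beta.

# coverage-standardized relative-abundance profile of one sample:
# expected rarefied profile (mean of B seeded subsamples) on the rarefaction
# side, the observed profile at/over the observed coverage
standardized_profile <- function(x, C_target, seed = NULL, B = 200,
                                 extrap_cap = 2) {
  x <- x[x > 0]
  if (is.null(C_target)) {
    return(list(p = x / sum(x), side = "observed", flagged = FALSE,
                m = sum(x), achieved = NA_real_))
  }
  fc <- frequency_counts(x)
  m <- size_for_coverage(fc, C_target, extrap_cap = extrap_cap)
  side <- attr(m, "side")
  achieved <- attr(m, "achieved_coverage")
  flagged <- side == "extrapolated" && achieved < C_target - 1e-6
  if (side == "interpolated") {
    mi <- attr(m, "m_integer")
    reads <- rep(names(x), x)
    p <- with_seed(seed, {
      acc <- setNames(rep(0, length(x)), names(x))
      for (b in seq_len(B)) {
        sub <- table(sample(reads, mi))
        acc[names(sub)] <- acc[names(sub)] + as.integer(sub) / mi
      }
      acc / B
    })
  } else {
    p <- x / sum(x)
  }
  list(p = p, side = side, flagged = flagged, m = as.numeric(m),
       achieved = achieved)
}

#' Pairwise beta decomposition and dissimilarity
#'
#' Standardizes both samples to the target coverage (see Details), then
#' decomposes their diversity: `gamma` is the Hill number of the pooled mean
#' relative abundances, `alpha = (1/2) (sum_ij (p_ij/2)^q)^(1/(1-q))` (limit
#' form at q = 1) and `beta = gamma/alpha` in `[1, 2]`. Both overlap
#' transforms are returned: the size-weighted `C_qN` and the richness-type
#' `U_qN`. The conventional named dissimilarities are `1 - U` at q = 0
#' (Jaccard), `log(beta)/log(2)` at q = 1 (Horn) and `1 - C` at q = 2
#' (Morisita-Horn); for a pair these equal `2 - 2/beta` at q = 0 and q = 2.
#'
#' With `C_target = NULL` the observed relative abundances are compared
#' directly (no standardization). A sample whose coverage target is
#' unreachable under the extrapolation cap is flagged so callers can exclude
#' the pair.
#'
#' @param xA,xB named count vectors (reads per OTU) for the two samples.
#' @param q Hill order (0, 1, 2).
#' @param C_target coverage target in (0, 1), or `NULL` for observed.
#' @param seed RNG seed for the rarefied expected profiles.
#' @param B subsamples per profile (default 200).
#' @param extrap_cap see [size_for_coverage()].
#' @return list of class `beta_pair`: `q`, `gamma`, `alpha`, `beta`,
#'   `CqN`, `UqN`, `dissimilarity` (the conventional index for that q),
#'   `dissimilarity_C`, `dissimilarity_U`, `flagged`.
#' @export
beta_pair <- function(xA, xB, q, C_target = NULL, seed = NULL, B = 200,
                      extrap_cap = 2) {
  check_q(q)
  if (!sum(xA) || !sum(xB)) stop_metadiv("both samples must be non-empty")
  sA <- standardized_profile(xA, C_target, seed = seed, B = B, extrap_cap = extrap_cap)
  sB <- standardized_profile(xB, C_target,
                             seed = if (is.null(seed)) NULL else seed + 1,
                             B = B, extrap_cap = extrap_cap)
  otus <- union(names(sA$p), names(sB$p))
  pA <- setNames(rep(0, length(otus)), otus); pA[names(sA$p)] <- sA$p
  pB <- setNames(rep(0, length(otus)), otus); pB[names(sB$p)] <- sB$p
  pool <- (pA + pB) / 2
  gamma <- hill_observed(pool, q)
  pj <- c(pA, pB) / 2
  pj <- pj[pj > 0]
  alpha <- if (q == 1) exp(-sum(pj * log(pj))) / 2
           else 0.5 * sum(pj^q)^(1 / (1 - q))
  beta <- min(max(gamma / alpha, 1), 2)
  CqN <- if (q == 1) 1 - log(beta) / log(2)
         else ((1 / beta)^(q - 1) - 0.5^(q - 1)) / (1 - 0.5^(q - 1))
  UqN <- if (q == 1) 1 - log(beta) / log(2)
         else ((1 / beta)^(1 - q) - 0.5^(1 - q)) / (1 - 0.5^(1 - q))
  diss <- switch(as.character(q),
                 "0" = 1 - UqN,       # Jaccard-type
                 "1" = log(beta) / log(2),  # Horn
                 "2" = 1 - CqN)       # Morisita-Horn
  structure(list(q = q, gamma = gamma, alpha = alpha, beta = beta,
                 CqN = CqN, UqN = UqN,
                 dissimilarity = diss,
                 dissimilarity_C = 1 - CqN, dissimilarity_U = 1 - UqN,
                 flagged = sA$flagged || sB$flagged),
            class = "beta_pair")
}

#' Pairwise community dissimilarity matrix
#'
#' Applies [beta_pair()] to every unordered pair of samples; deterministic
#' given the seed (each pair receives a seed derived from `seed` and the pair
#' index). Flagged pairs (coverage target unreachable) are set to `NA` with a
#' warning listing them.
#'
#' @param table community matrix (rows = samples, >= 2).
#' @param q Hill order.
#' @param C_target coverage target or `NULL`.
#' @param seed integer seed.
#' @param B,extrap_cap see [beta_pair()].
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
community_distance_matrix <- function(table, q, C_target = NULL, seed = NULL,
                                      B = 200, extrap_cap = 2) {
  table <- validate_otu_table(table)
  ids <- rownames(table)
  if (length(ids) < 2) stop_metadiv("need at least two samples")
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  flagged <- character(0)
  idx <- 0L
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      idx <- idx + 1L
      bp <- beta_pair(table[i, ], table[j, ], q, C_target = C_target,
                      seed = if (is.null(seed)) NULL else seed + 2L * idx,
                      B = B, extrap_cap = extrap_cap)
      if (bp$flagged) {
        D[i, j] <- D[j, i] <- NA_real_
        flagged <- c(flagged, paste(ids[i], ids[j], sep = ":"))
      } else {
        D[i, j] <- D[j, i] <- bp$dissimilarity
      }
    }
  }
  if (length(flagged)) {
    warning("pair(s) excluded (coverage target unreachable): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  D
}

#' Environmental distance matrices
#'
#' Euclidean distance on selected continuous variables (no implicit scaling;
#' `scale = TRUE` range-scales each column to `[0, 1]` first), or Gower
#' dissimilarity (via [cluster::daisy()]) mixing categorical 0/1 mismatches
#' with range-normalized absolute differences for continuous variables.
#'
#' @param env data.frame of per-sample variables, rownames = sample ids.
#' @param variables column names to use (default: all).
#' @param kind `"euclidean"` or `"gower"`.
#' @param scale range-scale continuous columns before Euclidean distance.
#' @return symmetric distance matrix.
#' @export
env_distance <- function(env, variables = NULL, kind = c("euclidean", "gower"),
                         scale = FALSE) {
  kind <- match.arg(kind)
  variables <- variables %||% colnames(env)
  missing_var <- setdiff(variables, colnames(env))
  if (length(missing_var)) stop_metadiv("unknown variable(s): ", paste(missing_var, collapse = ", "))
  sub <- env[, variables, drop = FALSE]
  bad <- rownames(sub)[!complete.cases(sub)]
  if (length(bad)) stop_metadiv("missing values for sample(s): ", paste(bad, collapse = ", "))
  if (kind == "euclidean") {
    num <- vapply(sub, is.numeric, logical(1))
    if (!all(num)) stop_metadiv("euclidean distance needs numeric variables; non-numeric: ",
                                paste(variables[!num], collapse = ", "))
    m <- as.matrix(sub)
    if (scale) {
      rng <- apply(m, 2, function(v) diff(range(v)))
      rng[rng == 0] <- 1
      m <- sweep(sweep(m, 2, apply(m, 2, min)), 2, rng, "/")
    }
    as.matrix(dist(m))
  } else {
    as.matrix(cluster::daisy(sub, metric = "gower"))
  }
}
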