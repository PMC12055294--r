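# Singleton-error correction.
#
# Sequencing errors inflate the number of OTUs seen with exactly one read.
# Because coverage and Hill estimation lean heavily on f1, the filter
# estimates the *true* number of singletons from the (assumed reliable)
# higher frequency counts and deletes the surplus singletons at random.

#' Default Good-Turing singleton estimator
#'
#' Estimates the expected true singleton count from doubletons and tripletons
#' via the Good-Turing frequency ratios: `f1_hat = 2 f2^2 / (3 f3)` when
#' `f3 > 0`, with the bias-corrected fallback `2 f2 (f2 - 1) / (3 (f3 + 1))`
#' when `f3 = 0`, and 0 when there are no doubletons. The estimator is a
#' plain function of `(f2, f3, f4)` so an alternative closed form can be
#' swapped in via the `estimator` argument of the calling functions.
#'
#' @param f2,f3,f4 doubleton, tripleton and quadrupleton counts.
#' @return estimated true singleton count (real, >= 0).
#' @export
good_turing_singletons <- function(f2, f3, f4 = 0) {
  if (f2 == 0) return(0)
  if (f3 > 0) 2 * f2^2 / (3 * f3) else 2 * f2 * (f2 - 1) / (3 * (f3 + 1))
}

#' Estimate the true number of singletons in a sample
#'
#' @param fc a [frequency_counts()] object (or a count vector).
#' @param estimator function of `(f2, f3, f4)` returning the estimate;
#'   defaults to [good_turing_singletons()].
#' @return estimated true singleton count `f1_hat` (>= 0).
#' @export
estimate_true_singletons <- function(fc, estimator = good_turing_singletons) {
  fc <- as_freq_counts(fc)
  max(0, estimator(f_r(fc, 2), f_r(fc, 3), f_r(fc, 4)))
}

#' Remove surplus (putatively erroneous) singletons from each sample
#'
#' For every sample the surplus is `max(0, f1_obs - round(f1_hat))` (rounding
#' half away from zero, then clamping to `[0, f1_obs]` -- with sparse data the
#' raw difference can be negative and must be adjusted). Exactly that many
#' OTUs with count 1 are set to 0, chosen uniformly at random among the
#' sample's singletons under the given seed. Counts >= 2 are never touched and
#' raw reads (not relative reads) enter the filter; all decisions are made
#' within each sample.
#'
#' @param table community matrix (rows = samples).
#' @param seed integer seed (required for reproducibility).
#' @param estimator singleton estimator, see [estimate_true_singletons()].
#' @param drop_empty drop OTUs whose column sum becomes 0 (with a message);
#'   set `FALSE` to keep the matrix dimensions fixed.
#' @return list of class `singleton_filter` with elements `table` (filtered
#'   matrix) and `corrections` (data.frame: sample_id, n, f1_obs, f2, f3, f4,
#'   f1_hat, surplus; attribute `"removed"` holds the removed OTU ids per
#'   sample).
#' @export
apply_singleton_filter <- function(table, seed, estimator = good_turing_singletons,
                                   drop_empty = TRUE) {
  table <- validate_otu_table(table)
  if (missing(seed) || is.null(seed)) stop_metadiv("a seed is required")
  out <- table
  removed <- vector("list", nrow(table))
  names(removed) <- rownames(table)
  rows <- vector("list", nrow(table))
  with_seed(seed, {
    for (i in seq_len(nrow(table))) {
      x <- table[i, ]
      fc <- frequency_counts(x)
      f1_obs <- f_r(fc, 1)
      f1_hat <- max(0, estimator(f_r(fc, 2), f_r(fc, 3), f_r(fc, 4)))
      surplus <- max(0, min(f1_obs, round_half_away(f1_obs - f1_hat)))
      if (surplus > 0) {
        singles <- names(x)[x == 1L]
        # sample() without the size-1 scalar pitfall
        kill <- singles[sample.int(length(singles), surplus)]
        out[i, kill] <- 0L
        removed[[i]] <- sort(kill)
      } else {
        removed[[i]] <- character(0)
      }
      rows[[i]] <- data.frame(sample_id = rownames(table)[i], n = fc$n,
                              f1_obs = f1_obs, f2 = f_r(fc, 2), f3 = f_r(fc, 3),
                              f4 = f_r(fc, 4), f1_hat = f1_hat, surplus = surplus,
                              stringsAsFactors = FALSE)
    }
  })
  corrections <- do.call(rbind, rows)
  attr(corrections, "removed") <- removed
  if (drop_empty) {
    gone <- colSums(out) == 0L & colSums(table) > 0L
    if (any(gone)) {
      message("dropping ", sum(gone), " OTU(s) zeroed in all samples: ",
              paste(head(colnames(out)[gone], 5L), collapse = ", "),
              if (sum(gone) > 5L) ", ...")
      out <- out[, !gone, drop = FALSE]
    }
  }
  structure(list(table = out, corrections = corrections, seed = seed),
            class = "singleton_filter")
}

#' @export
print.singleton_filter <- function(x, ...) {
  cat("Singleton filter (seed ", x$seed, "): removed ",
      sum(x$corrections$surplus), " surplus singleton cells over ",
      nrow(x$corrections), " sample(s)\n", sep = "")
  invisible(x)
}

#' Re-run the singleton filter under several seeds
#'
#' The random removal step introduces (usually minor) between-replicate
#' variation; running the filter under several seeds and carrying every
#' replicate through the downstream statistics quantifies it.
#'
#' @param table community matrix.
#' @param seeds integer vector of seeds (>= 1 seed).
#' @param ... passed to [apply_singleton_filter()].
#' @return list of `singleton_filter` results, one per seed.
#' @export
repeat_filter <- function(table, seeds, ...) {
  if (length(seeds) < 1) stop_metadiv("at least one seed required")
  lapply(seeds, function(s) apply_singleton_filter(table, seed = s, ...))
}

#' Dispersion of a statistic across filter replicates
#'
#' @param replicates list from [repeat_filter()].
#' @param statistic function mapping a filtered table to a numeric vector.
#' @return data.frame with the mean, sd and relative sd of each statistic
#'   component across replicates.
#' @export
replicate_dispersion <- function(replicates, statistic) {
  vals <- vapply(replicates, function(r) statistic(r$table), numeric(length(statistic(replicates[[1]]$table))))
  vals <- matrix(vals, ncol = length(replicates))
  m <- rowMeans(vals)
  s <- apply(vals, 1, sd)
  data.frame(mean = m, sd = s, rel_sd = ifelse(m > 0, s / m, 0))
}
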