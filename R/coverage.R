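# Turing sample-coverage estimation and the coverage--sample-size curve.
#
# Coverage is the proportion of the total community abundance that belongs to
# the species detected in the sample. Turing's insight: it can be estimated
# from the sample itself via the singleton and doubleton counts, which is what
# makes coverage standardization possible for metabarcoding read data.

# Good-Turing adjustment fraction A, shared by the coverage extrapolation and
# the asymptotic Shannon estimator.
good_turing_A <- function(fc) {
  fc <- as_freq_counts(fc)
  n <- fc$n
  f1 <- f_r(fc, 1); f2 <- f_r(fc, 2)
  if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
  else if (f1 > 0) 2 / ((n - 1) * (f1 - 1) + 2)
  else 1
}

#' Estimated sample coverage at the observed size
#'
#' The Turing/Good estimator with the standard small-sample modification:
#' `C_hat = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`. No singletons means
#' complete coverage (1); an all-singleton sample has estimated coverage 0.
#'
#' @param fc [frequency_counts()] object or count vector.
#' @return coverage estimate in `[0, 1]`.
#' @examples
#' estimate_coverage(c(5, 3, 1, 1))  # 0.8
#' @export
estimate_coverage <- function(fc) {
  fc <- as_freq_counts(fc)
  if (fc$n == 0) stop_metadiv("coverage undefined for an empty sample")
  n <- fc$n
  f1 <- f_r(fc, 1); f2 <- f_r(fc, 2)
  if (f1 == 0) return(1)
  if (n == 1) return(0)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}

#' Expected sample coverage at an arbitrary sample size
#'
#' Rarefaction side (`m < n`): the hypergeometric expectation
#' `C_hat(m) = 1 - sum_i (x_i/n) * C(n - x_i, m) / C(n - 1, m)`, computed with
#' log-gamma binomial-coefficient ratios so it is overflow-free and defined
#' for real-valued `m` (needed by the coverage-target root finder).
#' `m = n` reduces exactly to [estimate_coverage()]; the extrapolation side
#' uses `C_hat(n + m*) = 1 - (f1/n) (1 - A)^(m* + 1)` with the Good-Turing
#' fraction `A`.
#'
#' @param fc [frequency_counts()] object or count vector.
#' @param m reference sample size in reads (real, >= 1).
#' @return coverage estimate; attribute `"side"` is one of `"interpolated"`,
#'   `"observed"`, `"extrapolated"`.
#' @export
coverage_at_size <- function(fc, m) {
  fc <- as_freq_counts(fc)
  if (fc$n == 0) stop_metadiv("coverage undefined for an empty sample")
  if (m < 1) stop_metadiv("m must be >= 1")
  n <- fc$n
  if (m < n) {
    x <- counts_from_freq(fc)
    lr <- log_choose_ratio(n - x, m, n - 1)
    val <- 1 - sum((x / n) * exp(lr))
    side <- "interpolated"
  } else if (m == n) {
    val <- estimate_coverage(fc)
    side <- "observed"
  } else {
    f1 <- f_r(fc, 1)
    A <- good_turing_A(fc)
    val <- 1 - (f1 / n) * (1 - A)^(m - n + 1)
    side <- "extrapolated"
  }
  structure(min(max(val, 0), 1), side = side)
}

#' Sample size matching a target coverage
#'
#' Inverts the (monotone) coverage--size curve: bisection/Brent on the
#' rarefaction side, closed form on the extrapolation side. Extrapolation is
#' capped at `extrap_cap * n` reads (coverage targets far above the observed
#' coverage would otherwise rest almost entirely on extrapolation); hitting
#' the cap issues a warning and returns the cap.
#'
#' @param fc [frequency_counts()] object or count vector.
#' @param C_target target coverage in (0, 1).
#' @param extrap_cap multiplier of `n` bounding the extrapolation size
#'   (default 2).
#' @return real-valued size `m >= 1`; attributes: `"side"`,
#'   `"achieved_coverage"`, `"m_integer"` (rounded size).
#' @export
size_for_coverage <- function(fc, C_target, extrap_cap = 2) {
  fc <- as_freq_counts(fc)
  if (fc$n == 0) stop_metadiv("coverage undefined for an empty sample")
  if (!(C_target > 0 && C_target < 1)) stop_metadiv("C_target must lie in (0, 1)")
  n <- fc$n
  C_obs <- estimate_coverage(fc)
  finish <- function(m, side) {
    structure(m, side = side,
              achieved_coverage = as.numeric(coverage_at_size(fc, m)),
              m_integer = max(1L, as.integer(round(m))))
  }
  if (n > 1 && C_target <= as.numeric(coverage_at_size(fc, 1))) {
    warning("target coverage below the coverage of a single read; returning m = 1",
            call. = FALSE)
    return(finish(1, "interpolated"))
  }
  if (abs(C_target - C_obs) < 1e-12) return(finish(n, "observed"))
  if (C_target < C_obs) {
    if (n == 1) return(finish(1, "observed"))
    g <- function(m) as.numeric(coverage_at_size(fc, m)) - C_target
    if (g(1) >= 0) return(finish(1, "interpolated"))
    root <- stats::uniroot(g, interval = c(1, n), tol = 1e-12, maxiter = 1000)
    return(finish(root$root, "interpolated"))
  }
  # extrapolation: invert 1 - (f1/n) (1-A)^(m*+1) = C_target
  f1 <- f_r(fc, 1)
  A <- good_turing_A(fc)
  cap <- extrap_cap * n
  if (f1 == 0 || A >= 1) {
    warning("observed coverage is already 1; returning m = n", call. = FALSE)
    return(finish(n, "observed"))
  }
  mstar <- log(n * (1 - C_target) / f1) / log(1 - A) - 1
  m <- n + max(0, mstar)
  if (m > cap) {
    warning(sprintf("coverage target %.4f unreachable under the extrapolation cap (m <= %.0f); returning the cap",
                    C_target, cap), call. = FALSE)
    m <- cap
  }
  finish(m, "extrapolated")
}

#' True coverage and classical completeness of a detected species set
#'
#' Given the (known) relative abundances of a whole community and the index
#' set of detected species, coverage is the summed true abundance of the
#' detected species while classical completeness is the detected fraction of
#' the species count. The two can diverge wildly when many vanishingly rare
#' species exist: detecting only a few dominant species can already give very
#' high coverage at very low completeness.
#'
#' @param true_props numeric vector of community relative abundances
#'   (must sum to 1 within 1e-9).
#' @param detected integer or logical index of detected species.
#' @return a proportion in `[0, 1]`.
#' @examples
#' p <- c(0.50, 0.30, 0.15, rep(0.0005, 100))
#' true_coverage_of_detected(p, 1:3)   # 0.95
#' completeness_of_detected(p, 1:3)    # 3/103
#' @export
true_coverage_of_detected <- function(true_props, detected) {
  if (abs(sum(true_props) - 1) > 1e-9) stop_metadiv("proportions must sum to 1")
  sum(true_props[detected])
}

#' @rdname true_coverage_of_detected
#' @export
completeness_of_detected <- function(true_props, detected) {
  if (abs(sum(true_props) - 1) > 1e-9) stop_metadiv("proportions must sum to 1")
  if (is.logical(detected)) sum(detected) / length(true_props)
  else length(unique(detected)) / length(true_props)
}

#' Coverage summary table for a community matrix
#'
#' @param table community matrix (rows = samples).
#' @return data.frame: sample_id, n, S_obs, f1, f2, C_hat.
#' @export
coverage_table <- function(table) {
  table <- validate_otu_table(table)
  rows <- lapply(rownames(table), function(s) {
    fc <- frequency_counts(table, s)
    if (fc$n == 0) {
      return(data.frame(sample_id = s, n = 0L, S_obs = 0L, f1 = 0L, f2 = 0L,
                        C_hat = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(sample_id = s, n = fc$n, S_obs = fc$S_obs,
               f1 = f_r(fc, 1), f2 = f_r(fc, 2),
               C_hat = estimate_coverage(fc), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
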