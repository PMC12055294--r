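# Multiple regression on distance matrices (MRM).
#
# OLS of the unfolded strict lower triangle of a response distance matrix on
# those of one or more predictor matrices; inference by simultaneous
# row/column permutation of the response matrix (predictors fixed), the
# standard Mantel-style scheme. Dyads are not independent, hence the
# permutation null rather than parametric tests.

lower_vec <- function(M) M[lower.tri(M)]

#' Multiple regression on distance matrices
#'
#' @param response symmetric distance matrix (the community dissimilarities).
#' @param predictors named list of symmetric predictor matrices sharing the
#'   response's sample ids.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return object of class `mrm`: `coefficients` (intercept + one per
#'   predictor), `r.squared`, `p.values` (two-sided on |coefficient|;
#'   observed permutation included), `p.r.squared`, `n_perm`, `seed`, `n`
#'   (number of samples).
#' @examples
#' ids <- paste0("s", 1:6)
#' X <- as.matrix(dist(setNames(1:6, ids)))
#' fit <- mrm(2 * X, list(x = X), n_perm = 99, seed = 1)
#' fit$coefficients[["x"]]  # 2
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop_metadiv("n_perm must be >= 99")
  response <- as.matrix(response)
  ids <- rownames(response)
  if (is.null(ids)) stop_metadiv("response matrix must carry sample ids")
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("X", seq_along(predictors))
  }
  predictors <- lapply(predictors, function(P) {
    P <- as.matrix(P)
    if (is.null(rownames(P)) || !setequal(rownames(P), ids)) {
      stop_metadiv("predictor ids do not match the response ids")
    }
    P[ids, ids]
  })
  if (anyNA(response) || any(vapply(predictors, anyNA, logical(1)))) {
    stop_metadiv("distance matrices must not contain NA")
  }
  y <- lower_vec(response)
  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, lapply(predictors, lower_vec)))
  colnames(X) <- c("(Intercept)", names(predictors))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_metadiv("rank-deficient design; collinear predictor(s): ",
                 paste(dropped, collapse = ", "))
  }
  H <- solve(crossprod(X), t(X))   # (X'X)^-1 X'
  coef_obs <- drop(H %*% y)
  fit <- drop(X %*% coef_obs)
  ss_tot <- sum((y - mean(y))^2)
  r2_obs <- 1 - sum((y - fit)^2) / ss_tot

  n <- length(ids)
  perms <- with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  Yp <- vapply(perms, function(p) lower_vec(response[p, p]), numeric(length(y)))
  Yp <- cbind(y, Yp)               # observed arrangement included => n_perm + 1
  Coefs <- H %*% Yp
  Fits <- X %*% Coefs
  r2 <- 1 - colSums((Yp - Fits)^2) / apply(Yp, 2, function(v) sum((v - mean(v))^2))
  p_coef <- rowMeans(abs(Coefs) >= abs(coef_obs) - 1e-12)
  p_r2 <- mean(r2 >= r2_obs - 1e-12)
  structure(list(coefficients = setNames(coef_obs, colnames(X)),
                 r.squared = r2_obs,
                 p.values = setNames(p_coef, colnames(X)),
                 p.r.squared = p_r2,
                 n_perm = n_perm, seed = seed, n = n),
            class = "mrm")
}

#' @export
print.mrm <- function(x, ...) {
  cat("MRM over", x$n, "samples,", x$n_perm, "permutations\n")
  tab <- data.frame(coefficient = x$coefficients, p = x$p.values)
  print(tab, digits = 4)
  cat(sprintf("R-squared = %.4f (p = %.4g)\n", x$r.squared, x$p.r.squared))
  invisible(x)
}
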