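# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL leaves the RNG untouched (caller manages reproducibility).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# round half away from zero (symmetric, unlike round()'s banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# log of C(top, m) / C(bottom, m) for real-valued m >= 0, integer top <= bottom.
# Defined as -Inf (ratio 0) when m > top. Computed via lgamma so that large n
# never overflows and real m is permitted for root-finding.
log_choose_ratio <- function(top, m, bottom) {
  out <- rep(-Inf, length(top))
  ok <- (top - m) > -1 + 1e-12
  if (any(ok)) {
    t0 <- top[ok]
    out[ok] <- lgamma(t0 + 1) - lgamma(t0 - m + 1) -
      lgamma(bottom + 1) + lgamma(bottom - m + 1)
  }
  out
}

stop_metadiv <- function(...) stop(..., call. = FALSE)

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
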