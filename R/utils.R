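# Internal helpers shared across modules.

#' Derive a child RNG seed from a session seed
#'
#' All randomness in a session flows from one base seed. Independent streams
#' (schedule, each eye trace, each cell) use `split_seed(seed, k)` with a
#' documented stream index `k`: the child seed is
#' `(seed * 48271 + k * 8191) mod (2^31 - 1)`, mapped into `[1, 2^31 - 2]`.
#' The multipliers are the classical MINSTD constants; the rule is a fixed
#' convention, not a cryptographic guarantee.
#'
#' @param seed integer base seed.
#' @param k non-negative integer stream index.
#' @return an integer seed suitable for [set.seed()].
#' @export
split_seed <- function(seed, k) {
  m <- 2147483647
  v <- (as.double(seed) %% m) * 48271 + (as.double(k) %% m) * 8191
  as.integer((v %% (m - 1)) + 1)
}

# Count spikes in half-open windows [a, b). `spikes` must be sorted.
count_in_window <- function(spikes, a, b) {
  if (length(spikes) == 0L) return(numeric(length(a)))
  findInterval(b - 1e-12, spikes) - findInterval(a - 1e-12, spikes)
}

# Spikes falling in [a, b), re-expressed relative to `a0` (default: absolute).
spikes_in_window <- function(spikes, a, b, origin = NULL) {
  s <- spikes[spikes >= a & spikes < b]
  if (!is.null(origin)) s <- s - origin
  s
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Draw from a normal truncated below at `lo` by inverse-CDF sampling.
rtruncnorm_lower <- function(n, mean, sd, lo) {
  p_lo <- pnorm(lo, mean, sd)
  u <- runif(n, p_lo, 1)
  qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

# Analytic mean of a normal truncated below at `lo` (used to document the
# reaction-time floor bias).
truncnorm_lower_mean <- function(mean, sd, lo) {
  a <- (lo - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}
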