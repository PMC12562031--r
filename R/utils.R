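# Internal numerical helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used wherever a real-valued abundance
#' estimate must be converted to an integer binomial denominator. Base R's
#' `round()` rounds half to even, which would make 0.5-boundary denominators
#' depend on parity.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# log(sum(exp(x))) without overflow; x a numeric vector with at least one
# finite element.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_log_sum_exp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

# Deterministic 31-bit polynomial hash of a string; used to derive stable
# per-transect RNG substreams so that adding transects to a configuration
# does not perturb the draws of existing ones.
stable_hash <- function(s) {
  h <- 0
  for (x in utf8ToInt(s)) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

# Substream seed derived from a base seed and a string tag.
substream_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) + stable_hash(tag)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Aggregate a vector by an integer group index 1..S, returning a length-S
# vector (rowsum() returns groups in sorted label order, which for a
# complete 1..S index is exactly positional order).
group_sum <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}
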