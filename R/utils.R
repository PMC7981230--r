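# Internal numerical helpers shared across modules.
#
# The null-model engine evaluates grouped variances hundreds of thousands of
# times, so the grouped moment computations below stay in base R (rowsum on a
# pre-built factor) rather than going through a grouped tibble pipeline.

# Per-group n, mean and sample variance (n-1 divisor) of x by grouping factor g.
# NAs in x are dropped first (pairwise-complete convention). Groups with a
# single observation get var = NA, never 0.
group_moments <- function(x, g) {
  keep <- !is.na(x)
  x <- x[keep]
  f <- droplevels(factor(g[keep]))
  n <- tabulate(f, nbins = nlevels(f))
  s <- rowsum(x, f)[, 1L]          # rows ordered by levels(f)
  ss <- rowsum(x * x, f)[, 1L]
  m <- s / n
  v <- (ss - s * s / n) / (n - 1)
  v[n < 2] <- NA_real_
  # guard tiny negatives from floating-point cancellation
  v <- ifelse(!is.na(v) & v < 0 & v > -1e-12, 0, v)
  list(group = levels(f), n = n, mean = unname(m), var = unname(v))
}

# Sample variance that returns NA (not an error) for n < 2.
var_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::var(x)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stream index,
# so each (trait, scheme) pair gets its own RNG stream independent of
# evaluation order.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

# Run expr with a locally-set RNG seed (restores the caller's RNG state).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Trapezoidal integral of y over x (x strictly increasing, equal length).
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}
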