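# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain loops, stats::var, exhaustive enumeration.

# Brute-force nested variance components for one trait of a plain data frame
# (columns community, species, <trait>), sample-variance convention.
brute_components <- function(df, trait) {
  x <- df[[trait]]
  ok <- !is.na(x)
  df <- df[ok, ]
  x <- x[ok]
  pops <- unique(df[c("community", "species")])
  pop_means <- mapply(function(k, s) {
    mean(x[df$community == k & df$species == s])
  }, pops$community, pops$species)
  out <- list()
  for (k in unique(df$community)) {
    xk <- x[df$community == k]
    spk <- df$species[df$community == k]
    sp_vars <- c()
    sp_means <- c()
    for (s in unique(spk)) {
      xs <- xk[spk == s]
      sp_means <- c(sp_means, mean(xs))
      if (length(xs) >= 2) sp_vars <- c(sp_vars, stats::var(xs))
    }
    out[[k]] <- list(
      sigma2_IP = if (length(sp_vars) > 0) mean(sp_vars) else NA_real_,
      sigma2_IC = if (length(xk) >= 2) stats::var(xk) else NA_real_,
      sigma2_PC = if (length(sp_means) >= 2) stats::var(sp_means) else NA_real_,
      sigma2_IR = stats::var(x),
      sigma2_PR = if (length(pop_means) >= 2) stats::var(pop_means) else NA_real_
    )
  }
  out
}

# Random small trait table for property tests.
random_table <- function(n_communities = 3, n_species = 4, n_per_pop = 4,
                         seed = 1) {
  set.seed(seed)
  rows <- expand.grid(
    community = paste0("c", seq_len(n_communities)),
    species = paste0("s", seq_len(n_species)),
    rep = seq_len(n_per_pop),
    stringsAsFactors = FALSE
  )
  # drop some populations entirely and vary population sizes
  keep <- runif(nrow(rows)) > 0.2
  rows <- rows[keep, ]
  rows$mass <- exp(rnorm(nrow(rows), 0, 0.5))
  trait_table(rows[c("community", "species", "mass")])
}

# Exact expected rarefied richness at m individuals by exhaustive enumeration
# of all subsets (tiny n only).
enumerate_rarefaction <- function(species, m) {
  n <- length(species)
  subsets <- utils::combn(n, m)
  mean(apply(subsets, 2, function(idx) length(unique(species[idx]))))
}
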