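#' Null-model randomization schemes
#'
#' Each T-statistic ratio is tested against the randomization that breaks
#' exactly the association it measures, leaving everything else fixed:
#'
#' * `"shuffle_within_community"` — within each community independently,
#'   permute species labels across the community's individuals. Breaks the
#'   species–trait association while conserving each community's trait
#'   multiset and its per-species abundances. Null for `T_IP_IC`.
#' * `"draw_from_regional_individuals"` — reassign individuals to communities
#'   by permuting community labels over the pooled regional individuals
#'   (sampling without replacement within an iteration). Breaks the
#'   community–trait association while conserving community sizes and the
#'   regional trait multiset. Null for `T_IC_IR`.
#' * `"draw_from_regional_population_means"` — permute community labels over
#'   the regional pool of population (species-by-community) mean trait
#'   values, conserving each community's number of populations. Null for
#'   `T_PC_PR`.
#'
#' A fourth scheme, `"draw_from_regional_populations"`, is a variant of the
#' individual-level regional null that conserves each community's species
#' richness instead of its exact size: whole populations (a species'
#' individuals within a community) are reassigned to communities, conserving
#' per-community population counts. Because the default individual-level
#' null lets randomized communities mix individuals of many more species
#' than a real community holds, species-poor communities sit slightly below
#' its null mean even without filtering; the population-level variant
#' removes that richness effect at the cost of letting community sizes
#' fluctuate. Select it in [tstat_ses()] via `regional_null =
#' "populations"`.
#'
#' @name null_schemes
#' @return `null_schemes()` returns the scheme names with the metric each one
#'   tests, as a tibble.
#' @export
null_schemes <- function() {
  tibble::tibble(
    scheme = c("shuffle_within_community",
               "draw_from_regional_individuals",
               "draw_from_regional_population_means"),
    metric = c("T_IP_IC", "T_IC_IR", "T_PC_PR")
  )
}

scheme_for_metric <- function(metric, regional_null = "individuals") {
  s <- null_schemes()
  out <- s$scheme[match(metric, s$metric)]
  if (metric == "T_IC_IR" && regional_null == "populations") {
    out <- "draw_from_regional_populations"
  }
  out
}

#' Draw one randomized trait table under a null scheme
#'
#' Produces a single randomized copy of `table` under one of the
#' [null_schemes()]. For `"draw_from_regional_population_means"` the returned
#' table has one row per population carrying that population's mean trait
#' values (individual identity is not meaningful at that scale).
#'
#' @param table A `trait_tbl`.
#' @param scheme One of the scheme names of [null_schemes()].
#' @param seed Optional integer seed.
#' @return A `trait_tbl` of the same dimensions (or one row per population
#'   for the population-mean scheme).
#' @export
randomize_table <- function(table,
                            scheme = c(null_schemes()$scheme,
                                       "draw_from_regional_populations"),
                            seed = NULL) {
  scheme <- match.arg(scheme)
  traits <- trait_names(table)
  df <- as.data.frame(table)
  with_seed(seed, {
    out <- switch(
      scheme,
      shuffle_within_community = {
        blocks <- split(seq_len(nrow(df)), df$community)
        pos <- unlist(blocks, use.names = FALSE)
        idx <- unlist(lapply(blocks, function(b) b[sample.int(length(b))]),
                      use.names = FALSE)
        new <- df
        new$species[pos] <- df$species[idx]
        new
      },
      draw_from_regional_individuals = {
        new <- df
        new$community <- df$community[sample.int(nrow(df))]
        new
      },
      draw_from_regional_populations = {
        pop <- paste(df$community, df$species, sep = "\r")
        upop <- unique(pop)
        pcomm <- df$community[match(upop, pop)]
        new_comm <- pcomm[sample.int(length(pcomm))]
        new <- df
        new$community <- new_comm[match(pop, upop)]
        new
      },
      draw_from_regional_population_means = {
        pops <- dplyr::summarise(
          dplyr::group_by(tibble::as_tibble(df), .data$community, .data$species),
          dplyr::across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
          .groups = "drop")
        pops$community <- pops$community[sample.int(nrow(pops))]
        pops$individual <- paste0("pop_", seq_len(nrow(pops)))
        as.data.frame(pops)
      }
    )
    as_trait_tbl(out, traits)
  })
}

# Fast per-community null metric draws for one trait and one scheme.
# Returns a matrix: rows = iterations, cols = communities (sorted labels).
null_metric_draws <- function(x, comm, sp, scheme, n_iter, seed) {
  communities <- sort(unique(comm))
  out <- matrix(NA_real_, n_iter, length(communities),
                dimnames = list(NULL, communities))
  with_seed(seed, {
    if (scheme == "shuffle_within_community") {
      blocks <- split(seq_along(x), comm)
      ic <- vapply(communities, function(k) var_or_na(x[comm == k]),
                   numeric(1))
      for (it in seq_len(n_iter)) {
        sp_new <- sp
        for (b in blocks) sp_new[b] <- sp[b][sample.int(length(b))]
        gm <- group_moments(x, paste(comm, sp_new, sep = "\r"))
        gcomm <- sub("\r.*$", "", gm$group)
        ip <- tapply(gm$var, gcomm, function(v) {
          v <- v[!is.na(v)]
          if (length(v) > 0) mean(v) else NA_real_
        })
        out[it, names(ip)] <- unlist(ip) / ic[names(ip)]
      }
    } else if (scheme == "draw_from_regional_individuals") {
      ir <- var_or_na(x)
      for (it in seq_len(n_iter)) {
        gm <- group_moments(x, comm[sample.int(length(comm))])
        out[it, gm$group] <- gm$var / ir
      }
    } else if (scheme == "draw_from_regional_populations") {
      ir <- var_or_na(x)
      pop <- paste(comm, sp, sep = "\r")
      upop <- unique(pop)
      pidx <- match(pop, upop)
      pcomm <- comm[match(upop, pop)]
      for (it in seq_len(n_iter)) {
        new_comm <- pcomm[sample.int(length(pcomm))]
        gm <- group_moments(x, new_comm[pidx])
        out[it, gm$group] <- gm$var / ir
      }
    } else if (scheme == "draw_from_regional_population_means") {
      pop <- paste(comm, sp, sep = "\r")
      pm <- group_moments(x, pop)
      means <- pm$mean
      pcomm <- sub("\r.*$", "", pm$group)
      pr <- var_or_na(means)
      for (it in seq_len(n_iter)) {
        gm <- group_moments(means, pcomm[sample.int(length(pcomm))])
        out[it, gm$group] <- gm$var / pr
      }
    } else stop("unknown scheme: ", scheme, call. = FALSE)
  })
  out
}

#' Standardized effect sizes of T-statistics against permutation nulls
#'
#' For every community × trait × metric, computes the observed T-statistic,
#' its null distribution under the matching randomization scheme (see
#' [null_schemes()]), the standardized effect size
#' \deqn{SES = (I_{obs} - \bar I_{null}) / \sigma_{null},}
#' and a two-sided 95% significance envelope (2.5% and 97.5% quantiles of the
#' null metric distribution). An observation outside its envelope is flagged
#' significant. Iterations on which a metric is undefined (e.g. no species
#' with two individuals after shuffling) are dropped and counted in
#' `n_dropped`. A null distribution with zero spread yields `ses = NA` with
#' everything else reported.
#'
#' One RNG stream per (trait, scheme) pair is derived arithmetically from
#' `seed`, so results do not depend on which traits or metrics are requested
#' together.
#'
#' @param table A `trait_tbl`, normally log-transformed.
#' @param traits Traits to test (default: all).
#' @param metrics Metrics to test (default: all three ratios).
#' @param n_iter Number of null iterations (default 999).
#' @param seed Integer master seed.
#' @param envelope Two-sided envelope coverage (default 0.95).
#' @param regional_null `"individuals"` (default: conserve community sizes)
#'   or `"populations"` (conserve community species richness) for the
#'   `T_IC_IR` null; see [null_schemes()].
#' @return A tibble of class `tstat_ses` with columns `community`, `trait`,
#'   `metric`, `observed`, `null_mean`, `null_sd`, `ses`, `envelope_lo`,
#'   `envelope_hi`, `significant`, `n_iter`, `n_dropped`.
#' @export
tstat_ses <- function(table, traits = NULL,
                      metrics = c("T_IP_IC", "T_IC_IR", "T_PC_PR"),
                      n_iter = 999, seed = 1, envelope = 0.95,
                      regional_null = c("individuals", "populations")) {
  if (is.null(traits)) traits <- trait_names(table)
  metrics <- match.arg(metrics, several.ok = TRUE)
  regional_null <- match.arg(regional_null)
  stopifnot(n_iter >= 1)
  obs <- t_statistics(table, traits = traits, warn_untransformed = FALSE)
  df <- as.data.frame(table)
  alpha <- (1 - envelope) / 2

  grid <- tidyr::expand_grid(trait = traits, metric = metrics)
  res <- purrr::pmap_dfr(grid, function(trait, metric) {
    scheme <- scheme_for_metric(metric, regional_null)
    stream <- match(trait, traits) * 8L +
      match(metric, c("T_IP_IC", "T_IC_IR", "T_PC_PR"))
    x <- df[[trait]]
    ok <- !is.na(x)
    draws <- null_metric_draws(x[ok], df$community[ok], df$species[ok],
                               scheme, n_iter, derive_seed(seed, stream))
    purrr::map_dfr(colnames(draws), function(k) {
      null_k <- draws[, k]
      dropped <- sum(is.na(null_k))
      null_k <- null_k[!is.na(null_k)]
      o <- obs[[metric]][obs$community == k & obs$trait == trait]
      nm <- if (length(null_k) > 0) mean(null_k) else NA_real_
      ns <- if (length(null_k) > 1) sd(null_k) else NA_real_
      lo <- if (length(null_k) > 0) unname(quantile(null_k, alpha)) else NA_real_
      hi <- if (length(null_k) > 0) unname(quantile(null_k, 1 - alpha)) else NA_real_
      tibble::tibble(
        community = k, trait = trait, metric = metric,
        observed = o, null_mean = nm, null_sd = ns,
        ses = if (!is.na(ns) && ns > 0) (o - nm) / ns else NA_real_,
        envelope_lo = lo, envelope_hi = hi,
        significant = !is.na(o) & !is.na(lo) & (o < lo | o > hi),
        n_iter = n_iter, n_dropped = dropped
      )
    })
  })
  class(res) <- c("tstat_ses", class(res))
  res
}
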