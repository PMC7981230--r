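#' Define an individual-based community-assembly scenario
#'
#' Generative model for synthetic trait tables with known filter strength,
#' emulating an elevational study design: 13 communities spaced about 200 m
#' apart along a 200–2770 m gradient, a regional pool of 80 species, about
#' 250 individuals per community (roughly 3,300 in all), and three positive
#' traits (log-normal: body mass, wing loading, wing aspect ratio).
#'
#' Assembly proceeds per community: (1) regional species log-mean traits are
#' drawn from a normal distribution per trait; (2) each community's trait
#' optimum shifts linearly with elevation around the regional mean;
#' (3) `n_species_per_community` species are admitted by weighted sampling
#' without replacement, with Gaussian external-filter weights
#' \eqn{\exp(-(\mu_s - opt_k)^2 / (2 w_{ext}^2))} (so `w_ext = Inf` gives
#' uniform random subsets of the pool); (4) admitted species are greedily
#' thinned so consecutive sorted means (first trait) differ by at least
#' `limiting_similarity_gap` — a deterministic limiting-similarity
#' (internal) filter; (5) abundances follow a log-series scaled to the
#' community size target; (6) individuals are drawn log-normally around
#' their species mean with SD `within_sd`.
#'
#' The default trait parameters place the within- and between-species
#' variance structure in the regime reported for Himalayan hawkmoth
#' communities: regional individual-level log-trait variances near
#' 3.7e-2, 1.0e-2 and 0.21e-2 and within:community variance ratios near
#' 0.22, 0.56 and 0.54 for body mass, wing loading and aspect ratio
#' respectively (within-species SD 47–75% of the community SD).
#'
#' @param n_communities Number of communities.
#' @param elevations Strictly increasing elevations (m), one per community.
#' @param n_species Regional species-pool size.
#' @param trait_means Named numeric: regional log-scale mean per trait.
#' @param between_sd Between-species SD of log species means, per trait
#'   (recycled if scalar).
#' @param within_sd Within-species SD on the log scale, per trait (recycled
#'   if scalar) — the intraspecific-variability knob.
#' @param optimum_slope Shift of the community trait optimum (log units per
#'   meter of elevation), per trait; drives directional external filtering.
#' @param w_ext External-filter width on the log-trait scale, per trait;
#'   `Inf` disables the filter in that trait. Default: 3 standard deviations
#'   of the between-species spread (a weak filter).
#' @param limiting_similarity_gap Minimum spacing of admitted species means
#'   on the first trait (log units); 0 disables the internal thinning
#'   filter.
#' @param n_species_per_community Species admitted per community before
#'   thinning.
#' @param individuals_per_community Target community size.
#' @param abundance Abundance model: `"logseries"` (uneven, the classic
#'   insect light-trap form) or `"uniform"` (equal expected abundances, the
#'   oracle-friendly switch).
#' @param logseries_p Log-series abundance parameter in (0, 1); larger
#'   values give more uneven abundances.
#' @param missing_frac Fraction of trait cells deleted at random (exercises
#'   imputation); 0 disables.
#' @param seed Default seed used by [simulate_communities()].
#' @return A validated list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_communities = 13,
                         elevations = seq(200, 2770,
                                          length.out = n_communities),
                         n_species = 80,
                         trait_means = c(body_mass = log(2),
                                         wing_loading = log(6e-3),
                                         aspect_ratio = log(3.5)),
                         between_sd = c(0.1835, 0.0743, 0.0313),
                         within_sd = c(0.0802, 0.0674, 0.0313),
                         optimum_slope = c(7e-4, -4e-4, 2e-4),
                         w_ext = 3 * between_sd,
                         limiting_similarity_gap = 0,
                         n_species_per_community = 25,
                         individuals_per_community = 254,
                         abundance = c("logseries", "uniform"),
                         logseries_p = 0.98,
                         missing_frac = 0,
                         seed = 1) {
  n_traits <- length(trait_means)
  stopifnot(n_traits >= 1, !is.null(names(trait_means)))
  rec <- function(v) {
    if (length(v) == 1) v <- rep(v, n_traits)
    stopifnot(length(v) == n_traits)
    v
  }
  between_sd <- rec(between_sd)
  within_sd <- rec(within_sd)
  optimum_slope <- rec(optimum_slope)
  w_ext <- rec(w_ext)
  abundance <- match.arg(abundance)
  stopifnot(
    length(elevations) == n_communities,
    all(diff(elevations) > 0), all(elevations > 0),
    all(between_sd > 0), all(within_sd > 0), all(w_ext > 0),
    limiting_similarity_gap >= 0,
    n_species_per_community >= 1,
    individuals_per_community >= 2,
    logseries_p > 0, logseries_p < 1,
    missing_frac >= 0, missing_frac < 1
  )
  structure(list(
    n_communities = n_communities, elevations = elevations,
    n_species = n_species, trait_means = trait_means,
    between_sd = between_sd, within_sd = within_sd,
    optimum_slope = optimum_slope, w_ext = w_ext,
    limiting_similarity_gap = limiting_similarity_gap,
    n_species_per_community = n_species_per_community,
    individuals_per_community = individuals_per_community,
    abundance = abundance,
    logseries_p = logseries_p, missing_frac = missing_frac,
    seed = seed
  ), class = "sim_scenario")
}

# Log-series abundance sampler: P(k) proportional to p^k / k, k >= 1.
rlogseries <- function(n, p, kmax = 10000L) {
  k <- seq_len(kmax)
  pmf <- p^k / k
  sample(k, n, replace = TRUE, prob = pmf)
}

#' Simulate a trait table from an assembly scenario
#'
#' Runs the generative model of [sim_scenario()] and returns both the
#' emitted individual-level [trait_table()] (raw, exponentiated scale) and
#' the generating truth (species log-means, per-community pools and
#' abundances) for parameter-recovery checks. Byte-identical output under a
#' fixed seed.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Seed (defaults to the scenario's).
#' @return List with elements `table` (a `trait_tbl`) and `truth` (list:
#'   `scenario`, `species_means`, `communities`).
#' @export
simulate_communities <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  traits <- names(sc$trait_means)
  with_seed(seed, {
    mu <- sapply(seq_along(traits), function(t) {
      stats::rnorm(sc$n_species, sc$trait_means[t], sc$between_sd[t])
    })
    dimnames(mu) <- list(sprintf("sp%02d", seq_len(sc$n_species)), traits)
    mid <- mean(range(sc$elevations))

    per_comm <- purrr::map(seq_len(sc$n_communities), function(k) {
      elev <- sc$elevations[k]
      comm_id <- sprintf("E%04d", round(elev))
      opt <- sc$trait_means + sc$optimum_slope * (elev - mid)
      dist2 <- sweep(mu, 2, opt)^2
      expo <- dist2 %*% (1 / (2 * sc$w_ext^2))
      expo[is.na(expo)] <- 0  # w_ext = Inf contributes nothing
      w <- exp(-expo[, 1])
      if (all(w == 0)) {
        stop("external filter leaves no admissible species in community ",
             comm_id, " (w_ext too small?)", call. = FALSE)
      }
      n_pick <- min(sc$n_species_per_community, sum(w > 0))
      admitted <- sample.int(sc$n_species, n_pick, prob = w)
      # limiting-similarity thinning on the first trait
      if (sc$limiting_similarity_gap > 0) {
        ord <- admitted[order(mu[admitted, 1])]
        kept <- ord[1]
        last <- mu[ord[1], 1]
        for (s in ord[-1]) {
          if (mu[s, 1] - last >= sc$limiting_similarity_gap) {
            kept <- c(kept, s)
            last <- mu[s, 1]
          }
        }
        admitted <- kept
      }
      if (length(admitted) == 0) {
        stop("filters leave community ", comm_id, " empty", call. = FALSE)
      }
      counts <- if (sc$abundance == "uniform") rep(1, length(admitted)) else
        rlogseries(length(admitted), sc$logseries_p)
      raw <- counts * sc$individuals_per_community / sum(counts)
      n_ind <- pmax(1L, as.integer(round(raw)))
      species <- rownames(mu)[admitted]
      ind <- purrr::map_dfr(seq_along(admitted), function(j) {
        vals <- sapply(seq_along(traits), function(t) {
          exp(stats::rnorm(n_ind[j], mu[admitted[j], t], sc$within_sd[t]))
        })
        vals <- matrix(vals, nrow = n_ind[j],
                       dimnames = list(NULL, traits))
        dplyr::bind_cols(
          tibble::tibble(community = comm_id, species = species[j]),
          tibble::as_tibble(vals))
      })
      list(table = ind,
           pool = tibble::tibble(community = comm_id, elevation = elev,
                                 species = species, abundance = n_ind))
    })

    tab <- dplyr::bind_rows(purrr::map(per_comm, "table"))
    tab$individual <- sprintf("ind%05d", seq_len(nrow(tab)))
    if (sc$missing_frac > 0) {
      for (tr in traits) {
        del <- stats::runif(nrow(tab)) < sc$missing_frac
        tab[[tr]][del] <- NA_real_
      }
    }
    list(
      table = trait_table(tab, traits = traits),
      truth = list(
        scenario = sc,
        species_means = tibble::as_tibble(mu, rownames = "species"),
        communities = dplyr::bind_rows(purrr::map(per_comm, "pool"))
      )
    )
  })
}

#' Simulate an environment table along the elevational gradient
#'
#' Generates the four per-community environmental covariates as smooth
#' functions of elevation plus measurement noise: mean annual temperature
#' (`MAT`, degrees C, moist-adiabatic lapse), annual precipitation (`APPT`,
#' mm), vegetation index (`EVI`, unitless) and air density (`AD`, kg/m^3,
#' barometric decline). All four co-vary strongly with elevation, so their
#' first principal component captures most of the joint variance.
#'
#' @param elevations Community elevations in meters.
#' @param noise Multiplier on the default noise SDs (0 = deterministic).
#' @param seed Optional seed.
#' @return Tibble with `community`, `elevation`, `MAT`, `APPT`, `EVI`, `AD`.
#' @export
sim_environment <- function(elevations = seq(200, 2770, length.out = 13),
                            noise = 1, seed = NULL) {
  with_seed(seed, {
    n <- length(elevations)
    tibble::tibble(
      community = sprintf("E%04d", round(elevations)),
      elevation = elevations,
      MAT = 25.2 - 0.00545 * elevations + stats::rnorm(n, 0, 0.5 * noise),
      APPT = 3400 - 0.35 * elevations + stats::rnorm(n, 0, 90 * noise),
      EVI = 0.68 - 7e-5 * elevations + stats::rnorm(n, 0, 0.02 * noise),
      AD = 1.204 * exp(-elevations / 8434) + stats::rnorm(n, 0, 0.004 * noise)
    )
  })
}

#' Power / calibration sweep over assembly-filter settings
#'
#' For every row of `grid` (columns are [sim_scenario()] argument names,
#' e.g. `limiting_similarity_gap`, `w_ext`) and every replicate: simulate a
#' table, log-transform it, run [tstat_ses()], and record each community's
#' SES and envelope rejection. Used to verify that the null models are
#' calibrated (no filters: about 5% rejections) and that SES responds
#' monotonically to filter strength.
#'
#' @param base A `sim_scenario` providing unswept parameters.
#' @param grid Data frame of scenario overrides, one row per cell.
#' @param replicates Simulations per cell.
#' @param n_iter Null iterations per [tstat_ses()] call.
#' @param traits,metrics Restrict the SES computation (defaults: first trait,
#'   all metrics) to keep sweeps affordable.
#' @param seed Master seed; each cell × replicate gets a derived stream.
#' @param summarize If `TRUE` (default), return per-cell rejection rates and
#'   mean SES; otherwise the replicate-level table.
#' @return A tibble: grid columns plus `trait`, `metric`, `mean_ses`,
#'   `rejection_rate`, `n_cells` (or replicate-level rows).
#' @export
parameter_sweep <- function(base = sim_scenario(), grid,
                            replicates = 5, n_iter = 199,
                            traits = NULL, metrics = c("T_IP_IC", "T_IC_IR",
                                                       "T_PC_PR"),
                            seed = 1, summarize = TRUE) {
  grid <- tibble::as_tibble(grid)
  stopifnot(nrow(grid) >= 1)
  detail <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    args <- utils::modifyList(unclass(base), as.list(grid[i, ]))
    args$elevations <- base$elevations
    sc <- do.call(sim_scenario, args[setdiff(names(args), "seed")])
    purrr::map_dfr(seq_len(replicates), function(r) {
      s <- derive_seed(seed, i * 1000L + r)
      sim <- simulate_communities(sc, seed = s)
      use_traits <- traits %||% trait_names(sim$table)[1]
      ses <- tstat_ses(log_transform(sim$table), traits = use_traits,
                       metrics = metrics, n_iter = n_iter, seed = s)
      dplyr::bind_cols(grid[rep(i, nrow(ses)), , drop = FALSE],
                       tibble::tibble(replicate = r), ses)
    })
  })
  if (!summarize) return(detail)
  dplyr::summarise(
    dplyr::group_by(detail, dplyr::across(dplyr::all_of(names(grid))),
                    .data$trait, .data$metric),
    mean_ses = mean(.data$ses, na.rm = TRUE),
    rejection_rate = mean(.data$significant, na.rm = TRUE),
    n_cells = dplyr::n(),
    .groups = "drop")
}
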