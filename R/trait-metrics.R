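#' Community-weighted mean trait values
#'
#' The community-weighted mean of community \eqn{k} is
#' \eqn{CWM_k = \sum_i a_{ik} t_{ik}}, where \eqn{a_{ik}} is the relative
#' abundance of species \eqn{i} in \eqn{k} (individuals of \eqn{i} in
#' \eqn{k} over total individuals in \eqn{k}) and \eqn{t_{ik}} its mean
#' trait value. Two variants are provided:
#'
#' * `mode = "local"` — \eqn{t_{ik}} is the species mean *within* community
#'   \eqn{k} (incorporates intraspecific variability across communities);
#' * `mode = "regional"` — \eqn{t_i} is the species mean over the whole
#'   region (the species-mean-only convention).
#'
#' Abundances count all individuals of a species, including those missing
#' the trait; species with no measured value for the trait are dropped and
#' the remaining weights renormalized. CWM is computed on the raw trait
#' scale (no log transform).
#'
#' @param table A `trait_tbl`.
#' @param traits Traits to average (default: all).
#' @param mode `"local"` or `"regional"` species means.
#' @return A tibble with columns `community`, `trait`, `mode`, `cwm`.
#' @export
#' @examples
#' tt <- trait_table(tibble::tibble(
#'   community = "c1", species = c("A", "A", "B", "B"),
#'   mass = c(2, 2, 6, 6)
#' ))
#' cwm(tt) # equal abundances, means 2 and 6 -> 4
cwm <- function(table, traits = NULL, mode = c("local", "regional")) {
  mode <- match.arg(mode)
  if (is.null(traits)) traits <- trait_names(table)
  df <- tibble::as_tibble(as.data.frame(table))
  long <- tidyr::pivot_longer(
    df[c("community", "species", traits)],
    dplyr::all_of(traits), names_to = "trait", values_to = "value")
  ab <- dplyr::count(long, .data$community, .data$species, .data$trait,
                     name = "n_ind")
  sp_means <- if (mode == "local") {
    dplyr::summarise(dplyr::group_by(long, .data$community, .data$species,
                                     .data$trait),
                     t_mean = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  } else {
    dplyr::summarise(dplyr::group_by(long, .data$species, .data$trait),
                     t_mean = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  }
  joined <- dplyr::left_join(ab, sp_means,
                             by = intersect(names(ab), names(sp_means)))
  joined <- dplyr::filter(joined, is.finite(.data$t_mean))
  if (nrow(joined) == 0) stop("no measured trait values", call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$community, .data$trait),
    cwm = sum(.data$n_ind * .data$t_mean) / sum(.data$n_ind),
    .groups = "drop")
  dplyr::mutate(out, mode = mode, .before = "cwm")
}

#' Kernel density estimates of community trait distributions
#'
#' Estimates each community's trait distribution with a Gaussian kernel over
#' its individual values (each individual contributes one kernel — no
#' abundance weighting by species, so intraspecific variability enters the
#' estimate directly). All communities are evaluated on a common regular
#' grid spanning the pooled regional range extended by three pooled
#' bandwidths, so densities are directly comparable and integrable against
#' each other. Bandwidth defaults to Silverman's rule (`stats::bw.nrd0`) per
#' community.
#'
#' @param table A `trait_tbl`.
#' @param trait Trait name.
#' @param communities Communities to include (default: all with ≥ 2 measured
#'   individuals).
#' @param bw Bandwidth override: a single number applied to every community
#'   (and to the common-grid extension, keeping the grid a function of the
#'   data values alone).
#' @param n_grid Number of grid points (≥ 512).
#' @return A tibble of class `trait_kde` with columns `community`, `x`,
#'   `density`; attributes `trait` and `grid`.
#' @export
trait_kde <- function(table, trait, communities = NULL, bw = NULL,
                      n_grid = 512) {
  stopifnot(trait %in% trait_names(table), n_grid >= 512)
  df <- as.data.frame(table)
  x_all <- df[[trait]]
  ok <- !is.na(x_all)
  x_all <- x_all[ok]
  comm_all <- df$community[ok]
  if (is.null(communities)) communities <- sort(unique(comm_all))
  pooled_bw <- if (is.null(bw)) stats::bw.nrd0(x_all) else bw
  lo <- min(x_all) - 3 * pooled_bw
  hi <- max(x_all) + 3 * pooled_bw
  out <- purrr::map_dfr(communities, function(k) {
    xk <- x_all[comm_all == k]
    if (length(xk) < 2) {
      stop("community `", k, "` has fewer than 2 measured `", trait,
           "` values", call. = FALSE)
    }
    if (is.null(bw) && stats::sd(xk) == 0) {
      stop("zero `", trait, "` variance in community `", k,
           "`; supply a fixed `bw` bandwidth override", call. = FALSE)
    }
    bwk <- if (is.null(bw)) stats::bw.nrd0(xk) else bw
    if (!is.finite(bwk) || bwk <= 0) {
      stop("degenerate bandwidth for community `", k,
           "`; supply a positive `bw`", call. = FALSE)
    }
    d <- stats::density(xk, bw = bwk, kernel = "gaussian",
                        from = lo, to = hi, n = n_grid)
    tibble::tibble(community = k, x = d$x, density = d$y)
  })
  structure(out, trait = trait, grid = seq(lo, hi, length.out = n_grid),
            class = c("trait_kde", class(out)))
}

#' Overlap (area of intersection) of two trait densities
#'
#' The overlap of two community trait distributions is the area under the
#' pointwise minimum of their kernel densities, a number in \[0, 1\]:
#' 1 for identical distributions, near 0 for distributions separated by much
#' more than their bandwidths. Its complement is a functional beta diversity
#' between the two communities.
#'
#' @param kde_a,kde_b Tibbles with columns `x`, `density` on the *same* grid
#'   (two communities taken from one [trait_kde()] result).
#' @return Scalar overlap in \[0, 1\].
#' @export
overlap <- function(kde_a, kde_b) {
  if (nrow(kde_a) != nrow(kde_b) ||
      max(abs(kde_a$x - kde_b$x)) > 1e-8 * diff(range(kde_a$x))) {
    stop("densities are not on the same grid", call. = FALSE)
  }
  min(1, trapz(kde_a$x, pmin(kde_a$density, kde_b$density)))
}

#' Pairwise trait-overlap matrix across communities
#'
#' Computes [overlap()] for every unordered pair of communities from a
#' common-grid [trait_kde()] fit.
#'
#' @param kdes A `trait_kde` tibble.
#' @return A tibble of class `overlap_tbl` with one row per unordered pair:
#'   `community_a`, `community_b`, `overlap`.
#' @export
kde_overlap <- function(kdes) {
  communities <- unique(kdes$community)
  dens <- lapply(communities,
                 function(k) kdes[kdes$community == k, c("x", "density")])
  names(dens) <- communities
  pairs <- utils::combn(communities, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tibble::tibble(community_a = a, community_b = b,
                   overlap = overlap(dens[[a]], dens[[b]]))
  })
  structure(out, trait = attr(kdes, "trait"),
            class = c("overlap_tbl", class(out)))
}

#' @rdname kde_overlap
#' @param x An `overlap_tbl`.
#' @return `overlap_matrix()` returns the symmetric matrix form with unit
#'   diagonal.
#' @export
overlap_matrix <- function(x) {
  communities <- sort(unique(c(x$community_a, x$community_b)))
  m <- diag(1, length(communities))
  dimnames(m) <- list(communities, communities)
  for (j in seq_len(nrow(x))) {
    m[x$community_a[j], x$community_b[j]] <- x$overlap[j]
    m[x$community_b[j], x$community_a[j]] <- x$overlap[j]
  }
  m
}

#' Decay of trait overlap with elevational distance
#'
#' Regresses pairwise community trait overlap on the absolute elevational
#' distance between the pair — a declining overlap with distance indicates a
#' directional trait response to the gradient (external filtering).
#'
#' @param overlap_tbl An `overlap_tbl` from [kde_overlap()].
#' @param env Environment table with columns `community` and `elevation`.
#' @return A one-row [ols()] regression tibble of overlap on distance (in
#'   meters).
#' @export
overlap_decay <- function(overlap_tbl, env) {
  elev <- setNames(env$elevation, env$community)
  d <- abs(elev[overlap_tbl$community_a] - elev[overlap_tbl$community_b])
  if (length(d) < 3) stop("need at least 3 community pairs", call. = FALSE)
  ols(as.numeric(d), overlap_tbl$overlap,
      response = paste0("overlap_", attr(overlap_tbl, "trait") %||% "trait"),
      predictor = "elevational_distance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vegan::rarefy warns whenever a community lacks singletons ("most observed
# count data have counts 1..."); our inputs are genuine abundance counts, so
# that advisory is muffled.
rarefy_quiet <- function(counts, m) {
  withCallingHandlers(
    unname(vegan::rarefy(matrix(counts, nrow = 1), sample = m)),
    warning = function(w) {
      if (grepl("counts 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Rarefaction curves per community
#'
#' * `kind = "taxonomic"` — expected species richness in a random subsample
#'   of `m` individuals, from the analytic hypergeometric formula
#'   (delegated to [vegan::rarefy()]).
#' * `kind = "functional"` — for each trait, the mean over `n_resamples`
#'   random subsamples (without replacement) of `m` individuals of the
#'   community trait variance, a trait-space analogue of the species
#'   accumulation curve.
#'
#' Values of `m` above the community size are truncated at the size.
#'
#' @param table A `trait_tbl`.
#' @param community Community label.
#' @param kind `"taxonomic"` or `"functional"`.
#' @param m_grid Subsample sizes (default: 10 steps up to community size).
#' @param n_resamples Resamples per `m` for functional curves (default 100).
#' @param traits Traits for functional curves (default: all).
#' @param seed Optional seed for functional resampling.
#' @return A tibble with columns `community`, `kind`, `m`, `value` and, for
#'   functional curves, `trait`.
#' @export
rarefaction <- function(table, community,
                        kind = c("taxonomic", "functional"),
                        m_grid = NULL, n_resamples = 100, traits = NULL,
                        seed = NULL) {
  kind <- match.arg(kind)
  df <- as.data.frame(table)
  df <- df[df$community == community, , drop = FALSE]
  n <- nrow(df)
  if (n < 2) stop("community has fewer than 2 individuals", call. = FALSE)
  if (is.null(m_grid)) m_grid <- unique(round(seq(1, n, length.out = 10)))
  m_grid <- sort(unique(pmin(pmax(m_grid, 1), n)))

  if (kind == "taxonomic") {
    counts <- table(df$species)
    vals <- vapply(m_grid, function(m) rarefy_quiet(counts, m), numeric(1))
    return(tibble::tibble(community = community, kind = kind,
                          m = m_grid, value = vals))
  }

  if (is.null(traits)) traits <- trait_names(table)
  with_seed(seed, {
    purrr::map_dfr(traits, function(tr) {
      x <- df[[tr]]
      vals <- vapply(m_grid, function(m) {
        if (m < 2) return(NA_real_)
        mean(vapply(seq_len(n_resamples), function(i) {
          var_or_na(x[sample.int(n, m)])
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      tibble::tibble(community = community, kind = kind, trait = tr,
                     m = m_grid, value = vals)
    })
  })
}

#' Rarefied species richness at a common sampling depth
#'
#' Expected richness of every community at `m` individuals (default: the
#' smallest community's size), the standardized richness used as a predictor
#' in metric regressions.
#'
#' @param table A `trait_tbl`.
#' @param m Sampling depth; defaults to the minimum community size.
#' @return Tibble with `community`, `richness_observed`, `richness_rarefied`,
#'   `n_individuals`, `m`.
#' @export
rarefied_richness <- function(table, m = NULL) {
  df <- as.data.frame(table)
  sizes <- table(df$community)
  if (is.null(m)) m <- min(sizes)
  purrr::map_dfr(sort(unique(df$community)), function(k) {
    sub <- df[df$community == k, , drop = FALSE]
    counts <- table(sub$species)
    mk <- min(m, nrow(sub))
    tibble::tibble(
      community = k,
      richness_observed = length(counts),
      richness_rarefied = rarefy_quiet(counts, mk),
      n_individuals = nrow(sub),
      m = mk
    )
  })
}

#' Per-community profile of richness, CWM and trait variance
#'
#' Convenience summary joining observed and rarefied richness, local and
#' regional CWMs and the community trait variance for every community —
#' the per-community quantities regressed against the gradient.
#'
#' @param table A `trait_tbl` (raw scale; variances are computed on log
#'   traits internally).
#' @param env Optional environment table with `community` and `elevation`.
#' @return A tibble, one row per community × trait.
#' @export
community_profiles <- function(table, env = NULL) {
  rich <- rarefied_richness(table)
  cw_l <- dplyr::rename(cwm(table, mode = "local"), cwm_local = "cwm")
  cw_r <- dplyr::rename(cwm(table, mode = "regional"), cwm_regional = "cwm")
  comp <- variance_components(log_transform(table), warn_untransformed = FALSE)
  out <- dplyr::select(comp, "community", "trait",
                       community_variance = "sigma2_IC")
  out <- dplyr::left_join(out, dplyr::select(cw_l, -"mode"),
                          by = c("community", "trait"))
  out <- dplyr::left_join(out, dplyr::select(cw_r, -"mode"),
                          by = c("community", "trait"))
  out <- dplyr::left_join(out, rich, by = "community")
  if (!is.null(env)) {
    out <- dplyr::left_join(out,
                            dplyr::select(tibble::as_tibble(env),
                                          "community", "elevation"),
                            by = "community")
  }
  out
}
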