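#' Nested variance components of a trait across populations, communities and
#' the region
#'
#' Decomposes individual-level trait variance at the nested taxonomic and
#' spatial scales underlying the T-statistic ratios. For each community
#' \eqn{k} and trait:
#'
#' * `sigma2_IP` — mean, over the community's species with at least two
#'   measured individuals, of the within-population sample variance
#'   (the average niche width of a species);
#' * `sigma2_IC` — sample variance of all the community's individuals
#'   regardless of species (the community's occupied niche space);
#' * `sigma2_PC` — sample variance of the community's population mean trait
#'   values (defined only with two or more species present);
#' * `sigma2_IR` — sample variance of all individuals in the region (shared
#'   by every community);
#' * `sigma2_PR` — sample variance of all population means in the regional
#'   pool, where a *population* is a species-by-community pair (a species
#'   occurring in k communities contributes k means).
#'
#' All variances use the sample (n − 1) convention, applied uniformly so the
#' ratios are internally consistent. Missing trait cells are excluded
#' pairwise per trait. Species averaging for `sigma2_IP` is unweighted by
#' abundance; species with a single individual contribute nothing to it.
#' Undefined components are reported as `NA`, never as zero.
#'
#' Analyses are intended to run on log-transformed traits (see
#' [log_transform()]); a warning is emitted when the input is not flagged as
#' log-transformed.
#'
#' @param table A `trait_tbl`, normally log-transformed.
#' @param traits Traits to decompose (default: all).
#' @param warn_untransformed Warn when the table does not carry the
#'   log-transform flag.
#' @return A tibble with one row per community × trait and columns
#'   `community`, `trait`, `sigma2_IP`, `sigma2_IC`, `sigma2_PC`,
#'   `sigma2_IR`, `sigma2_PR`, `n_individuals`, `n_species`,
#'   `n_species_IP` (species entering the `sigma2_IP` average).
#' @seealso [t_statistics()]
#' @export
#' @examples
#' tt <- trait_table(tibble::tibble(
#'   community = "c1", species = rep(c("A", "B"), each = 2),
#'   mass = c(1, 3, 5, 7)
#' ))
#' variance_components(tt, warn_untransformed = FALSE)
variance_components <- function(table, traits = NULL,
                                warn_untransformed = TRUE) {
  if (is.null(traits)) traits <- trait_names(table)
  if (warn_untransformed && !isTRUE(attr(table, "log_transformed"))) {
    warning("table is not flagged as log-transformed; T-statistics are ",
            "normally computed on log traits", call. = FALSE)
  }
  df <- as.data.frame(table)
  purrr::map_dfr(traits, function(tr) {
    x <- df[[tr]]
    ok <- !is.na(x)
    x <- x[ok]
    comm <- df$community[ok]
    sp <- df$species[ok]
    pop <- paste(comm, sp, sep = "\r")

    sigma2_IR <- var_or_na(x)
    pop_m <- group_moments(x, pop)
    sigma2_PR <- var_or_na(pop_m$mean)

    purrr::map_dfr(sort(unique(df$community)), function(k) {
      in_k <- comm == k
      xk <- x[in_k]
      spk <- sp[in_k]
      gm <- if (length(xk) > 0) group_moments(xk, spk) else NULL
      n_sp <- if (is.null(gm)) 0L else length(gm$group)
      vars_ip <- if (is.null(gm)) numeric(0) else gm$var[!is.na(gm$var)]
      tibble::tibble(
        community = k,
        trait = tr,
        sigma2_IP = if (length(vars_ip) > 0) mean(vars_ip) else NA_real_,
        sigma2_IC = var_or_na(xk),
        sigma2_PC = if (n_sp >= 2) var_or_na(gm$mean) else NA_real_,
        sigma2_IR = sigma2_IR,
        sigma2_PR = sigma2_PR,
        n_individuals = length(xk),
        n_species = n_sp,
        n_species_IP = length(vars_ip)
      )
    })
  })
}

#' T-statistic variance ratios
#'
#' Computes the three T-statistic metrics per community and trait:
#'
#' * `T_IP_IC = sigma2_IP / sigma2_IC` — internal-filter metric: the niche
#'   width of an average species relative to the community's total trait
#'   space. Values well below 1 indicate that conspecific individuals
#'   cluster tightly relative to the community (internal filtering /
#'   niche packing).
#' * `T_IC_IR = sigma2_IC / sigma2_IR` — external-filter metric using
#'   individual values: how much of the regional trait space a community
#'   occupies.
#' * `T_PC_PR = sigma2_PC / sigma2_PR` — external-filter metric using
#'   population means only (ignores intraspecific variability).
#'
#' A single-species community has `T_IP_IC = 1` (the species is the
#' community). Ratios with an undefined or zero denominator are `NA`.
#'
#' @param x A `trait_tbl` (components are computed first) or a tibble of
#'   [variance_components()].
#' @param ... Passed on to [variance_components()] when `x` is a trait table.
#' @return A tibble with columns `community`, `trait`, `T_IP_IC`, `T_IC_IR`,
#'   `T_PC_PR`.
#' @export
t_statistics <- function(x, ...) {
  comp <- if (inherits(x, "trait_tbl")) variance_components(x, ...) else x
  needed <- c("sigma2_IP", "sigma2_IC", "sigma2_PC", "sigma2_IR", "sigma2_PR")
  stopifnot(all(needed %in% names(comp)))
  ratio <- function(num, den) {
    out <- num / den
    out[!is.na(den) & den == 0] <- NA_real_
    out
  }
  dplyr::transmute(
    comp,
    community = .data$community,
    trait = .data$trait,
    T_IP_IC = ratio(.data$sigma2_IP, .data$sigma2_IC),
    T_IC_IR = ratio(.data$sigma2_IC, .data$sigma2_IR),
    T_PC_PR = ratio(.data$sigma2_PC, .data$sigma2_PR)
  )
}

#' Standard-deviation ratio implied by a T-statistic
#'
#' Converts a variance ratio to the corresponding standard-deviation ratio in
#' percent: `100 * sqrt(T)`. For `T_IP_IC` this is the fraction of the
#' community trait spread (in SD units) occupied by an average species.
#'
#' @param t_value Variance ratio(s), e.g. a `T_IP_IC` column.
#' @return Percentages on the SD scale.
#' @export
#' @examples
#' sd_ratio_pct(c(0.22, 0.56, 0.54))
sd_ratio_pct <- function(t_value) 100 * sqrt(t_value)
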