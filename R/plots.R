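#' Plot observed T-statistics against their null envelopes
#'
#' One panel per trait × metric: observed metric values (points) with the
#' null 95% envelope (vertical bars) per community. Points falling outside
#' their bar are the significant community–trait combinations.
#'
#' @param object A `tstat_ses` tibble from [tstat_ses()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tstat_ses
#' @export
autoplot.tstat_ses <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$community)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$envelope_lo,
                                         ymax = .data$envelope_hi),
                            linewidth = 2, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$significant),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_grid(metric ~ trait, scales = "free_y") +
    ggplot2::labs(x = "community", y = "metric value",
                  colour = "outside envelope") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot community trait kernel densities
#'
#' @param object A `trait_kde` tibble from [trait_kde()].
#' @param ... Unused.
#' @return A ggplot of all communities' densities on the common grid.
#' @method autoplot trait_kde
#' @export
autoplot.trait_kde <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$density,
                                       colour = .data$community)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "trait"), y = "density") +
    ggplot2::theme_minimal()
}

#' Plot pairwise trait overlap
#'
#' Without `env`, a symmetric heat map of the overlap matrix; with `env`
#' (columns `community`, `elevation`), a scatter of overlap against
#' elevational distance with the OLS decay fit.
#'
#' @param object An `overlap_tbl` from [kde_overlap()].
#' @param env Optional environment table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_tbl
#' @export
autoplot.overlap_tbl <- function(object, env = NULL, ...) {
  if (is.null(env)) {
    m <- overlap_matrix(object)
    df <- tibble::as_tibble(as.data.frame.table(m, responseName = "overlap"))
    names(df)[1:2] <- c("community_a", "community_b")
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$community_a, .data$community_b,
                                       fill = .data$overlap)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
        ggplot2::labs(x = NULL, y = NULL,
                      title = attr(object, "trait")) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    )
  }
  elev <- setNames(env$elevation, env$community)
  df <- dplyr::mutate(tibble::as_tibble(object),
                      distance = abs(elev[.data$community_a] -
                                       elev[.data$community_b]))
  ggplot2::ggplot(df, ggplot2::aes(.data$distance, .data$overlap)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = "elevational distance (m)", y = "trait overlap",
                  title = attr(object, "trait")) +
    ggplot2::theme_minimal()
}

#' Scree-and-scores plot for an environmental PCA
#'
#' @param object An `env_pca`.
#' @param ... Unused.
#' @return A ggplot of PC1 scores against elevation, annotated with the
#'   variance share of PC1.
#' @method autoplot env_pca
#' @export
autoplot.env_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$elevation, .data$PC1)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "elevation (m)", y = "PC1",
      title = sprintf("PC1 explains %.0f%% of environmental variance",
                      100 * object$var_explained[1])) +
    ggplot2::theme_minimal()
}

#' Plot rarefaction curves
#'
#' @param curves Output of [rarefaction()] (rows from one or more
#'   communities may be bound together).
#' @return A ggplot, faceted by trait for functional curves.
#' @export
plot_rarefaction <- function(curves) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$m, .data$value,
                                            colour = .data$community)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "individuals sampled",
                  y = if (all(curves$kind == "taxonomic"))
                    "expected species richness" else "trait variance") +
    ggplot2::theme_minimal()
  if ("trait" %in% names(curves) && any(!is.na(curves$trait))) {
    p <- p + ggplot2::facet_wrap(~trait, scales = "free_y")
  }
  p
}
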