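#' Ordinary least-squares regression of a metric on a gradient
#'
#' Thin tidy wrapper around [stats::lm()] for the single-predictor
#' regressions used throughout gradient analyses. Reports intercept and
#' slope with standard errors, adjusted \eqn{R^2 = 1 - (1 - R^2)(n-1)/(n-2)}
#' and the two-sided t-test p-value of the slope. Rows with a missing
#' response or predictor are dropped pairwise and counted.
#'
#' @param x Predictor vector.
#' @param y Response vector.
#' @param response,predictor Names recorded in the output.
#' @return A one-row tibble of class `tf_ols`: `response`, `predictor`, `n`,
#'   `n_dropped`, `intercept`, `intercept_se`, `slope`, `slope_se`, `r2`,
#'   `adj_r2`, `p_value`.
#' @export
#' @examples
#' ols(1:10, 2 * (1:10) + 1)
ols <- function(x, y, response = "y", predictor = "x") {
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations",
                          call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # exact linear inputs (degenerate but valid here) trigger a summary.lm
  # warning about perfect fits; the estimates themselves are fine
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- s$coefficients
  tibble::tibble(
    response = response, predictor = predictor,
    n = length(x), n_dropped = n_dropped,
    intercept = co[1, 1], intercept_se = co[1, 2],
    slope = co[2, 1], slope_se = co[2, 2],
    r2 = s$r.squared, adj_r2 = s$adj.r.squared,
    p_value = co[2, 4]
  ) -> out
  class(out) <- c("tf_ols", class(out))
  out
}

#' Compare the slopes of two independent regressions
#'
#' Tests whether two independently fitted slopes differ, with the normal
#' statistic \eqn{z = (b_a - b_b) / \sqrt{SE_a^2 + SE_b^2}} and the
#' one-sided normal tail probability \eqn{p = \Phi(-|z|)} — the convention
#' used when contrasting, e.g., CWM–elevation slopes computed with and
#' without intraspecific variability.
#'
#' @param a,b One-row regression tibbles from [ols()] (or any data frame with
#'   `slope` and `slope_se` columns).
#' @return Tibble with `z`, `p_value` and the two slopes ± SE.
#' @export
#' @examples
#' fa <- ols(1:10, 2 * (1:10) + rnorm(10, sd = .1))
#' compare_slopes(fa, fa) # identical fits: z = 0, p = 0.5
compare_slopes <- function(a, b) {
  se <- sqrt(a$slope_se^2 + b$slope_se^2)
  if (!is.finite(se) || se == 0) stop("zero combined standard error",
                                      call. = FALSE)
  z <- (a$slope - b$slope) / se
  tibble::tibble(
    z = z, p_value = stats::pnorm(-abs(z)),
    slope_a = a$slope, slope_a_se = a$slope_se,
    slope_b = b$slope, slope_b_se = b$slope_se
  )
}

#' Principal component analysis of the environmental variables
#'
#' PCA of the per-community environmental variables (by default mean annual
#' temperature `MAT`, annual precipitation `APPT`, vegetation index `EVI`
#' and air density `AD`), each standardized to zero mean and unit variance.
#' Along a strong elevational gradient the first component typically
#' captures most of the joint variation and serves as a composite
#' environmental axis; its sign is oriented so that PC1 correlates
#' positively with elevation.
#'
#' @param env Data frame with columns `community`, `elevation` and the
#'   environmental variables.
#' @param variables Environmental variable names (default
#'   `c("MAT", "APPT", "EVI", "AD")`).
#' @return An object of class `env_pca`: list with `loadings` (variables ×
#'   components), `var_explained` (fractions summing to 1), `scores` (tibble
#'   with `community`, `elevation`, `PC1`, ...), and `pc1_elevation`, the
#'   [ols()] fit of PC1 on elevation.
#' @export
env_pca <- function(env, variables = c("MAT", "APPT", "EVI", "AD")) {
  env <- tibble::as_tibble(env)
  stopifnot(all(c("community", "elevation") %in% names(env)))
  missing_vars <- setdiff(variables, names(env))
  if (length(missing_vars) > 0) {
    stop("environment table lacks: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(env) < 3) stop("need at least 3 communities", call. = FALSE)
  m <- as.matrix(env[variables])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant environmental variable(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  # orient PC1 to correlate positively with elevation
  if (stats::cor(p$x[, 1], env$elevation) < 0) {
    p$x[, 1] <- -p$x[, 1]
    p$rotation[, 1] <- -p$rotation[, 1]
  }
  scores <- dplyr::bind_cols(env[c("community", "elevation")],
                             tibble::as_tibble(p$x))
  structure(
    list(
      loadings = p$rotation,
      var_explained = p$sdev^2 / sum(p$sdev^2),
      scores = scores,
      sdev = p$sdev,
      center = p$center,
      scale = p$scale,
      pc1_elevation = ols(env$elevation, p$x[, 1],
                          response = "PC1", predictor = "elevation")
    ),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  cat("Environmental PCA (", nrow(x$loadings), " variables, ",
      nrow(x$scores), " communities)\n", sep = "")
  cat("Variance explained: ",
      paste(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                    100 * x$var_explained), collapse = ", "), "\n")
  cat(sprintf("PC1 ~ elevation: R^2 = %.2f, p = %.3g\n",
              x$pc1_elevation$r2, x$pc1_elevation$p_value))
  invisible(x)
}

#' @method tidy env_pca
#' @export
tidy.env_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @method glance env_pca
#' @export
glance.env_pca <- function(x, ...) {
  tibble::tibble(
    n_communities = nrow(x$scores),
    n_variables = nrow(x$loadings),
    pc1_var_explained = x$var_explained[1],
    pc1_elevation_r2 = x$pc1_elevation$r2,
    pc1_elevation_p = x$pc1_elevation$p_value
  )
}

#' @method tidy tf_ols
#' @export
tidy.tf_ols <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$predictor),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @method glance tf_ols
#' @export
glance.tf_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, adj.r.squared = x$adj_r2,
                 p.value = x$p_value, nobs = x$n)
}

#' Regress community metrics against gradient predictors
#'
#' Fits one [ols()] per metric × trait × predictor: every per-community
#' metric (CWM, community variance, `sigma2_IP`, `T_IP_IC`, SES of each
#' T-statistic, ...) against elevation and/or rarefied species richness.
#' Significance is annotated with stars at p < .1 (`.`) and p < .05 (`*`);
#' no multiple-testing correction is applied across the table.
#'
#' @param metrics Long tibble with columns `community`, `trait` (may be
#'   `NA`), `metric`, `value`.
#' @param predictors Tibble with `community` and one column per predictor
#'   (e.g. `elevation`, `richness_rarefied`).
#' @param predictor_names Which predictor columns to use (default: all
#'   besides `community`).
#' @return Tibble of regression rows with `metric`, `trait`, `predictor`,
#'   the [ols()] columns and `signif`.
#' @export
metric_regressions <- function(metrics, predictors, predictor_names = NULL) {
  stopifnot(all(c("community", "metric", "value") %in% names(metrics)))
  if (!"trait" %in% names(metrics)) metrics$trait <- NA_character_
  if (is.null(predictor_names)) {
    predictor_names <- setdiff(names(predictors), "community")
  }
  cells <- dplyr::distinct(metrics[c("metric", "trait")])
  grid <- tidyr::expand_grid(cells, predictor = predictor_names)
  purrr::pmap_dfr(grid, function(metric, trait, predictor) {
    same_trait <- if (is.na(trait)) is.na(metrics$trait) else
      !is.na(metrics$trait) & metrics$trait == trait
    sub <- metrics[metrics$metric == metric & same_trait, ]
    sub <- dplyr::left_join(sub, predictors, by = "community")
    fit <- tryCatch(
      ols(sub[[predictor]], sub$value,
          response = paste(metric, trait, sep = ":"), predictor = predictor),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    dplyr::mutate(
      dplyr::bind_cols(tibble::tibble(metric = metric, trait = trait), fit),
      signif = dplyr::case_when(
        .data$p_value < 0.05 ~ "*",
        .data$p_value < 0.1 ~ ".",
        TRUE ~ ""
      ))
  })
}
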