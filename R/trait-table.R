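#' Construct and validate an individual-level trait table
#'
#' The canonical data structure of the package is a long-format tibble with
#' one row per measured individual: a `community` label, a `species` label, an
#' `individual` identifier unique across the whole table, and one numeric
#' column per functional trait (e.g. body mass, wing loading, wing aspect
#' ratio). Trait cells may be `NA` (unmeasured); every present value must be
#' finite and strictly positive, since traits are ratio-scale morphometrics
#' that are log-transformed downstream.
#'
#' All individuals of one species within one community form a *population*;
#' the union of all communities is the *regional pool*. These groupings are
#' the nested scales at which [variance_components()] decomposes trait
#' variance.
#'
#' @param data A data frame with columns `community`, `species`, optionally
#'   `individual` (generated as `"ind_<row>"` when absent), and one numeric
#'   column per trait.
#' @param traits Character vector naming the trait columns. Defaults to every
#'   numeric column other than `individual`-like metadata.
#' @return A validated tibble of class `trait_tbl` with the trait names stored
#'   in the `"traits"` attribute and an `imputed` logical column (all `FALSE`
#'   unless set by [impute_missing_traits()]).
#' @seealso [read_trait_table()], [log_transform()], [impute_missing_traits()]
#' @export
#' @examples
#' tt <- trait_table(tibble::tibble(
#'   community = c("low", "low", "high", "high"),
#'   species   = c("sp1", "sp2", "sp1", "sp2"),
#'   body_mass = c(1.2, 3.4, 1.5, 2.9)
#' ))
#' validate_trait_table(tt)
trait_table <- function(data, traits = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  for (col in c("community", "species")) {
    if (!col %in% names(data)) {
      stop("trait table must have a `", col, "` column", call. = FALSE)
    }
    data[[col]] <- as.character(data[[col]])
  }
  if (!"individual" %in% names(data)) {
    data$individual <- paste0("ind_", seq_len(nrow(data)))
  }
  data$individual <- as.character(data$individual)
  if (is.null(traits)) {
    reserved <- c("community", "species", "individual", "elevation", "imputed")
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
    traits <- setdiff(traits, reserved)
  }
  if (length(traits) == 0) {
    stop("no trait columns found or named", call. = FALSE)
  }
  missing_cols <- setdiff(traits, names(data))
  if (length(missing_cols) > 0) {
    stop("trait columns absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"imputed" %in% names(data)) data$imputed <- FALSE
  data <- dplyr::relocate(data, "individual", "community", "species",
                          dplyr::all_of(traits), "imputed")
  out <- structure(data, traits = traits,
                   class = c("trait_tbl", class(data)))
  check_trait_table(out)
  out
}

#' @rdname trait_table
#' @param x A `trait_tbl`.
#' @export
trait_names <- function(x) attr(x, "traits")

# Re-attach trait_tbl attributes after dplyr verbs strip them.
as_trait_tbl <- function(data, traits) {
  structure(tibble::as_tibble(data), traits = traits,
            class = c("trait_tbl", class(tibble::as_tibble(data))))
}

check_trait_table <- function(x) {
  dup <- x$individual[duplicated(x$individual)]
  if (length(dup) > 0) {
    stop("duplicate individual identifiers: ",
         paste(unique(head(dup, 5)), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(x$community)) || any(is.na(x$community))) {
    stop("empty community labels", call. = FALSE)
  }
  if (any(!nzchar(x$species)) || any(is.na(x$species))) {
    stop("empty species labels", call. = FALSE)
  }
  for (tr in trait_names(x)) {
    v <- x[[tr]]
    bad <- !is.na(v) & (!is.finite(v) | v <= 0)
    if (any(bad)) {
      stop("trait `", tr, "` has non-positive or non-finite values for ",
           "individuals: ",
           paste(head(x$individual[bad], 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' Summarize a trait table's coverage
#'
#' Counts records, species, communities and missing trait cells — the
#' validation report logged when a table is read from disk.
#'
#' @param table A `trait_tbl`.
#' @return A one-row tibble with counts plus one `missing_<trait>` column per
#'   trait.
#' @export
validate_trait_table <- function(table) {
  check_trait_table(table)
  traits <- trait_names(table)
  counts <- purrr::map_int(traits, ~ sum(is.na(table[[.x]])))
  out <- tibble::tibble(
    n_records = nrow(table),
    n_species = dplyr::n_distinct(table$species),
    n_communities = dplyr::n_distinct(table$community),
    n_populations = nrow(dplyr::distinct(as.data.frame(table)[c("community", "species")]))
  )
  dplyr::bind_cols(out, tibble::as_tibble(setNames(as.list(counts),
                                                   paste0("missing_", traits))))
}

#' Read or write an individual trait table
#'
#' `read_trait_table()` reads a delimited text file (CSV by default) into a
#' validated [trait_table()]. Column names are configurable through
#' `columns`, a named character vector mapping canonical names
#' (`community`, `species`, `individual`, and the traits) to the file's
#' headers. Cells that fail to parse as numbers are kept as missing trait
#' values (the record is retained), and a validation report is printed via
#' `message()`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector: names are canonical column names,
#'   values are the file's column headers. Defaults map the file's
#'   `community`, `species`, `body_mass`, `wing_loading`, `aspect_ratio`
#'   (and `individual`, `elevation` when present) onto themselves.
#' @param traits Canonical trait names among `names(columns)`.
#' @param delim Field delimiter, inferred from the file extension by default
#'   (`","` for `.csv`, `"\t"` for `.tsv`).
#' @param quiet Suppress the validation report.
#' @return A `trait_tbl`.
#' @export
read_trait_table <- function(path,
                             columns = NULL,
                             traits = c("body_mass", "wing_loading",
                                        "aspect_ratio"),
                             delim = NULL,
                             quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (is.null(columns)) {
    canonical <- intersect(c("individual", "community", "species", "elevation",
                             traits, "imputed"), names(raw))
    columns <- setNames(canonical, canonical)
  }
  for (need in c("community", "species")) {
    if (!need %in% names(columns)) {
      stop("column mapping must include `", need, "`", call. = FALSE)
    }
  }
  absent <- setdiff(unname(columns), names(raw))
  if (length(absent) > 0) {
    stop("mapped columns missing from file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  traits <- intersect(traits, names(columns))
  if (length(traits) == 0) stop("no mapped trait columns", call. = FALSE)
  out <- tibble::as_tibble(setNames(raw[unname(columns)], names(columns)))
  n_unparseable <- 0L
  for (tr in traits) {
    parsed <- suppressWarnings(as.numeric(out[[tr]]))
    n_unparseable <- n_unparseable +
      sum(is.na(parsed) & !is.na(out[[tr]]) & nzchar(trimws(out[[tr]])))
    out[[tr]] <- parsed
  }
  if ("elevation" %in% names(out)) {
    out$elevation <- suppressWarnings(as.numeric(out$elevation))
  }
  if ("imputed" %in% names(out)) {
    out$imputed <- as.logical(out$imputed)
  }
  tbl <- trait_table(out, traits = traits)
  if (!quiet) {
    rep <- validate_trait_table(tbl)
    message(sprintf(
      "read %d records, %d species, %d communities; %d missing trait cells (%d unparseable)",
      rep$n_records, rep$n_species, rep$n_communities,
      sum(purrr::map_int(traits, ~ sum(is.na(tbl[[.x]])))), n_unparseable))
  }
  tbl
}

#' @rdname read_trait_table
#' @param table A `trait_tbl` to write.
#' @export
write_trait_table <- function(table, path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::write_delim(as.data.frame(table), path, delim = delim)
  invisible(path)
}

#' Natural-log transform of all trait values
#'
#' Variance-ratio analyses are performed on log traits so that the ratios are
#' free of mean-variance scaling effects. Every present trait value is
#' replaced by its natural logarithm; the missingness pattern is unchanged.
#' The log base is immaterial for any variance ratio (a base change rescales
#' every variance by the same constant), so the natural log is used
#' throughout.
#'
#' @param table A `trait_tbl` with strictly positive trait values.
#' @return A `trait_tbl` on the log scale, marked with attribute
#'   `"log_transformed"`.
#' @export
log_transform <- function(table) {
  traits <- trait_names(table)
  for (tr in traits) {
    v <- table[[tr]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      stop("cannot log-transform non-positive `", tr, "` for individuals: ",
           paste(head(table$individual[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    table[[tr]] <- log(v)
  }
  out <- structure(table, traits = traits, log_transformed = TRUE)
  class(out) <- unique(c("trait_tbl", class(table)))
  out
}

#' Impute unmeasured individuals by resampling conspecifics
#'
#' Adds synthetic individuals for those that were identified to species but
#' whose traits could not be measured: each imputed individual receives the
#' complete trait vector of one measured conspecific from the *same
#' community*, drawn uniformly with replacement. Drawing whole vectors (all
#' traits from one donor) preserves within-individual trait correlations.
#' Imputed records are flagged in the `imputed` column.
#'
#' @param measured A `trait_tbl` of measured individuals.
#' @param unmeasured_counts Data frame with columns `community`, `species` and
#'   `n` (number of unmeasured individuals of that population).
#' @param seed Optional integer seed for reproducible draws.
#' @return A `trait_tbl` containing the measured records followed by the
#'   imputed ones.
#' @export
impute_missing_traits <- function(measured, unmeasured_counts, seed = NULL) {
  stopifnot(all(c("community", "species", "n") %in% names(unmeasured_counts)))
  counts <- dplyr::filter(tibble::as_tibble(unmeasured_counts), .data$n > 0)
  if (nrow(counts) == 0) return(measured)
  traits <- trait_names(measured)
  meas_df <- as.data.frame(measured)

  no_donor <- dplyr::anti_join(
    counts, dplyr::distinct(meas_df[c("community", "species")]),
    by = c("community", "species"))
  if (nrow(no_donor) > 0) {
    stop("no measured donors for population(s): ",
         paste(paste(no_donor$species, no_donor$community, sep = " @ "),
               collapse = "; "), call. = FALSE)
  }

  with_seed(seed, {
    imputed <- purrr::pmap_dfr(counts, function(community, species, n, ...) {
      donors <- meas_df[meas_df$community == community &
                          meas_df$species == species, , drop = FALSE]
      picks <- donors[sample.int(nrow(donors), n, replace = TRUE), , drop = FALSE]
      picks$individual <- paste0("imp_", community, "_", species, "_", seq_len(n))
      picks$imputed <- TRUE
      tibble::as_tibble(picks)
    })
    as_trait_tbl(dplyr::bind_rows(tibble::as_tibble(meas_df), imputed), traits)
  })
}
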