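#' Per-sample metadata
#'
#' Sample metadata is an ordinary tibble with one row per sample and at least
#' the columns `sample_id`, `individual_id` and `month_index`. The month
#' index places every sample on a common calendar axis:
#' `month_index = year * 12 + month`, so the interval between two samples in
#' months is simply the difference of their indices. Group definitions for
#' pairwise comparisons (1 month, 2-12, 13-24, >24 months) are stated in
#' calendar months, which is why the index is derived from the collection
#' date rather than from ordinal time-point labels -- repeated monthly
#' sampling schedules usually have gaps.
#'
#' Any further columns are treated as covariates (e.g. workspace, drug use,
#' yogurt and fruit consumption, travel history, blood pressure, blood
#' sugar) and are carried through verbatim; missing covariate values are
#' allowed.
#'
#' @param x A data frame with columns `sample_id`, `individual_id` and
#'   either `month_index` or a `date` column of `"YYYY-MM"` /
#'   `"YYYY-MM-DD"` strings.
#' @return A validated metadata tibble (class `gd_meta`).
#' @export
sample_metadata <- function(x) {
  x <- as_tibble(x)
  need <- c("sample_id", "individual_id")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("metadata is missing column(s): ", toString(miss)))
  if (anyNA(x$individual_id)) {
    abort(paste0("missing individual_id for sample(s): ",
                 toString(x$sample_id[is.na(x$individual_id)])))
  }
  if (!"month_index" %in% names(x)) {
    if (!"date" %in% names(x)) abort("metadata needs either a month_index or a date column")
    x$month_index <- month_index_from_date(x$date)
  }
  x$sample_id <- as.character(x$sample_id)
  x$individual_id <- as.character(x$individual_id)
  x$month_index <- as.integer(x$month_index)
  if (anyNA(x$month_index)) {
    abort(paste0("unparseable collection date for sample(s): ",
                 toString(x$sample_id[is.na(x$month_index)])))
  }
  if (any(x$month_index <= 0L)) abort("month_index must be strictly positive")
  dup <- duplicated(x$sample_id)
  if (any(dup)) abort(paste0("duplicate sample ID(s): ", toString(unique(x$sample_id[dup]))))
  key <- paste(x$individual_id, x$month_index)
  dup2 <- duplicated(key)
  if (any(dup2)) {
    abort(paste0("more than one sample for the same individual and month: ",
                 toString(unique(key[dup2]))))
  }
  if (!inherits(x, "gd_meta")) class(x) <- c("gd_meta", class(x))
  x
}

#' Calendar month index from a year-month date string
#'
#' @param date Character vector of `"YYYY-MM"` or `"YYYY-MM-DD"` dates.
#' @return Integer `year * 12 + month`; `NA` where the string does not parse.
#' @examples
#' month_index_from_date("2016-10")  # 24202
#' @export
month_index_from_date <- function(date) {
  m <- regmatches(date, regexec("^(\\d{4})-(\\d{2})(?:-\\d{2})?$", as.character(date)))
  purrr::map_int(m, function(g) {
    if (length(g) != 3L) return(NA_integer_)
    mo <- as.integer(g[3L])
    if (mo < 1L || mo > 12L) return(NA_integer_)
    as.integer(g[2L]) * 12L + mo
  })
}

#' Read sample metadata from a delimited file
#'
#' Expects a TSV with at least `sample_id`, `individual_id` and a collection
#' date (`date` column, ISO year-month). The month index is computed from
#' the date; all other columns are retained verbatim as covariates.
#'
#' @param path Path to a tab-delimited metadata file.
#' @return A metadata tibble, see [sample_metadata()].
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_sample_metadata
#' @param x A metadata tibble.
#' @export
write_sample_metadata <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path)
  invisible(path)
}

# internal: covariate column names (everything that is not identity/time)
covariate_names <- function(meta) {
  setdiff(names(meta), c("sample_id", "individual_id", "month_index",
                         "timepoint_label", "date"))
}

check_samples_covered <- function(table, meta) {
  missing <- setdiff(sample_ids(table), meta$sample_id)
  if (length(missing)) {
    abort(paste0("sample(s) in the table have no metadata: ", toString(missing)))
  }
  invisible(TRUE)
}
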