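#' Taxon-by-sample abundance tables
#'
#' An `abund_tbl` is a tibble with a `taxon` column followed by one numeric
#' column per sample, carrying two attributes: the taxonomic `level` at which
#' reads were aggregated (`"phylum"`, `"genus"`, `"species"`, `"otu"` or
#' `"asv"`) and the `mode` of the values (`"counts"` for non-negative integer
#' read counts, `"relative"` for per-sample fractions that sum to one).
#' It is the substrate of every downstream statistic: bloom detection and
#' Bray-Curtis dissimilarity operate on relative abundances, the
#' source-tracking Gibbs sampler on counts.
#'
#' @param x A data frame whose first column (named `taxon`) holds taxon
#'   labels and whose remaining columns hold one sample each.
#' @param level Taxonomic level of the rows.
#' @param mode Either `"counts"` or `"relative"`.
#' @return A validated `abund_tbl`.
#' @examples
#' abundance_table(
#'   data.frame(taxon = c("A", "B"), s1 = c(3, 1), s2 = c(1, 3)),
#'   level = "genus", mode = "counts"
#' )
#' @export
abundance_table <- function(x, level = c("genus", "phylum", "species", "otu", "asv"),
                            mode = c("counts", "relative")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  x <- as_tibble(x, .name_repair = "minimal")
  if (ncol(x) < 2L) abort("an abundance table needs a taxon column and at least one sample column")
  names(x)[1L] <- "taxon"
  x$taxon <- as.character(x$taxon)
  out <- structure(x, level = level, mode = mode,
                   class = c("abund_tbl", class(x)))
  validate_abund_tbl(out)
}

validate_abund_tbl <- function(x) {
  taxa <- x$taxon
  samples <- sample_ids(x)
  dup_t <- taxa[duplicated(taxa)]
  if (length(dup_t)) abort(paste0("duplicate taxon label(s): ", toString(unique(dup_t))))
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s)) abort(paste0("duplicate sample ID(s): ", toString(unique(dup_s))))
  m <- abund_matrix(x)
  if (any(!is.finite(m))) abort("non-finite abundance values")
  if (any(m < 0)) {
    bad <- samples[apply(m < 0, 2L, any)]
    abort(paste0("negative abundance in sample(s): ", toString(bad)))
  }
  if (abund_mode(x) == "counts") {
    if (any(abs(m - round(m)) > 1e-6)) abort("counts mode requires integer values")
  } else {
    cs <- colSums(m)
    zero <- samples[cs == 0]
    if (length(zero)) abort(paste0("zero-sum sample column(s): ", toString(zero)))
    off <- samples[abs(cs - 1) > 1e-9]
    if (length(off)) abort(paste0("relative abundances must sum to 1; offending sample(s): ", toString(off)))
  }
  x
}

#' @export
print.abund_tbl <- function(x, ...) {
  cat(sprintf("<abund_tbl> %d taxa x %d samples, level=%s, mode=%s\n",
              nrow(x), ncol(x) - 1L, abund_level(x), abund_mode(x)))
  NextMethod()
}

#' Accessors for `abund_tbl` objects
#'
#' @param x An `abund_tbl`.
#' @return `sample_ids()` the sample column names; `abund_level()` and
#'   `abund_mode()` the corresponding attributes; `abund_matrix()` the
#'   taxa-by-samples numeric matrix with dimnames.
#' @export
sample_ids <- function(x) names(x)[-1L]

#' @rdname sample_ids
#' @export
abund_level <- function(x) attr(x, "level")

#' @rdname sample_ids
#' @export
abund_mode <- function(x) attr(x, "mode")

#' @rdname sample_ids
#' @export
abund_matrix <- function(x) {
  m <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$taxon
  m
}

matrix_to_abund <- function(m, level, mode) {
  df <- as.data.frame(m, check.names = FALSE)
  df <- cbind(data.frame(taxon = rownames(m), stringsAsFactors = FALSE), df)
  rownames(df) <- NULL
  abundance_table(df, level = level, mode = mode)
}

#' Convert a counts table to relative abundance
#'
#' Divides every sample column by its total so columns sum to one
#' (sample-wise closure to the simplex). Within-sample rank order of taxa is
#' preserved. A relative table is returned unchanged.
#'
#' @param x An `abund_tbl`.
#' @return An `abund_tbl` in relative mode.
#' @export
as_relative <- function(x) {
  stopifnot(inherits(x, "abund_tbl"))
  if (abund_mode(x) == "relative") return(x)
  m <- abund_matrix(x)
  cs <- colSums(m)
  if (any(cs == 0)) {
    abort(paste0("zero-sum sample column(s): ", toString(colnames(m)[cs == 0])))
  }
  matrix_to_abund(sweep(m, 2L, cs, "/"), abund_level(x), "relative")
}

#' Read and write abundance tables
#'
#' Reads a taxon-by-sample table from either a tab-delimited text file (taxon
#' labels in the first column, one sample per remaining column, header row of
#' sample IDs) or a BIOM file (any format the biomformat package reads).
#' With `mode = "relative"`, counts on disk are column-normalised after
#' reading.
#'
#' @param path Path to a TSV or BIOM file.
#' @param level Taxonomic level of the rows.
#' @param mode Mode of the returned table. If the file stores counts and
#'   `mode = "relative"`, values are normalised per sample.
#' @param format `"auto"` sniffs BIOM by extension/content; `"tsv"` or
#'   `"biom"` force a reader.
#' @return An `abund_tbl`.
#' @export
read_abundance_table <- function(path, level = c("genus", "phylum", "species", "otu", "asv"),
                                 mode = c("counts", "relative"),
                                 format = c("auto", "tsv", "biom")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    df <- cbind(data.frame(taxon = rownames(m), stringsAsFactors = FALSE),
                as.data.frame(m, check.names = FALSE))
    rownames(df) <- NULL
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          name_repair = "minimal")
    names(df)[1L] <- "taxon"
  }
  looks_fractional <- all(abs(colSums(as.matrix(df[-1L])) - 1) < 1e-6)
  stored <- if (looks_fractional) "relative" else "counts"
  out <- abundance_table(df, level = level, mode = stored)
  if (mode == "relative") out <- as_relative(out)
  if (mode == "counts" && stored == "relative") {
    abort("file stores relative abundances; counts cannot be recovered")
  }
  out
}

#' @rdname read_abundance_table
#' @param x An `abund_tbl` to write.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abund_tbl"))
  readr::write_tsv(as_tibble(as.data.frame(x)), path)
  invisible(path)
}
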