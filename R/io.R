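## Plain-text interchange formats for the pipeline stages. All files are
## deterministic CSV/JSON so that repeated runs with one seed are
## byte-identical.

#' Write / read the individual life-history table
#'
#' The CSV stores calving ages as a semicolon-separated list in the
#' `calving_ages` column; all other columns are scalar. The round trip
#' `read_individuals_csv(write_individuals_csv(x))` is lossless.
#'
#' @param records individual table (see [simulate_population()]).
#' @param path file path.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_individuals_csv <- function(records, path) {
  flat <- records
  flat$calving_ages <- vapply(records$calving_ages, function(a) {
    paste(format(a, trim = TRUE, scientific = FALSE), collapse = ";")
  }, character(1))
  utils::write.csv(flat, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_individuals_csv
#' @export
read_individuals_csv <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  flat$region <- factor(flat$region)
  flat$calving_ages <- lapply(strsplit(ifelse(is.na(flat$calving_ages), "",
                                              flat$calving_ages), ";"),
                              function(s) as.numeric(s[nzchar(s)]))
  flat
}

#' Write / read the hormone-sample table
#'
#' @param samples GCM sample table (see [simulate_gcm()]).
#' @param path file path.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_gcm_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_gcm_csv
#' @export
read_gcm_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the observation-bin modelling table
#'
#' @param bins modelling table (see [attach_covariates()]).
#' @param path file path.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_bins_csv <- function(bins, path) {
  utils::write.csv(bins, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_bins_csv
#' @export
read_bins_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("birth_decade" %in% names(out))
    out$birth_decade <- factor(out$birth_decade)
  if ("region" %in% names(out)) out$region <- factor(out$region)
  out
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
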