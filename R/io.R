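validate_table <- function(data, response) {
  data <- as_tibble(data)
  if (!response %in% names(data))
    abort(sprintf("response column '%s' not found", response),
          class = "gigmm_config_error")
  y <- data[[response]]
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad))
    abort(sprintf("response must be strictly positive and non-missing; offending rows: %s",
                  paste(head(bad, 10), collapse = ", ")),
          class = "gigmm_data_error")
  data
}

#' Read and validate a modelling table
#'
#' Reads a CSV file (comma separator, header row, UTF-8, '.' decimal mark),
#' validates that the response column is present, non-missing and strictly
#' positive (offending rows are named in the error), coerces the grouping
#' columns to factors with levels ordered by first appearance, and appends the
#' log response as column `w`.
#'
#' @param path path to a CSV file.
#' @param response name of the response column.
#' @param groups optional character vector of grouping columns to coerce.
#' @return A validated tibble with an added `w = log(response)` column.
#' @export
load_table <- function(path, response, groups = NULL) {
  if (!file.exists(path))
    abort(sprintf("file '%s' does not exist", path), class = "gigmm_config_error")
  # base parser: correctly rounded doubles, so write_table() round-trips bitwise
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  data <- validate_table(data, response)
  for (g in groups) {
    if (!g %in% names(data))
      abort(sprintf("grouping column '%s' not found", g),
            class = "gigmm_config_error")
    data[[g]] <- factor(as.character(data[[g]]),
                        levels = unique(as.character(data[[g]])))
  }
  data$w <- log(data[[response]])
  data
}

#' Write a table as CSV with bit-exact doubles
#'
#' Writes a data frame as a plain CSV (comma separator, header row, '.'
#' decimal mark) with doubles formatted to 17 significant digits, so that a
#' [load_table()] round trip reproduces every value bitwise.
#'
#' @param data a data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  out <- as.data.frame(data)
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records seed, configuration hash and package version next to the outputs of
#' a run so that results can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param config a named list describing the run.
#' @param seed the seed used.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(
    seed = seed,
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    package = "gigmm",
    version = as.character(utils::packageVersion("gigmm")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
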