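#' Read count measurements from a delimited table
#'
#' Accepts CSV or TSV (auto-detected from the header line) with required
#' columns `count` (non-negative integer) and `fraction` (real in (0, 1]),
#' one row per measurement, and an optional `label` column.
#'
#' @param path File path.
#' @param with_replacement Sampling scheme to attach; default `FALSE`.
#' @return A [sample_counts()] tibble.
#' @export
read_counts <- function(path, with_replacement = FALSE) {
  if (!file.exists(path)) stop_parse(paste0("input file not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop_parse(paste0("input file is empty: ", path))
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(tab) == 0) stop_parse(paste0("input table has no rows: ", path))
  bad <- which(!is_whole(tab$count) | tab$count < 0 |
                 !is.finite(tab$fraction))
  if ("count" %in% names(tab) && length(bad) > 0) {
    stop_parse(paste0("malformed measurement in row ", bad[1], " of ", path))
  }
  as_sample_counts(tab, with_replacement = with_replacement)
}

#' Write / read a posterior table
#'
#' The posterior is stored as a tab-delimited table with columns `n`, `prob`,
#' `log_prob` at full (round-trippable) precision.
#'
#' @param post A `discrete_posterior`.
#' @param path Output file path.
#' @return `write_posterior()` returns `post` invisibly; `read_posterior()`
#'   returns a `discrete_posterior` (provenance attributes are not stored in
#'   the table).
#' @export
write_posterior <- function(post, path) {
  tab <- tidy(post)
  # %.17g guarantees an exact binary round-trip of the doubles
  out <- tibble(
    n = sprintf("%.17g", tab$n),
    prob = sprintf("%.17g", tab$prob),
    log_prob = sprintf("%.17g", tab$log_prob)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(post)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  # parse via strtod (correctly rounded), not vroom's approximate fast path
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  new_discrete_posterior(as.numeric(tab$n), as.numeric(tab$prob),
                         as.numeric(tab$log_prob), scheme = "unknown")
}

#' Serialize a posterior summary as JSON
#'
#' @param summary A `posterior_summary` row from [posterior_summary()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
summary_to_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "posterior_summary"))
  fields <- as.list(summary[1, c("map", "ci_lower", "ci_upper", "level",
                                 "tail_lower", "tail_upper", "mean",
                                 "variance", "n1", "n2", "K", "R", "scheme")])
  if (is.infinite(fields$n2)) fields$n2 <- "unbounded"
  json <- jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
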