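#' Count measurements with known sampling fractions
#'
#' Bundle a set of `m` count measurements, each a pair of a non-negative
#' integer count `k_i` and the sampling fraction `r_i` of the total volume it
#' was taken from, together with the sampling scheme. This is the input type
#' of every inference function in the package.
#'
#' Under sampling *without* replacement each sampled fraction is physically
#' removed before the next measurement, so the fractions must satisfy
#' `sum(fractions) <= 1`; under sampling *with* replacement every measurement
#' sees the full volume and fractions are only individually bounded by 1.
#'
#' @param counts Integer vector of non-negative counts `k_1..k_m`.
#' @param fractions Numeric vector of sampling fractions in `(0, 1]`, same
#'   length as `counts`.
#' @param with_replacement Logical; `FALSE` (the default) means sampled
#'   fractions are removed from the volume.
#'
#' @return A tibble of class `sample_counts` with columns `count` and
#'   `fraction`, one row per measurement, and a `with_replacement` attribute.
#'   The totals `K = sum(counts)` and `R = sum(fractions)` are available via
#'   [total_count()] and [total_fraction()].
#'
#' @examples
#' sample_counts(c(5, 3), c(0.01, 0.02))
#' sample_counts(4, 0.1, with_replacement = TRUE)
#' @export
sample_counts <- function(counts, fractions, with_replacement = FALSE) {
  as_sample_counts(
    tibble(count = counts, fraction = fractions),
    with_replacement = with_replacement
  )
}

#' Coerce a data frame of measurements to `sample_counts`
#'
#' @param data A data frame with columns `count` and `fraction` (an optional
#'   `label` column is carried along).
#' @inheritParams sample_counts
#' @return A validated [sample_counts()] tibble.
#' @export
as_sample_counts <- function(data, with_replacement = FALSE) {
  if (inherits(data, "sample_counts") && missing(with_replacement)) {
    return(validate_sample_counts(data))
  }
  if (!is.data.frame(data)) {
    stop_parse("`data` must be a data frame with columns `count` and `fraction`.")
  }
  missing_cols <- setdiff(c("count", "fraction"), names(data))
  if (length(missing_cols) > 0) {
    stop_parse(paste0(
      "`data` is missing required column(s): ",
      paste0("`", missing_cols, "`", collapse = ", "), "."
    ))
  }
  keep <- intersect(c("count", "fraction", "label"), names(data))
  out <- as_tibble(data)[keep]
  out$count <- as.numeric(out$count)
  out$fraction <- as.numeric(out$fraction)
  class(out) <- c("sample_counts", class(as_tibble(out)))
  attr(out, "with_replacement") <- isTRUE(with_replacement)
  validate_sample_counts(out)
}

validate_sample_counts <- function(x) {
  k <- x$count
  r <- x$fraction
  if (length(k) < 1L) stop_parse("at least one measurement is required.")
  if (anyNA(k) || anyNA(r)) stop_parse("counts and fractions must not contain NA.")
  if (!all(is_whole(k)) || any(k < 0)) {
    stop_domain("all counts must be non-negative integers.")
  }
  if (any(r <= 0) || any(r > 1)) {
    stop_domain("all sampling fractions must lie in (0, 1].")
  }
  if (!with_replacement(x) && sum(r) > 1 + 1e-12) {
    stop_domain(paste0(
      "without replacement the sampling fractions must sum to at most 1 ",
      "(got R = ", format(sum(r)), "): more than the whole volume cannot be removed."
    ))
  }
  x
}

#' @rdname sample_counts
#' @param x A `sample_counts` object.
#' @export
with_replacement <- function(x) {
  isTRUE(attr(x, "with_replacement"))
}

#' @rdname sample_counts
#' @export
total_count <- function(x) sum(x$count)

#' @rdname sample_counts
#' @export
total_fraction <- function(x) sum(x$fraction)

#' @export
print.sample_counts <- function(x, ...) {
  scheme <- if (with_replacement(x)) "with replacement" else "without replacement"
  cat(sprintf(
    "# Sample counts: m = %d measurement(s), %s; K = %g, R = %g\n",
    nrow(x), scheme, total_count(x), total_fraction(x)
  ))
  print(as_tibble(unclass_counts(x)), ...)
  invisible(x)
}

unclass_counts <- function(x) {
  class(x) <- setdiff(class(x), "sample_counts")
  x
}

# Residual-volume representation of a without-replacement series: measurement
# i removes fraction r_i of the ORIGINAL volume, i.e. samples a fraction
# r_i / (1 - sum_{j<i} r_j) of what is left at that point.
residual_fractions <- function(x) {
  r <- x$fraction
  removed <- c(0, cumsum(r)[-length(r)])
  r / (1 - removed)
}
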