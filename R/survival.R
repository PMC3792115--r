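#' Posterior population-size series over a time course
#'
#' Runs the without-replacement inference independently at every time point
#' of a long-format enumeration table and collects the MAP estimates and
#' credible intervals — the input of [fit_power_law()].
#'
#' @param data A data frame with columns `time`, `count`, `fraction` (several
#'   replicate rows per time point).
#' @param level Credibility level for the intervals.
#' @return A tibble of class `survival_series` with one row per time point:
#'   `time`, `map`, `ci_lower`, `ci_upper`, `mean`, `variance`, `K`, `R`.
#' @examples
#' series <- estimate_survival_series(dilution_series(seed = 1))
#' @export
estimate_survival_series <- function(data, level = 0.95) {
  need <- setdiff(c("time", "count", "fraction"), names(data))
  if (length(need) > 0) {
    stop_parse(paste0("`data` is missing column(s): ",
                      paste0("`", need, "`", collapse = ", "), "."))
  }
  out <- data |>
    dplyr::group_by(.data$time) |>
    dplyr::group_modify(function(d, key) {
      post <- compute_posterior(sample_counts(d$count, d$fraction))
      s <- posterior_summary(post, level = level)
      tibble(map = s$map, ci_lower = s$ci_lower, ci_upper = s$ci_upper,
             mean = s$mean, variance = s$variance, K = s$K, R = s$R)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$time)
  class(out) <- c("survival_series", class(out))
  out
}

#' Power-law survival-curve fit
#'
#' Fits `n(t) = a * t^(-beta) + c` to a series of population-size estimates
#' by nonlinear least squares ([stats::nls()]; the Levenberg-Marquardt
#' variant [minpack.lm::nlsLM()] is used when `nls`'s relative-offset
#' criterion cannot operate, e.g. on noiseless data). `t^(-beta)` is singular
#' at `t = 0`, so non-positive times are dropped before fitting with a
#' warning.
#'
#' Starting values: `beta = 0.2`, `a = ` the estimate at the earliest
#' positive time, `c = 0`. With `two_param = TRUE` the additive floor `c` is
#' fixed at zero and the residual degrees of freedom become `length(t) - 2`
#' instead of `length(t) - 3`.
#'
#' @param series A `survival_series` (or any data frame with columns `time`
#'   and `map`).
#' @param start Optional named list overriding starting values `a`, `beta`,
#'   `c`.
#' @param two_param Fix `c = 0`?
#' @return An object of class `power_law_fit`: a list with `amplitude`,
#'   `exponent`, `offset`, `residual_se` (`sqrt(RSS / df)`), `df`,
#'   `converged`, the underlying `fit` object and the fitting `data`.
#'   [tidy()] returns the coefficient table, [glance()] the one-row fit
#'   summary, [predict()] evaluates the curve.
#' @examples
#' s <- tibble::tibble(time = c(3, 7, 14, 21, 28),
#'                     map = 1e6 * c(3, 7, 14, 21, 28)^-0.5)
#' fit_power_law(s)
#' @export
fit_power_law <- function(series, start = NULL, two_param = FALSE) {
  if (!all(c("time", "map") %in% names(series))) {
    stop_parse("`series` must have columns `time` and `map`.")
  }
  d <- tibble(time = as.numeric(series$time), map = as.numeric(series$map))
  if (any(d$time <= 0)) {
    warn("dropping time points <= 0: t^(-beta) is singular at t = 0.")
    d <- d[d$time > 0, , drop = FALSE]
  }
  n_par <- if (two_param) 2L else 3L
  if (nrow(d) < n_par + 1L) {
    stop_domain(paste0("at least ", n_par + 1L, " positive time points are needed."))
  }
  if (any(d$map <= 0)) stop_domain("all estimates must be positive.")

  if (stats::sd(d$map) < 1e-12 * max(abs(d$map))) {
    # a constant series carries no decay signal: beta is non-identifiable
    return(new_power_law_fit(
      amplitude = 0, exponent = 0, offset = mean(d$map),
      residual_se = 0, df = nrow(d) - n_par, converged = FALSE,
      note = "non-identifiable: constant series", fit = NULL, data = d,
      two_param = two_param
    ))
  }

  init <- list(a = d$map[which.min(d$time)], beta = 0.2, c = 0)
  init[names(start)] <- start
  fit <- if (two_param) {
    fit_nls(map ~ a * time^(-beta), d, init[c("a", "beta")])
  } else {
    fit_nls(map ~ a * time^(-beta) + c, d, init)
  }
  est <- coef(fit)
  df <- nrow(d) - n_par
  rss <- sum(resid(fit)^2)
  new_power_law_fit(
    amplitude = unname(est["a"]), exponent = unname(est["beta"]),
    offset = if (two_param) 0 else unname(est["c"]),
    residual_se = sqrt(rss / df), df = df, converged = TRUE,
    note = NULL, fit = fit, data = d, two_param = two_param
  )
}

fit_nls <- function(formula, data, start) {
  tryCatch(
    nls(formula, data = data, start = start,
        control = stats::nls.control(maxiter = 200)),
    error = function(e) {
      fit <- tryCatch(
        minpack.lm::nlsLM(formula, data = data, start = start,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 1000, ftol = .Machine$double.eps,
                            ptol = .Machine$double.eps)),
        error = function(e2) NULL
      )
      if (is.null(fit)) {
        abort("power-law fit did not converge", class = "popsize_fit_error",
              parent = e)
      }
      fit
    }
  )
}

new_power_law_fit <- function(amplitude, exponent, offset, residual_se, df,
                              converged, note, fit, data, two_param) {
  structure(
    list(amplitude = amplitude, exponent = exponent, offset = offset,
         residual_se = residual_se, df = df, converged = converged,
         note = note, fit = fit, data = data, two_param = two_param),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> n(t) = %.6g * t^(-%.4g) + %.6g\n  residual SE %.4g on %d df%s\n",
    x$amplitude, x$exponent, x$offset, x$residual_se, x$df,
    if (x$converged) "" else paste0(" [", x$note %||% "did not converge", "]")
  ))
  invisible(x)
}

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = c("a", "beta", "c"),
                  estimate = c(x$amplitude, x$exponent, x$offset),
                  std.error = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, exponent = x$exponent, offset = x$offset,
         residual_se = x$residual_se, df = x$df, converged = x$converged,
         nobs = nrow(x$data))
}

#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else newdata$time
  object$amplitude * t^(-object$exponent) + object$offset
}
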