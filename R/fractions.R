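#' Relative response fraction
#'
#' The relative magnitude of a parameter's change under the provoking load,
#' `|K'' - K'| / K'`, where `K'` is the pre-load value and `K''` the value
#' immediately after the load. Direction is deliberately discarded: responses
#' in either direction are compared on a common, dimensionless scale.
#'
#' @param k_pre pre-load value(s); must be strictly positive (the fraction
#'   needs a positive reference magnitude).
#' @param k_load post-load value(s).
#' @param parameter optional parameter name(s) used in error messages.
#' @return numeric vector of non-negative dimensionless fractions.
#' @examples
#' response_fraction(13.8, 7.1)   # 0.485
#' response_fraction(170, 185)    # 0.088
#' @seealso [recovery_fraction()], [signed_term()]
#' @export
response_fraction <- function(k_pre, k_load, parameter = NULL) {
  .check_finite(k_pre, "k_pre", parameter)
  .check_finite(k_load, "k_load", parameter)
  .check_positive_ref(k_pre, parameter)
  abs(k_load - k_pre) / k_pre
}

#' Relative recovery fraction
#'
#' `|K''' - K'| / |K''' - K''|`: how far a parameter still is from its
#' pre-load value after the rest interval, relative to how much ground it
#' covered during recovery. Small values mean fast, complete recovery. A
#' parameter that has returned exactly to its pre-load value scores 0 by
#' convention (the numerator-zero case wins, including 0/0).
#'
#' When the parameter has not moved at all during rest (`K''' = K''` while
#' still away from `K'`) the fraction is undefined and typically signals a
#' rest interval too short to be informative; this raises an error unless a
#' finite `cap` is supplied, in which case the capped value is returned.
#'
#' @param k_pre pre-load value(s), strictly positive.
#' @param k_load post-load value(s).
#' @param k_rec value(s) after the rest interval.
#' @param cap optional finite non-negative number substituted when the
#'   denominator vanishes while the numerator does not. Default `NULL`
#'   (error).
#' @param parameter optional parameter name(s) for error messages.
#' @return numeric vector of non-negative dimensionless fractions.
#' @examples
#' recovery_fraction(170, 185, 176)       # 0.667
#' recovery_fraction(37.0, 112.9, 39.0)   # 0.027
#' recovery_fraction(16.5, 16.9, 16.5)    # 0 (full recovery)
#' @export
recovery_fraction <- function(k_pre, k_load, k_rec, cap = NULL,
                              parameter = NULL) {
  .check_finite(k_pre, "k_pre", parameter)
  .check_finite(k_load, "k_load", parameter)
  .check_finite(k_rec, "k_rec", parameter)
  .check_positive_ref(k_pre, parameter)
  num <- abs(k_rec - k_pre)
  den <- abs(k_rec - k_load)
  out <- ifelse(num == 0, 0, num / den)
  stuck <- num > 0 & den == 0
  if (any(stuck)) {
    if (is.null(cap)) {
      who <- if (is.null(parameter)) which(stuck) else parameter[stuck]
      stop("recovery fraction undefined (no movement during rest interval, ",
           "k_rec == k_load != k_pre) for: ", paste(who, collapse = ", "),
           ". Such rest intervals should be avoided; supply `cap` to ",
           "substitute a finite value.", call. = FALSE)
    }
    stopifnot(is.finite(cap), cap >= 0)
    out[stuck] <- cap
  }
  out
}

#' Stability coefficient of a parameter
#'
#' `S = 1 - SD/mean`, one minus the coefficient of variation of the parameter
#' in an intact baseline cohort. Near-constant parameters (blood pH, core
#' temperature) get `S` close to 1; labile ones get lower values. `S` weights
#' each parameter's term in the stability-weighted index: large deviations of
#' ultrastable parameters penalise adaptedness more than deviations of labile
#' ones.
#'
#' Values below 0.5 indicate a baseline distribution too dispersed for the
#' weighting rationale to be reliable and trigger a warning (not an error).
#' `SD >= mean` (coefficient of variation at or above 1, typical of Poisson
#' or strongly skewed variables) is outside the model and raises an error.
#'
#' @param x numeric series of baseline measurements (length >= 2). Ignored
#'   when `mean` and `sd` are given.
#' @param mean,sd summary statistics of the baseline series; `sd` is the
#'   sample standard deviation (n - 1 denominator) when computed from `x`.
#' @param parameter optional name for messages.
#' @return a single value in (0, 1].
#' @examples
#' stability_coefficient(mean = 13.8, sd = 1.2)  # 0.913
#' @export
stability_coefficient <- function(x = NULL, mean = NULL, sd = NULL,
                                  parameter = NULL) {
  if (is.null(mean) || is.null(sd)) {
    if (is.null(x) || length(x) < 2)
      stop("supply either a series of >= 2 baseline values or (mean, sd)",
           call. = FALSE)
    .check_finite(x, "baseline series", parameter)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  if (!is.finite(mean) || !is.finite(sd) || sd < 0)
    stop("mean and sd must be finite with sd >= 0", call. = FALSE)
  if (mean <= 0)
    stop("stability coefficient needs a positive baseline mean",
         if (!is.null(parameter)) paste0(" (", parameter, ")"), call. = FALSE)
  if (sd >= mean)
    stop("SD >= mean (coefficient of variation >= 1): the stability ",
         "weighting model does not apply",
         if (!is.null(parameter)) paste0(" (", parameter, ")"), call. = FALSE)
  s <- 1 - sd / mean
  if (s < 0.5)
    warning("stability coefficient ", format(round(s, 3)),
            if (!is.null(parameter)) paste0(" for ", parameter),
            " is below the practical minimum 0.5; the baseline distribution",
            " may be too dispersed for reliable weighting", call. = FALSE)
  s
}

.check_finite <- function(x, what, parameter = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric",
         if (!is.null(parameter))
           paste0(" (parameter: ", paste(unique(parameter), collapse = ", "), ")"),
         call. = FALSE)
  invisible(x)
}

.check_positive_ref <- function(k_pre, parameter = NULL) {
  bad <- k_pre <= 0
  if (any(bad)) {
    who <- if (is.null(parameter)) paste("position", which(bad))
           else parameter[bad]
    stop("pre-load reference value must be > 0 for: ",
         paste(unique(who), collapse = ", "), call. = FALSE)
  }
  invisible(k_pre)
}
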