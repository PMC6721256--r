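#' A subject's measurement profile
#'
#' One subject's per-parameter values at the pre-load (`k_pre`), post-load
#' (`k_load`) and optional recovery (`k_rec`) states. Recovery values must be
#' present for all parameters or for none: recovery terms enter the index
#' uniformly or not at all. An optional logical significance mask marks
#' parameters whose load response is statistically credible; unmarked
#' parameters can be zeroed via [zero_insignificant()].
#'
#' @param parameter character vector of parameter names (unique).
#' @param k_pre,k_load numeric vectors of pre- and post-load values; `k_pre`
#'   strictly positive.
#' @param k_rec optional numeric vector of recovery values (all present or
#'   all absent).
#' @param subject_id,group_id identifiers.
#' @param significant optional logical mask (TRUE = change is significant).
#' @param metadata optional list (descriptions of the conditioning factor P,
#'   the provoking load Q, the rest interval).
#' @return a `subject_profile` data frame with one row per parameter.
#' @examples
#' subject_profile(c("lactate", "heart_rate"), k_pre = c(5.5, 40),
#'                 k_load = c(12, 110), subject_id = "s1")
#' @export
subject_profile <- function(parameter, k_pre, k_load, k_rec = NULL,
                            subject_id = "subject", group_id = NA_character_,
                            significant = NULL, metadata = NULL) {
  parameter <- as.character(parameter)
  if (anyDuplicated(parameter))
    stop("duplicate parameters in profile: ",
         paste(unique(parameter[duplicated(parameter)]), collapse = ", "),
         call. = FALSE)
  n <- length(parameter)
  stopifnot(length(k_pre) == n, length(k_load) == n)
  .check_finite(k_pre, "k_pre", parameter)
  .check_finite(k_load, "k_load", parameter)
  .check_positive_ref(k_pre, parameter)
  if (!is.null(k_rec)) {
    stopifnot(length(k_rec) == n)
    if (anyNA(k_rec)) {
      if (!all(is.na(k_rec)))
        stop("recovery values must be present for all parameters or none ",
             "(missing: ", paste(parameter[is.na(k_rec)], collapse = ", "),
             ")", call. = FALSE)
      k_rec <- NULL
    } else .check_finite(k_rec, "k_rec", parameter)
  }
  out <- data.frame(parameter = parameter, k_pre = k_pre, k_load = k_load,
                    k_rec = if (is.null(k_rec)) NA_real_ else k_rec,
                    stringsAsFactors = FALSE)
  if (!is.null(significant)) {
    stopifnot(is.logical(significant), length(significant) == n)
    out$significant <- significant
  }
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "group_id") <- as.character(group_id)
  attr(out, "metadata") <- metadata
  class(out) <- c("subject_profile", "data.frame")
  out
}

has_recovery <- function(profile) !all(is.na(profile$k_rec))

#' Split long-format measurements into subject profiles
#'
#' Converts tidy long data (columns `subject_id`, `group_id`, `parameter`,
#' `state`, `value`) into a list of [subject_profile()] objects, one per
#' subject. State labels are normalised via [normalize_state()]; `baseline`
#' rows are ignored here (they feed [compute_stability()] only), and for
#' subjects lacking explicit `pre` rows the baseline values are used as
#' pre-load values (baseline and pre alias when no conditioning occurred).
#'
#' @param data a long-format data frame.
#' @return named list of `subject_profile` objects.
#' @export
profiles_from_long <- function(data) {
  need <- c("subject_id", "group_id", "parameter", "state", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  data$state <- normalize_state(data$state)
  key <- paste(data$subject_id, data$parameter, data$state)
  if (anyDuplicated(key))
    stop("duplicate (subject, parameter, state) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  out <- lapply(split(data, data$subject_id), function(d) {
    wide <- function(st) {
      v <- d$value[d$state == st]
      names(v) <- d$parameter[d$state == st]
      v
    }
    pre <- wide("pre")
    if (length(pre) == 0) pre <- wide("baseline")
    load <- wide("load")
    params <- unique(d$parameter)
    if (!setequal(names(pre), params) || !setequal(names(load), params))
      stop("subject ", d$subject_id[1],
           ": every parameter needs pre-load and post-load values",
           call. = FALSE)
    rec <- wide("recovery")
    if (length(rec) > 0 && !setequal(names(rec), params))
      stop("subject ", d$subject_id[1],
           ": recovery values present for some parameters but not all",
           call. = FALSE)
    subject_profile(params,
                    k_pre = unname(pre[params]),
                    k_load = unname(load[params]),
                    k_rec = if (length(rec)) unname(rec[params]) else NULL,
                    subject_id = d$subject_id[1],
                    group_id = d$group_id[1])
  })
  out[unique(data$subject_id)]
}
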