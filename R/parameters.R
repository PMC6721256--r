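#' Declare the parameter panel
#'
#' Builds the panel specification: each measured variable's name, its category
#' and optionally its units. The category is the sign carrier of the index:
#' homeostatic parameters (the ones a stressor primarily deflects — lactate,
#' glycogen, body temperature) contribute negatively, adaptive/allostatic
#' parameters (the compensating machinery — heart rate, corticosteroids)
#' contribute their load response positively, and indifferent parameters
#' contribute exactly zero. Which variable belongs where is a physiological
#' judgement the caller must make; the package never guesses.
#'
#' @param name character vector of parameter names (unique).
#' @param category one of `"homeostatic"`, `"adaptive"`, `"indifferent"` per
#'   parameter (recycled if scalar).
#' @param units optional free-text units per parameter.
#' @param S optional fixed stability coefficient per parameter (`NA` when it
#'   is to be computed from baseline data).
#' @return a `parameter_spec` data frame with columns `name`, `category`,
#'   `units`, `S`.
#' @examples
#' parameter_spec(c("lactate", "heart_rate"), c("homeostatic", "adaptive"))
#' @export
parameter_spec <- function(name, category, units = NA_character_,
                           S = NA_real_) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("duplicate parameter names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  category <- rep_len(as.character(category), length(name))
  bad <- !category %in% PARAM_CATEGORIES
  if (any(bad))
    stop("unknown category for ", paste(name[bad], collapse = ", "),
         ": categories must be one of ",
         paste(PARAM_CATEGORIES, collapse = ", "), call. = FALSE)
  out <- data.frame(
    name = name,
    category = category,
    units = rep_len(as.character(units), length(name)),
    S = rep_len(as.numeric(S), length(name)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("parameter_spec", "data.frame")
  out
}

#' Build a table of stability coefficients
#'
#' Collects per-parameter stability coefficients `S` together with their
#' provenance: `"supplied"` when taken as given (e.g. transcribed from a
#' publication) or `"computed"` when estimated from a baseline cohort via
#' [compute_stability()]. Entries below 0.5 are kept but flagged.
#'
#' @param S named numeric vector of coefficients in (0, 1], or a data frame
#'   with columns `name` and `S`.
#' @param provenance `"supplied"` or `"computed"`.
#' @param source optional description of the source cohort (group, state, n).
#' @return a `stability_table` data frame with columns `name`, `S`,
#'   `provenance`, `flag_low`.
#' @examples
#' stability_table(c(hexokinase = 0.913, lactate = 0.672))
#' @export
stability_table <- function(S, provenance = c("supplied", "computed"),
                            source = NULL) {
  provenance <- match.arg(provenance)
  if (is.data.frame(S)) {
    stopifnot(all(c("name", "S") %in% names(S)))
    nm <- as.character(S$name); s <- as.numeric(S$S)
  } else {
    if (is.null(names(S)))
      stop("S must be a named vector or a data frame with name/S columns",
           call. = FALSE)
    nm <- names(S); s <- as.numeric(S)
  }
  if (any(!is.finite(s)) || any(s <= 0) || any(s > 1))
    stop("stability coefficients must lie in (0, 1]", call. = FALSE)
  out <- data.frame(name = nm, S = s, provenance = provenance,
                    flag_low = s < 0.5, stringsAsFactors = FALSE)
  if (any(out$flag_low))
    warning("stability coefficient below 0.5 for: ",
            paste(out$name[out$flag_low], collapse = ", "), call. = FALSE)
  attr(out, "source") <- source
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Estimate stability coefficients from baseline data
#'
#' Computes `S = 1 - SD/mean` per parameter from a baseline cohort, either
#' from subject-level long-format data (columns `group_id`, `parameter`,
#' `state`, `value`) or from per-cell summaries (columns `group_id`,
#' `parameter`, `state`, `mean`, `sd`, `n`). The source cohort is
#' configurable: a designated reference group's baseline, the pooled baseline
#' of several groups, or the mean of per-group coefficients.
#'
#' @param data long-format measurements or cell summaries (see
#'   [read_measurements()]).
#' @param state which state supplies the baseline series (default
#'   `"baseline"`, falling back to `"pre"` when no baseline rows exist —
#'   unconditioned cohorts alias the two).
#' @param groups optional character vector restricting the source cohort to
#'   these groups (default: all groups present).
#' @param policy `"pooled"`: one S per parameter from the pooled series of
#'   the selected groups (summaries cannot be pooled exactly; for summary
#'   input with more than one group use `"mean_of_groups"`); `"per_group"`:
#'   S from each group separately (returns one table per group);
#'   `"mean_of_groups"`: arithmetic mean of the per-group coefficients.
#' @return a `stability_table` (or a named list of them for `"per_group"`).
#' @export
compute_stability <- function(data, state = "baseline",
                              groups = NULL,
                              policy = c("pooled", "per_group",
                                         "mean_of_groups")) {
  policy <- match.arg(policy)
  is_summary <- all(c("mean", "sd", "n") %in% names(data))
  state <- normalize_state(state)
  st <- normalize_state(data$state)
  if (!any(st == state) && state == "baseline") state <- "pre"
  rows <- data[st == state, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("no rows in state '", state, "' to estimate stability from",
         call. = FALSE)
  if (!is.null(groups)) {
    rows <- rows[rows$group_id %in% groups, , drop = FALSE]
    if (nrow(rows) == 0)
      stop("no baseline rows for group(s): ",
           paste(groups, collapse = ", "), call. = FALSE)
  }
  per_group_S <- function(g) {
    sub <- rows[rows$group_id == g, , drop = FALSE]
    s <- vapply(split(sub, sub$parameter), function(d) {
      if (is_summary)
        stability_coefficient(mean = d$mean[1], sd = d$sd[1],
                              parameter = d$parameter[1])
      else
        stability_coefficient(d$value, parameter = d$parameter[1])
    }, numeric(1))
    src <- list(groups = g, state = state,
                n = if (is_summary) sum(sub$n) else nrow(sub))
    stability_table(s, provenance = "computed", source = src)
  }
  gs <- unique(rows$group_id)
  if (policy == "per_group")
    return(setNames(lapply(gs, per_group_S), gs))
  if (policy == "mean_of_groups") {
    tabs <- lapply(gs, per_group_S)
    nm <- sort(unique(unlist(lapply(tabs, `[[`, "name"))))
    s <- vapply(nm, function(p)
      mean(vapply(tabs, function(t) t$S[match(p, t$name)], numeric(1))),
      numeric(1))
    return(stability_table(s, provenance = "computed",
                           source = list(groups = gs, state = state,
                                         policy = "mean_of_groups")))
  }
  # pooled
  if (is_summary && length(gs) > 1)
    stop("summary cells cannot be pooled exactly across groups; ",
         "use policy = 'mean_of_groups' or restrict `groups`", call. = FALSE)
  if (is_summary) return(per_group_S(gs))
  s <- vapply(split(rows, rows$parameter), function(d)
    stability_coefficient(d$value, parameter = d$parameter[1]), numeric(1))
  stability_table(s, provenance = "computed",
                  source = list(groups = gs, state = state, n = nrow(rows)))
}
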