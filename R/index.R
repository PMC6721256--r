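#' Index of adaptedness for one subject
#'
#' Sums the signed, optionally stability-weighted response and recovery
#' terms of every parameter in the panel:
#'
#' \deqn{a = \sum_j S_j\Big(-\frac{|K_j''-K_j'|}{K_j'}
#'           - \frac{|K_j'''-K_j'|}{|K_j'''-K_j''|}\Big)
#'         + \sum_h S_h\Big(+\frac{|K_h''-K_h'|}{K_h'}
#'           - \frac{|K_h'''-K_h'|}{|K_h'''-K_h''|}\Big)}
#'
#' with `j` running over homeostatic and `h` over adaptive parameters
#' (indifferent parameters are retained as zero rows). Recovery terms are
#' included when recovery measurements are present (or as forced by
#' `options$recovery`); under `weighting = "none"` all `S` weights are 1.
#' The index has no absolute meaning — it only orders subjects or groups
#' measured under identical panels, states and options.
#'
#' @param profile a [subject_profile()].
#' @param specs a [parameter_spec()] covering every parameter in the profile.
#' @param stability a [stability_table()] (or named numeric vector of S
#'   values); required for non-indifferent parameters under stability
#'   weighting. Fixed `S` values in `specs` are used as fallback.
#' @param options an [index_options()] list.
#' @return an `adaptedness_result` with fields `scope` (`"subject"`),
#'   `value`, `breakdown` (one `term_breakdown` row per parameter in input
#'   order), `subject_id`, `group_id`, `options`, `fingerprint`.
#' @examples
#' p <- subject_profile(c("lactate", "hr"), k_pre = c(5, 40),
#'                      k_load = c(10, 100))
#' specs <- parameter_spec(c("lactate", "hr"), c("homeostatic", "adaptive"))
#' subject_index(p, specs, options = index_options(weighting = "none"))
#' @export
subject_index <- function(profile, specs, stability = NULL,
                          options = index_options()) {
  stopifnot(inherits(profile, "subject_profile"))
  idx <- match(profile$parameter, specs$name)
  if (anyNA(idx))
    stop("parameter(s) not in the panel specification: ",
         paste(profile$parameter[is.na(idx)], collapse = ", "), call. = FALSE)
  category <- specs$category[idx]
  S <- lookup_S(profile$parameter, specs, stability)
  use_rec <- switch(options$recovery,
    auto = has_recovery(profile),
    include = {
      if (!has_recovery(profile))
        stop("recovery terms requested but no recovery values present",
             call. = FALSE)
      TRUE
    },
    exclude = FALSE)
  need_S <- options$weighting == "stability" & category != "indifferent"
  if (any(need_S & !is.finite(S)))
    stop("missing stability coefficient for: ",
         paste(profile$parameter[need_S & !is.finite(S)], collapse = ", "),
         call. = FALSE)

  resp <- response_fraction(profile$k_pre, profile$k_load,
                            parameter = profile$parameter)
  if (!is.null(profile$significant))
    resp[!profile$significant] <- 0
  rec <- if (use_rec)
    recovery_fraction(profile$k_pre, profile$k_load, profile$k_rec,
                      cap = options$recovery_cap,
                      parameter = profile$parameter)
  else rep(NA_real_, nrow(profile))

  # vectorised equivalent of signed_term() row by row
  w <- rep(1, length(category))
  if (options$weighting == "stability")
    w[category != "indifferent"] <- S[category != "indifferent"]
  rec0 <- ifelse(is.na(rec), 0, rec)
  contribution <- numeric(length(category))
  hom <- category == "homeostatic"; ada <- category == "adaptive"
  contribution[hom] <- w[hom] * (-resp[hom] - rec0[hom])
  contribution[ada] <- w[ada] * (+resp[ada] - rec0[ada])
  breakdown <- data.frame(
    parameter = profile$parameter, category = category, S = S,
    response_fraction = resp, recovery_fraction = rec,
    weighting = options$weighting, contribution = contribution,
    stringsAsFactors = FALSE)
  class(breakdown) <- c("term_breakdown", "data.frame")

  out <- list(
    scope = "subject",
    value = sum(breakdown$contribution),
    breakdown = breakdown,
    subject_id = attr(profile, "subject_id"),
    group_id = attr(profile, "group_id"),
    options = options,
    recovery_used = use_rec,
    fingerprint = options_fingerprint(options, specs[idx, , drop = FALSE],
                                      use_rec)
  )
  class(out) <- "adaptedness_result"
  out
}

# resolve S per parameter: stability table first, then fixed S in specs
lookup_S <- function(parameters, specs, stability) {
  S <- rep(NA_real_, length(parameters))
  if (!is.null(stability)) {
    if (is.numeric(stability) && !is.null(names(stability)))
      stability <- stability_table(stability)
    S <- stability$S[match(parameters, stability$name)]
  }
  fixed <- specs$S[match(parameters, specs$name)]
  S[!is.finite(S)] <- fixed[!is.finite(S)]
  S
}

#' Validate profiles or group cells for a joint analysis
#'
#' Checks that the units being compared were measured and scored under
#' identical conditions, and collects data-quality warnings. Comparisons are
#' rejected (hard error) when the compared units differ in their homeostatic
#' count `m`, adaptive count `d`, parameter identities, or recovery
#' availability — an index is a sum, so differing panels make the difference
#' meaningless. Collected as warnings, not errors: parameters whose response
#' direction differs between compared groups (paradoxical-change candidates),
#' stability coefficients below 0.5, and recovery fractions above 1 (a sign
#' that the rest interval was too short).
#'
#' @param x a list of [subject_profile()]s, or a group-cell summary data
#'   frame (see [group_cells()]).
#' @param specs a [parameter_spec()].
#' @param stability optional [stability_table()].
#' @param options an [index_options()] list.
#' @return a `validation_report` list with elements `ok`, `warnings`
#'   (character), `paradoxical` (parameter names), `low_S` (parameter
#'   names).
#' @export
validate_inputs <- function(x, specs, stability = NULL,
                            options = index_options()) {
  warnings <- character()
  if (is.data.frame(x)) x <- pseudo_profiles(x)
  stopifnot(length(x) >= 1, all(vapply(x, inherits, TRUE, "subject_profile")))

  counts <- function(p) {
    cat_ <- specs$category[match(p$parameter, specs$name)]
    if (anyNA(cat_))
      stop("parameter(s) not in the panel specification: ",
           paste(p$parameter[is.na(match(p$parameter, specs$name))],
                 collapse = ", "), call. = FALSE)
    c(m = sum(cat_ == "homeostatic"), d = sum(cat_ == "adaptive"))
  }
  cnt <- vapply(x, counts, numeric(2))
  if (length(unique(cnt["m", ])) > 1 || length(unique(cnt["d", ])) > 1)
    stop("compared units differ in parameter counts (homeostatic m: ",
         paste(unique(cnt["m", ]), collapse = " vs "), "; adaptive d: ",
         paste(unique(cnt["d", ]), collapse = " vs "),
         "); the equalities m_B = m_C and d_B = d_C must hold", call. = FALSE)
  panels <- lapply(x, function(p) sort(p$parameter))
  if (length(unique(vapply(panels, paste, "", collapse = "|"))) > 1)
    stop("compared units measure different parameter panels", call. = FALSE)
  recs <- vapply(x, has_recovery, TRUE)
  if (length(unique(recs)) > 1)
    stop("recovery measurements present for some units but not others; ",
         "recovery terms must be included uniformly or dropped via ",
         "options$recovery = 'exclude'", call. = FALSE)

  # paradoxical response directions between groups
  paradoxical <- character()
  groups <- vapply(x, function(p) attr(p, "group_id"), "")
  if (length(unique(groups)) > 1) {
    for (par in x[[1]]$parameter) {
      dirs <- vapply(x, function(p) {
        i <- match(par, p$parameter)
        sign(p$k_load[i] - p$k_pre[i])
      }, numeric(1))
      by_group <- tapply(dirs, groups, function(d) unique(sign(d[d != 0])))
      nz <- unlist(by_group)
      if (length(unique(nz)) > 1) paradoxical <- c(paradoxical, par)
    }
    if (length(paradoxical))
      warnings <- c(warnings, paste0(
        "response direction differs between groups (paradoxical-change ",
        "candidate): ", paste(paradoxical, collapse = ", ")))
  }

  low_S <- character()
  if (options$weighting == "stability") {
    S <- lookup_S(x[[1]]$parameter, specs, stability)
    low_S <- x[[1]]$parameter[is.finite(S) & S < 0.5]
    if (length(low_S))
      warnings <- c(warnings, paste0("stability coefficient below 0.5 for: ",
                                     paste(low_S, collapse = ", ")))
  }

  if (any(recs)) {
    big <- unique(unlist(lapply(x, function(p) {
      ok <- abs(p$k_rec - p$k_load) > 0
      fr <- ifelse(p$k_rec == p$k_pre, 0,
                   abs(p$k_rec - p$k_pre) / abs(p$k_rec - p$k_load))
      p$parameter[ok & fr > 1]
    })))
    if (length(big))
      warnings <- c(warnings, paste0(
        "recovery fraction above 1 (rest interval possibly too short) for: ",
        paste(big, collapse = ", ")))
  }

  out <- list(ok = TRUE, warnings = warnings, paradoxical = paradoxical,
              low_S = low_S)
  class(out) <- "validation_report"
  out
}
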