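#' Analysis options
#'
#' Bundles the options under which indices are computed. Results are only
#' comparable when computed under identical options and parameter panels; the
#' fingerprint recorded in every result enforces this.
#'
#' @param weighting `"stability"` (each term multiplied by its stability
#'   coefficient S; the default) or `"none"` (unweighted sum).
#' @param recovery `"auto"` (include recovery terms iff recovery measurements
#'   are present), `"include"`, or `"exclude"`.
#' @param alpha significance level used when zeroing non-significant changes
#'   (default 0.05).
#' @param conf_level confidence level for group intervals (default 0.95).
#' @param recovery_cap optional finite substitute for an undefined recovery
#'   fraction (parameter unchanged during rest); default `NULL` = error.
#' @param test pairwise group test: `"welch"` (two-sample Welch t) or
#'   `"permutation"` (label-shuffling, seeded).
#' @param permutations number of permutations for the permutation test.
#' @return an `index_options` list.
#' @export
index_options <- function(weighting = c("stability", "none"),
                          recovery = c("auto", "include", "exclude"),
                          alpha = 0.05, conf_level = 0.95,
                          recovery_cap = NULL,
                          test = c("welch", "permutation"),
                          permutations = 1999L) {
  opts <- list(
    weighting = match.arg(weighting),
    recovery = match.arg(recovery),
    alpha = alpha,
    conf_level = conf_level,
    recovery_cap = recovery_cap,
    test = match.arg(test),
    permutations = as.integer(permutations)
  )
  stopifnot(alpha > 0, alpha < 1, conf_level > 0, conf_level < 1)
  class(opts) <- "index_options"
  opts
}

# comparability fingerprint: options + panel composition
options_fingerprint <- function(options, specs, recovery_used) {
  paste(options$weighting,
        if (recovery_used) "recovery" else "no-recovery",
        paste(specs$name, specs$category, sep = ":", collapse = ","),
        sep = "|")
}

#' Signed, weighted contribution of one parameter
#'
#' Combines a parameter's response fraction and (optionally) recovery
#' fraction into its signed contribution to the index. Homeostatic
#' parameters contribute `w * (-response - recovery)`: any deflection under
#' load, and any sluggish recovery, count against adaptedness. Adaptive
#' parameters contribute `w * (+response - recovery)`: stronger activation of
#' compensatory machinery counts in favour, slow deactivation against.
#' Indifferent parameters contribute 0. The weight `w` is the stability
#' coefficient `S` under stability weighting and 1 otherwise.
#'
#' @param category parameter category (`"homeostatic"`, `"adaptive"`,
#'   `"indifferent"`).
#' @param S stability coefficient in (0, 1].
#' @param resp non-negative response fraction.
#' @param rec non-negative recovery fraction, or `NA` when recovery terms are
#'   excluded (treated as 0).
#' @param weighting `"stability"` or `"none"`.
#' @param name optional parameter name carried into the breakdown row.
#' @return a one-row `term_breakdown` data frame with columns `parameter`,
#'   `category`, `S`, `response_fraction`, `recovery_fraction`, `weighting`,
#'   `contribution`.
#' @examples
#' signed_term("homeostatic", S = 0.893, resp = 0.530)            # -0.473
#' signed_term("adaptive", S = 1, resp = 2.059, rec = 0.027,
#'             weighting = "none")                                # +2.032
#' @export
signed_term <- function(category, S, resp, rec = NA_real_,
                        weighting = c("stability", "none"),
                        name = NA_character_) {
  weighting <- match.arg(weighting)
  if (!category %in% PARAM_CATEGORIES)
    stop("unknown parameter category: ", category, call. = FALSE)
  stopifnot(is.finite(resp), resp >= 0)
  if (!is.na(rec)) stopifnot(is.finite(rec), rec >= 0)
  if (weighting == "stability" && category != "indifferent") {
    stopifnot(is.finite(S), S > 0, S <= 1)
    w <- S
  } else w <- 1
  rec0 <- if (is.na(rec)) 0 else rec
  contribution <- switch(category,
    homeostatic = w * (-resp - rec0),
    adaptive    = w * (+resp - rec0),
    indifferent = 0
  )
  out <- data.frame(
    parameter = name, category = category, S = S,
    response_fraction = resp, recovery_fraction = rec,
    weighting = weighting, contribution = contribution,
    stringsAsFactors = FALSE
  )
  class(out) <- c("term_breakdown", "data.frame")
  out
}
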