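#' Physiological state labels
#'
#' The four states of a subject recognised by the index: `baseline` (intact
#' state before any conditioning factor; used only to estimate stability
#' coefficients), `pre` (after conditioning, immediately before the provoking
#' load), `load` (immediately after the load) and `recovery` (after a rest
#' interval). `pre` and `load` are mandatory for any index computation;
#' `recovery` is optional. For unconditioned subjects baseline and pre may
#' alias the same measurements.
#'
#' @format A character vector of the four canonical labels.
#' @export
STATE_LABELS <- c("baseline", "pre", "load", "recovery")

# accepted synonyms in input files (case-insensitive)
.state_synonyms <- c(
  f0 = "baseline", baseline = "baseline", rest0 = "baseline",
  f1 = "pre",      pre = "pre",           rest = "pre",
  f2 = "load",     load = "load",         post = "load",
  f3 = "recovery", recovery = "recovery", rec = "recovery"
)

#' Normalise state labels
#'
#' Maps the accepted synonyms (`F0`/`F1`/`F2`/`F3`, `baseline`/`pre`/`load`/
#' `recovery`, `rest`/`post`/`rec`) to the canonical labels, case-insensitively.
#'
#' @param x character vector of state labels as found in an input file.
#' @return character vector of canonical labels.
#' @examples
#' normalize_state(c("F1", "F2", "Recovery"))
#' @export
normalize_state <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- .state_synonyms[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         " (accepted: F0/F1/F2/F3 or baseline/pre/load/recovery)",
         call. = FALSE)
  }
  unname(out)
}

PARAM_CATEGORIES <- c("homeostatic", "adaptive", "indifferent")
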