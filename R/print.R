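#' @export
print.adaptedness_result <- function(x, digits = 3, ...) {
  cat("Index of adaptedness (", x$scope, ")\n", sep = "")
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$group_id)) cat("  group:  ", x$group_id, "\n")
  cat("  a =", formatC(x$value, digits = digits, format = "f"), "\n")
  cat("  weighting:", x$options$weighting,
      "| recovery terms:", if (x$recovery_used) "included" else "absent",
      "\n\n")
  b <- x$breakdown
  b$response_fraction <- round(b$response_fraction, digits)
  b$recovery_fraction <- round(b$recovery_fraction, digits)
  b$contribution <- round(b$contribution, digits)
  print.data.frame(b, row.names = FALSE)
  invisible(x)
}

#' @export
print.subject_comparison <- function(x, digits = 3, ...) {
  ab <- x$result_b$value; ac <- x$result_c$value
  cat("Pairwise comparison of adaptedness\n")
  cat(sprintf("  a(%s) = %.*f   a(%s) = %.*f\n",
              x$result_b$subject_id, digits, ab,
              x$result_c$subject_id, digits, ac))
  cat("  verdict:",
      switch(x$verdict,
             B = paste(x$result_b$subject_id, "is more adaptive"),
             C = paste(x$result_c$subject_id, "is more adaptive"),
             equal = "equal within tolerance"), "\n")
  for (w in x$validation$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat("Group adaptedness comparison (design ", x$design, ")\n", sep = "")
  if (!is.null(x$uncertainty) && x$uncertainty != "none")
    cat("  uncertainty:", x$uncertainty, "\n")
  g <- x$groups
  num <- vapply(g, is.numeric, TRUE) & names(g) != "n"
  g[num] <- lapply(g[num], round, digits)
  print.data.frame(g, row.names = FALSE)
  if (!is.null(x$pairwise) && nrow(x$pairwise)) {
    cat("\nPairwise tests (raw p, no multiplicity correction):\n")
    p <- x$pairwise
    p$statistic <- round(p$statistic, digits)
    p$p <- signif(p$p, 3)
    print.data.frame(p, row.names = FALSE)
  }
  for (w in x$validation$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation:", if (x$ok) "OK" else "FAILED", "\n")
  if (length(x$warnings))
    cat(paste0("  warning: ", x$warnings, collapse = "\n"), "\n")
  else cat("  no warnings\n")
  invisible(x)
}
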