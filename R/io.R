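#' Read tabular study measurements
#'
#' Reads delimiter-separated text (comma or tab, auto-detected, header
#' mandatory, UTF-8). Two schemas are understood:
#'
#' * subject-level long format (designs `case1`/`case2`): columns
#'   `subject_id`, `group_id`, `parameter`, `state`, `value` — returned as a
#'   list of [subject_profile()]s;
#' * cell-summary format (design `case3`): columns `group_id`, `parameter`,
#'   `state`, `mean`, `sd`, `n` — returned as a [group_cells()] table.
#'
#' State labels accept the synonyms listed in [normalize_state()]. Duplicate
#' keys, unknown states, and non-numeric values are reported with their row
#' numbers.
#'
#' @param path file path.
#' @param design `"case1"`, `"case2"` or `"case3"`.
#' @return list of `subject_profile`s, or a `group_cells` data frame.
#' @export
read_measurements <- function(path, design = c("case2", "case1", "case3")) {
  design <- match.arg(design)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  rowno <- seq_len(nrow(df)) + 1L  # +1 for header

  check_numeric <- function(col) {
    v <- df[[col]]
    if (is.character(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- is.na(suppress) & !is.na(v)
      if (any(bad))
        stop("non-numeric '", col, "' at row(s) ",
             paste(rowno[bad], collapse = ", "), " of ", path, call. = FALSE)
      v <- suppress
    }
    if (anyNA(v))
      stop("missing '", col, "' at row(s) ",
           paste(rowno[is.na(v)], collapse = ", "), " of ", path,
           call. = FALSE)
    v
  }
  check_state <- function() {
    st <- tolower(trimws(as.character(df$state)))
    bad <- !st %in% names(.state_synonyms)
    if (any(bad))
      stop("unknown state label(s) ",
           paste(unique(df$state[bad]), collapse = ", "), " at row(s) ",
           paste(rowno[bad], collapse = ", "), " of ", path, call. = FALSE)
    normalize_state(df$state)
  }

  if (design == "case3") {
    need <- c("group_id", "parameter", "state", "mean", "sd", "n")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing column(s) for case3 input: ",
           paste(miss, collapse = ", "), call. = FALSE)
    df$state <- check_state()
    key <- with(df, paste(group_id, parameter, state))
    if (anyDuplicated(key))
      stop("duplicate (group, parameter, state) at row(s) ",
           paste(rowno[duplicated(key)], collapse = ", "), " of ", path,
           call. = FALSE)
    return(group_cells(df$group_id, df$parameter, df$state,
                       check_numeric("mean"), check_numeric("sd"),
                       check_numeric("n")))
  }

  need <- c("subject_id", "group_id", "parameter", "state", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) for subject-level input: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$state <- check_state()
  df$value <- check_numeric("value")
  key <- with(df, paste(subject_id, parameter, state))
  if (anyDuplicated(key))
    stop("duplicate (subject, parameter, state) at row(s) ",
         paste(rowno[duplicated(key)], collapse = ", "), " of ", path,
         call. = FALSE)
  profiles_from_long(df)
}

#' Read an analysis configuration file
#'
#' YAML with top-level keys `design` (`case1`/`case2`/`case3`), `weighting`
#' (`stability`/`none`), `recovery` (`auto`/`include`/`exclude`), optional
#' `alpha`, `conf_level`, `stability_source` (`policy`, `state`, `groups`),
#' `metadata`, and a `parameters` list of `{name, category, units, S}`
#' entries. Every parameter appearing in the data must be declared here.
#'
#' @param path YAML file path.
#' @return a `study_config` list: `design`, `specs` ([parameter_spec()]),
#'   `options` ([index_options()]), `stability` (a [stability_table()] when
#'   all S are supplied, else `NULL`), `stability_source`, `metadata`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters) || !length(cfg$parameters))
    stop("config must declare a 'parameters' list", call. = FALSE)
  design <- match.arg(cfg$design %||% "case2", c("case1", "case2", "case3"))
  specs <- parameter_spec(
    name = vapply(cfg$parameters, function(p) as.character(p$name), ""),
    category = vapply(cfg$parameters, function(p) as.character(p$category),
                      ""),
    units = vapply(cfg$parameters,
                   function(p) as.character(p$units %||% NA_character_), ""),
    S = vapply(cfg$parameters, function(p) as.numeric(p$S %||% NA_real_),
               numeric(1))
  )
  options <- index_options(
    weighting = cfg$weighting %||% "stability",
    recovery = cfg$recovery %||% "auto",
    alpha = cfg$alpha %||% 0.05,
    conf_level = cfg$conf_level %||% 0.95,
    recovery_cap = cfg$recovery_cap,
    test = cfg$test %||% "welch"
  )
  stability <- NULL
  if (all(is.finite(specs$S)))
    stability <- suppressWarnings(
      stability_table(setNames(specs$S, specs$name)))
  out <- list(design = design, specs = specs, options = options,
              stability = stability,
              stability_source = cfg$stability_source,
              metadata = cfg$metadata)
  class(out) <- "study_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a bundled worked example
#'
#' Two published studies ship with the package, transcribed from their
#' printed tables:
#'
#' * `example1_rats`: rat biochemistry under an acute swimming load after
#'   training and/or eleutheroside administration — 4 groups (B control
#'   untrained, C control trained, D eleutherosides untrained, E
#'   eleutherosides trained), 5 parameters (plasma 11-hydroxycorticosteroids
#'   adaptive; muscle hexokinase, blood ammonia, muscle glycogen, blood
#'   lactate homeostatic), rest and post-swim states, destructively sampled.
#'   Stability weighting on, recovery terms absent, S as printed.
#' * `example2_horses`: race horses before/after a race with 1 h recovery —
#'   2 groups, 6 parameters (blood oxygen release capacities P95/P50,
#'   hemoglobin, heart rate adaptive; lactate, reserve alkalinity
#'   homeostatic), n = 6. Unweighted mode (the published index aggregates
#'   unweighted terms), recovery terms included. A semi-quantitative
#'   perspiration score in the source is excluded from the panel.
#'
#' @param name `"example1_rats"` or `"example2_horses"`.
#' @return a list: `name`, `data` (a [group_cells()] table), `config` (a
#'   `study_config`), `printed` (list of `terms` and `index` data frames of
#'   the published per-term values, group indices and ranks, for
#'   reproduction checks), `paths`.
#' @examples
#' fx <- load_fixture("example1_rats")
#' head(fx$data)
#' @export
load_fixture <- function(name = c("example1_rats", "example2_horses")) {
  name <- match.arg(name)
  dir <- system.file("extdata", package = "adaptindex", mustWork = TRUE)
  paths <- list(
    data = file.path(dir, paste0(name, ".tsv")),
    config = file.path(dir, paste0(name, ".yaml")),
    terms = file.path(dir, paste0(name, "_printed_terms.tsv")),
    index = file.path(dir, paste0(name, "_printed_index.tsv"))
  )
  config <- read_study_config(paths$config)
  data <- read_measurements(paths$data, design = config$design)
  printed <- list(
    terms = utils::read.delim(paths$terms, stringsAsFactors = FALSE),
    index = utils::read.delim(paths$index, stringsAsFactors = FALSE)
  )
  list(name = name, data = data, config = config, printed = printed,
       paths = paths)
}

#' Write an analysis report
#'
#' `tsv`: a human-readable table mirroring the published layout — one row
#' per parameter, one column per group with the signed contribution at 3
#' decimals, final rows `A` and `adaptive_rank`; commented header lines
#' carry the options fingerprint and any validation warnings. `json`: a
#' machine-readable twin of the full result object at full precision that
#' round-trips through [read_report()].
#'
#' @param results a `group_comparison` (from [group_index_repeated()] or
#'   [group_index_destructive()]).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(results, "group_comparison"))
  if (format == "json") {
    payload <- unclass(results)
    payload$options <- unclass(payload$options)
    payload$validation <- unclass(payload$validation)
    payload$breakdown <- lapply(payload$breakdown, as.data.frame)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    return(invisible(path))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# fingerprint: ", results$fingerprint), con)
  writeLines(paste0("# design: ", results$design), con)
  if (!is.null(results$uncertainty) && results$uncertainty != "none")
    writeLines(paste0("# uncertainty: ", results$uncertainty), con)
  for (w in results$validation$warnings)
    writeLines(paste0("# warning: ", w), con)
  g <- results$groups
  if (!is.null(results$breakdown)) {
    params <- results$breakdown[[1]]$parameter
    mat <- vapply(results$breakdown[g$group_id], function(b)
      b$contribution[match(params, b$parameter)], numeric(length(params)))
    mat <- matrix(mat, nrow = length(params),
                  dimnames = list(params, g$group_id))
    body <- data.frame(parameter = params,
                       apply(mat, 2, function(x) sprintf("%.3f", x)),
                       check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    body <- NULL
  }
  header <- c("parameter", g$group_id)
  writeLines(paste(header, collapse = "\t"), con)
  if (!is.null(body))
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  writeLines(paste(c("A", sprintf("%.3f", g$A)), collapse = "\t"), con)
  if (!all(is.na(g$sd)))
    writeLines(paste(c("SD", sprintf("%.3f", g$sd)), collapse = "\t"), con)
  writeLines(paste(c("n", g$n), collapse = "\t"), con)
  writeLines(paste(c("adaptive_rank", g$rank), collapse = "\t"), con)
  invisible(path)
}

#' Read back a JSON report
#'
#' Restores the `group_comparison` object written by
#' [write_report(format = "json")][write_report()].
#'
#' @param path JSON file path.
#' @return a `group_comparison`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$groups <- as.data.frame(x$groups, stringsAsFactors = FALSE)
  x$groups$rank <- setNames(as.integer(x$groups$rank), x$groups$group_id)
  if (!is.null(x$subject_a))
    x$subject_a <- as.data.frame(x$subject_a, stringsAsFactors = FALSE)
  if (!is.null(x$pairwise) && length(x$pairwise))
    x$pairwise <- as.data.frame(x$pairwise, stringsAsFactors = FALSE)
  if (!is.null(x$breakdown))
    x$breakdown <- lapply(x$breakdown, function(b) {
      b <- as.data.frame(b, stringsAsFactors = FALSE)
      class(b) <- c("term_breakdown", "data.frame")
      b
    })
  opts <- x$options
  x$options <- index_options(
    weighting = opts$weighting, recovery = opts$recovery,
    alpha = opts$alpha, conf_level = opts$conf_level,
    recovery_cap = opts$recovery_cap, test = opts$test,
    permutations = opts$permutations)
  x$validation <- structure(
    list(ok = isTRUE(x$validation$ok),
         warnings = as.character(unlist(x$validation$warnings %||%
                                          character())),
         paradoxical = as.character(unlist(x$validation$paradoxical %||%
                                             character())),
         low_S = as.character(unlist(x$validation$low_S %||% character()))),
    class = "validation_report")
  class(x) <- "group_comparison"
  x
}
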