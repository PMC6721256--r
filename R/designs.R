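#' Group-cell summaries for destructively sampled designs
#'
#' In many biochemical studies each state is measured on different animals
#' (the measurement is terminal), so no subject has a full profile. The
#' design is then described by per-cell summaries — one (mean, SD, n) per
#' (group, parameter, state) — and group means substitute for individual
#' values in the index.
#'
#' @param group_id,parameter,state,mean,sd,n vectors of equal length, one
#'   entry per cell; `mean > 0`, `sd >= 0`, `n >= 1`.
#' @return a `group_cells` data frame.
#' @export
group_cells <- function(group_id, parameter, state, mean, sd, n) {
  state <- normalize_state(state)
  out <- data.frame(group_id = as.character(group_id),
                    parameter = as.character(parameter),
                    state = state, mean = as.numeric(mean),
                    sd = as.numeric(sd), n = as.integer(n),
                    stringsAsFactors = FALSE)
  key <- with(out, paste(group_id, parameter, state))
  if (anyDuplicated(key))
    stop("duplicate (group, parameter, state) cells: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  if (any(!is.finite(out$mean)) || any(out$mean <= 0))
    stop("cell means must be finite and > 0", call. = FALSE)
  if (any(!is.finite(out$sd)) || any(out$sd < 0))
    stop("cell SDs must be finite and >= 0", call. = FALSE)
  if (any(is.na(out$n)) || any(out$n < 1))
    stop("cell n must be >= 1", call. = FALSE)
  class(out) <- c("group_cells", "data.frame")
  out
}

# one pseudo-profile per group built from cell means (mean substitution)
pseudo_profiles <- function(cells) {
  stopifnot(is.data.frame(cells))
  groups <- unique(cells$group_id)
  missing <- character()
  profs <- list()
  for (g in groups) {
    sub <- cells[cells$group_id == g, , drop = FALSE]
    params <- unique(sub$parameter)
    grab <- function(st) {
      v <- sub$mean[sub$state == st][match(params,
             sub$parameter[sub$state == st])]
      v
    }
    pre <- grab("pre")
    if (all(is.na(pre))) pre <- grab("baseline")
    load <- grab("load")
    bad_pre <- params[is.na(pre)]
    bad_load <- params[is.na(load)]
    if (length(bad_pre))
      missing <- c(missing, paste0(g, "/", bad_pre, "/pre"))
    if (length(bad_load))
      missing <- c(missing, paste0(g, "/", bad_load, "/load"))
    rec <- grab("recovery")
    if (any(is.na(rec)) && !all(is.na(rec)))
      missing <- c(missing, paste0(g, "/", params[is.na(rec)], "/recovery"))
    if (length(missing)) next
    mask <- attr(cells, "zero_mask")
    signif <- NULL
    if (!is.null(mask)) {
      mg <- mask[mask$group_id == g, , drop = FALSE]
      signif <- !mg$zeroed[match(params, mg$parameter)]
      signif[is.na(signif)] <- TRUE
    }
    profs[[g]] <- subject_profile(params, k_pre = pre, k_load = load,
                                  k_rec = if (all(is.na(rec))) NULL else rec,
                                  subject_id = paste0("group-mean:", g),
                                  group_id = g, significant = signif)
  }
  if (length(missing))
    stop("missing cell(s) (group/parameter/state): ",
         paste(missing, collapse = ", "), call. = FALSE)
  profs
}

#' Compare two subjects' adaptedness
#'
#' Computes both indices under identical options after joint validation and
#' reports which subject is more adaptive to the load. The indices have no
#' absolute meaning; only this ordering does.
#'
#' @param profile_b,profile_c [subject_profile()]s over the same panel.
#' @param specs,stability,options as in [subject_index()].
#' @param tol absolute tolerance below which the two indices are declared
#'   equal.
#' @return a `subject_comparison` list: `result_b`, `result_c`, `verdict`
#'   (`"B"`, `"C"` or `"equal"`), `validation`.
#' @export
compare_subjects <- function(profile_b, profile_c, specs, stability = NULL,
                             options = index_options(), tol = 1e-9) {
  report <- validate_inputs(list(profile_b, profile_c), specs, stability,
                            options)
  rb <- subject_index(profile_b, specs, stability, options)
  rc <- subject_index(profile_c, specs, stability, options)
  verdict <- if (abs(rb$value - rc$value) <= tol) "equal"
             else if (rb$value > rc$value) "B" else "C"
  out <- list(result_b = rb, result_c = rc, verdict = verdict,
              validation = report)
  class(out) <- "subject_comparison"
  out
}

#' Group index for repeated-measure designs
#'
#' Case II: every subject is measured in every state, so each subject gets an
#' individual index `a`; the group index `A` is the mean of its subjects'
#' values, with sample SD, a normal-approximation confidence interval, a
#' descending rank, and pairwise between-group tests of the `a` values
#' (Welch's t by default, or a seeded permutation test for small groups).
#'
#' @param profiles list of [subject_profile()]s; group membership is taken
#'   from each profile's `group_id`.
#' @param specs,stability,options as in [subject_index()].
#' @param seed seed for the permutation test (ignored for Welch).
#' @return a `group_comparison` list: `groups` data frame (`group_id`, `A`,
#'   `sd`, `n`, `ci_lo`, `ci_hi`, `rank`), `pairwise` data frame, `subject_a`
#'   data frame of individual indices, `validation`, `fingerprint`,
#'   `options`.
#' @export
group_index_repeated <- function(profiles, specs, stability = NULL,
                                 options = index_options(), seed = NULL) {
  report <- validate_inputs(profiles, specs, stability, options)
  res <- lapply(profiles, subject_index, specs = specs,
                stability = stability, options = options)
  a <- vapply(res, `[[`, numeric(1), "value")
  grp <- vapply(res, `[[`, character(1), "group_id")
  subject_a <- data.frame(
    subject_id = vapply(res, `[[`, character(1), "subject_id"),
    group_id = grp, a = a, stringsAsFactors = FALSE, row.names = NULL)

  z <- qnorm(1 - (1 - options$conf_level) / 2)
  gs <- unique(grp)
  groups <- do.call(rbind, lapply(gs, function(g) {
    ai <- a[grp == g]
    n <- length(ai)
    if (n < 2)
      warning("group ", g, " has a single subject; no dispersion estimate",
              call. = FALSE)
    s <- if (n >= 2) sd(ai) else NA_real_
    se <- if (n >= 2) s / sqrt(n) else NA_real_
    data.frame(group_id = g, A = mean(ai), sd = s, n = n,
               ci_lo = mean(ai) - z * se, ci_hi = mean(ai) + z * se,
               stringsAsFactors = FALSE)
  }))
  groups$rank <- rank_groups(setNames(groups$A, groups$group_id))

  pairwise <- pairwise_tests(subject_a, options, seed)
  out <- list(groups = groups, pairwise = pairwise, subject_a = subject_a,
              validation = report,
              fingerprint = res[[1]]$fingerprint, options = options,
              design = "case2")
  class(out) <- "group_comparison"
  out
}

pairwise_tests <- function(subject_a, options, seed = NULL) {
  gs <- unique(subject_a$group_id)
  if (length(gs) < 2)
    return(data.frame(group_1 = character(), group_2 = character(),
                      statistic = numeric(), p = numeric(),
                      test = character(), stringsAsFactors = FALSE))
  combos <- utils::combn(gs, 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    x <- subject_a$a[subject_a$group_id == g1]
    y <- subject_a$a[subject_a$group_id == g2]
    degenerate <- (length(x) < 2 || length(y) < 2 ||
                   (sd(x) == 0 && sd(y) == 0))
    if (options$test == "welch") {
      if (degenerate) {
        stat <- NA_real_; p <- NA_real_
      } else {
        tt <- stats::t.test(x, y)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      test <- "welch"
    } else {
      if (!is.null(seed)) set.seed(seed + i)
      obs <- mean(x) - mean(y)
      pool <- c(x, y); nx <- length(x)
      perm <- replicate(options$permutations, {
        sh <- sample(pool)
        mean(sh[seq_len(nx)]) - mean(sh[-seq_len(nx)])
      })
      stat <- obs
      p <- (1 + sum(abs(perm) >= abs(obs))) / (options$permutations + 1)
      test <- "permutation"
    }
    data.frame(group_1 = g1, group_2 = g2, statistic = stat, p = p,
               test = test, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group index for destructively sampled designs
#'
#' Case III: different animals are sampled at each state, so group means
#' substitute for individual values — one pseudo-profile per group is built
#' from the cell means and scored with [subject_index()]. The source data
#' give no subject-level dispersion for the index; an uncertainty estimate
#' is available as a beyond-source extension via [bootstrap_uncertainty()]
#' (`bootstrap > 0`).
#'
#' @param cells a [group_cells()] summary table.
#' @param specs,stability,options as in [subject_index()].
#' @param bootstrap number of parametric-bootstrap replicates for the
#'   uncertainty extension (0 = none).
#' @param seed seed for the bootstrap.
#' @return a `group_comparison` list as in [group_index_repeated()] (with
#'   `sd`/intervals `NA` or bootstrap-based, and `uncertainty =
#'   "parametric bootstrap (beyond-source extension)"` when used).
#' @export
group_index_destructive <- function(cells, specs, stability = NULL,
                                    options = index_options(),
                                    bootstrap = 0, seed = NULL) {
  profs <- pseudo_profiles(cells)
  report <- validate_inputs(profs, specs, stability, options)
  res <- lapply(profs, subject_index, specs = specs, stability = stability,
                options = options)
  A <- vapply(res, `[[`, numeric(1), "value")
  n_per_group <- vapply(names(profs), function(g)
    min(cells$n[cells$group_id == g]), numeric(1))
  groups <- data.frame(group_id = names(profs), A = A,
                       sd = NA_real_, n = as.integer(n_per_group),
                       ci_lo = NA_real_, ci_hi = NA_real_,
                       stringsAsFactors = FALSE, row.names = NULL)
  uncertainty <- "none"
  if (bootstrap > 0) {
    bt <- bootstrap_uncertainty(cells, specs, stability, options,
                                replicates = bootstrap, seed = seed)
    groups$sd <- bt$sd[match(groups$group_id, bt$group_id)]
    groups$ci_lo <- bt$ci_lo[match(groups$group_id, bt$group_id)]
    groups$ci_hi <- bt$ci_hi[match(groups$group_id, bt$group_id)]
    uncertainty <- "parametric bootstrap (beyond-source extension)"
  }
  groups$rank <- rank_groups(setNames(groups$A, groups$group_id))
  out <- list(groups = groups, pairwise = NULL,
              breakdown = lapply(res, `[[`, "breakdown"),
              validation = report, fingerprint = res[[1]]$fingerprint,
              options = options, design = "case3", uncertainty = uncertainty)
  class(out) <- "group_comparison"
  out
}

#' Parametric-bootstrap uncertainty for destructively sampled designs
#'
#' The source model leaves the dispersion of a mean-substituted index as an
#' open problem. This extension resamples each cell mean from
#' `Normal(mean, sd/sqrt(n))` (the standard error of the cell mean),
#' recomputes `A` per replicate, and reports the empirical SD and percentile
#' interval. Deterministic under a fixed seed. Clearly an extension beyond
#' the published method; reports label it as such.
#'
#' @param cells a [group_cells()] table; every cell needs `sd` and `n`.
#' @param specs,stability,options as in [subject_index()].
#' @param replicates number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return data frame `group_id`, `sd`, `ci_lo`, `ci_hi`, `replicates`.
#' @export
bootstrap_uncertainty <- function(cells, specs, stability = NULL,
                                  options = index_options(),
                                  replicates = 1000, seed = NULL) {
  stopifnot(replicates >= 100)
  bad <- !is.finite(cells$sd) | !is.finite(cells$n)
  if (any(bad))
    stop("cells lacking sd/n: ",
         paste(paste0(cells$group_id[bad], "/", cells$parameter[bad], "/",
                      cells$state[bad]), collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  se <- cells$sd / sqrt(cells$n)
  groups <- unique(cells$group_id)
  alpha <- 1 - options$conf_level
  draws <- matrix(NA_real_, nrow = replicates, ncol = length(groups),
                  dimnames = list(NULL, groups))
  for (r in seq_len(replicates)) {
    cells_r <- cells
    cells_r$mean <- rnorm(nrow(cells), cells$mean, se)
    # keep resampled means physiologically positive
    cells_r$mean <- pmax(cells_r$mean, 1e-6 * cells$mean)
    profs <- pseudo_profiles(cells_r)
    for (g in groups) {
      val <- tryCatch(
        subject_index(profs[[g]], specs, stability, options)$value,
        error = function(e) NA_real_)
      draws[r, g] <- val
    }
  }
  data.frame(
    group_id = groups,
    sd = apply(draws, 2, sd, na.rm = TRUE),
    ci_lo = apply(draws, 2, quantile, probs = alpha / 2, na.rm = TRUE),
    ci_hi = apply(draws, 2, quantile, probs = 1 - alpha / 2, na.rm = TRUE),
    replicates = replicates,
    failed = apply(draws, 2, function(x) sum(is.na(x))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Zero statistically non-significant load responses
#'
#' Changes that do not reach significance — in particular "paradoxical" ones
#' running against the group consensus — can be treated as zero response.
#' Either a user-supplied logical mask is applied, or (for summary cells) a
#' Welch two-sample test between the pre-load and post-load cells decides per
#' parameter. Off by default in all pipelines: silently zeroing terms would
#' change published-table reproduction, so the caller must opt in.
#'
#' @param x a [subject_profile()] (mask mode) or [group_cells()] (test mode).
#' @param mask logical vector, one entry per profile parameter (TRUE =
#'   significant, keep).
#' @param alpha significance level for the automatic test (default 0.05).
#' @return the masked copy, with attribute `zeroing_log`: a data frame of
#'   parameters, p-values (test mode) and actions.
#' @export
zero_insignificant <- function(x, mask = NULL, alpha = 0.05) {
  if (inherits(x, "subject_profile")) {
    if (is.null(mask))
      stop("a logical mask is required to zero terms of a single profile ",
           "(no replicate information to test with)", call. = FALSE)
    stopifnot(is.logical(mask), length(mask) == nrow(x))
    x$significant <- mask
    attr(x, "zeroing_log") <- data.frame(
      parameter = x$parameter, p = NA_real_,
      zeroed = !mask, stringsAsFactors = FALSE)
    return(x)
  }
  if (!all(c("mean", "sd", "n") %in% names(x)))
    stop("automatic zeroing needs summary cells with mean, sd, n ",
         "(or supply a mask on a profile)", call. = FALSE)
  cells <- x
  key <- unique(cells[, c("group_id", "parameter")])
  log <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    g <- key$group_id[i]; p <- key$parameter[i]
    pre <- cells[cells$group_id == g & cells$parameter == p &
                   cells$state == "pre", , drop = FALSE]
    if (nrow(pre) == 0)
      pre <- cells[cells$group_id == g & cells$parameter == p &
                     cells$state == "baseline", , drop = FALSE]
    post <- cells[cells$group_id == g & cells$parameter == p &
                    cells$state == "load", , drop = FALSE]
    if (nrow(pre) == 0 || nrow(post) == 0)
      stop("cannot test ", g, "/", p, ": missing pre or load cell",
           call. = FALSE)
    pv <- welch_p_from_summary(pre$mean, pre$sd, pre$n,
                               post$mean, post$sd, post$n)
    data.frame(group_id = g, parameter = p, p = pv,
               zeroed = is.na(pv) || pv > alpha, stringsAsFactors = FALSE)
  }))
  out <- cells
  attr(out, "zeroing_log") <- log
  attr(out, "zero_mask") <- log
  class(out) <- class(cells)
  out
}

# Welch two-sample t-test p-value from summary statistics
welch_p_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  if (v1 + v2 == 0) return(if (m1 == m2) NA_real_ else 0)
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}

#' Rank groups by adaptedness
#'
#' Descending order: rank 1 is the largest `A` (most adaptive group). Ties
#' receive equal (dense) ranks, broken nowhere — a warning reminds the caller
#' that tied groups are not distinguishable.
#'
#' @param A named numeric vector of group indices.
#' @return integer vector of ranks, in the input order, named like `A`.
#' @examples
#' rank_groups(c(B = -1.665, C = 1.043, D = -0.272, E = -0.382))
#' @export
rank_groups <- function(A) {
  stopifnot(is.numeric(A), length(A) >= 1)
  if (anyDuplicated(A))
    warning("tied adaptedness indices; tied groups share a dense rank",
            call. = FALSE)
  r <- match(-A, sort(unique(-A)))
  setNames(as.integer(r), names(A))
}
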