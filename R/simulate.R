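#' Default synthetic biomarker panel
#'
#' A five-parameter exercise-physiology panel used by the simulator when no
#' panel is supplied: three homeostatic variables (blood lactate, muscle
#' glycogen, blood ammonia) that deflect under load, and two adaptive ones
#' (plasma corticosterone, heart rate) whose activation scales with fitness.
#' Baseline means and SDs are typical resting rodent values; the relative
#' load effects `delta` (homeostatic deflection of a completely unadapted
#' subject) and `gamma` (adaptive activation of a fully adapted subject) are
#' of the magnitude seen in acute exhaustive exercise.
#'
#' @return a data frame with columns `name`, `category`, `mu`, `sigma`,
#'   `delta`, `gamma`.
#' @export
default_sim_parameters <- function() {
  data.frame(
    name = c("lactate", "glycogen", "ammonia", "corticosterone",
             "heart_rate"),
    category = c("homeostatic", "homeostatic", "homeostatic", "adaptive",
                 "adaptive"),
    mu = c(5.5, 700, 90, 12, 40),
    sigma = c(1.0, 180, 14, 2.4, 3.5),
    delta = c(1.7, 0.9, 1.0, 0, 0),
    gamma = c(0, 0, 0, 2.0, 2.0),
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic cohort study
#'
#' Describes the generative model. Each subject's pre-load value is
#' `K' ~ Normal(mu, sigma)` per parameter. Under load, a homeostatic
#' parameter shifts by the relative amount `delta * (1 - theta)` — a fully
#' adapted group (`theta = 1`) shows no homeostatic deflection — and an
#' adaptive parameter by `gamma * theta` — adaptive machinery activates in
#' proportion to adaptedness. During the rest interval every parameter
#' returns the fraction `rho(theta) = rho0 + rho1 * theta` of the way back
#' to its pre-load value: recovery accelerates with adaptedness. All effects
#' are multiplicative (relative), matching the relative fractions the index
#' is built on; Gaussian stage noise of relative SD `noise_sd` is added at
#' the load and recovery stages. Generated values are clipped below at 1% of
#' the baseline mean (clip events are counted on the output).
#'
#' @param groups data frame with columns `group_id`, `theta` (latent
#'   adaptedness in `[0, 1]`), `n` (subjects).
#' @param parameters panel data frame as in [default_sim_parameters()].
#' @param rho0,rho1 intercept and slope of the recovery-rate rule;
#'   `rho(theta)` must stay in `[0, 1]` for every configured theta.
#' @param noise_sd relative SD of the load/recovery stage noise.
#' @param recovery whether to generate recovery-state values.
#' @param seed RNG seed used by [simulate_study()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(groups, parameters = default_sim_parameters(),
                              rho0 = 0.3, rho1 = 0.6, noise_sd = 0.03,
                              recovery = TRUE, seed = NULL) {
  problems <- character()
  need_g <- c("group_id", "theta", "n")
  if (!is.data.frame(groups) || !all(need_g %in% names(groups)))
    problems <- c(problems, paste("groups must have columns",
                                  paste(need_g, collapse = ", ")))
  need_p <- c("name", "category", "mu", "sigma", "delta", "gamma")
  if (!is.data.frame(parameters) || !all(need_p %in% names(parameters)))
    problems <- c(problems, paste("parameters must have columns",
                                  paste(need_p, collapse = ", ")))
  if (!length(problems)) {
    if (any(groups$theta < 0 | groups$theta > 1))
      problems <- c(problems, "theta must lie in [0, 1]")
    if (any(groups$n < 1))
      problems <- c(problems, "group sizes must be >= 1")
    if (any(parameters$mu <= 0))
      problems <- c(problems, "baseline means mu must be > 0")
    if (any(parameters$sigma < 0))
      problems <- c(problems, "baseline sigma must be >= 0")
    if (any(parameters$delta < 0) || any(parameters$gamma < 0))
      problems <- c(problems, "effect sizes delta/gamma must be >= 0")
    if (!all(parameters$category %in% PARAM_CATEGORIES))
      problems <- c(problems, "unknown parameter category")
    if (rho0 < 0 || rho1 < 0)
      problems <- c(problems, "rho0 and rho1 must be >= 0")
    else if (any(rho0 + rho1 * groups$theta > 1))
      problems <- c(problems, "rho(theta) exceeds 1 for a configured theta")
    if (noise_sd < 0)
      problems <- c(problems, "noise_sd must be >= 0")
  }
  if (length(problems))
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  out <- list(groups = groups, parameters = parameters, rho0 = rho0,
              rho1 = rho1, noise_sd = noise_sd, recovery = recovery,
              seed = seed)
  class(out) <- "simulation_config"
  out
}

#' Simulate one cohort
#'
#' Draws the subjects of a single configured group under the model described
#' in [simulation_config()]. Uses the current RNG state; seed management is
#' done by [simulate_study()].
#'
#' @param config a [simulation_config()].
#' @param group a `group_id` present in `config$groups`.
#' @return a list of [subject_profile()]s with attribute `clip_events`
#'   (number of values clipped at the positivity floor).
#' @export
simulate_cohort <- function(config, group) {
  stopifnot(inherits(config, "simulation_config"))
  gi <- match(group, config$groups$group_id)
  if (is.na(gi)) stop("unknown group: ", group, call. = FALSE)
  theta <- config$groups$theta[gi]
  n <- config$groups$n[gi]
  p <- config$parameters
  rho <- config$rho0 + config$rho1 * theta
  clip <- 0L
  floor_ <- 0.01 * p$mu
  clipv <- function(x) {
    hit <- x < floor_
    clip <<- clip + sum(hit)
    pmax(x, floor_)
  }
  effect <- ifelse(p$category == "homeostatic", p$delta * (1 - theta),
            ifelse(p$category == "adaptive", p$gamma * theta, 0))
  profs <- lapply(seq_len(n), function(i) {
    k_pre <- clipv(rnorm(nrow(p), p$mu, p$sigma))
    k_load <- clipv(k_pre * (1 + effect +
                               rnorm(nrow(p), 0, config$noise_sd)))
    k_rec <- if (config$recovery)
      clipv(k_load + rho * (k_pre - k_load) +
              k_pre * rnorm(nrow(p), 0, config$noise_sd))
    else NULL
    subject_profile(p$name, k_pre = k_pre, k_load = k_load, k_rec = k_rec,
                    subject_id = sprintf("%s_%03d", group, i),
                    group_id = group)
  })
  attr(profs, "clip_events") <- clip
  profs
}

#' Simulate a full repeated-measure study
#'
#' Generates every configured cohort (reproducibly under `config$seed`) and
#' returns the profiles, the same data in standard long format (so it flows
#' through [read_measurements()] / [profiles_from_long()] unchanged), and
#' the ground-truth adaptedness ordering for validation.
#'
#' @param config a [simulation_config()] with at least 2 groups (1 allowed,
#'   but then there is nothing to compare).
#' @param seed optional override of `config$seed`.
#' @return a list: `profiles` (list of [subject_profile()]s across all
#'   groups), `data` (long-format data frame), `truth` (data frame
#'   `group_id`, `theta`, `true_rank` with rank 1 = highest theta),
#'   `clip_events`.
#' @export
simulate_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  profs <- list(); clip <- 0L
  for (g in config$groups$group_id) {
    cohort <- simulate_cohort(config, g)
    clip <- clip + attr(cohort, "clip_events")
    profs <- c(profs, cohort)
  }
  data <- do.call(rbind, lapply(profs, function(pr) {
    states <- c("pre", "load", if (has_recovery(pr)) "recovery")
    do.call(rbind, lapply(states, function(st) data.frame(
      subject_id = attr(pr, "subject_id"),
      group_id = attr(pr, "group_id"),
      parameter = pr$parameter,
      state = st,
      value = switch(st, pre = pr$k_pre, load = pr$k_load,
                     recovery = pr$k_rec),
      stringsAsFactors = FALSE)))
  }))
  rownames(data) <- NULL
  truth <- config$groups[, c("group_id", "theta")]
  truth$true_rank <- rank_groups(setNames(truth$theta, truth$group_id))
  list(profiles = profs, data = data, truth = truth, clip_events = clip)
}
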