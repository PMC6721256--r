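# Independent naive evaluation of the index, term by term, kept deliberately
# separate from the package's vectorised implementation.
naive_index <- function(profile, specs, S = NULL,
                        weighting = "stability", use_rec = NULL) {
  if (is.null(use_rec)) use_rec <- !all(is.na(profile$k_rec))
  total <- 0
  for (i in seq_len(nrow(profile))) {
    p <- profile$parameter[i]
    cat_ <- specs$category[specs$name == p]
    w <- if (weighting == "stability" && cat_ != "indifferent") S[[p]] else 1
    resp <- abs(profile$k_load[i] - profile$k_pre[i]) / profile$k_pre[i]
    rec <- 0
    if (use_rec) {
      num <- abs(profile$k_rec[i] - profile$k_pre[i])
      den <- abs(profile$k_rec[i] - profile$k_load[i])
      rec <- if (num == 0) 0 else num / den
    }
    term <- if (cat_ == "homeostatic") w * (-resp - rec)
            else if (cat_ == "adaptive") w * (resp - rec)
            else 0
    total <- total + term
  }
  total
}

# random small profile + matching specs/S for property tests
random_case <- function(with_recovery = TRUE) {
  np <- sample(2:8, 1)
  nm <- paste0("par", seq_len(np))
  cat_ <- sample(c("homeostatic", "adaptive", "indifferent"), np,
                 replace = TRUE)
  k_pre <- runif(np, 0.1, 100)
  k_load <- runif(np, 0.1, 100)
  k_rec <- if (with_recovery) runif(np, 0.1, 100) else NULL
  list(
    profile = subject_profile(nm, k_pre, k_load, k_rec,
                              subject_id = "rnd", group_id = "g"),
    specs = parameter_spec(nm, cat_),
    S = setNames(runif(np, 0.5, 1), nm)
  )
}
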