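make_pair <- function() {
  sp <- parameter_spec(c("lab", "ultra"), c("adaptive", "adaptive"))
  S <- c(lab = 0.7, ultra = 0.9)
  # changes of 5 and 10 relative units against a unit reference
  b <- subject_profile(c("lab", "ultra"), c(1, 1), c(6, 11),
                       subject_id = "B", group_id = "B")
  c_ <- subject_profile(c("lab", "ultra"), c(1, 1), c(11, 6),
                        subject_id = "C", group_id = "C")
  list(specs = sp, S = S, b = b, c = c_)
}

test_that("stability weighting separates subjects whose raw change totals tie", {
  x <- make_pair()
  a_b <- subject_index(x$b, x$specs, x$S)$value
  a_c <- subject_index(x$c, x$specs, x$S)$value
  expect_equal(a_b, 0.7 * 5 + 0.9 * 10)  # 12.5
  expect_equal(a_c, 0.7 * 10 + 0.9 * 5)  # 11.5
  # unweighted, both total 15 and the comparison is uninformative
  o <- index_options(weighting = "none")
  expect_equal(subject_index(x$b, x$specs, options = o)$value,
               subject_index(x$c, x$specs, options = o)$value)
  cmp <- compare_subjects(x$b, x$c, x$specs, x$S)
  expect_equal(cmp$verdict, "B")
})

test_that("identical profiles compare as equal; opposite case picks C", {
  x <- make_pair()
  same <- compare_subjects(x$b, x$b, x$specs, x$S)
  expect_equal(same$verdict, "equal")
  rev_ <- compare_subjects(x$c, x$b, x$specs, x$S)
  expect_equal(rev_$verdict, "C")
})

test_that("repeated-measure groups aggregate subject indices with dispersion", {
  sp <- parameter_spec(c("h", "a"), c("homeostatic", "adaptive"))
  o <- index_options(weighting = "none")
  mk <- function(id, g, shift) subject_profile(
    c("h", "a"), c(10, 10), c(10 + shift, 10 + 2 * shift),
    subject_id = id, group_id = g)
  profs <- c(lapply(1:4, function(i) mk(paste0("hi", i), "HI", 1 + 0.1 * i)),
             lapply(1:4, function(i) mk(paste0("lo", i), "LO", 0.1 * i)))
  gc <- group_index_repeated(profs, sp, options = o)
  expect_setequal(gc$groups$group_id, c("HI", "LO"))
  hi <- gc$groups[gc$groups$group_id == "HI", ]
  a_hi <- gc$subject_a$a[gc$subject_a$group_id == "HI"]
  expect_equal(hi$A, mean(a_hi))
  expect_equal(hi$sd, sd(a_hi))
  expect_equal(hi$n, 4L)
  z <- qnorm(0.975)
  expect_equal(hi$ci_lo, hi$A - z * hi$sd / 2)
  expect_true(all(c(1L, 2L) %in% gc$groups$rank))
  expect_equal(nrow(gc$pairwise), 1)
  expect_equal(gc$pairwise$test, "welch")
})

test_that("groups of identical subjects give SD 0 and a flagged degenerate test", {
  sp <- parameter_spec("h", "homeostatic")
  o <- index_options(weighting = "none")
  mk <- function(id, g) subject_profile("h", 10, 14, subject_id = id,
                                        group_id = g)
  profs <- list(mk("a1", "G1"), mk("a2", "G1"), mk("b1", "G2"),
                mk("b2", "G2"))
  gc <- suppressWarnings(group_index_repeated(profs, sp, options = o))
  expect_equal(gc$groups$sd, c(0, 0))
  expect_equal(gc$groups$A[1], gc$groups$A[2])
  expect_true(gc$pairwise$degenerate)
  expect_true(is.na(gc$pairwise$p))
})

test_that("simulated cohorts at distant theta are separated and ranked correctly", {
  cfg <- simulation_config(
    groups = data.frame(group_id = c("high", "low"), theta = c(0.8, 0.2),
                        n = 20))
  sim <- simulate_study(cfg, seed = 7)
  sp <- parameter_spec(cfg$parameters$name, cfg$parameters$category)
  gc <- group_index_repeated(sim$profiles, sp,
                             options = index_options(weighting = "none"))
  A <- setNames(gc$groups$A, gc$groups$group_id)
  expect_gt(A["high"], A["low"])
  expect_lt(gc$pairwise$p, 0.05)
})

test_that("with equal group sizes the A ordering equals the summed-a ordering", {
  cfg <- simulation_config(
    groups = data.frame(group_id = c("g1", "g2"), theta = c(0.6, 0.3),
                        n = 10))
  sim <- simulate_study(cfg, seed = 11)
  sp <- parameter_spec(cfg$parameters$name, cfg$parameters$category)
  gc <- group_index_repeated(sim$profiles, sp,
                             options = index_options(weighting = "none"))
  sums <- tapply(gc$subject_a$a, gc$subject_a$group_id, sum)
  means <- setNames(gc$groups$A, gc$groups$group_id)
  expect_equal(order(sums[names(means)]), order(means))
})

test_that("permutation test is seeded and detects a clear group difference", {
  sp <- parameter_spec("a", "adaptive")
  o <- index_options(weighting = "none", test = "permutation",
                     permutations = 499)
  mk <- function(id, g, v) subject_profile("a", 10, v, subject_id = id,
                                           group_id = g)
  profs <- c(lapply(1:6, function(i) mk(paste0("x", i), "X", 19 + i / 10)),
             lapply(1:6, function(i) mk(paste0("y", i), "Y", 11 + i / 10)))
  g1 <- group_index_repeated(profs, sp, options = o, seed = 99)
  g2 <- group_index_repeated(profs, sp, options = o, seed = 99)
  expect_equal(g1$pairwise$p, g2$pairwise$p)
  expect_lt(g1$pairwise$p, 0.05)
})

test_that("destructive design on SD-0 cells reproduces the single-subject index", {
  sp <- parameter_spec(c("h", "a"), c("homeostatic", "adaptive"))
  S <- c(h = 0.8, a = 0.9)
  prof <- subject_profile(c("h", "a"), c(10, 40), c(16, 90),
                          k_rec = c(11, 50), subject_id = "s",
                          group_id = "G")
  cells <- group_cells(
    group_id = "G",
    parameter = rep(c("h", "a"), each = 3),
    state = rep(c("pre", "load", "recovery"), 2),
    mean = c(10, 16, 11, 40, 90, 50), sd = 0, n = 1)
  gc <- suppressWarnings(group_index_destructive(cells, sp, S))
  expect_equal(gc$groups$A, subject_index(prof, sp, S)$value,
               tolerance = 1e-12)
})

test_that("destructive design with all states at baseline scores zero", {
  sp <- parameter_spec("h", "homeostatic")
  cells <- group_cells("G", rep("h", 2), c("pre", "load"),
                       mean = c(5, 5), sd = c(0.1, 0.1), n = 8)
  gc <- group_index_destructive(cells, sp, c(h = 0.9))
  expect_equal(gc$groups$A, 0)
  expect_equal(unname(gc$groups$rank), 1L)
})

test_that("missing cells are enumerated in a single error", {
  sp <- parameter_spec(c("h", "a"), c("homeostatic", "adaptive"))
  cells <- group_cells(c("G", "G", "G"), c("h", "h", "a"),
                       c("pre", "load", "pre"), mean = c(5, 7, 3),
                       sd = 0.1, n = 5)
  expect_error(group_index_destructive(cells, sp, c(h = .9, a = .9)),
               "G/a/load")
})

test_that("bootstrap uncertainty is deterministic under a fixed seed and 0 for SD-0 cells", {
  sp <- parameter_spec(c("h", "a"), c("homeostatic", "adaptive"))
  S <- c(h = 0.8, a = 0.9)
  cells <- group_cells(
    group_id = rep(c("G1", "G2"), each = 4),
    parameter = rep(rep(c("h", "a"), each = 2), 2),
    state = rep(c("pre", "load"), 4),
    mean = c(10, 16, 40, 90, 10, 12, 40, 60),
    sd = c(1, 1.5, 3, 6, 1, 1.2, 3, 5), n = 8)
  b1 <- bootstrap_uncertainty(cells, sp, S, replicates = 200, seed = 42)
  b2 <- bootstrap_uncertainty(cells, sp, S, replicates = 200, seed = 42)
  expect_identical(b1, b2)
  expect_true(all(b1$sd > 0))

  cells0 <- group_cells("G", c("h", "h"), c("pre", "load"),
                        mean = c(10, 15), sd = 0, n = 5)
  sp0 <- parameter_spec("h", "homeostatic")
  b0 <- bootstrap_uncertainty(cells0, sp0, c(h = 0.9),
                              replicates = 100, seed = 1)
  expect_equal(b0$sd, 0)
})

test_that("zeroing by mask and by Welch test from summaries", {
  sp <- parameter_spec(c("h", "a"), c("homeostatic", "adaptive"))
  prof <- subject_profile(c("h", "a"), c(10, 10), c(15, 20))
  masked <- zero_insignificant(prof, mask = c(FALSE, TRUE))
  r <- subject_index(masked, sp, options = index_options(weighting = "none"))
  expect_equal(r$breakdown$contribution, c(0, 1))
  expect_error(zero_insignificant(prof), "mask")

  # non-significant load shift detected from printed-style summaries
  cells <- group_cells(
    group_id = "C", parameter = rep(c("hexokinase", "hcs11"), each = 2),
    state = rep(c("pre", "load"), 2),
    mean = c(13.4, 12.7, 8.1, 30.2), sd = c(1.7, 2.0, 2.9, 5.7),
    n = c(8, 9, 8, 9))
  zc <- zero_insignificant(cells, alpha = 0.05)
  log <- attr(zc, "zeroing_log")
  expect_true(log$zeroed[log$parameter == "hexokinase"])
  expect_false(log$zeroed[log$parameter == "hcs11"])
  # identical means are always zeroed
  cells_eq <- group_cells("G", c("k", "k"), c("pre", "load"),
                          mean = c(5, 5), sd = c(1, 1), n = 6)
  expect_true(attr(zero_insignificant(cells_eq), "zeroing_log")$zeroed)
  # the mask flows into the mean-substituted index
  spx <- parameter_spec(c("hexokinase", "hcs11"),
                        c("homeostatic", "adaptive"))
  gz <- group_index_destructive(zc, spx,
                                options = index_options(weighting = "none"))
  bz <- gz$breakdown[["C"]]
  expect_equal(bz$response_fraction[bz$parameter == "hexokinase"], 0)
})

test_that("group ranking is descending, dense on ties, with a warning", {
  A <- c(B = -1.665, C = 1.043, D = -0.272, E = -0.382)
  expect_equal(rank_groups(A), c(B = 4L, C = 1L, D = 2L, E = 3L))
  expect_equal(rank_groups(c(g1 = -0.094, g2 = -0.346)),
               c(g1 = 1L, g2 = 2L))
  expect_equal(rank_groups(c(solo = 2.2)), c(solo = 1L))
  expect_warning(r <- rank_groups(c(a = 1, b = 1, c = 0)), "tied")
  expect_equal(unname(r), c(1L, 1L, 2L))
})

test_that("single-member groups degenerate to the pairwise comparison", {
  x <- make_pair()
  gc <- suppressWarnings(group_index_repeated(list(x$b, x$c), x$specs, x$S))
  A <- setNames(gc$groups$A, gc$groups$group_id)
  expect_equal(unname(A["B"]), 12.5)
  expect_equal(unname(A["C"]), 11.5)
  cmp <- compare_subjects(x$b, x$c, x$specs, x$S)
  expect_equal(unname(A[c("B", "C")]),
               c(cmp$result_b$value, cmp$result_c$value))
})

test_that("rank order is stable under perturbations below half the minimum gap", {
  A <- c(a = 2.0, b = 1.0, c = -0.5)
  base <- rank_groups(A)
  gap <- min(diff(sort(A)))
  set.seed(5)
  for (i in 1:20) {
    eps <- runif(3, -gap / 2 + 1e-9, gap / 2 - 1e-9)
    expect_equal(rank_groups(A + eps), base)
  }
})
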