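# Statistical battery: mixed ANOVA, rank tests, multiple comparisons,
# effect sizes and sample size.

null_cohort <- function(seed, n1 = 10, n2 = 10) {
  set.seed(seed)
  r0 <- perturbation_response()
  rbind(simulate_recovery_cohort(n1, r0, n_pert = 1, group = "A"),
        simulate_recovery_cohort(n2, r0, n_pert = 1, group = "B",
                                 participant_prefix = "Q"))
}

test_that("mixed ANOVA reproduces the classical mixed-design layout", {
  coh <- null_cohort(101, n1 = 8, n2 = 12)
  a <- mixed_anova(coh)
  # 20 participants x 10 steps: F(1, 18) between, F(9, 162) within
  expect_equal(a$effects$df1, c(1, 9, 9))
  expect_equal(a$effects$df2, c(18, 162, 162))
  expect_true(all(a$effects$p >= 0 & a$effects$p <= 1))
  # sums of squares partition the total exactly
  expect_equal(sum(a$ss), a$total_ss, tolerance = 1e-12)
  # degenerate input is flagged, not tested
  coh0 <- coh; coh0$mos <- 0.05
  a0 <- mixed_anova(coh0)
  expect_true(a0$degenerate)
  expect_true(all(is.na(a0$effects$F)))
  # missing cells refuse silently imputing
  expect_error(mixed_anova(coh[-1, ]), "balanced")
  # GG correction shrinks the within dfs
  ag <- mixed_anova(coh, gg_correction = TRUE)
  expect_lt(ag$effects$df1[2], 9 + 1e-9)
  expect_true(ag$epsilon <= 1 && ag$epsilon >= 1 / 9)
})

test_that("a built-in group-by-step interaction is detected reliably", {
  hits <- 0
  for (i in 1:60) {
    set.seed(400 + i)
    slow <- perturbation_response(delay_steps = 3, response_sd = 0.005)
    fast <- perturbation_response(delay_steps = 0, response_sd = 0.005)
    coh <- rbind(
      simulate_recovery_cohort(10, fast, n_pert = 1, group = "A",
                               noise_sd = 0.005),
      simulate_recovery_cohort(10, slow, n_pert = 1, group = "B",
                               noise_sd = 0.005, participant_prefix = "Q"))
    a <- mixed_anova(coh)
    if (a$effects$p[3] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 48)  # >= 80%
})

test_that("Mann-Whitney U and p match definition and enumeration", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(1, 1)$U, 0.5)  # tied singletons
  expect_equal(mann_whitney_u(1, 1)$p, 1)
  set.seed(55)
  for (i in 1:20) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    x <- runif(n); y <- runif(m)
    res <- mann_whitney_u(x, y)
    expect_true(res$exact)
    expect_equal(res$p, enum_mw_p(x, y), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("Friedman statistic handles perfect ranks, ties and 2 conditions", {
  # identical rankings across 3 conditions, 12 blocks: maximal statistic 24
  perfect <- matrix(rep(c(1, 2, 3), each = 12), nrow = 12)
  fr <- friedman_rm(perfect)
  expect_equal(fr$statistic, 24)
  # agreement with stats::friedman.test on tie-free data
  set.seed(66)
  x <- matrix(rnorm(40), nrow = 10)
  fr2 <- friedman_rm(x)
  ref <- friedman.test(x)
  expect_equal(fr2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fr2$p, ref$p.value, tolerance = 1e-12)
  # two conditions reduce to a sign test
  set.seed(67)
  y <- matrix(rnorm(24), nrow = 12, ncol = 2)
  fr3 <- friedman_rm(y)
  b <- sum(y[, 1] > y[, 2])
  # Friedman chi-square with k=2 equals the squared standardized sign count
  expect_equal(fr3$statistic, (2 * b - 12)^2 / 12, tolerance = 1e-12)
  expect_error(friedman_rm(rbind(c(1, NA, 2), c(1, 2, 3))), "incomplete")
  # fully tied blocks carry no evidence
  expect_equal(friedman_rm(matrix(1, 5, 3))$p, 1)
})

test_that("signed-rank p-values match exhaustive sign-flip enumeration", {
  # constant positive shift, n = 8: one-sided p = 1 / 2^8
  x <- c(1.2, 2.1, 2.9, 4.4, 5.0, 6.3, 7.7, 8.1)
  w <- wilcoxon_signed_rank(x, x + 2, alternative = "less")
  expect_equal(w$p, 1 / 256)
  expect_true(wilcoxon_signed_rank(x, x)$degenerate)
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    res <- wilcoxon_signed_rank(a, b)
    expect_equal(res$p, enum_wsr_p(a, b), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo Dunnett adjustment matches its reference points", {
  set.seed(88)
  d <- data.frame(y = rnorm(40), g = rep(c("ctrl", "a", "b", "c"), 10))
  res <- dunnett_vs_control(d, "y", "g", control = "ctrl")
  expect_true(all(res$p_adjusted >= res$p_unadjusted - 1e-12))
  # single comparison: adjusted equals unadjusted
  d1 <- d[d$g %in% c("ctrl", "a"), ]
  r1 <- dunnett_vs_control(d1, "y", "g", control = "ctrl")
  expect_equal(r1$p_adjusted, r1$p_unadjusted, tolerance = 0.01)
  # identical data in all arms: everything near 1
  d0 <- data.frame(y = rep(rnorm(10), 4), g = rep(c("ctrl", "a", "b", "c"),
                                                  each = 10))
  d0$y <- d0$y + rnorm(40, 0, 1e-8)
  r0 <- dunnett_vs_control(d0, "y", "g", control = "ctrl")
  expect_true(all(r0$p_adjusted > 0.99))
  # cross-check against multcomp's multivariate-t computation
  skip_if_not_installed("multcomp")
  set.seed(89)
  dd <- data.frame(y = rnorm(30) + rep(c(0, 0.6, 1.2), each = 10),
                   g = factor(rep(c("ctrl", "a", "b"), each = 10),
                              levels = c("ctrl", "a", "b")))
  mine <- dunnett_vs_control(dd, "y", "g", control = "ctrl")
  ref <- summary(multcomp::glht(aov(y ~ g, dd),
                                linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(mine$p_adjusted, as.numeric(ref$test$pvalues),
               tolerance = 0.02)
  # within-subject route
  set.seed(90)
  long <- expand.grid(id = 1:12, step = c("Base", paste0("P", 1:4)))
  long$y <- rnorm(nrow(long)) + (long$step == "P1") * 1.5
  rw <- dunnett_vs_control(long, "y", "step", control = "Base",
                           block = "id")
  expect_equal(nrow(rw), 4)
  expect_lt(rw$p_adjusted[rw$comparison == "P1 - Base"], 0.05)
})

test_that("Sidak adjustment follows the closed form", {
  expect_equal(sidak_adjust(0), 0)
  expect_equal(sidak_adjust(0.05, k = 10), 1 - 0.95^10)
  expect_equal(sidak_adjust(0.3, k = 1), 0.3)
  expect_equal(sidak_adjust(0.9, k = 50), 1)
  expect_error(sidak_adjust(1.2), "0, 1")
})

test_that("effect-size conversion and its round trip are exact", {
  expect_identical(cohens_f_to_d(0.5), 1)
  expect_identical(cohens_f_to_d(0), 0)
  expect_equal(cohens_d_to_f(cohens_f_to_d(0.73)), 0.73)
  expect_error(cohens_f_to_d(-1), "non-negative")
})

test_that("sample-size search matches the noncentral-t oracle", {
  # f = 0.5, one measure, two groups: classic two-sample d = 1
  res <- sample_size_rm_between(0.5, alpha = 0.05, power = 0.8,
                                n_groups = 2, n_measures = 1)
  oracle_n <- ceiling(power.t.test(delta = 1, sd = 1, power = 0.8)$n)
  expect_equal(res$N, 2 * oracle_n)
  expect_gte(res$achieved_power, 0.8)
  # rho -> 1 removes the repeated-measures efficiency gain
  r_many <- sample_size_rm_between(0.5, n_measures = 10, rho = 1 - 1e-12)
  expect_equal(r_many$N, res$N)
  # N is monotone non-decreasing in rho (multiplier shrinks)
  ns <- vapply(c(0, 0.25, 0.5, 0.75, 0.9),
               function(r) sample_size_rm_between(0.4, n_measures = 10,
                                                  rho = r)$N,
               numeric(1))
  expect_true(all(diff(ns) >= 0))
  expect_error(sample_size_rm_between(0.5, rho = 1), "rho")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(91)
  x <- runif(7); y <- runif(6)
  f <- function(v) exp(3 * v) + v
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(f(x), f(y))$p)
  m <- matrix(runif(30), nrow = 10)
  expect_equal(friedman_rm(m)$p, friedman_rm(f(m))$p)
})
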