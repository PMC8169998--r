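# Group-comparison statistics: mixed repeated-measures ANOVA, rank tests,
# many-to-one and Sidak multiple comparisons, effect-size and sample-size
# utilities.

#' Mixed two-way repeated-measures ANOVA
#'
#' Classical mixed-design decomposition with one between factor (group) and
#' one within factor (step): the group effect is tested against the
#' between-participant stratum, the step and group-by-step effects against
#' the participant-by-step stratum. Greenhouse-Geisser correction is off by
#' default (integer within dfs, e.g. F(9, 162) for 20 participants and 10
#' steps); enable it with `gg_correction = TRUE`.
#'
#' @param data long data frame.
#' @param dv,subject,group,within column names of the response, the
#'   participant id, the between factor and the within factor.
#' @param gg_correction apply the Greenhouse-Geisser sphericity correction
#'   to the within-factor tests.
#' @return object of class `"mixed_anova"`: `effects` (data frame with
#'   `effect`, `df1`, `df2`, `F`, `p`), `ss` (all sums of squares),
#'   `epsilon` (GG estimate), `degenerate` flag.
#' @export
mixed_anova <- function(data, dv = "mos", subject = "participant",
                        group = "group", within = "step",
                        gg_correction = FALSE) {
  d <- data.frame(y = data[[dv]],
                  id = factor(data[[subject]]),
                  g = factor(data[[group]]),
                  w = factor(data[[within]]))
  if (anyNA(d)) stop("missing cells are not supported (no imputation)")
  tab <- table(d$id, d$w)
  if (any(tab != 1)) stop("design must be balanced: one observation per ",
                          "participant and step")
  if (nlevels(d$g) < 2 || any(table(unique(d[, c("id", "g")])$g) < 2)) {
    stop("need at least 2 participants per group")
  }
  degenerate <- var(d$y) < .Machine$double.eps * 100
  fit <- aov(y ~ g * w + Error(id / w), data = d)
  sm <- summary(fit)
  between <- sm[["Error: id"]][[1]]
  within_t <- sm[["Error: id:w"]][[1]]
  pick <- function(tb, name) {
    i <- match(name, trimws(rownames(tb)))
    c(df = tb[i, "Df"], ss = tb[i, "Sum Sq"], f = tb[i, "F value"],
      p = tb[i, "Pr(>F)"])
  }
  g_row <- pick(between, "g")
  w_row <- pick(within_t, "w")
  gw_row <- pick(within_t, "g:w")
  res_b <- pick(between, "Residuals")
  res_w <- pick(within_t, "Residuals")
  eff <- data.frame(
    effect = c("group", "step", "group:step"),
    df1 = c(g_row["df"], w_row["df"], gw_row["df"]),
    df2 = c(res_b["df"], res_w["df"], res_w["df"]),
    F = c(g_row["f"], w_row["f"], gw_row["f"]),
    p = c(g_row["p"], w_row["p"], gw_row["p"]))
  eps <- gg_epsilon(d)
  correction <- "none"
  if (gg_correction) {
    correction <- "GG"
    for (i in 2:3) {
      eff$df1[i] <- eff$df1[i] * eps
      eff$df2[i] <- eff$df2[i] * eps
      eff$p[i] <- pf(eff$F[i], eff$df1[i], eff$df2[i], lower.tail = FALSE)
    }
  }
  if (degenerate) eff$F <- eff$p <- NA_real_
  rownames(eff) <- NULL
  ss <- c(group = unname(g_row["ss"]), subjects = unname(res_b["ss"]),
          step = unname(w_row["ss"]), group_step = unname(gw_row["ss"]),
          residual = unname(res_w["ss"]))
  structure(list(effects = eff, ss = ss, epsilon = eps,
                 correction = correction, degenerate = degenerate,
                 total_ss = sum((d$y - mean(d$y))^2)),
            class = "mixed_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# participant-by-step matrix.
gg_epsilon <- function(d) {
  k <- nlevels(d$w)
  ids <- levels(d$id)
  M <- t(vapply(ids, function(i) {
    sub <- d[d$id == i, ]
    sub$y[order(sub$w)]
  }, numeric(k)))
  grp <- d$g[match(ids, d$id)]
  S <- matrix(0, k, k)
  dfp <- 0
  for (g in levels(grp)) {
    Mg <- M[grp == g, , drop = FALSE]
    if (nrow(Mg) > 1) {
      S <- S + (nrow(Mg) - 1) * var(Mg)
      dfp <- dfp + nrow(Mg) - 1
    }
  }
  S <- S / dfp
  Dc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  eps <- sum(diag(Dc))^2 / ((k - 1) * sum(Dc^2))
  min(1, max(eps, 1 / (k - 1)))
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed two-way repeated-measures ANOVA",
      if (x$correction == "GG") "(Greenhouse-Geisser corrected)" else "",
      "\n")
  if (x$degenerate) cat("  [degenerate: zero response variance]\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-10s F(%.3g, %.4g) = %.3f, p = %.4g\n", eff$effect[i],
                eff$df1[i], eff$df2[i], eff$F[i], eff$p[i]))
  }
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U1, U2)` with an exact p-value for small tie-free
#' samples (both n at most `exact_limit`) and the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_limit largest per-group n for the exact null distribution.
#' @return list with `U` and `p`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 8) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u <- min(u1, n * m - u1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && max(n, m) <= exact_limit
  p <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1  # zero-variance normal approximation (all tied)
  list(U = u, p = p, exact = use_exact)
}

#' Friedman test with tie correction
#'
#' Rank-based Friedman chi-square over complete blocks, with the standard
#' tie correction applied to the denominator.
#'
#' @param x blocks-by-conditions numeric matrix (participants in rows).
#' @return list with `statistic`, `df`, `p`.
#' @export
friedman_rm <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 conditions")
  if (anyNA(x)) {
    stop("incomplete blocks; remove participants with missing conditions ",
         "or use pairwise Wilcoxon tests")
  }
  R <- t(apply(x, 1, rank))
  Rj <- colSums(R)
  S <- sum((Rj - n * (k + 1) / 2)^2)
  chi <- 12 * S / (n * k * (k + 1))
  tie_sum <- sum(apply(x, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (C <= 0) return(list(statistic = 0, df = k - 1, p = 1))
  chi <- chi / C
  list(statistic = chi, df = k - 1,
       p = pchisq(chi, k - 1, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test
#'
#' Paired test on `x - y`; zero differences are dropped. The null is exact
#' for at most `exact_limit` tie-free non-zero differences (signed-rank
#' distribution); with tied absolute differences and n at most 12 the
#' exact conditional null is obtained by enumerating all sign patterns on
#' the average ranks; otherwise the normal approximation is used.
#'
#' @param x,y equal-length numeric vectors.
#' @param exact_limit largest n for the exact tie-free null.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for x - y).
#' @return list with `W` (sum of positive ranks), `p`, and a `degenerate`
#'   flag (TRUE when all differences are zero).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25,
                                 alternative = "two.sided") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  n <- length(d)
  ties <- anyDuplicated(abs(d)) > 0
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (ties && n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(mean(Vs <= W), mean(Vs >= W))),
                less = mean(Vs <= W),
                greater = mean(Vs >= W))
    return(list(W = W, p = p, degenerate = FALSE, exact = TRUE))
  }
  use_exact <- !ties && n <= exact_limit
  res <- suppressWarnings(
    wilcox.test(d, exact = use_exact, correct = TRUE,
                alternative = alternative))
  list(W = W, p = res$p.value, degenerate = FALSE, exact = use_exact)
}

#' Dunnett-style many-to-one comparisons
#'
#' Compares every condition to a control with a multivariate-t adjustment
#' whose quantiles are obtained by seeded Monte Carlo (common denominator,
#' correlation from the design). Supports the within-subject case (each
#' condition differenced against the control per block) and the one-way
#' between-group case.
#'
#' @param data long data frame.
#' @param value,condition column names of the response and the condition.
#' @param control control level of `condition`.
#' @param block column name of the block (participant) id for the
#'   within-subject design; `NULL` for the between-group design.
#' @param nsim Monte Carlo draws.
#' @param seed seed for the Monte Carlo quantiles (the global RNG state is
#'   preserved).
#' @return data frame: `comparison`, `estimate`, `t`, `df`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunnett_vs_control <- function(data, value, condition, control,
                               block = NULL, nsim = 1e5, seed = 20260101) {
  v <- data[[value]]
  cond <- factor(data[[condition]])
  if (!control %in% levels(cond)) stop("control level '", control,
                                       "' not present")
  others <- setdiff(levels(cond), control)
  k <- length(others)
  if (!is.null(block)) {
    b <- factor(data[[block]])
    wide <- tapply(v, list(b, cond), mean)
    if (anyNA(wide)) stop("incomplete blocks")
    D <- wide[, others, drop = FALSE] - wide[, control]
    n <- nrow(D)
    est <- colMeans(D)
    se <- apply(D, 2, sd) / sqrt(n)
    tval <- est / se
    df <- n - 1
    R <- if (n >= k + 3) stats::cor(D) else matrix(0.5, k, k)
  } else {
    ns <- table(cond)
    ms <- tapply(v, cond, mean)
    sp2 <- sum(tapply(v, cond, function(z) sum((z - mean(z))^2))) /
      (length(v) - nlevels(cond))
    est <- ms[others] - ms[control]
    se <- sqrt(sp2 * (1 / ns[others] + 1 / ns[control]))
    tval <- as.numeric(est / se)
    df <- length(v) - nlevels(cond)
    nj <- as.numeric(ns[others]); n0 <- as.numeric(ns[control])
    R <- outer(seq_len(k), seq_len(k), function(i, j) {
      sqrt(nj[i] * nj[j] / ((nj[i] + n0) * (nj[j] + n0)))
    })
  }
  diag(R) <- 1
  p_un <- 2 * stats::pt(-abs(tval), df)
  p_adj <- with_preserved_seed(seed, {
    L <- chol(R)
    Z <- matrix(rnorm(nsim * k), nsim, k) %*% L
    s <- sqrt(rchisq(nsim, df) / df)
    Mx <- apply(abs(Z / s), 1, max)
    vapply(abs(tval), function(t0) mean(Mx >= t0), numeric(1))
  })
  p_adj <- pmin(1, pmax(p_adj, p_un))
  data.frame(comparison = paste(others, "-", control),
             estimate = as.numeric(est), t = as.numeric(tval), df = df,
             p_unadjusted = as.numeric(p_un), p_adjusted = p_adj)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Sidak adjustment for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^k`, capped at 1.
#'
#' @param p vector of unadjusted p-values in \[0, 1\].
#' @param k number of comparisons in the family (defaults to `length(p)`).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, k = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, 1 - (1 - p)^k)
}

#' Convert Cohen's f to Cohen's d (two-group contrast)
#'
#' For two groups, `d = 2 f`; an ANOVA effect size of f = 0.5 corresponds
#' to d = 1.
#'
#' @param f Cohen's f, non-negative.
#' @return Cohen's d.
#' @export
cohens_f_to_d <- function(f) {
  if (any(f < 0)) stop("f must be non-negative")
  2 * f
}

#' Convert Cohen's d to Cohen's f (two-group contrast)
#'
#' @param d Cohen's d, non-negative.
#' @return Cohen's f.
#' @export
cohens_d_to_f <- function(d) {
  if (any(d < 0)) stop("d must be non-negative")
  d / 2
}

#' Sample size for a between-group effect in a repeated-measures design
#'
#' Smallest balanced total N whose achieved power for the between-group
#' effect reaches the target, under a noncentral F with
#' `ncp = f^2 * N * m / (1 + (m - 1) * rho)` (the repeated-measures
#' efficiency multiplier for m measures with assumed correlation rho),
#' numerator df `n_groups - 1` and denominator df `N - n_groups`.
#'
#' @param f Cohen's f for the between-group effect.
#' @param alpha significance level.
#' @param power target power.
#' @param n_groups number of groups (balanced).
#' @param n_measures repeated measures per participant.
#' @param rho assumed correlation among repeated measures, in \[0, 1).
#' @param max_n search limit for total N.
#' @return list with `N` (total), `n_per_group`, `achieved_power`.
#' @export
sample_size_rm_between <- function(f, alpha = 0.05, power = 0.8,
                                   n_groups = 2, n_measures = 1, rho = 0.5,
                                   max_n = 1e5) {
  if (f <= 0) stop("f must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  mult <- n_measures / (1 + (n_measures - 1) * rho)
  for (N in seq(2 * n_groups, max_n, by = n_groups)) {
    lambda <- f^2 * N * mult
    df2 <- N - n_groups
    crit <- qf(1 - alpha, n_groups - 1, df2)
    pow <- pf(crit, n_groups - 1, df2, ncp = lambda, lower.tail = FALSE)
    if (pow >= power) {
      return(list(N = N, n_per_group = N / n_groups, achieved_power = pow))
    }
  }
  stop("target power unattainable within max_n = ", max_n)
}
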