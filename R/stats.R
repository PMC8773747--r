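#' Assign stress groups from salivary alpha-amylase
#'
#' Applies the enrollment thresholds: sAA < 28 KU/L is control; sAA > 33
#' KU/L is the stress group, subdivided into eustress (33 < sAA < 44) and
#' distress (sAA > 44). The gap \[28, 33\] and the boundary 44 itself fall in
#' no group (the thresholds are strict) and are labelled `unclassified`.
#' The three-group label refines the two-group label: eustress and distress
#' are both `stress` in the two-group column.
#'
#' @param saa_kul Non-negative sAA level(s) in KU/L.
#' @return Data frame with columns `saa_kul`, `two_group`
#'   (`control`/`stress`/`unclassified`) and `three_group`
#'   (`control`/`eustress`/`distress`/`unclassified`).
#' @export
#' @examples
#' classify_by_saa(c(12.73, 37.82, 61.82, 30))
classify_by_saa <- function(saa_kul) {
  assert_that(is.numeric(saa_kul) && length(saa_kul) >= 1,
              "saa_kul must be numeric")
  if (any(!is.finite(saa_kul)) || any(saa_kul < 0)) {
    stop_nirslat("sAA levels must be finite and non-negative",
                 "nirslat_validation_error")
  }
  three <- ifelse(saa_kul < 28, "control",
           ifelse(saa_kul > 33 & saa_kul < 44, "eustress",
           ifelse(saa_kul > 44, "distress", "unclassified")))
  two <- ifelse(three == "control", "control",
         ifelse(three %in% c("eustress", "distress"), "stress",
                "unclassified"))
  data.frame(saa_kul = saa_kul, two_group = two, three_group = three)
}

# Levene's homogeneity-of-variance check (classic, mean-centred), reported
# alongside every group comparison.
levene_check <- function(values, groups) {
  g <- factor(groups)
  if (all(tapply(values, g, sd) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  lev <- car::leveneTest(values ~ g, center = mean)
  list(statistic = lev[1, "F value"], p_value = lev[1, "Pr(>F)"])
}

group_summary <- function(values, groups) {
  agg <- aggregate(values, list(group = groups),
                   function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  data.frame(group = agg$group, mean = agg$x[, "mean"], sd = agg$x[, "sd"],
             n = as.integer(agg$x[, "n"]))
}

#' Two-group comparison (Levene then t-test)
#'
#' Runs Levene's homogeneity-of-variance test, then an independent two-sample
#' t-test: pooled-variance when Levene does not reject homogeneity at 0.05,
#' Welch otherwise.
#'
#' @param values Numeric outcome values.
#' @param groups Two-level grouping vector aligned with `values`.
#' @return A `test_report` list: `test_name`, `statistic`, `df`, `p_value`,
#'   `groups` (per-group mean/sd/n), `levene` (statistic and p).
#' @export
compare_two_groups <- function(values, groups) {
  g <- factor(groups)
  assert_that(nlevels(g) == 2, "exactly two groups are required")
  assert_that(all(table(g) >= 2), "each group needs at least 2 values")
  split_v <- split(values, g)
  if (sd(values) == 0) {
    stop_nirslat("all values identical: test statistic undefined",
                 "nirslat_degenerate_data")
  }
  lev <- levene_check(values, g)
  pooled <- is.na(lev$p_value) || lev$p_value >= 0.05
  tt <- t.test(split_v[[1]], split_v[[2]], var.equal = pooled)
  structure(list(
    test_name = if (pooled) "two-sample t (pooled)" else "two-sample t (Welch)",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    groups = group_summary(values, g),
    levene = lev
  ), class = "test_report")
}

#' Three-group comparison (one-way ANOVA with Dunnett T3 post hoc)
#'
#' One-way analysis of variance across three groups followed by the Dunnett
#' T3 post hoc procedure: pairwise Welch-type statistics referred to the
#' studentized maximum modulus distribution, appropriate when group
#' variances are unequal.
#'
#' @param values Numeric outcome values.
#' @param groups Three-level grouping vector aligned with `values`.
#' @return A `test_report` list: ANOVA `statistic` (F), `df` (num, den),
#'   `p_value`, `groups`, `levene`, and `posthoc` (data frame of pairwise
#'   Dunnett T3 comparisons with statistics, Welch df and p-values).
#' @export
compare_three_groups <- function(values, groups) {
  g <- factor(groups)
  assert_that(nlevels(g) == 3, "exactly three groups are required")
  assert_that(all(table(g) >= 2), "each group needs at least 2 values")
  lev <- levene_check(values, g)
  aov_res <- oneway.test(values ~ g, var.equal = TRUE)
  structure(list(
    test_name = "one-way ANOVA",
    statistic = unname(aov_res$statistic),
    df = unname(aov_res$parameter),
    p_value = aov_res$p.value,
    groups = group_summary(values, g),
    levene = lev,
    posthoc = dunnett_t3(values, g)
  ), class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  print(x$groups)
  if (!is.null(x$posthoc)) {
    cat("Dunnett T3 post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Studentized maximum modulus distribution function
#'
#' `P(max_i |T_i| <= q)` for `m` standardized contrasts sharing a chi-based
#' variance estimate with `df` degrees of freedom:
#' `F(q) = integral over s of (2 Phi(q s) - 1)^m f(s) ds`, where
#' `s = sqrt(chi^2_df / df)`. With `m = 1` this is the two-sided Student-t
#' probability. Used as the reference distribution of Dunnett T3.
#'
#' @param q Non-negative quantile.
#' @param m Number of comparisons.
#' @param df Degrees of freedom of the variance estimate.
#' @return Probability in \[0, 1\].
#' @export
psmm <- function(q, m, df) {
  assert_that(is_scalar_number(q) && q >= 0, "q must be non-negative")
  assert_that(m >= 1 && df > 0, "m >= 1 and df > 0 required")
  f <- function(s) {
    # density of s = sqrt(X/df), X ~ chi^2_df
    (2 * stats::pnorm(q * s) - 1)^m * 2 * s * df * dchisq(s^2 * df, df)
  }
  val <- integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
  min(1, max(0, val))
}

#' Dunnett T3 pairwise post hoc comparisons
#'
#' For every pair of groups computes the Welch-type statistic
#' `t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with Welch-Satterthwaite
#' degrees of freedom and refers `|t|` to the studentized maximum modulus
#' distribution with `m = k(k-1)/2` comparisons.
#'
#' @param values Numeric outcome values.
#' @param groups Grouping vector (>= 2 levels).
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `mean_diff`, `statistic`, `df`, `p_value`.
#' @export
dunnett_t3 <- function(values, groups) {
  g <- factor(groups)
  lv <- levels(g)
  k <- length(lv)
  assert_that(k >= 2, "at least two groups are required")
  stats_by <- lapply(split(values, g), function(v)
    list(m = mean(v), v = stats::var(v), n = length(v)))
  pairs <- utils::combn(k, 2)
  m_comp <- ncol(pairs)
  rows <- lapply(seq_len(m_comp), function(j) {
    a <- stats_by[[pairs[1, j]]]; b <- stats_by[[pairs[2, j]]]
    se2 <- a$v / a$n + b$v / b$n
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    stat <- (a$m - b$m) / sqrt(se2)
    data.frame(group1 = lv[pairs[1, j]], group2 = lv[pairs[2, j]],
               mean_diff = a$m - b$m, statistic = stat, df = df,
               p_value = 1 - psmm(abs(stat), m_comp, df))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-tailed Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with non-zero variance.
#' @return List with `r`, `p_value`, `n`, and the t statistic on `n - 2`
#'   degrees of freedom.
#' @export
correlate <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_nirslat("correlation undefined: zero variance input",
                 "nirslat_degenerate_data")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       statistic = unname(ct$statistic))
}
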