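#' Group summary (n, mean, sd)
#'
#' Published group comparisons are often reported only as mean ± sd with a
#' sample size; this container carries exactly that, so two-sample t-tests
#' can be recomputed from printed numbers.
#'
#' @param label group name.
#' @param n sample size (>= 2).
#' @param mean,sd summary statistics (sd >= 0).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

# uniform result row
.test_result <- function(test, statistic, df, p_value, sidedness,
                         comparison) {
  tibble::tibble(test = test, statistic = statistic, df = df,
                 p_value = p_value, sidedness = sidedness,
                 comparison = comparison)
}

#' Two-sample t-test from summary statistics
#'
#' Closed-form unpaired t-test using only group means, standard deviations
#' and sizes, for re-analysis of published summaries. Both the
#' pooled-variance (Student) and the Welch variant are available; p-values
#' are two-sided by default.
#'
#' @param a,b [group_summary()] objects.
#' @param variant `"pooled"` or `"welch"`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of a vs b).
#' @return a one-row `TestResult` tibble (`test`, `statistic`, `df`,
#'   `p_value`, `sidedness`, `comparison`).
#' @export
t_test_from_summary <- function(a, b, variant = c("pooled", "welch"),
                                alternative = "two.sided") {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  variant <- match.arg(variant)
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- if (se > 0) (a$mean - b$mean) / se else 0
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              stop("unknown alternative"))
  if (se == 0) p <- if (alternative == "two.sided") 1 else 0.5
  .test_result(paste0("t (", variant, ")"), t, df, p, alternative,
               paste(a$label, "vs", b$label))
}

#' Rank-based group comparisons
#'
#' Dispatches the rank tests used for islet-volume and morphology cohorts:
#' with two groups a Mann-Whitney U test (exact for small tie-free samples,
#' normal approximation with tie correction otherwise); with three or more
#' groups a Kruskal-Wallis test followed by Dunn's pairwise post-hoc z
#' tests with Bonferroni adjustment over the tested pairs. The direction of
#' a one-tailed Mann-Whitney must be declared explicitly — there is no
#' silent default.
#'
#' @param values numeric observations.
#' @param groups group label per observation (2+ levels).
#' @param alternative for 2 groups: `"two.sided"`, `"less"`, `"greater"`
#'   (first group level vs second); required explicitly for one-tailed use.
#' @param posthoc run Dunn's comparisons after Kruskal-Wallis (default TRUE).
#' @return `TestResult` tibble; for the Kruskal-Wallis path the omnibus row
#'   is followed by one row per Dunn comparison (Bonferroni-adjusted p).
#'   Attribute `flagged` is TRUE when all values are tied.
#' @export
rank_tests <- function(values, groups, alternative = "two.sided",
                       posthoc = TRUE) {
  groups <- factor(groups)
  lv <- levels(groups)
  stopifnot(length(values) == length(groups), length(lv) >= 2L)
  all_tied <- length(unique(values)) == 1L
  if (length(lv) == 2L) {
    x <- values[groups == lv[1]]; y <- values[groups == lv[2]]
    if (all_tied) {
      out <- .test_result("Mann-Whitney U", length(x) * length(y) / 2, NA,
                          1, alternative, paste(lv[1], "vs", lv[2]))
      attr(out, "flagged") <- TRUE
      return(out)
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y,
                                              alternative = alternative))
    out <- .test_result("Mann-Whitney U", unname(wt$statistic), NA,
                        wt$p.value, alternative, paste(lv[1], "vs", lv[2]))
    attr(out, "flagged") <- alternative != "two.sided" && wt$p.value >= 0.5
    return(out)
  }
  if (all_tied) {
    out <- .test_result("Kruskal-Wallis", 0, length(lv) - 1, 1, "two.sided",
                        paste(lv, collapse = " | "))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  kw <- stats::kruskal.test(values, groups)
  rows <- list(.test_result("Kruskal-Wallis", unname(kw$statistic),
                            unname(kw$parameter), kw$p.value, "two.sided",
                            paste(lv, collapse = " | ")))
  if (posthoc) rows <- c(rows, list(dunn_posthoc(values, groups)))
  out <- dplyr::bind_rows(rows)
  attr(out, "flagged") <- FALSE
  out
}

#' Dunn's pairwise post-hoc comparisons
#'
#' Rank-sum z statistics on the pooled ranks (with tie correction),
#' Bonferroni-adjusted over all tested pairs — the conventional follow-up
#' to a significant Kruskal-Wallis test.
#'
#' @param values numeric observations.
#' @param groups factor of group labels (3+ levels for a meaningful
#'   post-hoc).
#' @return `TestResult` tibble, one row per pair; `p_value` is the
#'   Bonferroni-adjusted two-sided p, capped at 1.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  nn <- tapply(r, groups, length)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nn[g1] + 1 / nn[g2]))
    z <- (rbar[g1] - rbar[g2]) / se
    p <- min(1, 2 * stats::pnorm(-abs(z)) * m)
    .test_result("Dunn", unname(z), NA, p, "two.sided",
                 paste(g1, "vs", g2))
  })
  dplyr::bind_rows(rows)
}

#' One-way ANOVA with Dunnett's many-to-one post-test
#'
#' Omnibus one-way F test followed by Dunnett comparisons of every
#' treatment group against the named control, using multivariate-t critical
#' values. Degenerate designs (zero within-group variance everywhere) are
#' flagged rather than reported as infinite F.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @param control label of the control group.
#' @return `TestResult` tibble: the ANOVA row, then one Dunnett row per
#'   treatment (adjusted p). Attribute `flagged` marks the degenerate case.
#' @export
anova_dunnett <- function(values, groups, control) {
  groups <- factor(groups)
  stopifnot(control %in% levels(groups), nlevels(groups) >= 2L)
  if (any(tapply(values, groups, length) < 2))
    stop("every group needs at least 2 observations")
  groups <- stats::relevel(groups, ref = control)
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0)) {
    out <- .test_result("one-way ANOVA", NA, NA, NA, "two.sided",
                        paste(levels(groups), collapse = " | "))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  dat <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = dat)
  s <- summary(fit)[[1]]
  rows <- list(.test_result("one-way ANOVA", s[1, "F value"],
                            s[1, "Df"], s[1, "Pr(>F)"], "two.sided",
                            paste(levels(groups), collapse = " | ")))
  if (nlevels(groups) > 2L) {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    rows <- c(rows, lapply(seq_along(sm$test$tstat), function(i)
      .test_result("Dunnett", unname(sm$test$tstat[i]),
                   fit$df.residual, unname(sm$test$pvalues[i]), "two.sided",
                   names(sm$test$tstat)[i])))
  } else {
    # two groups: Dunnett reduces to the pooled t-test
    tt <- t_test_from_summary(
      group_summary(levels(groups)[2],
                    sum(groups == levels(groups)[2]),
                    mean(values[groups == levels(groups)[2]]),
                    stats::sd(values[groups == levels(groups)[2]])),
      group_summary(control, sum(groups == control),
                    mean(values[groups == control]),
                    stats::sd(values[groups == control])))
    rows <- c(rows, list(tt))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "flagged") <- FALSE
  out
}
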