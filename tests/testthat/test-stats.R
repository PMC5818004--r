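# expected exact one-tailed p for {1,2,3} vs {4,5,6}, frozen from full
# enumeration of the 20 equally likely rank splits (computed once below and
# asserted against the closed count 1/20)
test_that("Mann-Whitney exact p for fully separated triples equals full enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # independent oracle: enumerate every split of ranks 1..6 into two triples
  splits <- utils::combn(6, 3)
  u_obs <- sum(outer(a, b, `<`))   # = 9 wins for b, U_a = 0
  u_all <- apply(splits, 2, function(ix) {
    ra <- (1:6)[ix]; rb <- (1:6)[-ix]
    sum(outer(ra, rb, `<`))
  })
  p_enum <- mean(u_all >= u_obs)
  expect_equal(p_enum, 1 / 20)

  res <- rank_tests(c(a, b), rep(c("A", "B"), each = 3),
                    alternative = "less")
  expect_equal(res$p_value, 0.05, tolerance = 1e-12)
})

test_that("identical groups give p = 1 and the one-tailed result is flagged", {
  res <- rank_tests(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3),
                    alternative = "less")
  expect_gte(res$p_value, 0.5)
  expect_true(attr(res, "flagged"))
  tied <- rank_tests(rep(5, 6), rep(c("A", "B"), each = 3))
  expect_equal(tied$p_value, 1)
  expect_true(attr(tied, "flagged"))
})

test_that("Kruskal-Wallis null simulation holds its nominal type-I error", {
  set.seed(515)
  reps <- 1000L
  # 20 observations per group: large enough that the chi-square reference
  # distribution holds its nominal level
  rej <- vapply(seq_len(reps), function(r) {
    y <- rnorm(60)
    g <- rep(c("a", "b", "c"), each = 20)
    stats::kruskal.test(y, factor(g))$p.value < 0.05
  }, TRUE)
  ci_half <- 2 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), ci_half)
})

test_that("Dunn post-hoc follows a significant Kruskal-Wallis and adjusts p", {
  set.seed(6)
  y <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 4))
  g <- rep(c("ctl", "t1", "t2"), each = 10)
  res <- rank_tests(y, g)
  expect_equal(res$test[1], "Kruskal-Wallis")
  expect_lt(res$p_value[1], 0.01)
  dunn <- res[res$test == "Dunn", ]
  expect_equal(nrow(dunn), 3L)
  expect_lt(dunn$p_value[dunn$comparison == "ctl vs t2"], 0.05)
  expect_gt(dunn$p_value[dunn$comparison == "ctl vs t1"], 0.05)
  expect_true(all(dunn$p_value >= 0 & dunn$p_value <= 1))
})

test_that("summary t-test reproduces the raw-data t-test on matched data", {
  # construct samples with exactly the requested mean and sd
  mk <- function(n, m, s) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / stats::sd(x)
  }
  set.seed(31)
  x <- mk(16, 17, 4); y <- mk(14, 5, 2)
  for (variant in c("pooled", "welch")) {
    res <- t_test_from_summary(group_summary("a", 16, 17, 4),
                               group_summary("b", 14, 5, 2), variant)
    ref <- stats::t.test(x, y, var.equal = variant == "pooled")
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical summaries give t = 0, p = 1; p is monotone in the effect size", {
  g <- group_summary("a", 10, 5, 2)
  res <- t_test_from_summary(g, group_summary("b", 10, 5, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  ps <- vapply(c(5.5, 6, 7, 9), function(m)
    t_test_from_summary(group_summary("a", 10, m, 2),
                        group_summary("b", 10, 5, 2))$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(group_summary("bad", 1, 0, 1))
})

test_that("two-group ANOVA reduces to the pooled t-test (F = t^2)", {
  set.seed(77)
  y <- c(rnorm(8, 0, 1), rnorm(9, 1.2, 1))
  g <- rep(c("ctl", "trt"), c(8, 9))
  res <- anova_dunnett(y, g, control = "ctl")
  f_row <- res[res$test == "one-way ANOVA", ]
  t_row <- res[grepl("^t", res$test), ]
  expect_equal(f_row$statistic, t_row$statistic^2, tolerance = 1e-9)
  expect_equal(f_row$p_value, t_row$p_value, tolerance = 1e-9)
})

test_that("degenerate constant groups are flagged rather than reported as infinite F", {
  y <- rep(c(1, 2, 3), each = 4)
  g <- rep(c("ctl", "t1", "t2"), each = 4)
  res <- anova_dunnett(y, g, control = "ctl")
  expect_true(attr(res, "flagged"))
  expect_true(is.na(res$statistic[1]))
  expect_error(anova_dunnett(c(1, 2, 3), c("a", "a", "b"), "a"),
               "at least 2")
})

test_that("Dunnett familywise error stays near nominal under the null", {
  set.seed(88)
  reps <- 300L
  fw <- vapply(seq_len(reps), function(r) {
    y <- rnorm(30)
    g <- rep(c("ctl", "t1", "t2"), each = 10)
    res <- suppressWarnings(anova_dunnett(y, g, "ctl"))
    any(res$p_value[res$test == "Dunnett"] < 0.05)
  }, TRUE)
  expect_lte(mean(fw), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("synthetic PI3K-inhibition cohorts reproduce the compactness direction", {
  ctl <- unlist(lapply(1:4, function(i)
    render_cell_frames(n_frames = 3, n_protrusions = 5, protrusion_length = 4,
                       body_radius = 5.5, seed = i,
                       cell_id = paste0("ctl", i))), recursive = FALSE)
  wort <- unlist(lapply(1:4, function(i)
    render_cell_frames(n_frames = 3, n_protrusions = 1,
                       protrusion_length = 1.5, body_radius = 4.5,
                       seed = 20 + i, cell_id = paste0("w", i))),
    recursive = FALSE)
  tab <- morphology_table(list(CTL = ctl, WORT = wort))
  med <- function(v) tapply(tab[[v]], tab$group, stats::median)
  expect_gt(med("solidity")[["WORT"]], med("solidity")[["CTL"]])
  expect_gt(med("circularity")[["WORT"]], med("circularity")[["CTL"]])
  expect_lt(med("area_um2")[["WORT"]], med("area_um2")[["CTL"]])
  for (v in c("solidity", "circularity", "area_um2")) {
    p <- rank_tests(tab[[v]], tab$group)$p_value
    expect_lt(p, 0.01)
  }
})

test_that("figure parity report renders available panels and lists missing inputs", {
  out <- withr::local_tempdir()
  cl <- tibble::tibble(frame = 1:5, time_min = (0:4) * 18,
                       hull_volume_um3 = c(5000, 4000, 3500, 3300, 3200),
                       n_points = 5, degenerate = FALSE)
  filo <- data.frame(group = rep(c("ext", "ret"), each = 10),
                     rate_um_min = c(rnorm(10, 3.2, 1), rnorm(10, -2.9, 1)))
  rpt <- figure_parity_report(out, clustering = cl, filo_rates = filo)
  txt <- readLines(rpt)
  expect_true(file.exists(file.path(out, "clustering.png")))
  expect_true(file.exists(file.path(out, "filopodia_rates.png")))
  expect_true(any(grepl("Missing inputs", txt)))
  expect_true(any(grepl("islet volume table", txt)))
  # rerun is identical in content
  out2 <- withr::local_tempdir()
  rpt2 <- figure_parity_report(out2, clustering = cl, filo_rates = filo)
  expect_identical(readLines(rpt), readLines(rpt2))
})
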