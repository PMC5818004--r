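test_that("traced straight and curved filopodia recover known lengths", {
  tr <- trace_filopodium(masks = list(fx_filopodium_mask(6)), base = c(30, 20),
                         pixel_size = 0.1, frame_times = 0)
  expect_equal(tr$length_um, 6, tolerance = 0.2 / 6)

  # quarter circle of radius 4: arc length 2*pi exceeds the chord 4*sqrt(2)
  px <- 0.1
  yy <- (1:100 - 0.5) * px; xx <- (1:120 - 0.5) * px
  dy <- outer(yy - 2, rep(1, 120)); dx <- outer(rep(1, 100), xx - 2)
  rr <- sqrt(dy^2 + dx^2)
  arc <- abs(rr - 4) <= 0.25 & dy >= 0 & dx >= 0
  trc <- trace_filopodium(masks = list(arc), base = c(20, 60),
                          pixel_size = px, frame_times = 0)
  expect_equal(trc$length_um, 2 * pi, tolerance = 0.05)
  expect_gt(trc$length_um, 4 * sqrt(2))

  # empty frame records length 0 with no tip
  tr0 <- trace_filopodium(masks = list(matrix(FALSE, 20, 20)), base = c(10, 1),
                          pixel_size = px, frame_times = 0)
  expect_equal(tr0$length_um, 0)
  expect_true(is.na(tr0$tip_x))
})

test_that("manual tip annotations override tracing and handle retracted frames", {
  tips <- data.frame(frame = c(1, 3), y_um = c(0, 0), x_um = c(4, 6))
  tr <- trace_filopodium(base = c(0, 0), frame_times = c(0, 0.25, 0.5),
                         tips = tips)
  expect_equal(tr$length_um, c(4, 0, 6))
  expect_true(all(tr$method == "annotated"))
})

test_that("linear growth at 3.2 um/min yields that exact instantaneous rate everywhere", {
  fs <- filopodium_spec(segments = data.frame(duration_min = 2,
                                              rate_um_min = 3.2))
  tr <- trace_from_spec(fs, frame_times = seq(0, 2, by = 0.25))
  rr <- filopodium_rates(tr, dead_band = 0)
  expect_true(all(abs(rr$rates$rate_um_min - 3.2) < 1e-9))
  expect_equal(rr$mean_extension_rate, 3.2)
})

test_that("piecewise programs recover segment rates and max length exactly", {
  fs <- filopodium_spec(segments = data.frame(duration_min = c(1, 1),
                                              rate_um_min = c(3, -2)))
  tr <- trace_from_spec(fs, frame_times = seq(0, 2, by = 0.25))
  rr <- filopodium_rates(tr, dead_band = 0)
  expect_equal(rr$max_length_um, 3)
  expect_equal(rr$mean_extension_rate, 3)
  expect_equal(rr$mean_retraction_rate, 2)
})

test_that("stochastic rate simulations recover the mean within 2 standard errors", {
  set.seed(202)
  true_rate <- 3.2; sd_rate <- 1.2; n_steps <- 60L; dt <- 0.25
  reps <- 20L
  means <- vapply(seq_len(reps), function(r) {
    rates <- rnorm(n_steps, true_rate, sd_rate)
    lens <- cumsum(c(5, rates * dt))     # start long enough to stay positive
    tr <- tibble::tibble(time_min = seq(0, by = dt, length.out = n_steps + 1),
                         length_um = lens, filopodium_id = "f")
    rr <- filopodium_rates(tr, dead_band = 0)
    mean(rr$rates$rate_um_min)
  }, 0)
  sem <- sd_rate / sqrt(n_steps * reps)
  expect_lt(abs(mean(means) - true_rate), 2 * sem)
})

test_that("rates are antisymmetric under time reversal and telescope to the net change", {
  set.seed(9)
  lens <- abs(cumsum(rnorm(12, 0, 1))) + 2
  tm <- cumsum(runif(12, 0.2, 0.4))
  tr <- tibble::tibble(time_min = tm, length_um = lens, filopodium_id = "f")
  rr <- filopodium_rates(tr, dead_band = 0)
  rev_tr <- tibble::tibble(time_min = max(tm) - rev(tm),
                           length_um = rev(lens), filopodium_id = "f")
  rr_rev <- filopodium_rates(rev_tr, dead_band = 0)
  expect_equal(rr_rev$rates$rate_um_min, -rev(rr$rates$rate_um_min),
               tolerance = 1e-9)
  total <- sum(rr$rates$rate_um_min * diff(tm))
  expect_equal(total, lens[12] - lens[1], tolerance = 1e-9)
})

test_that("max length is invariant to subsampling for monotone growth", {
  fs <- filopodium_spec(segments = data.frame(duration_min = 3,
                                              rate_um_min = 2))
  t_full <- seq(0, 3, by = 0.25)
  tr_full <- trace_from_spec(fs, t_full)
  tr_sub <- trace_from_spec(fs, t_full[seq(1, length(t_full), by = 2)])
  expect_equal(filopodium_rates(tr_full, 0)$max_length_um,
               filopodium_rates(tr_sub, 0)$max_length_um)
})

test_that("length distribution reports the below/above threshold descriptors", {
  traces <- lapply(c(2, 5, 8, 16), function(mx)
    tibble::tibble(time_min = c(0, 1), length_um = c(0, mx)))
  ld <- length_distribution(traces)
  expect_equal(ld$fraction_below, 0.75)
  expect_equal(ld$n_above, 1L)
  # degenerate: all equal -> step CDF
  same <- lapply(1:3, function(i)
    tibble::tibble(time_min = c(0, 1), length_um = c(0, 7)))
  lds <- length_distribution(same)
  expect_equal(lds$ecdf(6.9), 0)
  expect_equal(lds$ecdf(7), 1)
})

test_that("cohort max-length fractions match the generating mixture", {
  set.seed(404)
  n <- 200L
  short <- runif(round(n * 0.8), 2, 8)     # 80% short filopodia
  long <- runif(n - length(short), 10, 18)
  traces <- lapply(c(short, long), function(mx)
    tibble::tibble(time_min = c(0, 1), length_um = c(0, mx)))
  ld <- length_distribution(traces, below_um = 9, above_um = 15)
  ci_half <- 2 * sqrt(0.8 * 0.2 / n)
  expect_lt(abs(ld$fraction_below - 0.8), ci_half)
})
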