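test_that("the local linear smoother reproduces lines and constants", {
  x <- 1:20
  expect_equal(loess_smooth(x, 3 + 2 * x, span = 0.5, degree = 1),
               3 + 2 * x, tolerance = 1e-10)
  expect_equal(loess_smooth(x, rep(4, 20), span = 0.3, degree = 0),
               rep(4, 20), tolerance = 1e-12)
  expect_error(loess_smooth(1, 1, span = 1, degree = 1), "degree \\+ 1")
  expect_error(loess_smooth(c(1, 1, 2), 1:3, span = 1), "strictly increasing")
})

test_that("the smoother matches a direct weighted-least-squares fit", {
  # 7 points, span 5/7 (q = 5 neighbours), local linear fit at the centre
  xs <- as.numeric(1:7)
  set.seed(13)
  ys <- stats::rnorm(7, 10, 3)
  i <- 4
  d <- abs(xs - xs[i])
  idx <- order(d)[1:5]
  w <- (1 - (d[idx] / max(d[idx]))^3)^3
  fit <- stats::lm.wfit(cbind(1, xs[idx]), ys[idx], w)
  expected <- sum(fit$coefficients * c(1, xs[i]))
  got <- loess_smooth(xs, ys, span = 5 / 7, degree = 1)[i]
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("exact additive structure is recovered without noise", {
  n <- 96
  t_idx <- 0:(n - 1)
  pattern <- 8 * sin(2 * pi * (0:11) / 12)
  x <- 30 + 0.2 * t_idx + pattern[t_idx %% 12 + 1]
  d <- stl_periodic(x, period = 12)
  expect_equal(unname(d$monthly_component), pattern - mean(pattern),
               tolerance = 1e-6)
  expect_lt(max(abs(d$remainder)), 1e-6)
  expect_identical(d$peak_month, "April")    # sin peaks at t = 3 (April)
  expect_true(d$seasonal_present)

  flat <- stl_periodic(rep(12, 48), period = 12)
  expect_equal(unname(flat$monthly_component), numeric(12))
  expect_equal(flat$trend, rep(12, 48), tolerance = 1e-9)
  expect_true(flat$degenerate)
})

test_that("decomposition identities hold on arbitrary series", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(c(36, 60, 96, 192), 1)
    x <- stats::runif(n, 0, 100)
    d <- stl_periodic(x, period = 12)
    expect_lt(max(abs(d$trend + d$seasonal + d$remainder - x)), 1e-9)
    expect_lt(abs(sum(d$monthly_component)), 1e-9)
    expect_gte(d$amplitude, 0)
    expect_identical(d$peak_month,
                     names(which.max(d$monthly_component)))
    expect_identical(d$trough_month,
                     names(which.min(d$monthly_component)))
  }
})

test_that("amplitude is invariant to added constants and linear trends", {
  set.seed(17)
  pattern <- c(4, 2, 0, -3, -5, -2, 1, 3, 5, 2, -2, -5)
  pattern <- pattern - mean(pattern)
  x <- 40 + pattern[rep(1:12, 16)] + stats::rnorm(192, 0, 1)
  a0 <- stl_periodic(x, period = 12)$amplitude
  a_const <- stl_periodic(x + 25, period = 12)$amplitude
  a_trend <- stl_periodic(x + 3 * (0:191) / 12, period = 12)$amplitude
  expect_equal(a_const, a0, tolerance = 1e-9)
  expect_lt(abs(a_trend - a0), 0.5)
})

test_that("periodic decomposition agrees with stats::stl", {
  w <- make_world_fixture("study", seed = 3)
  for (id in c("cellulite", "itch", "dandruff")) {
    s <- impute_censored(simulate_interest_over_time(w, id))
    d <- stl_periodic(s)
    ref <- stats::stl(stats::ts(s$values, frequency = 12),
                      s.window = "periodic")
    ref_monthly <- ref$time.series[1:12, "seasonal"]
    expect_lt(max(abs(unname(d$monthly_component) - ref_monthly)), 0.5)
  }
})

test_that("the harmonic F-test flags seasonal series and not pure trends", {
  t_idx <- 0:191
  seas <- 10 * sin(2 * pi * t_idx / 12) + 0.3 * t_idx / 12 + 20
  st <- seasonality_test(seas, period = 12)
  expect_true(st$seasonal_present)
  expect_lt(st$seasonal_p, 1e-6)

  set.seed(8)
  trend_only <- 20 + 2 * t_idx / 12 + stats::rnorm(192, 0, 0.5)
  st2 <- seasonality_test(trend_only, period = 12)
  expect_gt(st2$seasonal_p, 0.001)  # no systematic seasonal signal

  # aseasonal topic in the study world: trend + noise only
  w <- make_world_fixture("study", seed = 12)
  hl <- impute_censored(simulate_interest_over_time(w, "hair_loss"))
  expect_false(stl_periodic(hl)$seasonal_present)
})

test_that("seasonal summary reports peak, trough and max-minus-min amplitude", {
  comps <- stats::setNames(numeric(12), month.name)
  comps["May"] <- 21.61; comps["December"] <- -22.16
  s <- seasonal_summary(comps)
  expect_equal(s$amplitude, 43.77)
  expect_identical(s$peak_month, "May")
  expect_identical(s$trough_month, "December")

  comps2 <- stats::setNames(numeric(12), month.name)
  comps2["July"] <- 5.32; comps2["December"] <- -3.20
  expect_equal(seasonal_summary(comps2)$amplitude, 8.52)

  zero <- seasonal_summary(numeric(12))
  expect_identical(zero$amplitude, 0)
  expect_true(zero$degenerate)
  expect_true(zero$tie)
  expect_identical(zero$peak_month, "January")  # earliest month on ties
})
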