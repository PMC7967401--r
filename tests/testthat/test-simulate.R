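test_that("latent simulation follows the additive model deterministically", {
  m <- latent_topic_model("t", baseline = 40, slope = 0,
                          noise_sd = 0, popularity_ratio = 1.5)
  mo <- months_n(24)
  expect_equal(simulate_latent(m, mo, seed = 1), rep(60, 24))  # baseline*rho

  m2 <- latent_topic_model("t", baseline = 10, slope = 12, noise_sd = 0)
  x <- simulate_latent(m2, mo, seed = 1)
  expect_equal(diff(x), rep(1, 23))  # 12/year = +1 per month

  m3 <- latent_topic_model("t", baseline = 50, slope = 1, noise_sd = 3)
  expect_identical(simulate_latent(m3, mo, seed = 99),
                   simulate_latent(m3, mo, seed = 99))
  expect_false(identical(simulate_latent(m3, mo, seed = 99),
                         simulate_latent(m3, mo, seed = 100)))
})

test_that("latent model validates its invariants", {
  expect_error(latent_topic_model("t", baseline = 5,
                                  monthly_pattern = c(rep(-6, 1), rep(6/11, 11))),
               "non-positive")
  expect_error(latent_topic_model("t", baseline = 10,
                                  monthly_pattern = rep(1, 12)),
               "sum to 0")
  expect_error(latent_topic_model("t", baseline = 10, december_dip = 2),
               "december_dip")
})

test_that("the single-series transform rescales to max 100 with censoring", {
  mo <- months_n(4)
  lat <- c(500, 2, 250, 0)
  s <- gt_transform_single(lat, "t", mo)
  expect_identical(s$values, c("100", "<1", "50", "0"))
  expect_equal(attr(s, "scale_factor"), 100 / 500)

  # scale invariance: multiplying the latent series changes nothing
  s7 <- gt_transform_single(lat * 7, "t", mo)
  expect_identical(s7$values, s$values)

  expect_error(gt_transform_single(rep(0, 4), "t", mo), "all-zero")

  cont <- gt_transform_single(lat, "t", mo, quantize = FALSE)
  expect_true(cont$imputed)
  expect_equal(cont$values, 100 * lat / 500)
})

test_that("the pairwise transform shares one scale across both series", {
  mo <- months_n(3)
  b <- c(10, 50, 30)
  pw <- gt_transform_pairwise(2 * b, b, "a", "scar", mo, quantize = FALSE)
  expect_equal(max(pw$topic$values), 100)
  expect_equal(max(pw$reference$values), 50)

  same <- gt_transform_pairwise(b, b, "a", "scar", mo)
  expect_identical(same$topic$values, same$reference$values)
})

test_that("a known popularity ratio survives the pipeline end to end", {
  mo <- months_n(12)
  ref_latent <- seq(40, 95, length.out = 12)
  pw <- gt_transform_pairwise(0.3 * ref_latent, ref_latent, "t", "scar", mo)
  est <- adjusted_proportion(pairwise_comparison(
    impute_censored(pw$topic), impute_censored(pw$reference)))
  expect_lt(abs(est$value - 0.3), 0.01)
})

test_that("region breakdown shares follow the weight ratios", {
  w <- make_world_fixture("study", seed = 2)
  # overwrite two countries' weights to known values
  w$weights["DE", "itch"] <- 4; w$weights["DE", "scar"] <- 4
  w$weights["FR", "itch"] <- 8; w$weights["FR", "scar"] <- 2
  rb <- simulate_region_breakdown(w, "itch", "scar")
  tbl <- rb$table
  expect_equal(tbl$share_topic[tbl$country == "DE"], 50)
  expect_equal(tbl$share_topic[tbl$country == "FR"], 80)
  expect_equal(tbl$share_reference[tbl$country == "FR"], 20)
  # masked countries emit masked rows and the truth is carried alongside
  expect_identical(tbl$masked, w$countries$masked | is.na(rb$truth$true_share_topic))
  expect_equal(rb$truth$true_share_topic[tbl$country == "FR"], 80)
})

test_that("world fixtures are deterministic functions of preset and seed", {
  expect_identical(make_world_fixture("study", seed = 5),
                   make_world_fixture("study", seed = 5))
  expect_false(identical(make_world_fixture("study", seed = 5)$weights,
                         make_world_fixture("study", seed = 6)$weights))
  expect_error(make_world_fixture("volcanic", seed = 1), "arg")
})

test_that("presets encode the intended study conditions", {
  w <- make_world_fixture("study", seed = 4)
  rho <- vapply(w$topics, function(t) t$popularity_ratio, numeric(1))
  expect_equal(unname(range(rho)), c(0.01, 2.21))
  expect_identical(names(which.max(rho)), "itch")
  expect_equal(w$topics$scar$popularity_ratio, 1)
  # one aseasonal topic
  aseasonal <- vapply(w$topics, function(t) all(t$monthly_pattern == 0),
                      logical(1))
  expect_identical(names(which(aseasonal)), "hair_loss")
  # about a tenth of countries masked
  expect_lt(mean(w$countries$masked), 0.25)

  null_w <- make_world_fixture("null", seed = 4)
  expect_true(all(vapply(null_w$topics, function(t) t$slope == 0,
                         logical(1))))
  expect_true(all(vapply(null_w$topics,
                         function(t) all(t$monthly_pattern == 0),
                         logical(1))))

  south <- make_world_fixture("southern", seed = 4)
  for (id in c("itch", "cellulite", "dandruff")) {
    p_n <- which.max(w$topics[[id]]$monthly_pattern)
    p_s <- which.max(south$topics[[id]]$monthly_pattern)
    expect_equal((p_n - 1 + 6) %% 12 + 1, p_s)  # 6 months apart
  }
})

test_that("world CSV export round-trips through the parsers", {
  w <- make_world_fixture("study", seed = 8, n_months = 48)
  dir <- withr::local_tempdir()
  simulate_world_csvs(w, dir)
  expect_true(file.exists(file.path(dir, "pairwise_itch.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))

  s <- parse_interest_over_time(
    readLines(file.path(dir, "pairwise_itch.csv")))
  expect_length(s, 2)
  expect_identical(s[[2]]$topic_id, "scar")
  expect_length(s[[1]]$values, 48L)

  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$topics$itch$popularity_ratio, 2.21)
  expect_identical(gt$seed, 8L)
})
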