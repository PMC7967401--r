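test_that("adjusted proportion is a ratio of means anchored at 1 for the reference", {
  ref <- imputed_series(rep(40, 24), "scar")
  top <- imputed_series(rep(80, 24), "itch")
  expect_identical(
    adjusted_proportion(pairwise_comparison(top, ref))$value, 2)

  # reference against itself is exactly 1.00 by construction
  self <- adjusted_proportion(
    pairwise_comparison(imputed_series(rep(37, 24), "scar"),
                        imputed_series(rep(37, 24), "scar")))
  expect_identical(self$value, 1)

  # fully censored topic: 0.5 / 50
  cens <- impute_censored(raw_series(rep("<1", 192), "rare"))
  ref50 <- imputed_series(rep(50, 192), "scar")
  expect_equal(adjusted_proportion(pairwise_comparison(cens, ref50))$value,
               0.01)
})

test_that("adjusted proportion is invariant to the joint scale factor", {
  set.seed(11)
  for (c_mult in c(0.03, 1, 7, 250)) {
    a <- runif(36, 1, 90)
    b <- runif(36, 1, 90)
    p1 <- adjusted_proportion(pairwise_comparison(
      imputed_series(pmin(a, 100), "t"), imputed_series(pmin(b, 100), "scar")))
    p2 <- adjusted_proportion(pairwise_comparison(
      imputed_series(pmin(a * c_mult, 100 * c_mult) / c_mult, "t"),
      imputed_series(pmin(b * c_mult, 100 * c_mult) / c_mult, "scar")))
    expect_equal(p2$value, p1$value, tolerance = 1e-12)
  }
})

test_that("pairwise comparison enforces matching months and imputation", {
  a <- imputed_series(rep(10, 24), "a")
  b <- imputed_series(rep(10, 24), "b", start = "2005-01")
  expect_error(pairwise_comparison(a, b), "share months")
  expect_error(pairwise_comparison(a, raw_series(rep("5", 24), "b")),
               "imputed")
  short <- imputed_series(rep(5, 6), "a")
  expect_error(
    adjusted_proportion(pairwise_comparison(short,
                                            imputed_series(rep(5, 6), "b"))),
    "12 months")
})

test_that("region anchoring pins the reference at 50", {
  tbl <- impute_censored(region_share_table(
    "itch", "scar",
    c("DE", "FR", "NO", "IS"),
    c(50, 80, 0, NA), c(50, 20, 100, NA),
    masked = c(FALSE, FALSE, FALSE, TRUE)))
  a <- anchor_region(tbl)
  expect_equal(a$value[a$country == "DE"], 50)
  expect_equal(a$value[a$country == "FR"], 200)
  expect_equal(a$value[a$country == "NO"], 50 * 0.1 / 100)  # 0.05
  expect_true(is.na(a$value[a$country == "IS"]))
  expect_identical(a$reason[a$country == "IS"], "masked")
  expect_error(anchor_region(region_share_table("a", "b", "DE", 50, 50)),
               "imputed")
})

test_that("low-volume exclusion uses the strict five-topic boundary", {
  mk_country <- function(cty, n_pos, n_topics = 8) {
    data.frame(country = cty, topic_id = paste0("t", seq_len(n_topics)),
               value = c(rep("10", n_pos), rep("0", n_topics - n_pos)),
               stringsAsFactors = FALSE)
  }
  rv <- rbind(mk_country("four", 4), mk_country("five", 5),
              mk_country("all", 8))
  expect_identical(exclude_low_volume(rv), "four")

  # censored values count as above null; masked cells do not
  rv2 <- data.frame(country = "c", topic_id = paste0("t", 1:6),
                    value = c("<1", "<1", "3", "9", "1", NA),
                    stringsAsFactors = FALSE)
  expect_length(exclude_low_volume(rv2), 0)
  rv2$value[1:2] <- NA
  expect_identical(exclude_low_volume(rv2), "c")
})

test_that("country ranking orders by anchored value with registry tie-breaks", {
  reg <- default_registry()
  anchored <- data.frame(
    country = rep(c("DE", "TIE", "FLAT"), each = 2),
    topic_id = rep(c("itch", "hair_loss"), 3),
    value = c(110, 80, 70, 70, 50, 50),
    stringsAsFactors = FALSE)
  rk <- rank_topics_by_country(anchored, reg)
  expect_identical(rk$winner[rk$country == "DE"], "itch")
  # tie at 70: hair_loss precedes itch in registry order
  expect_identical(rk$winner[rk$country == "TIE"], "hair_loss")
  expect_true(rk$tie[rk$country == "TIE"])
  # all listed topics at 50 tie with the reference; earliest registry topic
  # wins and the tie is recorded
  expect_true(rk$tie[rk$country == "FLAT"])

  rk2 <- rank_topics_by_country(anchored, reg, excluded = c("DE"))
  expect_true(rk2$excluded[rk2$country == "DE"])
  expect_true(is.na(rk2$winner[rk2$country == "DE"]))
  expect_identical(rk2$reason[rk2$country == "DE"], "low_volume")
})

test_that("ranking is invariant under strictly increasing transforms", {
  reg <- default_registry()
  set.seed(5)
  vals <- runif(34, 1, 200)
  anchored <- data.frame(country = "X", topic_id = reg$topics$id,
                         value = vals, stringsAsFactors = FALSE)
  anchored$value[anchored$topic_id == "scar"] <- 50
  base_rank <- rank_topics_by_country(anchored, reg)
  # strictly increasing transforms that keep the reference anchor at 50
  fs <- list(function(x) 50 * (x / 50)^3,
             function(x) 2 * x - 50,
             function(x) 50 + 10 * log(x / 50))
  for (f in fs) {
    tr <- anchored
    tr$value <- f(tr$value)
    expect_identical(rank_topics_by_country(tr, reg)$top5, base_rank$top5)
  }
})
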