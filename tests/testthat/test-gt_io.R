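test_that("interest-over-time parser maps tokens and shares months", {
  txt <- gt_csv(c("2004-01", "2004-02", "2004-03"),
                itch = c("100", "<1", "0"))
  s <- parse_interest_over_time(txt)
  expect_length(s, 1)
  expect_identical(s[[1]]$values, c("100", "<1", "0"))
  expect_false(s[[1]]$imputed)

  two <- parse_interest_over_time(
    gt_csv(c("2004-01", "2004-02"), itch = c(10, 20), scar = c(5, "<1%")))
  expect_length(two, 2)
  expect_identical(two[[1]]$months, two[[2]]$months)
  expect_identical(two[[2]]$values, c("5", "<1%"))
})

test_that("parser rejects malformed, non-monthly, and out-of-range input", {
  expect_error(parse_interest_over_time("Month,x\n2004-13,5"),
               "row 2.*2004-13")
  expect_error(parse_interest_over_time("Month,x\n2004-01,5\n2004-03,6"),
               "non-contiguous")
  expect_error(parse_interest_over_time("Month,x\n2004-01,105"),
               "outside integer range")
  expect_error(parse_interest_over_time("Month,x\n2004-01-04,5"),
               "day component")
  expect_error(parse_interest_over_time("Month,x\n2004-01,3.7"),
               "outside integer range")
})

test_that("region parser handles shares, masking, and bad sums", {
  txt <- paste("Country,itch,scar", "Germany,60,40", "Iceland,,",
               sep = "\n")
  tbl <- parse_interest_by_region(txt)
  expect_identical(tbl$share_topic[tbl$country == "Germany"], 60)
  expect_false(tbl$masked[tbl$country == "Germany"])
  expect_true(tbl$masked[tbl$country == "Iceland"])

  expect_error(parse_interest_by_region("Country,a,b\nFrance,70,40"),
               "France")
})

test_that("imputation maps censored to 0.5 and zero to 0.1, preserving order", {
  s <- impute_censored(raw_series(c("57", "<1", "0", "1")))
  expect_identical(s$values, c(57, 0.5, 0.1, 1))
  expect_true(s$imputed)
  expect_error(impute_censored(s), "already imputed")
  # numeric order matches token order: zero < censored < 1 <= integers
  imp_all <- impute_censored(raw_series(c("0", "<1", "1", "2")))
  expect_true(all(diff(imp_all$values) > 0))

  tbl <- region_share_table("itch", "scar", c("DE", "NO"),
                            c(0, 100), c(100, 0))
  imp <- impute_censored(tbl)
  expect_identical(imp$share_topic, c(0.1, 100))
  expect_identical(imp$share_reference, c(100, 0.1))
  expect_error(impute_censored(imp), "already imputed")
})

test_that("parse -> write -> parse is the identity on well-formed exports", {
  txt <- gt_csv(months_n(24), itch = sample(0:100, 24, TRUE),
                scar = c("<1", sample(0:100, 23, TRUE)), preamble = FALSE)
  s1 <- parse_interest_over_time(txt)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interest_over_time(s1, path)
  s2 <- parse_interest_over_time(readLines(path))
  expect_identical(lapply(s2, unclass), lapply(s1, unclass))

  tbl <- parse_interest_by_region(
    paste("Country,itch,scar", "DE,60,40", "IS,,", "NO,99,1", sep = "\n"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_interest_by_region(tbl, path2)
  tbl2 <- parse_interest_by_region(readLines(path2))
  expect_equal(tbl2$share_topic, tbl$share_topic)
  expect_identical(tbl2$masked, tbl$masked)
})

test_that("write_table renders tables deterministically in both modes", {
  rows <- data.frame(topic = c("cellulite", "itch"),
                     amplitude = c(43.77, 8.524999),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(rows, path, format = "csv", mode = "report", digits = 2)
  back <- utils::read.csv(path)
  expect_equal(back$amplitude, c(43.77, 8.52))

  pj <- withr::local_tempfile(fileext = ".json")
  write_table(rows, pj, format = "json")
  back_j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(back_j$amplitude, rows$amplitude)  # machine mode: full precision

  expect_error(write_table(rows[0, ], path), "non-empty")
})
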