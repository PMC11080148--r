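# Indicator arithmetic: therapy-date combination, strict 35-day boundary,
# published per-center count pairs, monotonicity, exactness of stored
# ratios versus display rounding.

test_that("first therapy date is the earlier of neoadjuvant start and surgery", {
  expect_equal(first_therapy_date(as.Date("2021-02-01"), as.Date("2021-03-10")),
               as.Date("2021-02-01"))
  expect_equal(first_therapy_date(as.Date(NA), as.Date("2021-03-10")),
               as.Date("2021-03-10"))
  expect_equal(first_therapy_date(as.Date("2021-03-10"), as.Date("2021-03-10")),
               as.Date("2021-03-10"))
})

make_wait_rows <- function(waits, localization = "colon") {
  n <- length(waits)
  data.frame(
    tumor_localization = rep(localization, n), referred = rep(FALSE, n),
    date_of_diagnosis = rep(as.Date("2021-01-01"), n),
    date_neoadjuvant_start = as.Date(rep(NA_character_, n)),
    date_of_surgery = as.Date("2021-01-01") + waits,
    stringsAsFactors = FALSE
  )
}

test_that("the 5-week boundary is strict: exactly 35 days is excluded", {
  rows <- make_wait_rows(c(33L, 34L, 35L, 36L))
  res <- qi2b(rows)
  expect_equal(res$denominator, 4L)
  expect_equal(res$numerator, 2L)  # 33 and 34 only
  expect_equal(res$ratio, 0.5)
})

test_that("qi2b reproduces the published per-center colon counts", {
  res2 <- qi2b(make_wait_rows(c(rep(10L, 7L), rep(40L, 3L))), center_id = "c2")
  expect_equal(res2$denominator, 10L)
  expect_equal(res2$numerator, 7L)
  expect_equal(res2$ratio, 0.70)

  res1 <- qi2b(make_wait_rows(rep(20L, 546L)), center_id = "c1")
  expect_equal(res1$denominator, 546L)
  expect_equal(res1$numerator, 546L)
  expect_equal(res1$ratio, 1.0)
})

make_comp_rows <- function(complications, localization = "rectum",
                           referred = FALSE) {
  data.frame(tumor_localization = localization, referred = referred,
             postop_complication = complications, stringsAsFactors = FALSE)
}

test_that("qi8 reproduces the published per-center rectum rates", {
  res2 <- qi8(make_comp_rows(c(rep(TRUE, 4L), rep(FALSE, 3L))))
  expect_equal(res2$denominator, 7L)
  expect_equal(res2$numerator, 4L)
  expect_equal(round(res2$ratio, 3), 0.571)

  res1 <- qi8(make_comp_rows(c(rep(TRUE, 2144L), rep(FALSE, 4153L - 2144L))))
  expect_equal(res1$denominator, 4153L)
  expect_equal(res1$numerator, 2144L)
  expect_equal(round(res1$ratio, 3), 0.516)

  res0 <- qi8(make_comp_rows(rep(FALSE, 9L)))
  expect_equal(res0$ratio, 0)
})

test_that("referred patients and other localizations leave the cohort", {
  rows <- rbind(make_comp_rows(c(TRUE, FALSE)),
                make_comp_rows(TRUE, referred = TRUE),
                make_comp_rows(TRUE, localization = "colon"))
  res <- qi8(rows)
  expect_equal(res$denominator, 2L)
  expect_equal(res$numerator, 1L)
  res_incl <- qi8(rows, indicator_spec("qi8", exclude_referred = FALSE))
  expect_equal(res_incl$denominator, 3L)
})

test_that("empty cohorts warn and return an undefined ratio", {
  expect_warning(res <- qi8(make_comp_rows(TRUE, localization = "colon")),
                 "undefined")
  expect_true(is.na(res$ratio))
  expect_equal(res$denominator, 0L)
  expect_warning(qi2b(make_wait_rows(integer(0))), "undefined")
})

test_that("adding a numerator record never lowers the ratio, and vice versa", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    rows <- make_comp_rows(sample(c(TRUE, FALSE), n, replace = TRUE))
    base <- qi8(rows)$ratio
    up <- qi8(rbind(rows, make_comp_rows(TRUE)))$ratio
    down <- qi8(rbind(rows, make_comp_rows(FALSE)))$ratio
    expect_gte(up, base)
    expect_lte(down, base)
  }
})

test_that("results store exact integers; rounding is display-only", {
  res <- qi8(make_comp_rows(c(rep(TRUE, 4L), rep(FALSE, 3L))))
  expect_identical(res$numerator, 4L)
  expect_identical(res$denominator, 7L)
  expect_identical(res$ratio, 4 / 7)
  expect_identical(fedqi:::format_ratio(res$ratio, "qi8"), "0.571")
  expect_identical(fedqi:::format_ratio(0.7, "qi2b"), "70%")
})
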