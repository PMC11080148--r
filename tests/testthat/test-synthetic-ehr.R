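# Synthetic cohort generator: sizes, determinism, quota exactness,
# marginal-parameter recovery, config validation, CSV round trips.

test_that("generator produces the requested number of valid records", {
  tab <- generate_center(generator_config("c", 40L, seed = 1L))
  expect_s3_class(tab, "flat_table")
  expect_equal(nrow(tab$records), 40L)
  expect_true(all(tab$records$hospital_id == "c"))
  expect_false(anyDuplicated(tab$records$patient_id) > 0)
  r <- tab$records
  expect_true(all(r$date_of_diagnosis <= r$date_of_surgery))
  neo <- !is.na(r$date_neoadjuvant_start)
  expect_true(all(r$date_of_diagnosis[neo] <= r$date_neoadjuvant_start[neo]))
  expect_true(all(r$date_neoadjuvant_start[neo] <= r$date_of_surgery[neo]))
  expect_true(all(r$asa_class %in% 1:5))
  expect_true(all(r$age >= 0))
  expect_true(all(r$bmi > 0))

  empty <- generate_center(generator_config("c", 0L, seed = 1L))
  expect_equal(nrow(empty$records), 0L)
})

test_that("same config and seed give a byte-identical serialized table", {
  cfg <- generator_config("det", 25L, seed = 99L)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_flat_table(generate_center(cfg), f1)
  write_flat_table(generate_center(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  cfg2 <- generator_config("det", 25L, seed = 100L)
  expect_false(identical(readLines(f1),
                         {write_flat_table(generate_center(cfg2), f2); readLines(f2)}))
})

test_that("quota mode matches requested marginal counts exactly", {
  set.seed(5)
  for (seed in sample.int(10000L, 10L)) {
    den_c <- sample(3:20, 1); num_c <- sample.int(den_c, 1)
    den_r <- sample(3:20, 1); num_r <- sample.int(den_r, 1)
    n <- den_c + den_r + sample(0:10, 1)
    tab <- generate_center(generator_config(
      "q", n, seed = seed,
      quota_counts = list(colon = c(den_c, num_c), rectum = c(den_r, num_r))))
    r <- tab$records
    expect_equal(nrow(r), n)
    colon <- r[r$tumor_localization == "colon" & !r$referred, ]
    rectum <- r[r$tumor_localization == "rectum" & !r$referred, ]
    expect_equal(nrow(colon), den_c)
    expect_equal(nrow(rectum), den_r)
    therapy <- first_therapy_date(colon$date_neoadjuvant_start, colon$date_of_surgery)
    expect_equal(sum(as.integer(therapy - colon$date_of_diagnosis) < 35L), num_c)
    expect_equal(sum(rectum$postop_complication), num_r)
    # records beyond the quota denominators are referred
    expect_equal(sum(!r$referred), den_c + den_r)
  }
})

test_that("bernoulli mode recovers the complication probability at n = 5000", {
  p <- 0.3; n <- 5000L
  tab <- generate_center(generator_config("bern", n, seed = 321L,
                                          referred_fraction = 0,
                                          complication_prob = p))
  k <- sum(tab$records$postop_complication)
  ci <- stats::binom.test(k, n, conf.level = 0.99)$conf.int
  expect_gte(p, ci[1])
  expect_lte(p, ci[2])
})

test_that("invalid configurations fail with errors naming the field", {
  expect_error(generator_config("c", 10L, seed = 1L, complication_prob = 1.2),
               "complication_prob")
  expect_error(generator_config("c", 10L, seed = 1L,
                                quota_counts = list(rectum = c(5L, 9L))),
               "quota infeasible")
  expect_error(generator_config("c", 5L, seed = 1L,
                                quota_counts = list(colon = c(4L, 1L),
                                                    rectum = c(4L, 1L))),
               "quota infeasible")
  expect_error(generator_config("c", 10L, seed = 1L,
                                age = list(name = "sphere")),
               "age")
  expect_error(
    generate_center(generator_config("c", 10L, seed = 1L,
                                     bmi = list(name = "normal", mean = 25))),
    "bmi")
})

test_that("CSV round trip is the identity, including absent optional dates", {
  tab <- tiny_table()
  path <- tempfile(fileext = ".csv")
  write_flat_table(tab, path)
  back <- read_flat_table(path)
  expect_identical(back$records, tab$records)
  expect_identical(back$center_id, tab$center_id)
  # the missing neoadjuvant date serializes to an empty cell
  raw <- read.csv(path, colClasses = "character")
  expect_identical(raw$date_neoadjuvant_start[1], "")
  expect_true(is.na(back$records$date_neoadjuvant_start[1]))

  big <- generate_center(generator_config("rt", 60L, seed = 3L))
  write_flat_table(big, path)
  expect_identical(read_flat_table(path)$records, big$records)
})

test_that("schema problems in CSV input are reported by name", {
  tab <- tiny_table()
  path <- tempfile(fileext = ".csv")
  write_flat_table(tab, path)
  lines <- readLines(path)
  # drop the surgery-date column
  drop_col <- function(lines, idx) {
    vapply(lines, function(l) {
      parts <- strsplit(l, ",", fixed = TRUE)[[1]]
      paste(parts[-idx], collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  header <- strsplit(lines[1], ",")[[1]]
  idx <- which(header == "date_of_surgery")
  writeLines(drop_col(lines, idx), path)
  expect_error(read_flat_table(path), "date_of_surgery")

  write_flat_table(tab, path)
  lines <- readLines(path)
  lines[3] <- sub("2021-04-15", "not-a-date", lines[3], fixed = TRUE)
  writeLines(lines, path)
  expect_error(read_flat_table(path), "row 2.*date_of_surgery|date_of_surgery.*row 2")
})

test_that("distribution specs sample within their stated bounds", {
  withr::with_seed(1, {
    x <- sample_dist(list(name = "normal", mean = 50, sd = 30, min = 0, max = 60,
                          integer = TRUE), 500)
    expect_true(all(x >= 0 & x <= 60))
    expect_true(all(x == round(x)))
    asa <- sample_dist(list(name = "categorical", values = 1:4,
                            probs = c(.2, .5, .25, .05)), 500)
    expect_true(all(asa %in% 1:4))
    expect_identical(sample_dist(list(name = "constant", value = 7), 3), rep(7, 3))
    expect_error(sample_dist(list(name = "normal", mean = 1), 5, field = "age"), "sd")
  })
})
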