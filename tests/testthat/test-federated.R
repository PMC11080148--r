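# Train dispatch and master aggregation: payload discipline, pooled-equals-
# federated sums, permutation invariance, mean semantics.

two_center_stations <- function() {
  list(
    host_station(triplify(generate_center(center1_quota_config())), "center1"),
    host_station(triplify(generate_center(center2_quota_config())), "center2")
  )
}

test_that("a train against the small-center fixture returns the published payload", {
  st <- host_station(triplify(generate_center(center2_quota_config())), "center2")
  res <- run_train(st, build_train(indicator_spec("qi8")))
  expect_equal(res$denominator, 7L)
  expect_equal(res$numerator, 4L)
  expect_equal(round(res$ratio, 3), 0.571)

  st_empty <- host_station(fair_graph(), "void")
  expect_warning(res0 <- run_train(st_empty, build_train(indicator_spec("qi8"))),
                 "undefined")
  expect_true(is.na(res0$ratio))
})

test_that("payloads carry exactly the aggregate fields, serialized and back", {
  st <- host_station(triplify(tiny_table()), "s")
  res <- run_train(st, build_train(indicator_spec("qi2b")))
  json <- jsonlite::toJSON(unclass(res), auto_unbox = TRUE)
  back <- jsonlite::fromJSON(json)
  expect_setequal(names(back),
                  c("center_id", "indicator_id", "denominator", "numerator",
                    "ratio", "suppressed"))
  expect_length(validate_payload(back), 0L)
})

test_that("payload validation rejects smuggled or inconsistent fields", {
  good <- list(center_id = "c", indicator_id = "qi8", denominator = 7L,
               numerator = 4L, ratio = 4 / 7, suppressed = FALSE)
  expect_length(validate_payload(good), 0L)

  bad <- good
  bad$patient_ids <- c("p1", "p2")
  v <- validate_payload(bad)
  expect_match(v, "patient_ids", all = FALSE)

  bad2 <- good
  bad2$numerator <- 9L
  expect_match(validate_payload(bad2), "exceeds", all = FALSE)

  bad3 <- good[-3]
  expect_match(validate_payload(bad3), "missing field 'denominator'", all = FALSE)
})

test_that("an adversarial train cannot push record-level data past the master", {
  leaky <- host_station(triplify(tiny_table()), "leak")
  # a compromised station implementation that appends patient ids
  orig <- leaky$return_payload
  leaky$return_payload <- function() {
    p <- orig()
    p$patient_ids <- c("p1", "p2", "p3")
    p
  }
  expect_error(run_train(leaky, build_train(indicator_spec("qi8"))),
               "patient_ids")
})

test_that("federated sums equal the pooled computation on concatenated tables", {
  tabs <- list(generate_center(center2_quota_config()),
               generate_center(generator_config("x", 35L, seed = 91L)),
               generate_center(generator_config("y", 50L, seed = 92L,
                                                rectum_fraction = 0.6)))
  stations <- lapply(tabs, function(t) host_station(triplify(t), t$center_id))
  for (qid in c("qi2b", "qi8")) {
    train <- build_train(indicator_spec(qid))
    global <- run_federated(stations, train)
    pooled <- do.call(rbind, lapply(tabs, function(t) t$records))
    loc <- if (qid == "qi2b") "colon" else "rectum"
    oracle <- rowSums(vapply(tabs, oracle_counts, numeric(2),
                             indicator_id = qid, localization = loc))
    expect_equal(sum(vapply(global$local_results, function(x) x$denominator,
                            numeric(1))), unname(oracle["denominator"]))
    expect_equal(sum(vapply(global$local_results, function(x) x$numerator,
                            numeric(1))), unname(oracle["numerator"]))
  }
})

test_that("the mean line and derived statistics match the published arithmetic", {
  stations <- two_center_stations()
  g2b <- run_federated(stations, build_train(indicator_spec("qi2b")))
  expect_equal(g2b$mean_ratio, 0.85)  # mean of 100% and 70%

  g8 <- run_federated(stations, build_train(indicator_spec("qi8")))
  r1 <- 2144 / 4153; r2 <- 4 / 7
  m <- mean(c(r1, r2))
  expect_equal(g8$mean_ratio, m)
  expect_equal(unname(g8$per_center_expected_events),
               c(m * 4153, m * 7))
  expect_equal(unname(g8$per_center_rate_of_mean), c(r1 / m, r2 / m))
  # with equal weights the rate-of-mean values average to exactly 1
  expect_equal(mean(g8$per_center_rate_of_mean), 1)

  pooled <- run_federated(stations, build_train(indicator_spec("qi8")),
                          mean_mode = "pooled")
  expect_equal(pooled$mean_ratio, (2144 + 4) / (4153 + 7))
})

test_that("station order does not change the global result", {
  stations <- two_center_stations()
  train <- build_train(indicator_spec("qi8"))
  a <- run_federated(stations, train)
  b <- run_federated(rev(stations), train)
  expect_equal(a$mean_ratio, b$mean_ratio)
  expect_equal(a$per_center_expected_events[sort(names(a$per_center_expected_events))],
               b$per_center_expected_events[sort(names(b$per_center_expected_events))])
})

test_that("a single station is its own mean; no computable centers errors", {
  st <- host_station(triplify(generate_center(center2_quota_config())), "c2")
  g <- run_federated(list(st), build_train(indicator_spec("qi8")))
  expect_equal(g$mean_ratio, g$local_results[[1]]$ratio)
  expect_equal(unname(g$per_center_rate_of_mean), 1)

  empty <- host_station(fair_graph(), "void")
  expect_error(suppressWarnings(
    run_federated(list(empty), build_train(indicator_spec("qi8")))),
    "no computable centers")
})

test_that("global results survive the JSON round trip", {
  stations <- two_center_stations()
  globals <- list(qi8 = run_federated(stations, build_train(indicator_spec("qi8"))))
  path <- tempfile(fileext = ".json")
  write_global_results(globals, path)
  back <- read_global_results(path)
  expect_equal(back$qi8$mean_ratio, globals$qi8$mean_ratio)
  expect_equal(back$qi8$per_center_expected_events,
               globals$qi8$per_center_expected_events)
  expect_equal(back$qi8$local_results[[2]]$numerator, 4L)
})
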