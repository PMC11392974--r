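two_season_design <- function(n = 4) {
  survey_design(n_sites = n, season_labels = c("S1", "S2"),
                season_starts = as.Date(c("2020-01-01", "2020-06-01")),
                occasion_days = 5, n_occasions = 3)
}

test_that("an eventless, fully deployed survey gives all-zero histories", {
  d <- two_season_design()
  ev <- tibble::tibble(site_id = integer(), species = character(),
                       timestamp = as.POSIXct(character(), tz = "UTC"))
  h <- build_detection_history(ev, full_deployments(d), d, "fox")
  expect_true(all(h$y == 0))
  expect_true(all(h$effort == 5))
})

test_that("events bin into half-open 5-day occasions anchored at season start", {
  d <- two_season_design()
  # day 7 of season 1 falls in occasion 2 (day 7 is in [5, 10))
  ev <- tibble::tibble(site_id = 2, species = "fox",
                       timestamp = as.POSIXct("2020-01-08 12:00:00",
                                              tz = "UTC"))
  h <- build_detection_history(ev, full_deployments(d), d, "fox")
  expect_equal(h$y[2, 1, ], c(0L, 1L, 0L))
  expect_true(all(h$y[-2, , ] == 0))
  # exactly at an occasion boundary (day 5 start) -> occasion 2, not 1
  ev2 <- tibble::tibble(site_id = 1, species = "fox",
                        timestamp = as.POSIXct("2020-01-06 00:00:00",
                                               tz = "UTC"))
  h2 <- build_detection_history(ev2, full_deployments(d), d, "fox")
  expect_equal(h2$y[1, 1, ], c(0L, 1L, 0L))
})

test_that("effort follows deployment coverage and the 1-day rule", {
  d <- two_season_design(2)
  # site 1: deployed only for the first 6 days of season 1;
  # site 2: deployed from day 4 12:00, so day 4 has exactly 12 h -> active
  dep <- tibble::tibble(
    site_id = c(1, 2),
    start = as.POSIXct(c("2020-01-01 00:00:00", "2020-01-05 12:00:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2020-01-07 00:00:00", "2020-09-01 00:00:00"),
                     tz = "UTC")
  )
  ev <- tibble::tibble(site_id = integer(), species = character(),
                       timestamp = as.POSIXct(character(), tz = "UTC"))
  h <- build_detection_history(ev, dep, d, "fox")
  # site 1, occasion 1 fully covered; occasion 2 has 1 day; occasion 3 none
  expect_equal(h$effort[1, 1, ], c(5, 1, 0))
  expect_identical(h$y[1, 1, ], c(0L, 0L, NA_integer_))
  # site 1, season 2 entirely undeployed -> all NA
  expect_true(all(is.na(h$y[1, 2, ])))
  # site 2: day 5 (2020-01-05) half covered counts (>= 12 h)
  expect_equal(h$effort[2, 1, 1], 1)
  expect_equal(h$effort[2, 1, 2], 5)
})

test_that("events outside deployments are dropped with a warning", {
  d <- two_season_design(2)
  dep <- tibble::tibble(site_id = 1:2,
                        start = as.POSIXct("2020-01-01", tz = "UTC"),
                        end = as.POSIXct("2020-01-16", tz = "UTC"))
  ev <- tibble::tibble(
    site_id = c(1, 1, 2),
    species = "fox",
    timestamp = as.POSIXct(c("2020-01-03 10:00:00",  # in deployment
                             "2020-02-01 10:00:00",  # outside deployment
                             "2020-01-02 10:00:00"), tz = "UTC")
  )
  expect_warning(h <- build_detection_history(ev, dep, d, "fox"),
                 "dropped")
  expect_equal(attr(h, "report")$n_outside_deployment, 1L)
  expect_equal(h$y[1, 1, 1], 1L)
  expect_equal(h$y[2, 1, 1], 1L)
})

test_that("events between seasons are excluded but counted", {
  d <- two_season_design(1)
  ev <- tibble::tibble(site_id = 1, species = "fox",
                       timestamp = as.POSIXct("2020-03-01 10:00:00",
                                              tz = "UTC"))
  h <- build_detection_history(ev, full_deployments(d), d, "fox")
  expect_true(all(h$y == 0))
  expect_equal(attr(h, "report")$n_outside_season, 1L)
})

test_that("naive occupancy counts sites with any detection over surveyed sites", {
  d <- make_design(10, T = 1, K = 3)
  y <- array(0L, c(10, 1, 3))
  y[1:3, 1, 2] <- 1L
  h <- make_history(y, d)
  expect_equal(naive_occupancy(h)$naive_occ, 0.3)
  # duplicated detections within an occasion do not change the result
  y[1, 1, 1] <- 1L
  expect_equal(naive_occupancy(make_history(y, d))$naive_occ, 0.3)
  # NA-only sites leave the denominator: 3 detected of 8 surveyed
  y2 <- array(0L, c(10, 1, 3))
  y2[1:3, 1, 1] <- 1L
  y2[9:10, 1, ] <- NA_integer_
  expect_equal(naive_occupancy(make_history(y2, d))$naive_occ, 3 / 8)
  # all-zero history
  expect_equal(naive_occupancy(make_history(array(0L, c(10, 1, 3)),
                                            d))$naive_occ, 0)
})

test_that("subsetting seasons slices history and covariates consistently", {
  d <- make_design(5, T = 4, K = 2)
  set.seed(1)
  y <- array(rbinom(40, 1, 0.4), c(5, 4, 2))
  h <- make_history(y, d)
  covs <- covariate_set(
    site = tibble::tibble(x = rnorm(5)),
    season_site = list(g = matrix(rnorm(20), 5, 4)),
    observation = list(e = array(rnorm(40), c(5, 4, 2)))
  )
  # identity subset
  all_l <- subset_seasons(h, covs, keep = paste0("S", 1:4))
  expect_equal(all_l$history$y, h$y)
  # keeping seasons 1 and 3 leaves one transition
  ss <- subset_seasons(h, covs, keep = c("S1", "S3"))
  expect_equal(dim(ss$history$y), c(5, 2, 2))
  expect_equal(ss$history$design$seasons$label, c("S1", "S3"))
  expect_equal(ss$covs$season_site$g, covs$season_site$g[, c(1, 3)])
  expect_equal(dim(ss$covs$observation$e), c(5, 2, 2))
  # single season: no transitions remain
  s1 <- subset_seasons(h, keep = "S2")
  expect_equal(dim(s1$y)[2], 1)
  expect_error(subset_seasons(h, keep = "W99"), "unknown season")
})

test_that("standardization centers and scales with the sample SD", {
  cs <- covariate_set(site = tibble::tibble(x = c(1, 2, 3)))
  out <- standardize_covariates(cs)
  expect_equal(out$site$x, c(-1, 0, 1))
  expect_equal(unname(out$standardization$x), c(2, 1))
  # idempotent up to floating tolerance
  out2 <- standardize_covariates(out)
  expect_equal(out2$site$x, out$site$x, tolerance = 1e-12)
  # constant column errors with the covariate named
  expect_error(standardize_covariates(
    covariate_set(site = tibble::tibble(flat = rep(2, 4)))), "flat")
  # factors untouched
  cs2 <- covariate_set(site = tibble::tibble(f = factor(c("a", "b", "a"))))
  expect_identical(standardize_covariates(cs2)$site$f, cs2$site$f)
})

test_that("long-format round trip preserves every cell once", {
  d <- make_design(3, T = 2, K = 2)
  set.seed(2)
  y <- array(rbinom(12, 1, 0.5), c(3, 2, 2))
  y[1, 1, 1] <- NA_integer_
  h <- make_history(y, d)
  long <- history_to_long(h)
  expect_equal(nrow(long), 12)
  # each (site, season, occasion) appears exactly once
  expect_false(any(duplicated(long[, c("site", "season", "occasion")])))
  for (r in seq_len(nrow(long))) {
    t <- match(long$season[r], d$seasons$label)
    expect_identical(long$y[r], h$y[long$site[r], t, long$occasion[r]])
  }
})

test_that("history invariants are enforced at construction", {
  d <- make_design(2, T = 1, K = 2)
  y <- array(0L, c(2, 1, 2))
  eff <- array(5, c(2, 1, 2))
  y[1, 1, 1] <- NA_integer_  # NA without effort < 1
  expect_error(detection_history(y, eff, "sp", d), "NA exactly")
  eff2 <- array(7, c(2, 1, 2))
  expect_error(detection_history(array(0L, c(2, 1, 2)), eff2, "sp", d),
               "occasion_days")
})
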