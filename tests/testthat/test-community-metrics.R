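test_that("diversity indices match their closed forms", {
  d <- diversity_indices(c(10, 10, 10, 10))
  expect_identical(d$richness, 4L)
  expect_equal(d$shannon, log(4))
  expect_equal(d$simpson, 0.75)

  one <- diversity_indices(c(5))
  expect_identical(one$richness, 1L)
  expect_identical(one$shannon, 0)
  expect_identical(one$simpson, 0)

  h <- diversity_indices(c(1, 2, 3))
  expect_equal(h$shannon,
               -(1 / 6 * log(1 / 6) + 2 / 6 * log(2 / 6) +
                   3 / 6 * log(3 / 6)))
  expect_equal(round(h$shannon, 4), 1.0114)
})

test_that("diversity agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:5) {
    counts <- rpois(7, lambda = 8) + c(1, rep(0, 6))
    d <- diversity_indices(counts)
    expect_equal(d$shannon, unname(vegan::diversity(counts)))
    expect_equal(d$simpson,
                 unname(vegan::diversity(counts, index = "simpson")))
  }
})

test_that("diversity is invariant to label order and total count", {
  x <- c(a = 4, b = 9, c = 2)
  expect_equal(diversity_indices(x), diversity_indices(rev(x)))
  expect_equal(diversity_indices(x)$shannon,
               diversity_indices(10 * x)$shannon)
  expect_error(diversity_indices(c(0, 0)), "positive")
  expect_error(diversity_indices(c(-1, 3)), "non-negative")
  # data.frame input aggregates duplicate labels
  df <- data.frame(species = c("a", "b", "a"), count = c(1, 2, 3))
  expect_identical(diversity_indices(df)$richness, 2L)
})

test_that("an exact linear relation is recovered perfectly", {
  x <- 1:10
  # lm warns about the (intentionally) perfect fit
  a <- suppressWarnings(associate_aci(2 * x + 1, x))
  expect_equal(a$slope, 2)
  expect_equal(a$intercept, 1)
  expect_equal(a$r_squared, 1)
  expect_identical(a$n, 10L)
})

test_that("a permuted predictor shows no systematic slope", {
  set.seed(30)
  aci <- seq(0.3, 0.6, length.out = 30) + rnorm(30, 0, 0.02)
  pred <- seq(10, 100, length.out = 30)
  slopes <- vapply(1:200, function(i) {
    associate_aci(aci, sample(pred))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 2 * stats::sd(slopes))
})

test_that("degenerate association inputs are rejected", {
  expect_error(associate_aci(1:2, 1:2), "at least 3")
  expect_error(associate_aci(c(1, 2, 3), c(4, 4, 4)), "zero-variance")
  expect_error(associate_aci(1:5, 1:5,
                             grouping = "within_date_centered"),
               "dates required")
})

test_that("daily ACI tracks vocalization richness across a season", {
  # rates low enough that daily richness actually varies (species can be
  # silent on a given day)
  cfg <- scene_config(season = as.Date(c("2012-03-01", "2012-03-30")),
                      arrival_day = as.Date("2012-03-16"),
                      pre_arrival_rate = 0.2, post_arrival_rate = 4,
                      seed = 77)
  season <- synthesize_season(cfg)
  dates <- as.Date(names(season$days))
  aci <- vapply(season$days, function(d) {
    aci_total(restrict_bands(d$spec))$aci_tot
  }, numeric(1))
  rich <- vapply(split(season$truth, format(season$truth$date)),
                 function(day) diversity_indices(table(day$species))$richness,
                 integer(1))
  rich_full <- rich[format(dates)]
  rich_full[is.na(rich_full)] <- 0L
  expect_gt(stats::sd(rich_full), 0)
  expect_gt(stats::cor(aci, rich_full, method = "spearman"), 0)
})
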