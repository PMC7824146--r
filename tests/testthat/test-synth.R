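test_that("moment calibration reproduces the targets analytically", {
  # fish-like row: 61.9% consumers, overall mean 35.6, SD 53.2
  fish <- tibble::tibble(component = "fish", p_consume = 0.619,
                         target_mean = 35.6, target_sd = 53.2,
                         day_correlation = 0.3)
  cal <- calibrate_intake_model(fish)
  p <- cal$p_consume
  m <- cal$consumer_mean
  v <- cal$consumer_var
  # zero-inflated mixture identities, closed form
  expect_equal(p * m, 35.6, tolerance = 1e-9)
  expect_equal(p * v + p * (1 - p) * m^2, 53.2^2, tolerance = 1e-9)
  # lognormal moment inversion round trip
  expect_equal(exp(cal$meanlog + cal$sdlog^2 / 2), m, tolerance = 1e-9)
  expect_equal((exp(cal$sdlog^2) - 1) * m^2, v, tolerance = 1e-9)
})

test_that("every default component calibration is moment-consistent", {
  cal <- calibrate_intake_model(wish_distributions())
  consuming <- cal[cal$p_consume > 0 & !cal$degenerate, ]
  expect_gt(nrow(consuming), 10)
  with(consuming, {
    expect_equal(p_consume * consumer_mean, target_mean, tolerance = 1e-9)
    expect_equal(p_consume * consumer_var +
                   p_consume * (1 - p_consume) * consumer_mean^2,
                 target_sd^2, tolerance = 1e-9)
  })
})

test_that("degenerate and empty components are handled explicitly", {
  point <- tibble::tibble(component = "x", p_consume = 1,
                          target_mean = 10, target_sd = 0,
                          day_correlation = 0)
  expect_warning(cal <- calibrate_intake_model(point), "point mass")
  expect_true(cal$degenerate)
  expect_equal(cal$consumer_mean, 10)

  none <- tibble::tibble(component = "x", p_consume = 0,
                         target_mean = 0, target_sd = 0,
                         day_correlation = 0)
  cal0 <- calibrate_intake_model(none)
  expect_equal(cal0$consumer_mean, 0)

  bad <- tibble::tibble(component = "x", p_consume = 0,
                        target_mean = 5, target_sd = 1,
                        day_correlation = 0)
  expect_error(calibrate_intake_model(bad), "no consumers")

  sim <- simulate_intakes(n_subjects = 20, seed = 1, distributions = none)
  expect_true(all(sim$x == 0))
})

test_that("a fixed seed gives bit-identical simulations", {
  a <- simulate_intakes(n_subjects = 50, n_recalls = 2, seed = 123)
  b <- simulate_intakes(n_subjects = 50, n_recalls = 2, seed = 123)
  expect_identical(a, b)
  c <- simulate_intakes(n_subjects = 50, n_recalls = 2, seed = 124)
  expect_false(identical(b, c))
})

test_that("large simulations recover the calibration targets", {
  n <- 5000
  sim <- simulate_intakes(n_subjects = n, n_recalls = 2, seed = 77)
  subjects <- average_recalls(sim)
  targets <- wish_distributions()
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    daily <- sim[[tg$component]]
    # day-level mean over all records; SE bounded by target_sd / sqrt(n)
    se_mean <- tg$target_sd / sqrt(n)
    expect_lt(abs(mean(daily) - tg$target_mean), 3 * se_mean + 1e-9,
              label = paste(tg$component, "mean"))
    # subject-level non-consumer percentage
    pct <- 100 * mean(subjects[[tg$component]] == 0)
    target_pct <- 100 * (1 - tg$p_consume)
    se_pct <- 100 * sqrt(tg$p_consume * (1 - tg$p_consume) / n)
    expect_lt(abs(pct - target_pct), 3 * se_pct + 1e-9,
              label = paste(tg$component, "nonconsumer pct"))
  }
})

test_that("calibration error shrinks with sample size", {
  targets <- wish_distributions()
  err <- function(n) {
    sim <- simulate_intakes(n_subjects = n, n_recalls = 1, seed = 11)
    mean(abs(vapply(seq_len(nrow(targets)), function(i) {
      mean(sim[[targets$component[i]]]) - targets$target_mean[i]
    }, numeric(1))) / pmax(targets$target_sd, 1))
  }
  expect_lt(err(5000), err(500) + 1e-9)
})

test_that("day correlation controls between-day dependence", {
  rank_cor_between_days <- function(rho) {
    sim <- simulate_intakes(
      n_subjects = 2000, n_recalls = 2, seed = 99,
      distributions = tibble::tibble(
        component = "veg", p_consume = 1, target_mean = 200,
        target_sd = 80, day_correlation = rho
      )
    )
    d1 <- sim$veg[sim$recall_day == 1]
    d2 <- sim$veg[sim$recall_day == 2]
    stats::cor(d1, d2, method = "spearman")
  }
  expect_lt(abs(rank_cor_between_days(0)), 0.08)
  expect_gt(rank_cor_between_days(0.9), 0.8)
})

test_that("consumer status is constant within subject by default", {
  sim <- simulate_intakes(n_subjects = 300, n_recalls = 2, seed = 55)
  for (cmp in c("fish", "nuts", "added_sugars")) {
    zero_by_day <- tapply(sim[[cmp]] == 0, sim$subject_id, function(z) {
      length(unique(z))
    })
    expect_true(all(zero_by_day == 1), info = cmp)
  }
  # per-day variant may legitimately mix zero and positive days
  per_day <- simulate_intakes(n_subjects = 500, n_recalls = 2, seed = 56,
                              consumer_per_day = TRUE)
  mixed <- tapply(per_day$fish == 0, per_day$subject_id,
                  function(z) length(unique(z)))
  expect_gt(sum(mixed == 2), 0)
})

test_that("simulated scoring echoes the reference population's extremes", {
  # across several seeds the two bivariate limiting components average ~10
  rounded <- vapply(1:5, function(s) {
    sim <- simulate_intakes(n_subjects = 396, n_recalls = 2, seed = s)
    scores <- score_wish(average_recalls(sim))
    c(round(mean(scores$sat_oils)), round(mean(scores$added_sugars)))
  }, numeric(2))
  expect_true(all(rounded == 10))
})
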