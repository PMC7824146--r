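# one row per documented breakpoint or worked example, checked exactly
breakpoint_cases <- tibble::tribble(
  ~component,     ~intake, ~expected,
  "whole_grains", 125,     10,
  "whole_grains", 99,      0,
  "whole_grains", 100,     0,     # ramp formula yields 0 at its lower bound
  "whole_grains", 112.5,   5,
  "whole_grains", 200,     10,    # no upper restriction
  "vegetables",   300,     10,
  "vegetables",   199.99,  0,
  "vegetables",   250,     5,
  "fruits",       150,     5,
  "dairy",        125,     5,
  "dairy",        250,     10,
  "dairy",        500,     10,    # plateau boundary inclusive
  "dairy",        500.01,  0,
  "dairy",        600,     0,
  "red_meat",     10,      10,
  "red_meat",     14,      10,
  "red_meat",     21,      5,
  "red_meat",     28,      0,
  "red_meat",     28.01,   0,
  "fish",         28,      10,
  "fish",         100,     10,
  "fish",         100.01,  0,
  "fish",         14,      5,
  "eggs",         13,      10,
  "eggs",         19,      5,
  "eggs",         25,      0,
  "eggs",         26,      0,
  "poultry",      29,      10,
  "poultry",      43.5,    5,
  "poultry",      58.01,   0,
  "legumes",      75,      10,
  "legumes",      37.5,    5,
  "legumes",      200,     10,    # no upper restriction
  "nuts",         50,      10,
  "nuts",         75,      10,
  "nuts",         76,      0,
  "unsat_oils",   19.99,   0,
  "unsat_oils",   30,      5,
  "unsat_oils",   40,      10,
  "unsat_oils",   60,      10,
  "unsat_oils",   80,      10,
  "unsat_oils",   81,      0,
  "sat_oils",     11.8,    10,
  "sat_oils",     11.81,   0,
  "sat_oils",     0,       10,
  "added_sugars", 0,       10,
  "added_sugars", 31,      10,
  "added_sugars", 32,      0
)

test_that("every documented breakpoint scores exactly as published", {
  for (i in seq_len(nrow(breakpoint_cases))) {
    case <- breakpoint_cases[i, ]
    expect_equal(
      score_component(case$intake, case$component),
      case$expected,
      info = paste(case$component, case$intake)
    )
  }
})

test_that("engine agrees with the literal per-group transcription oracle", {
  idx <- wish_index()
  for (i in seq_len(nrow(idx$components))) {
    spec <- idx$components[i, ]
    grid <- oracle_grid(spec)
    expect_gte(length(grid), 1000)
    engine <- score_component(grid, spec$component, index = idx)
    oracle <- vapply(grid, function(x) {
      oracle_component_score(spec$component, x)
    }, numeric(1))
    expect_equal(engine, oracle, tolerance = 1e-12, info = spec$component)
  }
})

test_that("scores stay in [0, 10] for random intakes of every component", {
  idx <- wish_index()
  set.seed(11)
  for (cmp in idx$components$component) {
    intake <- stats::runif(800, 0, 1000)
    s <- score_component(intake, cmp, index = idx)
    expect_true(all(s >= 0 & s <= 10), info = cmp)
  }
})

test_that("shapes are monotone where the rules say they are", {
  idx <- wish_index()
  comps <- idx$components
  grid <- seq(0, 700, by = 0.5)
  for (i in seq_len(nrow(comps))) {
    spec <- comps[i, ]
    s <- score_component(grid, spec$component, index = idx)
    d <- diff(s)
    if (spec$shape == "ramp_up_open") {
      expect_true(all(d >= -1e-12), info = spec$component)
    } else if (spec$shape %in% c("ramp_down", "bivariate_limit")) {
      expect_true(all(d <= 1e-12), info = spec$component)
    } else if (spec$shape == "optimum_band") {
      on_band <- grid[-1] <= spec$upper
      expect_true(all(d[on_band] >= -1e-12), info = spec$component)
    }
  }
})

test_that("shapes are continuous except at their documented jumps", {
  idx <- wish_index()
  eps <- 1e-9
  for (i in seq_len(nrow(idx$components))) {
    spec <- idx$components[i, ]
    jumps <- switch(spec$shape,
                    ramp_up_capped = spec$upper,
                    optimum_band = spec$upper,
                    bivariate_limit = spec$recommended,
                    numeric(0))
    breaks <- stats::na.omit(c(spec$lower, spec$recommended, spec$upper))
    for (b in unique(breaks)) {
      lo <- score_component(max(b - eps, 0), spec$component, index = idx)
      hi <- score_component(b + eps, spec$component, index = idx)
      gap <- abs(hi - lo)
      if (b %in% jumps) {
        expect_gt(gap, 9, label = paste(spec$component, "jump at", b))
      } else {
        expect_lt(gap, 1e-6, label = paste(spec$component, "continuity at", b))
      }
    }
  }
})

test_that("the falling-ramp formula hits 10 at recommended and 0 at upper", {
  for (cmp in c("red_meat", "eggs", "poultry")) {
    spec <- wish_index()$components
    spec <- spec[spec$component == cmp, ]
    expect_equal(score_component(spec$recommended, cmp), 10)
    expect_equal(score_component(spec$upper, cmp), 0)
  }
})

test_that("invalid intakes raise errors naming the component", {
  expect_error(score_component(-1, "fish"), "fish")
  expect_error(score_component(NaN, "dairy"), "dairy")
  expect_error(score_component(Inf, "nuts"), "nuts")
  expect_error(score_component(10, "chocolate"), "Unknown component")
})

test_that("a fully adherent diet totals 130 and an empty diet totals 50", {
  full <- score_wish(intake_row())
  expect_equal(full$total, 130)
  expect_equal(full$healthy, 100)
  expect_equal(full$less_healthy, 30)
  expect_equal(full$low_env, 60)
  expect_equal(full$high_env, 70)

  zero_amounts <- stats::setNames(as.list(rep(0, 13)), component_ids())
  zero <- score_wish(do.call(intake_row, c(list(subject_id = "Z"),
                                           zero_amounts)))
  # at zero intake only the falling and bivariate components score
  scoring_10 <- c("eggs", "poultry", "red_meat", "sat_oils", "added_sugars")
  for (cmp in component_ids()) {
    expect_equal(zero[[cmp]], if (cmp %in% scoring_10) 10 else 0, info = cmp)
  }
  expect_equal(zero$total, 50)
  expect_equal(zero$healthy, 20)
  expect_equal(zero$less_healthy, 30)
  expect_equal(zero$low_env, 10)
  expect_equal(zero$high_env, 40)
})

test_that("missing component columns zero-fill with a warning by default", {
  data <- intake_row()
  data$nuts <- NULL
  expect_warning(scored <- score_wish(data), "nuts")
  expect_equal(scored$nuts, 0)
  expect_equal(scored$total, 120)
  expect_error(score_wish(data, missing = "strict"), "nuts")
})

test_that("tidy and glance expose per-component and population views", {
  scores <- score_wish(dplyr::bind_rows(intake_row("A"),
                                        intake_row("B", fish = 0)))
  long <- tidy(scores)
  expect_equal(nrow(long), 26)
  expect_named(long, c("subject_id", "component", "score"))
  g <- glance(scores)
  expect_equal(g$n, 2)
  expect_equal(g$mean_total, 125)
})
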