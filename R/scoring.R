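#' Score a single food-group component
#'
#' Evaluates the 0-10 piecewise-linear adherence score of one WISH component
#' at one or more daily intakes. The rising ramp between the lower and
#' recommended intake is
#' `10 * (intake - lower) / (recommended - lower)`, and the falling ramp
#' between the recommended and upper intake is
#' `10 * ((upper - recommended) - (intake - recommended)) / (upper - recommended)`.
#' Plateau boundaries are inclusive (an intake exactly at the saturated-oils
#' cut-off of 11.8 g/day scores 10; dairy at exactly 500 g/day scores 10)
#' while "above"/"below" bounds are strict (dairy at 500.01 g/day scores 0).
#'
#' @param intake Numeric vector of daily intakes in g/day; must be
#'   non-negative and finite.
#' @param component Component id, e.g. `"red_meat"`; must appear in `index`.
#' @param index A [wish_index()].
#' @return Numeric vector of scores in `[0, 10]`, same length as `intake`.
#' @examples
#' score_component(c(0, 14, 21, 28, 30), "red_meat")
#' score_component(125, "whole_grains")
#' @export
score_component <- function(intake, component, index = wish_index()) {
  spec <- index$components[index$components$component == component, ]
  if (nrow(spec) != 1) {
    abort(paste0("Unknown component: ", component))
  }
  if (any(!is.finite(intake)) || any(intake < 0)) {
    abort(paste0("Intake for `", component,
                 "` must be non-negative and finite."))
  }
  piecewise_score(intake, spec$shape, spec$lower, spec$recommended, spec$upper)
}

# Vectorised over intake; scalar shape/thresholds.
piecewise_score <- function(intake, shape, lower, recommended, upper) {
  ramp_up <- function(x) 10 * (x - lower) / (recommended - lower)
  ramp_down <- function(x) {
    10 * ((upper - recommended) - (x - recommended)) / (upper - recommended)
  }
  switch(
    shape,
    ramp_up_open = dplyr::case_when(
      intake < lower ~ 0,
      intake < recommended ~ ramp_up(intake),
      TRUE ~ 10
    ),
    ramp_up_capped = dplyr::case_when(
      intake > upper ~ 0,
      intake < lower ~ 0,
      intake < recommended ~ ramp_up(intake),
      TRUE ~ 10
    ),
    optimum_band = dplyr::case_when(
      intake > upper ~ 0,
      intake < recommended ~ 10 * intake / recommended,
      TRUE ~ 10
    ),
    ramp_down = dplyr::case_when(
      intake <= recommended ~ 10,
      intake <= upper ~ ramp_down(intake),
      TRUE ~ 0
    ),
    bivariate_limit = dplyr::if_else(intake <= recommended, 10, 0),
    abort(paste0("Unknown scoring shape: ", shape))
  )
}

#' Score subjects on all WISH components
#'
#' Takes one row per subject of recall-averaged daily intakes (g/day, one
#' column per component as produced by [average_recalls()] or
#' [simulate_intakes()] + [average_recalls()]) and returns the 13 component
#' scores, the total WISH score and the four sub-scores. All components carry
#' equal weight in the total.
#'
#' Missing component columns are handled by `missing`: `"zero"` (default)
#' treats the component as not consumed (0 g/day) and warns -- non-consumers
#' are legitimate in 24-hour-recall data, but a silently absent column would
#' usually signal a mapping error -- while `"strict"` raises an error.
#'
#' @param data Data frame with a `subject_id` column and one numeric column
#'   per component id in `index`.
#' @param index A [wish_index()].
#' @param missing Policy for absent component columns: `"zero"` or `"strict"`.
#' @return A `wish_scores` tibble: `subject_id`, one column per component
#'   (its 0-10 score), `total`, and one column per sub-score. The index used
#'   is attached as attribute `"index"`.
#' @examples
#' intakes <- tibble::tibble(
#'   subject_id = "A", whole_grains = 125, vegetables = 300, fruits = 200,
#'   dairy = 250, red_meat = 0, fish = 28, eggs = 0, poultry = 0,
#'   legumes = 75, nuts = 50, unsat_oils = 40, sat_oils = 0, added_sugars = 0
#' )
#' score_wish(intakes)$total  # 130, the maximum
#' @export
score_wish <- function(data, index = wish_index(),
                       missing = c("zero", "strict")) {
  missing <- match.arg(missing)
  if (!"subject_id" %in% names(data)) {
    abort("`data` must have a `subject_id` column.")
  }
  ids <- index_components(index)
  absent <- setdiff(ids, names(data))
  if (length(absent) > 0) {
    if (missing == "strict") {
      abort(paste0("Missing component columns: ",
                   paste(absent, collapse = ", ")))
    }
    warn(paste0("Missing component columns treated as 0 g/day: ",
                paste(absent, collapse = ", ")))
    data[absent] <- 0
  }

  scores <- purrr::map(ids, function(cmp) {
    score_component(data[[cmp]], cmp, index = index)
  })
  names(scores) <- ids
  scores <- tibble::as_tibble(scores)
  scores$subject_id <- data$subject_id
  scores <- dplyr::relocate(scores, "subject_id")
  aggregate_scores(scores, index = index)
}

#' @describeIn score_wish `tidy()` pivots a `wish_scores` table to one row
#'   per subject x component with the component's score.
#' @param x A `wish_scores` tibble.
#' @param ... Unused.
#' @export
tidy.wish_scores <- function(x, ...) {
  index <- attr(x, "index")
  tidyr::pivot_longer(
    tibble::as_tibble(x)[c("subject_id", index_components(index))],
    cols = -"subject_id",
    names_to = "component", values_to = "score"
  )
}

#' @describeIn score_wish `glance()` gives a one-row population overview:
#'   number of subjects and mean (SD) of the total and each sub-score.
#' @export
glance.wish_scores <- function(x, ...) {
  index <- attr(x, "index")
  cols <- c("total", names(index$subscores))
  out <- tibble::tibble(n = nrow(x))
  for (col in cols) {
    out[[paste0("mean_", col)]] <- mean(x[[col]])
    out[[paste0("sd_", col)]] <- if (nrow(x) > 1) stats::sd(x[[col]]) else 0
  }
  out
}

#' @describeIn score_wish `autoplot()` draws mean component scores (0-10
#'   scale) as a bar chart with SD whiskers.
#' @param object A `wish_scores` tibble.
#' @export
autoplot.wish_scores <- function(object, ...) {
  long <- tidy(object)
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$component),
    mean = mean(.data$score),
    sd = if (dplyr::n() > 1) stats::sd(.data$score) else 0,
    .groups = "drop"
  )
  order <- index_components(attr(object, "index"))
  summ$component <- factor(summ$component, levels = order)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$component, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = pmin(.data$mean + .data$sd, 10)),
      width = 0.3
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 10)) +
    ggplot2::labs(x = NULL, y = "Mean component score (0-10)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
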