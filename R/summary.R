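#' Direction of intake change that would raise the score
#'
#' Labels each food group with the population-level advice implied by
#' comparing the mean intake to the recommended intake: for protective and
#' neutral groups, `"Increase"` when the mean intake is below the
#' recommendation, `"Decrease"` when above, `"Good"` when exactly at it; for
#' limiting groups (red meat, saturated oils, added sugars), `"Good"` when
#' at or below the recommendation and `"Decrease"` otherwise. Comparing to
#' the point recommendation (not the tolerated range) is a deliberate
#' convention: a group such as fish whose mean lies inside its 10-point band
#' but above the recommended amount is still labelled `"Decrease"`, because
#' lowering intake towards the recommendation reduces environmental pressure
#' without a health penalty.
#'
#' @param mean_intake Numeric vector of population mean intakes (g/day).
#' @param component Component id(s), recycled against `mean_intake`.
#' @param index A [wish_index()].
#' @return Character vector: `"Increase"`, `"Decrease"` or `"Good"`.
#' @examples
#' direction_of_change(c(222.5, 25.1, 1.1),
#'                     c("vegetables", "eggs", "added_sugars"))
#' @export
direction_of_change <- function(mean_intake, component,
                                index = wish_index()) {
  n <- max(length(mean_intake), length(component))
  mean_intake <- rep_len(mean_intake, n)
  component <- rep_len(component, n)
  spec <- index$components
  i <- match(component, spec$component)
  if (anyNA(i)) {
    abort(paste0("Unknown component: ",
                 paste(unique(component[is.na(i)]), collapse = ", ")))
  }
  rec <- spec$recommended[i]
  limiting <- spec$health_class[i] == "limit"
  dplyr::case_when(
    limiting & mean_intake <= rec ~ "Good",
    limiting ~ "Decrease",
    mean_intake < rec ~ "Increase",
    mean_intake > rec ~ "Decrease",
    TRUE ~ "Good"
  )
}

#' Population summary of intakes and scores
#'
#' Produces the descriptive table used to characterise a study population:
#' per component, the percentage of non-consumers (subjects whose
#' recall-averaged intake is exactly zero), the mean (SD) intake in g/day
#' over all subjects, the mean (SD) component score, and the
#' direction-of-change label; plus, in `glance()`, the mean (SD) of the
#' total score and each sub-score. SDs use the sample (n-1) convention; for
#' a single subject the SD is reported as 0 with a warning so tabular output
#' stays well-formed.
#'
#' @param intakes Subject-level intake tibble from [average_recalls()] (one
#'   row per subject, recall-averaged g/day per component).
#' @param scores Optional `wish_scores` tibble for the same subjects; when
#'   `NULL` it is computed with [score_wish()] under the default
#'   missing-column policy.
#' @param index A [wish_index()].
#' @return A `wish_summary` tibble with one row per component and columns
#'   `component`, `pct_nonconsumers`, `mean_intake`, `sd_intake`,
#'   `mean_score`, `sd_score`, `direction`. The aggregate means/SDs are held
#'   in the `"aggregates"` attribute and exposed through `glance()`.
#' @export
summarize_wish <- function(intakes, scores = NULL, index = wish_index()) {
  if (nrow(intakes) == 0) {
    abort("Cannot summarise an empty population.")
  }
  if (is.null(scores)) {
    scores <- score_wish(intakes, index = index)
  }
  scores <- scores[match(intakes$subject_id, scores$subject_id), ]
  if (anyNA(scores$subject_id)) {
    abort("`scores` does not cover every subject in `intakes`.")
  }
  n <- nrow(intakes)
  sd_or_zero <- function(x) {
    if (n < 2) {
      warn("Single-subject population: SDs reported as 0.")
      return(0)
    }
    stats::sd(x)
  }
  ids <- index_components(index)
  out <- purrr::map_dfr(ids, function(cmp) {
    x <- intakes[[cmp]]
    if (is.null(x)) x <- rep(0, n)
    tibble::tibble(
      component = cmp,
      pct_nonconsumers = 100 * mean(x == 0),
      mean_intake = mean(x),
      sd_intake = suppressWarnings(sd_or_zero(x)),
      mean_score = mean(scores[[cmp]]),
      sd_score = suppressWarnings(sd_or_zero(scores[[cmp]]))
    )
  })
  if (n < 2) warn("Single-subject population: SDs reported as 0.")
  out$direction <- direction_of_change(out$mean_intake, out$component,
                                       index = index)
  agg_cols <- c("total", names(index$subscores))
  aggregates <- purrr::map_dfr(agg_cols, function(col) {
    tibble::tibble(score = col, mean = mean(scores[[col]]),
                   sd = suppressWarnings(sd_or_zero(scores[[col]])),
                   max = wish_maxima(index)[[col]])
  })
  structure(out, aggregates = aggregates, n = n, index = index,
            class = c("wish_summary", class(tibble::tibble())))
}

#' @describeIn summarize_wish `glance()` returns the population size and the
#'   mean (SD) total and sub-scores alongside their maxima.
#' @param x A `wish_summary`.
#' @param ... Unused.
#' @export
glance.wish_summary <- function(x, ...) {
  agg <- attr(x, "aggregates")
  out <- tibble::tibble(n = attr(x, "n"))
  for (i in seq_len(nrow(agg))) {
    out[[paste0("mean_", agg$score[i])]] <- agg$mean[i]
    out[[paste0("sd_", agg$score[i])]] <- agg$sd[i]
  }
  out
}

#' @describeIn summarize_wish `autoplot()` draws the total and sub-score
#'   means with SD error bars, each annotated with its maximum.
#' @param object A `wish_summary`.
#' @export
autoplot.wish_summary <- function(object, ...) {
  agg <- attr(object, "aggregates")
  agg$score <- factor(agg$score, levels = agg$score)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$score, y = .data$mean)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = .data$mean + .data$sd),
      width = 0.25
    ) +
    ggplot2::geom_text(ggplot2::aes(y = .data$max,
                                    label = paste0("max ", .data$max)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Mean score (SD)") +
    ggplot2::theme_minimal()
}

#' Export a population summary as CSV
#'
#' Writes the per-component summary table (and, in a companion file suffixed
#' `_aggregates.csv`, the total/sub-score means) for reporting.
#'
#' @param summary A `wish_summary`.
#' @param path Output CSV path for the component table.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "wish_summary"))
  readr::write_csv(tibble::as_tibble(summary), path)
  agg_path <- sub("\\.csv$", "_aggregates.csv", path)
  if (identical(agg_path, path)) agg_path <- paste0(path, "_aggregates.csv")
  readr::write_csv(attr(summary, "aggregates"), agg_path)
  invisible(path)
}
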