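#' Read a per-recall intake table
#'
#' Reads a CSV of daily food-group intakes, one row per subject x recall day.
#' Two dialects are accepted: wide (columns `subject_id`, `recall_day`, and
#' one g/day column per component -- the canonical layout) and long (columns
#' `subject_id`, `recall_day`, `component`, `intake`). Long input is pivoted
#' to wide. Validation rejects negative or non-finite intakes (with the
#' offending row reported) and duplicate (subject, day) pairs; unknown extra
#' columns are reported and dropped.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param index A [wish_index()].
#' @param missing Policy for component columns absent from the file, as in
#'   [score_wish()].
#' @return A tibble with `subject_id`, `recall_day` (integer) and one numeric
#'   column per component, in index order.
#' @export
read_intakes <- function(path, index = wish_index(),
                         missing = c("zero", "strict")) {
  missing <- match.arg(missing)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "recall_day")
  absent <- setdiff(required, names(data))
  if (length(absent) > 0) {
    abort(paste0("Intake file must have columns: ",
                 paste(absent, collapse = ", ")))
  }
  ids <- index_components(index)

  long_form <- all(c("component", "intake") %in% names(data))
  if (long_form) {
    unknown <- setdiff(unique(data$component), ids)
    if (length(unknown) > 0) {
      abort(paste0("Unknown components in long input: ",
                   paste(unknown, collapse = ", ")))
    }
    data <- tidyr::pivot_wider(data, names_from = "component",
                               values_from = "intake", values_fill = 0)
  }

  extra <- setdiff(names(data), c(required, ids))
  if (length(extra) > 0) {
    inform(paste0("Ignoring non-component columns: ",
                  paste(extra, collapse = ", ")))
    data <- data[setdiff(names(data), extra)]
  }
  missing_cols <- setdiff(ids, names(data))
  if (length(missing_cols) > 0) {
    if (missing == "strict") {
      abort(paste0("Missing component columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    warn(paste0("Missing component columns treated as 0 g/day: ",
                paste(missing_cols, collapse = ", ")))
    data[missing_cols] <- 0
  }

  data <- dplyr::mutate(data,
                        subject_id = as.character(.data$subject_id),
                        recall_day = as.integer(.data$recall_day))
  for (cmp in ids) {
    bad <- which(!is.finite(data[[cmp]]) | data[[cmp]] < 0)
    if (length(bad) > 0) {
      abort(paste0("Negative or non-finite intake for `", cmp,
                   "`, row ", bad[1], "."))
    }
  }
  dup <- duplicated(data[c("subject_id", "recall_day")])
  if (any(dup)) {
    key <- data[which(dup)[1], ]
    abort(paste0("Duplicate recall: subject `", key$subject_id,
                 "`, day ", key$recall_day, "."))
  }
  dplyr::select(data, "subject_id", "recall_day", dplyr::all_of(ids))
}

#' Map per-food-item records to food-group intakes
#'
#' Collapses an item-level table (e.g. disaggregated 24-hour-recall entries)
#' into per-recall component intakes by summing grams within
#' (subject, day, component) according to a user-supplied mapping table.
#' Items mapped to the sentinel `"EXCLUDED"` (refined grains, fruit juice,
#' tubers, pickled vegetables, ...) are dropped from all components. A
#' template mapping with the food-group definitions is shipped at
#' `system.file("extdata", "food_item_mapping_template.csv",
#' package = "wishindex")`.
#'
#' @param items Data frame with columns `subject_id`, `recall_day`,
#'   `food_item`, `grams`.
#' @param mapping Data frame with columns `food_item`, `component` (a
#'   component id of `index` or `"EXCLUDED"`), or a path to such a CSV.
#' @param index A [wish_index()].
#' @param strict If `TRUE` (default) an unmapped food item is an error
#'   listing the items; if `FALSE` unmapped items are dropped and reported
#'   via the `"unmapped"` attribute.
#' @return A wide per-recall intake tibble as from [read_intakes()], with
#'   attributes `"excluded_grams"`, `"unmapped_grams"` and `"unmapped"`
#'   (character vector of item names) for mass accounting.
#' @export
map_food_items <- function(items, mapping, index = wish_index(),
                           strict = TRUE) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- readr::read_csv(mapping, show_col_types = FALSE,
                               progress = FALSE, comment = "#")
  }
  need <- c("subject_id", "recall_day", "food_item", "grams")
  if (!all(need %in% names(items))) {
    abort(paste0("`items` must have columns: ", paste(need, collapse = ", ")))
  }
  if (!all(c("food_item", "component") %in% names(mapping))) {
    abort("`mapping` must have columns food_item, component.")
  }
  ids <- index_components(index)
  bad_targets <- setdiff(unique(mapping$component), c(ids, "EXCLUDED"))
  if (length(bad_targets) > 0) {
    abort(paste0("Mapping targets unknown components: ",
                 paste(bad_targets, collapse = ", ")))
  }
  if (any(!is.finite(items$grams) | items$grams < 0)) {
    abort("Item grams must be non-negative and finite.")
  }

  joined <- dplyr::left_join(items, mapping[c("food_item", "component")],
                             by = "food_item")
  unmapped <- unique(joined$food_item[is.na(joined$component)])
  if (length(unmapped) > 0 && strict) {
    abort(paste0("Unmapped food items: ", paste(unmapped, collapse = ", ")))
  }
  unmapped_grams <- sum(joined$grams[is.na(joined$component)])
  excluded_grams <- sum(joined$grams[!is.na(joined$component) &
                                       joined$component == "EXCLUDED"])
  kept <- dplyr::filter(joined, !is.na(.data$component),
                        .data$component != "EXCLUDED")
  wide <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(kept, .data$subject_id, .data$recall_day,
                      .data$component),
      grams = sum(.data$grams), .groups = "drop"
    ),
    names_from = "component", values_from = "grams", values_fill = 0
  )
  # subjects whose every item was excluded/unmapped still get an all-zero row
  all_keys <- dplyr::distinct(items, .data$subject_id, .data$recall_day)
  wide <- dplyr::left_join(all_keys, wide,
                           by = c("subject_id", "recall_day"))
  for (cmp in ids) {
    if (!cmp %in% names(wide)) wide[[cmp]] <- 0
    wide[[cmp]][is.na(wide[[cmp]])] <- 0
  }
  out <- dplyr::select(
    dplyr::mutate(wide, subject_id = as.character(.data$subject_id),
                  recall_day = as.integer(.data$recall_day)),
    "subject_id", "recall_day", dplyr::all_of(ids)
  )
  attr(out, "excluded_grams") <- excluded_grams
  attr(out, "unmapped_grams") <- unmapped_grams
  attr(out, "unmapped") <- unmapped
  out
}

#' Average replicate recall days per subject
#'
#' Food intakes from replicate 24-hour recalls are averaged (unweighted
#' arithmetic mean per component) before scoring, and subjects with fewer
#' than `min_recalls` recall days are dropped. The default of 2 reflects the
#' duplicate-recall design usual for this kind of survey; set
#' `min_recalls = 1` to keep every subject.
#'
#' @param data Per-recall intake tibble as from [read_intakes()] or
#'   [simulate_intakes()].
#' @param index A [wish_index()].
#' @param min_recalls Minimum number of recall days a subject must have.
#' @return A tibble with `subject_id`, `n_recalls` and the per-component mean
#'   intakes; dropped subjects are recorded in the `"dropped"` attribute.
#' @examples
#' recalls <- tibble::tibble(subject_id = "A", recall_day = 1:2,
#'                           fish = c(40, 20))
#' average_recalls(recalls, min_recalls = 2)$fish  # 30
#' @export
average_recalls <- function(data, index = wish_index(), min_recalls = 2) {
  stopifnot(min_recalls >= 1)
  if (nrow(data) == 0) {
    warn("No recall records; returning an empty table.")
    return(tibble::tibble(subject_id = character(), n_recalls = integer()))
  }
  ids <- intersect(index_components(index), names(data))
  out <- dplyr::summarise(
    dplyr::group_by(data, .data$subject_id),
    n_recalls = dplyr::n(),
    dplyr::across(dplyr::all_of(ids), mean),
    .groups = "drop"
  )
  dropped <- out$subject_id[out$n_recalls < min_recalls]
  if (length(dropped) > 0) {
    inform(paste0(length(dropped), " subject(s) with fewer than ",
                  min_recalls, " recalls dropped."))
  }
  out <- dplyr::filter(out, .data$n_recalls >= min_recalls)
  attr(out, "dropped") <- dropped
  out
}
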