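#' Aggregate component scores into the total and sub-scores
#'
#' Sums the 13 component scores (equal weights) into the total WISH score
#' and into the four sub-scores defined by the index membership lists:
#' `healthy` (protective + neutral groups, max 100), `less_healthy` (the
#' limiting groups red meat, saturated oils and added sugars, max 30),
#' `low_env` (low environmental impact groups, max 60) and `high_env`
#' (medium + high impact groups, max 70). Each membership pair partitions
#' the component set, so `healthy + less_healthy` and `low_env + high_env`
#' both equal `total` by construction.
#'
#' @param data Data frame with `subject_id` and one numeric score column
#'   (each in `[0, 10]`) per component of `index`; extra non-component
#'   columns are not allowed beyond `subject_id`.
#' @param index A [wish_index()].
#' @return A `wish_scores` tibble: the component scores plus `total` and the
#'   sub-score columns.
#' @examples
#' perfect <- tibble::as_tibble(c(
#'   list(subject_id = "A"),
#'   setNames(as.list(rep(10, 13)), wish_index()$components$component)
#' ))
#' aggregate_scores(perfect)[, c("total", "healthy", "high_env")]
#' @export
aggregate_scores <- function(data, index = wish_index()) {
  ids <- index_components(index)
  if (!"subject_id" %in% names(data)) {
    abort("`data` must have a `subject_id` column.")
  }
  absent <- setdiff(ids, names(data))
  if (length(absent) > 0) {
    abort(paste0("Missing component score columns: ",
                 paste(absent, collapse = ", ")))
  }
  extra <- setdiff(names(data), c("subject_id", ids))
  if (length(extra) > 0) {
    abort(paste0("Unexpected columns (not components of the index): ",
                 paste(extra, collapse = ", ")))
  }
  mat <- as.matrix(data[ids])
  if (any(!is.finite(mat)) || any(mat < -1e-9) || any(mat > 10 + 1e-9)) {
    abort("Component scores must be finite and within [0, 10].")
  }

  out <- tibble::as_tibble(data[c("subject_id", ids)])
  out$total <- rowSums(mat)
  for (nm in names(index$subscores)) {
    out[[nm]] <- rowSums(mat[, index$subscores[[nm]], drop = FALSE])
  }
  structure(out, index = index,
            class = c("wish_scores", class(tibble::tibble())))
}
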