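#' The WISH index definition
#'
#' The World Index for Sustainability and Health (WISH) scores daily intakes
#' of 13 EAT-Lancet food groups on a 0-10 scale each. A `wish_index` object
#' holds the component registry -- identity, health classification
#' (protective / neutral / limit), environmental impact classification
#' (low / medium / high), intake thresholds in g/day and the piecewise-linear
#' scoring shape -- together with the four sub-score membership lists.
#'
#' `wish_index()` with no arguments returns the published default: the
#' EAT-Lancet-derived thresholds (whole-grain recommendation taken from the
#' Global Burden of Disease study). Passing a YAML file path loads a locally
#' adapted index instead; the file must carry a `components` list and a
#' `subscores` mapping (see the shipped template
#' `system.file("extdata", "wish_default.yaml", package = "wishindex")`).
#'
#' The five scoring shapes are:
#' \describe{
#'   \item{ramp_up_open}{0 below `lower`, linear up to `recommended`, 10 at or
#'     above it (whole grains, vegetables, fruits, legumes).}
#'   \item{ramp_up_capped}{as `ramp_up_open` but 0 strictly above `upper`
#'     (unsaturated oils).}
#'   \item{optimum_band}{linear 0 to 10 from zero intake to `recommended`,
#'     plateau at 10 up to `upper`, 0 above it (dairy, fish, nuts).}
#'   \item{ramp_down}{10 at or below `recommended`, linear down to 0 at
#'     `upper`, 0 above it (red meat, eggs, poultry).}
#'   \item{bivariate_limit}{10 at or below `recommended`, 0 above it
#'     (saturated oils, added sugars).}
#' }
#'
#' @param path Optional path to a YAML index definition. `NULL` (default)
#'   returns the built-in registry.
#' @return A `wish_index` object: a list with `components` (tibble, 13 rows)
#'   and `subscores` (named list of component-id character vectors).
#' @examples
#' idx <- wish_index()
#' tidy(idx)
#' @export
wish_index <- function(path = NULL) {
  if (is.null(path)) {
    idx <- default_index()
  } else {
    idx <- read_index_yaml(path)
    absent <- setdiff(index_components(default_index()),
                      idx$components$component)
    if (length(absent) > 0) {
      abort(paste0("Missing component: ", paste(absent, collapse = ", ")))
    }
  }
  violations <- validate_index(idx)
  if (nrow(violations) > 0) {
    abort(c(
      "Invalid index definition:",
      stats::setNames(paste(violations$component, "-", violations$rule),
                      rep("x", nrow(violations)))
    ))
  }
  idx
}

wish_shapes <- c("ramp_up_open", "ramp_up_capped", "optimum_band",
                 "ramp_down", "bivariate_limit")

default_index <- function() {
  components <- tibble::tribble(
    ~component,      ~health_class, ~env_class, ~lower, ~recommended, ~upper, ~shape,
    "whole_grains",  "protective",  "low",      100,    125,          150,    "ramp_up_open",
    "vegetables",    "protective",  "low",      200,    300,          600,    "ramp_up_open",
    "fruits",        "protective",  "low",      100,    200,          300,    "ramp_up_open",
    "dairy",         "protective",  "medium",   0,      250,          500,    "optimum_band",
    "red_meat",      "limit",       "high",     0,      14,           28,     "ramp_down",
    "fish",          "protective",  "high",     0,      28,           100,    "optimum_band",
    "eggs",          "neutral",     "medium",   0,      13,           25,     "ramp_down",
    "poultry",       "neutral",     "medium",   0,      29,           58,     "ramp_down",
    "legumes",       "protective",  "low",      0,      75,           100,    "ramp_up_open",
    "nuts",          "protective",  "medium",   0,      50,           75,     "optimum_band",
    "unsat_oils",    "protective",  "low",      20,     40,           80,     "ramp_up_capped",
    "sat_oils",      "limit",       "high",     0,      11.8,         11.8,   "bivariate_limit",
    "added_sugars",  "limit",       "low",      0,      31,           31,     "bivariate_limit"
  )
  subscores <- list(
    healthy      = c("whole_grains", "vegetables", "fruits", "dairy", "fish",
                     "eggs", "poultry", "legumes", "nuts", "unsat_oils"),
    less_healthy = c("red_meat", "sat_oils", "added_sugars"),
    low_env      = c("whole_grains", "vegetables", "fruits", "legumes",
                     "unsat_oils", "added_sugars"),
    high_env     = c("sat_oils", "dairy", "red_meat", "fish", "eggs",
                     "poultry", "nuts")
  )
  new_wish_index(components, subscores)
}

new_wish_index <- function(components, subscores) {
  structure(
    list(components = components, subscores = subscores),
    class = "wish_index"
  )
}

read_index_yaml <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Index config not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$components)) {
    abort("Index config must have a top-level `components` key.")
  }
  required <- c("id", "health_class", "env_class", "lower", "recommended", "shape")
  components <- purrr::map_dfr(raw$components, function(cmp) {
    missing <- setdiff(required, names(cmp))
    if (length(missing) > 0) {
      abort(paste0("Component `", cmp$id %||% "<unnamed>",
                   "` is missing fields: ", paste(missing, collapse = ", ")))
    }
    tibble::tibble(
      component    = as.character(cmp$id),
      health_class = as.character(cmp$health_class),
      env_class    = as.character(cmp$env_class),
      lower        = as.numeric(cmp$lower),
      recommended  = as.numeric(cmp$recommended),
      upper        = as.numeric(cmp$upper %||% NA_real_),
      shape        = as.character(cmp$shape)
    )
  })
  subscores <- purrr::map(raw$subscores %||% list(), as.character)
  new_wish_index(components, subscores)
}

#' Serialize an index definition to YAML
#'
#' Writes a `wish_index` to the YAML layout accepted by [wish_index()], so
#' that a round trip (`wish_index(write_index(idx, f))`) reproduces the
#' definition exactly. Use this to export the default registry as a starting
#' point for local adaptation of thresholds.
#'
#' @param index A `wish_index`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "wish_index"))
  components <- purrr::pmap(index$components, function(component, health_class,
                                                      env_class, lower,
                                                      recommended, upper, shape) {
    cmp <- list(id = component, health_class = health_class,
                env_class = env_class, lower = lower,
                recommended = recommended, shape = shape)
    if (!is.na(upper)) cmp$upper <- upper
    cmp
  })
  yaml::write_yaml(list(components = components, subscores = index$subscores),
                   path)
  invisible(path)
}

#' Validate an index definition
#'
#' Checks the structural invariants of a `wish_index`: 13 components with
#' known scoring shapes, non-negative ordered thresholds
#' (`lower <= recommended <= upper`), and the two sub-score partitions
#' (healthy + less-healthy, and low- + high-environmental-impact, each
#' covering all components exactly once). Violations are returned, not
#' raised, so a config under development can be inspected in full.
#'
#' @param index A `wish_index` (possibly invalid).
#' @return A tibble with columns `component` and `rule`, one row per
#'   violation; zero rows when the definition is valid.
#' @examples
#' validate_index(wish_index())  # 0 rows
#' @export
validate_index <- function(index) {
  comps <- index$components
  v <- list()
  note <- function(component, rule) {
    tibble::tibble(component = component, rule = rule)
  }

  if (anyDuplicated(comps$component)) {
    dup <- unique(comps$component[duplicated(comps$component)])
    v <- c(v, purrr::map(dup, note, rule = "duplicated component id"))
  }
  bad_shape <- comps$component[!comps$shape %in% wish_shapes]
  v <- c(v, purrr::map(bad_shape, note, rule = "unknown scoring shape"))

  for (i in seq_len(nrow(comps))) {
    row <- comps[i, ]
    thr <- c(row$lower, row$recommended, row$upper)
    if (any(!is.finite(thr[1:2])) || any(thr < 0, na.rm = TRUE)) {
      v <- c(v, list(note(row$component, "thresholds must be finite and >= 0")))
      next
    }
    if (row$lower > row$recommended) {
      v <- c(v, list(note(row$component, "lower > recommended")))
    }
    if (!is.na(row$upper) && row$recommended > row$upper) {
      v <- c(v, list(note(row$component, "recommended > upper")))
    }
    needs_upper <- row$shape %in% c("ramp_up_capped", "optimum_band", "ramp_down")
    if (needs_upper && is.na(row$upper)) {
      v <- c(v, list(note(row$component, "shape requires an upper threshold")))
    }
    if (row$shape %in% c("ramp_up_open", "ramp_up_capped") &&
        row$lower == row$recommended) {
      v <- c(v, list(note(row$component, "ramp requires lower < recommended")))
    }
  }

  required_sets <- c("healthy", "less_healthy", "low_env", "high_env")
  missing_sets <- setdiff(required_sets, names(index$subscores))
  v <- c(v, purrr::map(missing_sets, note, rule = "sub-score membership missing"))

  ids <- comps$component
  for (pair in list(c("healthy", "less_healthy"), c("low_env", "high_env"))) {
    if (!all(pair %in% names(index$subscores))) next
    a <- index$subscores[[pair[1]]]
    b <- index$subscores[[pair[2]]]
    overlap <- intersect(a, b)
    v <- c(v, purrr::map(overlap, note,
                         rule = paste0("in both ", pair[1], " and ", pair[2])))
    uncovered <- setdiff(ids, union(a, b))
    v <- c(v, purrr::map(uncovered, note,
                         rule = paste0("in neither ", pair[1], " nor ", pair[2])))
    unknown <- setdiff(union(a, b), ids)
    v <- c(v, purrr::map(unknown, note,
                         rule = "sub-score member is not a component"))
  }

  if (length(v) == 0) {
    return(tibble::tibble(component = character(), rule = character()))
  }
  dplyr::distinct(dplyr::bind_rows(v))
}

#' Maximum attainable scores of an index
#'
#' Each component scores at most 10, so the total maximum is `10 * 13 = 130`
#' for the default index and each sub-score maximum is ten times its
#' membership size (100, 30, 60 and 70 for the default healthy, less-healthy,
#' low- and high-environmental-impact sub-scores). Maxima are derived from
#' the membership lists rather than hard-coded so that locally adapted
#' indices report correct ranges.
#'
#' @param index A `wish_index`.
#' @return A named numeric vector with elements `total` and one per sub-score.
#' @examples
#' wish_maxima(wish_index())
#' @export
wish_maxima <- function(index = wish_index()) {
  c(total = 10 * nrow(index$components),
    vapply(index$subscores, function(ids) 10 * length(ids), numeric(1)))
}

#' @export
print.wish_index <- function(x, ...) {
  cat("<wish_index> ", nrow(x$components), " components\n", sep = "")
  print(x$components, n = nrow(x$components))
  cat("sub-scores: ",
      paste(sprintf("%s (%d)", names(x$subscores),
                    lengths(x$subscores)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn wish_index `tidy()` returns the component registry as a tibble
#'   with one row per food group and a `subscore` membership summary column.
#' @param x A `wish_index`.
#' @param ... Unused.
#' @export
tidy.wish_index <- function(x, ...) {
  dplyr::mutate(
    x$components,
    health_subscore = dplyr::if_else(.data$component %in% x$subscores$healthy,
                                     "healthy", "less_healthy"),
    env_subscore = dplyr::if_else(.data$component %in% x$subscores$low_env,
                                  "low_env", "high_env")
  )
}

# component ids of an index, in registry order
index_components <- function(index) index$components$component
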