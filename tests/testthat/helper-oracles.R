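# Independent oracles and fixture builders shared across tests.

# Literal transcription of each food group's scoring rule, written as
# scalar prose-to-code, deliberately independent of the piecewise engine.
oracle_component_score <- function(component, x) {
  stopifnot(length(x) == 1, x >= 0)
  switch(
    component,
    whole_grains = if (x < 100) 0 else if (x >= 125) 10 else
      10 * (x - 100) / (125 - 100),
    vegetables = if (x < 200) 0 else if (x >= 300) 10 else
      10 * (x - 200) / (300 - 200),
    fruits = if (x < 100) 0 else if (x >= 200) 10 else
      10 * (x - 100) / (200 - 100),
    dairy = if (x > 500) 0 else if (x >= 250) 10 else 10 * x / 250,
    red_meat = if (x <= 14) 10 else if (x > 28) 0 else
      10 * ((28 - 14) - (x - 14)) / (28 - 14),
    fish = if (x > 100) 0 else if (x >= 28) 10 else 10 * x / 28,
    eggs = if (x <= 13) 10 else if (x > 25) 0 else
      10 * ((25 - 13) - (x - 13)) / (25 - 13),
    poultry = if (x <= 29) 10 else if (x > 58) 0 else
      10 * ((58 - 29) - (x - 29)) / (58 - 29),
    legumes = if (x >= 75) 10 else 10 * (x - 0) / (75 - 0),
    nuts = if (x > 75) 0 else if (x >= 50) 10 else 10 * x / 50,
    unsat_oils = if (x > 80) 0 else if (x >= 40) 10 else if (x < 20) 0 else
      10 * (x - 20) / (40 - 20),
    sat_oils = if (x <= 11.8) 10 else 0,
    added_sugars = if (x <= 31) 10 else 0,
    stop("oracle: unknown component ", component)
  )
}

# dense evaluation grid per component: ~1000 points spanning past the upper
# threshold, plus every breakpoint and breakpoint +/- 1e-9
oracle_grid <- function(spec) {
  breaks <- unique(stats::na.omit(c(spec$lower, spec$recommended, spec$upper)))
  top <- max(breaks, 1) * 1.5
  pts <- c(seq(0, top, length.out = 1000),
           breaks, breaks + 1e-9, pmax(breaks - 1e-9, 0))
  sort(unique(pts))
}

# Spearman oracle: own average-rank assignment, then the explicit Pearson
# product-moment formula on the ranks.
oracle_avg_rank <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

oracle_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
}

# one-subject wide intake row; defaults to full-adherence amounts
intake_row <- function(subject_id = "A", ...) {
  amounts <- list(
    whole_grains = 125, vegetables = 300, fruits = 200, dairy = 250,
    red_meat = 0, fish = 28, eggs = 0, poultry = 0, legumes = 75,
    nuts = 50, unsat_oils = 40, sat_oils = 0, added_sugars = 0
  )
  amounts <- utils::modifyList(amounts, list(...))
  tibble::as_tibble(c(list(subject_id = subject_id), amounts))
}

component_ids <- function() wish_index()$components$component

# random valid score table (n subjects x 13 components in [0, 10])
random_scores <- function(n) {
  mat <- matrix(stats::runif(n * 13, 0, 10), nrow = n)
  colnames(mat) <- component_ids()
  dplyr::bind_cols(tibble::tibble(subject_id = as.character(seq_len(n))),
                   tibble::as_tibble(mat))
}
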