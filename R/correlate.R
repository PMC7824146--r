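#' Spearman correlations among component, sub- and total scores
#'
#' Computes the pairwise Spearman rank correlation matrix over the 13
#' component scores, the four sub-scores and the total score, the analysis
#' used to identify which components drive the index in a given population.
#' Components are left inside the total when correlated with it (the
#' part-whole correlation is intentional; set `leave_one_out = TRUE` to
#' remove each component from the total before correlating it).
#'
#' Scores with zero variance across subjects -- typical when nearly the
#' whole population scores 0 or 10 on a component -- admit no rank
#' correlation and are excluded with reason `"constant score"`. Exact
#' equality is the right test here because scores are piecewise-linear
#' outputs that often sit exactly on 0 or 10; `tol` loosens it for noisy
#' inputs.
#'
#' Two-sided p-values use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' For very small samples (`n <= 10`, no ties) `exact = TRUE` switches to
#' the exact null distribution of the rank statistic. No multiple-testing
#' correction is applied by default; `p_adjust = "BH"` applies
#' Benjamini-Hochberg across the upper triangle.
#'
#' @param scores A `wish_scores` tibble from [score_wish()].
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @param tol Zero-variance tolerance: a score whose range across subjects
#'   is `<= tol` is treated as constant (default 0, exact equality).
#' @param exact Use the exact small-sample null distribution for p-values
#'   (only when `n <= 10` and there are no ties).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param leave_one_out Correlate each component against the total with that
#'   component removed from the total.
#' @return A `wish_corr` object: list with `rho` and `p` (symmetric
#'   matrices), `n`, `alpha`, and `excluded` (tibble of label + reason).
#' @export
correlate_wish <- function(scores, alpha = 0.05, tol = 0, exact = FALSE,
                           p_adjust = c("none", "BH"),
                           leave_one_out = FALSE) {
  p_adjust <- match.arg(p_adjust)
  index <- attr(scores, "index")
  if (is.null(index)) index <- wish_index()
  n <- nrow(scores)
  if (n < 3) abort("Spearman correlation needs at least 3 subjects.")

  labels <- c(index_components(index), names(index$subscores), "total")
  mat <- as.matrix(tibble::as_tibble(scores)[labels])

  spread <- apply(mat, 2, function(x) diff(range(x)))
  constant <- spread <= tol
  if (all(constant[index_components(index)])) {
    abort("All component scores are constant; no correlations can be made.")
  }
  excluded <- tibble::tibble(label = labels[constant],
                             reason = rep("constant score", sum(constant)))
  keep <- labels[!constant]
  mat <- mat[, keep, drop = FALSE]

  rho <- stats::cor(mat, method = "spearman")
  if (leave_one_out && "total" %in% keep) {
    for (cmp in intersect(index_components(index), keep)) {
      partial_total <- scores$total - scores[[cmp]]
      if (diff(range(partial_total)) > tol) {
        r <- stats::cor(scores[[cmp]], partial_total, method = "spearman")
        rho[cmp, "total"] <- rho["total", cmp] <- r
      }
    }
  }

  p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  use_exact <- exact && n <= 10 && !has_ties(mat)
  for (i in seq_len(nrow(rho))) {
    for (j in seq_len(ncol(rho))) {
      if (i == j) { p[i, j] <- 0; next }
      if (j < i) { p[i, j] <- p[j, i]; next }
      if (use_exact) {
        p[i, j] <- suppressWarnings(
          stats::cor.test(mat[, i], mat[, j], method = "spearman",
                          exact = TRUE)$p.value
        )
      } else {
        p[i, j] <- spearman_p_approx(rho[i, j], n)
      }
    }
  }
  if (p_adjust == "BH") {
    upper <- upper.tri(p)
    p[upper] <- stats::p.adjust(p[upper], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }

  structure(
    list(rho = rho, p = p, n = n, alpha = alpha, excluded = excluded),
    class = "wish_corr"
  )
}

# two-sided p from the t approximation; rho = +-1 => p = 0
spearman_p_approx <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

has_ties <- function(mat) {
  any(apply(mat, 2, function(x) anyDuplicated(x) > 0))
}

#' @export
print.wish_corr <- function(x, ...) {
  cat("<wish_corr> Spearman correlations, n = ", x$n, ", ",
      ncol(x$rho), " scores\n", sep = "")
  if (nrow(x$excluded) > 0) {
    cat("excluded:", paste(x$excluded$label, collapse = ", "),
        "(constant score)\n")
  }
  print(round(x$rho, 2))
  invisible(x)
}

#' @describeIn correlate_wish `tidy()` returns one row per score pair (upper
#'   triangle): `item1`, `item2`, `rho`, `p_value`, `significant`.
#' @param x A `wish_corr`.
#' @param ... Unused.
#' @export
tidy.wish_corr <- function(x, ...) {
  labels <- colnames(x$rho)
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    item1 = labels[pairs[, 1]],
    item2 = labels[pairs[, 2]],
    rho = x$rho[pairs],
    p_value = x$p[pairs],
    significant = x$p[pairs] <= x$alpha
  )
}

#' @describeIn correlate_wish `glance()` reports the sample size, number of
#'   scores correlated, number excluded and share of significant pairs.
#' @export
glance.wish_corr <- function(x, ...) {
  pairs <- tidy(x)
  tibble::tibble(
    n = x$n,
    n_scores = ncol(x$rho),
    n_excluded = nrow(x$excluded),
    prop_significant = mean(pairs$significant)
  )
}

#' @describeIn correlate_wish `autoplot()` draws the correlation heatmap;
#'   cells whose p-value exceeds `alpha` are crossed out.
#' @param object A `wish_corr`.
#' @export
autoplot.wish_corr <- function(object, ...) {
  labels <- colnames(object$rho)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object$rho, rownames = "item1"),
    cols = -"item1", names_to = "item2", values_to = "rho"
  )
  long$p <- as.vector(t(object$p))
  long$item1 <- factor(long$item1, levels = labels)
  long$item2 <- factor(long$item2, levels = rev(labels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$item1, y = .data$item2,
                                     fill = .data$rho)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_point(data = dplyr::filter(long, .data$p > object$alpha),
                        shape = 4, size = 2, color = "grey30") +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Export correlation matrices as CSV
#'
#' Writes the Spearman rho matrix to `path` and the p-value matrix to a
#' companion file suffixed `_pvalues.csv`; excluded scores (constant across
#' the population) are listed in `_excluded.csv` when any exist.
#'
#' @param corr A `wish_corr` from [correlate_wish()].
#' @param path Output CSV path for the rho matrix.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(corr, path) {
  stopifnot(inherits(corr, "wish_corr"))
  readr::write_csv(tibble::as_tibble(corr$rho, rownames = "score"), path)
  stem <- sub("\\.csv$", "", path)
  readr::write_csv(tibble::as_tibble(corr$p, rownames = "score"),
                   paste0(stem, "_pvalues.csv"))
  if (nrow(corr$excluded) > 0) {
    readr::write_csv(corr$excluded, paste0(stem, "_excluded.csv"))
  }
  invisible(path)
}
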