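#' Upper-tail probability of a 1-df chi-square statistic
#'
#' Uses the closed form `p = erfc(sqrt(x / 2)) = 2 * pnorm(sqrt(x),
#' lower.tail = FALSE)`; monotone decreasing in x.
#'
#' @param x non-negative statistic(s).
#' @return upper-tail probability in \[0, 1\].
#' @export
chi2_sf_1df <- function(x) {
  if (any(x < 0)) stop("chi-square statistic must be >= 0")
  2 * pnorm(sqrt(x), lower.tail = FALSE)
}

#' Yates-corrected goodness-of-fit chi-square for a (match, no-match) pair
#'
#' `statistic = sum over the two cells of (max(|O - E| - 0.5, 0))^2 / E`,
#' with 1 degree of freedom. The continuity correction is clamped at zero
#' so that `O = E` gives a statistic of exactly 0.
#'
#' @param observed length-2 numeric: observed (match, no-match) counts.
#' @param expected length-2 numeric: expected counts, both > 0.
#' @return object of class `gof_result`: list with `statistic`, `df` (1),
#'   `p_value`.
#' @examples
#' yates_chi_square(c(110, 73), c(11, 172))   # 938.43
#' @export
yates_chi_square <- function(observed, expected) {
  observed <- as.numeric(observed); expected <- as.numeric(expected)
  if (length(observed) != 2L || length(expected) != 2L)
    stop("observed and expected must each have two cells")
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop("undefined statistic: expected cell is zero or non-finite")
  if (any(observed < 0)) stop("observed counts must be >= 0")
  dev <- pmax(abs(observed - expected) - 0.5, 0)
  stat <- sum(dev^2 / expected)
  structure(list(statistic = stat, df = 1L,
                 p_value = chi2_sf_1df(stat)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("chi-square (Yates, 1 df) = ", format(x$statistic, digits = 6),
      ", p = ", format_p_value(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Observed-vs-expected match table with goodness-of-fit statistics
#'
#' Assembles the per-cohort, per-cutoff comparison of observed leave-one-out
#' match counts with their random-ranking expectations, one row per
#' (cohort, k), in the layout of the published tables.
#'
#' @param fb a [facebase] with embeddings.
#' @param cfg a [rank_config()].
#' @param null_mode `"exact"` (real-valued expectations, the default) or
#'   `"rounded"` (integer expected counts, mirroring the published
#'   arithmetic). Rounded mode errors when a rounded expected cell is zero
#'   (the statistic is undefined there), which can happen for small cohorts
#'   at k = 1; exact mode never does.
#' @param evaluation optional precomputed result of [evaluate_all()];
#'   recomputed when NULL.
#' @return data.frame with columns `cohort`, `n_images`, `k`, `obs_match`,
#'   `obs_no_match`, `exp_match`, `exp_no_match`, `exp_match_exact`,
#'   `chi_square`, `p_value`.
#' @export
build_match_table <- function(fb, cfg = rank_config(),
                              null_mode = c("exact", "rounded"),
                              evaluation = NULL) {
  null_mode <- match.arg(null_mode)
  if (is.null(evaluation)) evaluation <- evaluate_all(fb, cfg)
  obs <- evaluation$counts
  rows <- lapply(unique(obs$cohort), function(co) {
    e <- expected_counts(fb, co, k = cfg$k_set)
    o <- obs[obs$cohort == co, , drop = FALSE]
    stopifnot(all(o$k == e$k))
    em <- if (null_mode == "rounded") e$expected_match_rounded else
      e$expected_match
    en <- if (null_mode == "rounded") e$expected_no_match_rounded else
      e$expected_no_match
    data.frame(cohort = co, n_images = o$n_images, k = o$k,
               obs_match = o$match, obs_no_match = o$no_match,
               exp_match = em, exp_no_match = en,
               exp_match_exact = e$expected_match,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  gof <- mapply(function(om, on, em, en)
    unlist(yates_chi_square(c(om, on), c(em, en))[c("statistic",
                                                    "p_value")]),
    out$obs_match, out$obs_no_match, out$exp_match, out$exp_no_match)
  out$chi_square <- gof["statistic", ]
  out$p_value <- gof["p_value", ]
  rownames(out) <- NULL
  out
}

#' Goodness-of-fit statistics from a table of printed counts
#'
#' Applies [yates_chi_square()] row-wise to a data.frame of observed and
#' expected (match, no-match) pairs, e.g. fixture tables of published
#' counts.
#'
#' @param counts data.frame with columns `obs_match`, `obs_no_match`,
#'   `exp_match`, `exp_no_match`.
#' @return `counts` with `chi_square` and `p_value` columns appended.
#' @export
match_table_from_counts <- function(counts) {
  stopifnot(all(c("obs_match", "obs_no_match", "exp_match",
                  "exp_no_match") %in% names(counts)))
  gof <- mapply(function(om, on, em, en)
    unlist(yates_chi_square(c(om, on), c(em, en))[c("statistic",
                                                    "p_value")]),
    counts$obs_match, counts$obs_no_match,
    counts$exp_match, counts$exp_no_match)
  counts$chi_square <- gof["statistic", ]
  counts$p_value <- gof["p_value", ]
  counts
}
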