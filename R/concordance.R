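#' Clinician panel diagnosis call from three scores
#'
#' Scores are 1 = definitely would have considered the diagnosis,
#' 2 = unlikely, 3 = possibly. A "definite" vote is a score of exactly 1;
#' set `definite_scores = c(1, 3)` to also count "possibly" as a vote (kept
#' behind this switch because the published table captions are ambiguous on
#' the all-three rule).
#'
#' @param scores length-3 vector, or an n x 3 matrix / data.frame of rater
#'   scores, each in \{1, 2, 3\}.
#' @param rule `"two_of_three_definite"` (at least two raters vote yes) or
#'   `"all_three_definite"` (all three vote yes).
#' @param definite_scores scores counted as a yes vote (default 1).
#' @return logical vector of panel calls, one per image.
#' @export
clinician_call <- function(scores,
                           rule = c("two_of_three_definite",
                                    "all_three_definite"),
                           definite_scores = 1L) {
  rule <- match.arg(rule)
  s <- if (is.null(dim(scores))) matrix(as.integer(scores), nrow = 1)
  else as.matrix(scores)
  storage.mode(s) <- "integer"
  if (ncol(s) != 3L) stop("exactly three rater scores per image required")
  if (!all(s %in% 1:3)) stop("scores must be in {1, 2, 3}")
  votes <- rowSums(matrix(s %in% definite_scores, nrow(s)))
  if (rule == "two_of_three_definite") votes >= 2L else votes == 3L
}

#' Software diagnosis call at cutoff k
#'
#' The software "makes a diagnosis" for a test image when a same-syndrome
#' image of another individual appears within the top k closest matches,
#' i.e. the top-k flag produced by the retrieval stage.
#'
#' @param flags named logical vector (`k1`, `k5`, ...) or the `flags`
#'   data.frame of [evaluate_cohort()] / [evaluate_all()].
#' @param k rank cutoff; must be one of the configured cutoffs.
#' @return logical call(s).
#' @export
software_call <- function(flags, k) {
  key <- paste0("k", as.integer(k))
  if (is.data.frame(flags)) {
    if (!key %in% names(flags))
      stop("no flags for k = ", k, " (available: ",
           paste(grep("^k", names(flags), value = TRUE), collapse = ", "),
           ")")
    return(flags[[key]])
  }
  if (!key %in% names(flags)) stop("no flag for k = ", k)
  unname(flags[key])
}

#' Paired 2x2 table of software vs clinician calls
#'
#' @param software,clinician aligned logical vectors of per-image calls.
#' @return object of class `paired_table`: counts `neither` (a), `both`
#'   (d), `software_only` (b), `clinician_only` (c); they sum to the number
#'   of images.
#' @export
paired_table <- function(software, clinician) {
  if (length(software) != length(clinician))
    stop("call vectors have different lengths")
  software <- as.logical(software); clinician <- as.logical(clinician)
  if (anyNA(software) || anyNA(clinician)) stop("calls must not be NA")
  structure(list(neither = sum(!software & !clinician),
                 both = sum(software & clinician),
                 software_only = sum(software & !clinician),
                 clinician_only = sum(!software & clinician)),
            class = "paired_table")
}

#' Paired table from its four cell counts
#'
#' @param neither,both,software_only,clinician_only non-negative counts
#'   (a, d, b, c).
#' @return a `paired_table`.
#' @export
as_paired_table <- function(neither, both, software_only, clinician_only) {
  cells <- c(neither, both, software_only, clinician_only)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  structure(list(neither = neither, both = both,
                 software_only = software_only,
                 clinician_only = clinician_only),
            class = "paired_table")
}

#' @export
print.paired_table <- function(x, ...) {
  cat("paired 2x2 (n = ",
      x$neither + x$both + x$software_only + x$clinician_only,
      "): neither=", x$neither, " both=", x$both,
      " software-only=", x$software_only,
      " clinician-only=", x$clinician_only, "\n", sep = "")
  invisible(x)
}

#' McNemar's test of marginal homogeneity (no continuity correction)
#'
#' `statistic = (b - c)^2 / (b + c)` on the discordant cells, 1 df. When
#' both discordant cells are zero the statistic is undefined (0/0) and is
#' reported as such (`NA` with `defined = FALSE`) rather than an error.
#'
#' @param t a `paired_table`.
#' @return list with `statistic`, `p_value`, `defined`.
#' @export
mcnemar_stat <- function(t) {
  stopifnot(inherits(t, "paired_table"))
  b <- t$software_only; c_ <- t$clinician_only
  if (b + c_ == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                defined = FALSE))
  stat <- (b - c_)^2 / (b + c_)
  list(statistic = stat, p_value = chi2_sf_1df(stat), defined = TRUE)
}

#' Cohen's kappa for a paired 2x2 table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (a + d) / n` and chance agreement `p_e` from the marginal
#' products. With a degenerate marginal that forces `p_e = 1`, observed
#' agreement is necessarily perfect too and kappa is reported as 0 (no
#' agreement beyond chance is demonstrable).
#'
#' @param t a `paired_table`.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "paired_table"))
  a <- t$neither; d <- t$both
  b <- t$software_only; c_ <- t$clinician_only
  n <- a + b + c_ + d
  if (n == 0) stop("empty paired table")
  p_o <- (a + d) / n
  p_e <- ((b + d) * (c_ + d) + (a + c_) * (a + b)) / n^2
  if (abs(1 - p_e) < 1e-12) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Per-cohort software-vs-clinician concordance
#'
#' For each syndrome cohort, pairs the software top-k call with the
#' clinician panel call for every test image and reports the 2x2 cells,
#' McNemar's statistic (NA when undefined) and Cohen's kappa.
#'
#' @param fb a [facebase].
#' @param flags the `flags` data.frame of [evaluate_all()] (or
#'   [evaluate_cohort()]).
#' @param ratings a rating table (`image_id`, `rater1..3`), e.g. from
#'   [generate_clinician_scores()]; every flagged image must be rated.
#' @param rule clinician panel rule, see [clinician_call()].
#' @param k software cutoff, see [software_call()].
#' @param definite_scores passed to [clinician_call()].
#' @return data.frame with one row per cohort: `cohort`, `n`, `neither`,
#'   `both`, `software_only`, `clinician_only`, `mcnemar`, `p_value`,
#'   `kappa`.
#' @export
concordance_table <- function(fb, flags, ratings,
                              rule = "two_of_three_definite", k = 1,
                              definite_scores = 1L) {
  stopifnot(inherits(fb, "facebase"))
  idx <- match(flags$image_id, ratings$image_id)
  if (anyNA(idx))
    stop("missing ratings for image(s): ",
         paste(utils::head(flags$image_id[is.na(idx)], 5), collapse = ", "))
  cl_all <- clinician_call(ratings[idx, c("rater1", "rater2", "rater3")],
                           rule = rule, definite_scores = definite_scores)
  sw_all <- software_call(flags, k)
  rows <- lapply(unique(flags$cohort), function(co) {
    sel <- flags$cohort == co
    t <- paired_table(sw_all[sel], cl_all[sel])
    mc <- mcnemar_stat(t)
    data.frame(cohort = co, n = sum(sel), neither = t$neither,
               both = t$both, software_only = t$software_only,
               clinician_only = t$clinician_only,
               mcnemar = mc$statistic, p_value = mc$p_value,
               kappa = cohen_kappa(t), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' All six concordance table variants
#'
#' \{top-1, top-5, top-10\} x \{two-of-three, all-three\} (or whatever
#' cutoffs `cfg` configures).
#'
#' @param fb a [facebase].
#' @param flags the `flags` data.frame of [evaluate_all()].
#' @param ratings a rating table.
#' @param cfg a [rank_config()].
#' @param rules character vector of clinician rules.
#' @return named list of [concordance_table()] data.frames, keyed
#'   `top<k>_<rule>`.
#' @export
concordance_all <- function(fb, flags, ratings, cfg = rank_config(),
                            rules = c("two_of_three_definite",
                                      "all_three_definite")) {
  out <- list()
  for (k in cfg$k_set)
    for (rule in rules)
      out[[paste0("top", k, "_", rule)]] <-
        concordance_table(fb, flags, ratings, rule = rule, k = k)
  out
}
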