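#' Probability of a top-k match under a uniformly random ranking
#'
#' If a test image has `M` candidates of which `m` are same-syndrome, and
#' the candidate order is uniformly random, the k best candidates are a
#' uniform size-k subset, so the probability that at least one success lands
#' in the top k is the hypergeometric tail
#' `1 - choose(M - m, k) / choose(M, k)`, computed stably in log space.
#' Equals `m / M` at `k = 1`, and 1 whenever `k > M - m`.
#'
#' @param m number of same-syndrome candidate images (excluding the test
#'   image and its same-individual images), `0 <= m <= M`.
#' @param M total candidate count.
#' @param k rank cutoff, `1 <= k <= M`.
#' @return probability in \[0, 1\]; vectorised with recycling.
#' @export
match_probability <- function(m, M, k) {
  n <- max(length(m), length(M), length(k))
  m <- rep_len(m, n); M <- rep_len(M, n); k <- rep_len(k, n)
  if (any(m < 0 | m > M)) stop("require 0 <= m <= M")
  if (any(k < 1 | k > M)) stop("require 1 <= k <= M")
  # lchoose(M - m, k) is -Inf when k > M - m, giving probability 1
  -expm1(lchoose(M - m, k) - lchoose(M, k))
}

#' Per-test-image null parameters for a cohort
#'
#' For every test image of the cohort at the given stage: `M` = candidates
#' remaining after removing the test individual's images, `m` = same-cohort
#' images among them.
#'
#' @param fb a [facebase] (embeddings not required).
#' @param cohort syndrome cohort name.
#' @param stage analysis stage; defaults to [analysis_stage()].
#' @return data.frame with columns `image_id`, `m`, `M`.
#' @export
null_spec <- function(fb, cohort, stage = NULL) {
  stopifnot(inherits(fb, "facebase"))
  if (cohort == CONTROL_COHORT) stop("controls are not test cases")
  if (is.null(stage)) stage <- analysis_stage(fb, cohort)
  rec <- fb$records[fb$records$stage <= as.integer(stage), , drop = FALSE]
  test <- rec[rec$cohort == cohort, , drop = FALSE]
  if (nrow(test) == 0L) stop("unknown cohort or empty at stage: ", cohort)
  N <- nrow(rec)
  n_s <- nrow(test)
  ind_sizes <- table(rec$individual_id)
  own <- as.integer(ind_sizes[test$individual_id])
  data.frame(image_id = test$image_id,
             m = n_s - own,     # same-cohort candidates excl. own images
             M = N - own,
             stringsAsFactors = FALSE)
}

#' Analytic expected top-k match counts for a cohort
#'
#' Sums the per-image random-ranking match probabilities; the rounded
#' variant mirrors the integer expected counts of the published tables
#' (no-match = cohort size minus rounded match).
#'
#' @param fb a [facebase].
#' @param cohort syndrome cohort name.
#' @param k rank cutoff(s).
#' @param stage analysis stage; defaults to [analysis_stage()].
#' @return data.frame with one row per k: `cohort`, `n_images`, `k`,
#'   `expected_match` (real-valued; `expected_match + expected_no_match`
#'   equals the cohort size exactly), `expected_no_match`,
#'   `expected_match_rounded`, `expected_no_match_rounded`.
#' @export
expected_counts <- function(fb, cohort, k = c(1L, 5L, 10L), stage = NULL) {
  spec <- null_spec(fb, cohort, stage)
  n_s <- nrow(spec)
  e <- vapply(k, function(ki)
    sum(match_probability(spec$m, spec$M, ki)), numeric(1))
  er <- round(e)
  data.frame(cohort = cohort, n_images = n_s, k = as.integer(k),
             expected_match = e, expected_no_match = n_s - e,
             expected_match_rounded = er,
             expected_no_match_rounded = n_s - er,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo expected top-k match counts under random ranking
#'
#' Each replicate assigns a uniformly random ranking to every test image's
#' candidates and counts how many test images have a same-syndrome candidate
#' in the top k. Method `"hypergeom"` draws the number of successes in the
#' random top-k directly from the hypergeometric distribution (identical in
#' distribution, much faster); method `"ranking"` performs the literal
#' uniform permutation draw and serves as the slow cross-check.
#'
#' @param fb a [facebase].
#' @param cohort syndrome cohort name.
#' @param k rank cutoff.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed; estimates are deterministic per seed.
#' @param method `"hypergeom"` (default) or `"ranking"`.
#' @param stage analysis stage; defaults to [analysis_stage()].
#' @return list with `estimate` (mean matched count over replicates), `se`
#'   (standard error of that mean), `n_reps`, `method`.
#' @export
simulate_expected_counts <- function(fb, cohort, k, n_reps = 10000L,
                                     seed = 1L,
                                     method = c("hypergeom", "ranking"),
                                     stage = NULL) {
  method <- match.arg(method)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  spec <- null_spec(fb, cohort, stage)
  with_seed(seed, {
    totals <- numeric(n_reps)
    for (i in seq_len(nrow(spec))) {
      m <- spec$m[i]; M <- spec$M[i]
      if (k > M) stop("k exceeds candidate count for image ",
                      spec$image_id[i])
      if (m == 0L) next
      hit <- if (method == "hypergeom") {
        rhyper(n_reps, m, M - m, k) >= 1L
      } else {
        # success iff a uniformly drawn top-k set meets the first m labels
        vapply(seq_len(n_reps),
               function(r) any(sample.int(M, k) <= m), logical(1))
      }
      totals <- totals + hit
    }
    se <- if (n_reps > 1L) sd(totals) / sqrt(n_reps) else NA_real_
    list(estimate = mean(totals), se = se, n_reps = n_reps,
         method = method)
  })
}
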