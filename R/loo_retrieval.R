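#' Rank cutoffs for top-k matching
#'
#' @param k_set strictly increasing positive integers (default `c(1, 5, 10)`:
#'   top match, top five, top ten).
#' @return an object of class `rank_config`.
#' @export
rank_config <- function(k_set = c(1L, 5L, 10L)) {
  k_set <- as.integer(k_set)
  if (length(k_set) == 0L || any(k_set < 1L) ||
      any(diff(k_set) <= 0L))
    stop("k_set must be strictly increasing positive integers")
  structure(list(k_set = k_set), class = "rank_config")
}

# Resolve the database index set for one test image: records at the given
# stage, minus every image of the test individual ("all photographs were
# removed" so a face never matches itself at another age).
candidate_index <- function(fb, test_idx, stage_keep) {
  ind <- fb$records$individual_id[test_idx]
  which(stage_keep & fb$records$individual_id != ind)
}

#' Rank all candidates for one leave-one-out test image
#'
#' Removes the test image and every other image of the same individual from
#' the database, then ranks the remaining images by cosine similarity to the
#' test embedding (descending; ties broken by ascending `image_id` for
#' determinism).
#'
#' @param fb a [facebase] with embeddings.
#' @param test_image_id id of a syndrome image (controls are never test
#'   cases).
#' @param stage optional analysis stage; candidates are restricted to
#'   records whose entry stage is <= `stage`.
#' @return data.frame with columns `candidate_id`, `cohort`, `similarity`,
#'   ordered best-first; `N - n_images(test individual)` rows.
#' @export
rank_candidates <- function(fb, test_image_id, stage = NULL) {
  stopifnot(inherits(fb, "facebase"))
  if (is.null(fb$embeddings))
    stop("facebase has no embeddings; cannot rank")
  test_idx <- match(test_image_id, fb$records$image_id)
  if (is.na(test_idx)) stop("unknown image_id: ", test_image_id)
  if (fb$records$cohort[test_idx] == CONTROL_COHORT)
    stop("controls are not test cases")
  stage_keep <- if (is.null(stage)) rep(TRUE, n_images(fb)) else
    fb$records$stage <= as.integer(stage)
  if (!stage_keep[test_idx])
    stop("test image is not in the database at stage ", stage)
  cand <- candidate_index(fb, test_idx, stage_keep)
  sims <- as.vector(fb$embeddings[cand, , drop = FALSE] %*%
                      fb$embeddings[test_idx, ])
  ids <- fb$records$image_id[cand]
  ord <- order(-sims, ids, method = "radix")
  data.frame(candidate_id = ids[ord],
             cohort = fb$records$cohort[cand][ord],
             similarity = sims[ord],
             stringsAsFactors = FALSE)
}

#' Top-k same-syndrome flags for a ranked candidate list
#'
#' `flag_k` is TRUE iff any of the first k ranked candidates belongs to the
#' test image's cohort. Same-individual images were excluded upstream, so a
#' success is always a match to a different individual.
#'
#' @param ranked data.frame from [rank_candidates()] (needs a `cohort`
#'   column in rank order).
#' @param cohort_of_test the test image's cohort.
#' @param cfg a [rank_config()].
#' @return named logical vector (`k1`, `k5`, ...), monotone non-decreasing
#'   in k. A cutoff beyond the candidate count is evaluated over the
#'   available candidates, with a warning.
#' @export
topk_flags <- function(ranked, cohort_of_test, cfg = rank_config()) {
  n <- nrow(ranked)
  if (n == 0L) stop("ranked candidate list is empty")
  if (any(cfg$k_set > n))
    warning("k exceeds candidate count (", n,
            "); evaluating over available candidates")
  same <- ranked$cohort == cohort_of_test
  hits <- cumsum(same) > 0
  flags <- hits[pmin(cfg$k_set, n)]
  names(flags) <- paste0("k", cfg$k_set)
  flags
}

#' Leave-one-out evaluation of one syndrome cohort
#'
#' Runs every image of the cohort as a test case against the database at the
#' cohort's analysis stage and tallies observed top-k same-syndrome match
#' counts.
#'
#' @param fb a [facebase] with embeddings.
#' @param cohort syndrome cohort name.
#' @param cfg a [rank_config()].
#' @param stage analysis stage; defaults to [analysis_stage()] of the
#'   cohort (the stage at which its images were complete).
#' @return list with `counts` (data.frame `cohort`, `n_images`, `k`,
#'   `match`, `no_match`; the two counts sum to the cohort size for every k)
#'   and `flags` (data.frame `image_id`, `cohort`, one logical column per
#'   cutoff).
#' @export
evaluate_cohort <- function(fb, cohort, cfg = rank_config(), stage = NULL) {
  stopifnot(inherits(fb, "facebase"), inherits(cfg, "rank_config"))
  if (is.null(fb$embeddings)) stop("facebase has no embeddings")
  if (cohort == CONTROL_COHORT) stop("controls are not test cases")
  if (is.null(stage)) stage <- analysis_stage(fb, cohort)
  stage_keep <- fb$records$stage <= as.integer(stage)
  test_idx <- which(fb$records$cohort == cohort & stage_keep)
  if (length(test_idx) == 0L)
    stop("unknown cohort or no images at stage ", stage, ": ", cohort)

  ids <- fb$records$image_id
  cohorts <- fb$records$cohort
  # all similarities of test images against the staged database at once
  S <- fb$embeddings %*% t(fb$embeddings[test_idx, , drop = FALSE])
  flags <- matrix(NA, length(test_idx), length(cfg$k_set))
  for (j in seq_along(test_idx)) {
    ti <- test_idx[j]
    cand <- candidate_index(fb, ti, stage_keep)
    ord <- order(-S[cand, j], ids[cand], method = "radix")
    same <- cohorts[cand][ord] == cohort
    if (any(cfg$k_set > length(cand)))
      warning("k exceeds candidate count for image ", ids[ti])
    flags[j, ] <- (cumsum(same) > 0)[pmin(cfg$k_set, length(cand))]
  }
  colnames(flags) <- paste0("k", cfg$k_set)
  n_s <- length(test_idx)
  counts <- data.frame(cohort = cohort, n_images = n_s, k = cfg$k_set,
                       match = as.integer(colSums(flags)),
                       stringsAsFactors = FALSE)
  counts$no_match <- n_s - counts$match
  flag_df <- data.frame(image_id = ids[test_idx], cohort = cohort,
                        as.data.frame(flags), stringsAsFactors = FALSE)
  rownames(flag_df) <- NULL
  list(counts = counts, flags = flag_df)
}

#' Leave-one-out evaluation of every syndrome cohort
#'
#' @param fb a [facebase] with embeddings.
#' @param cfg a [rank_config()].
#' @return list with stacked `counts` and `flags` data.frames (one block per
#'   cohort, each evaluated at its own analysis stage).
#' @export
evaluate_all <- function(fb, cfg = rank_config()) {
  res <- lapply(syndrome_cohorts(fb), function(co)
    evaluate_cohort(fb, co, cfg))
  list(counts = do.call(rbind, lapply(res, `[[`, "counts")),
       flags = do.call(rbind, lapply(res, `[[`, "flags")))
}
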