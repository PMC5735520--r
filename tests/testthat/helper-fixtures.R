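# Shared fixture builders and independent oracles.

# Tiny facebase with explicit 2-d embeddings (cosine geometry is obvious).
geometry_facebase <- function() {
  rec <- data.frame(
    image_id = c("A1", "B1", "C1"),
    individual_id = c("ind-a", "ind-b", "ind-c"),
    cohort = c("W", "X", "Y"),
    stringsAsFactors = FALSE)
  emb <- rbind(c(1, 0), c(0.995, 0.0999), c(0, 1))
  facebase(rec, emb)
}

# Random labelled facebase with <= n_max images, duplicate individuals and
# controls; embeddings are raw gaussians (unit-normalised on construction).
random_facebase <- function(seed, n_max = 100, d = 8) {
  set.seed(seed)
  n_syn <- sample(2:4, 1)
  cohorts <- paste0("S", seq_len(n_syn))
  recs <- list()
  for (co in cohorts) {
    n_ind <- sample(3:8, 1)
    counts <- ifelse(runif(n_ind) < 0.3, sample(2:3, n_ind, TRUE), 1L)
    ind <- rep(seq_len(n_ind), counts)
    recs[[co]] <- data.frame(
      image_id = paste0(co, "-", ind, ".", sequence(counts)),
      individual_id = paste0(co, "-", ind),
      cohort = co, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  n_ctrl <- min(sample(10:30, 1), n_max - nrow(rec))
  rec <- rbind(rec, data.frame(
    image_id = paste0("CTRL-", seq_len(n_ctrl)),
    individual_id = paste0("CTRL-", seq_len(n_ctrl)),
    cohort = "CONTROL", stringsAsFactors = FALSE))
  rownames(rec) <- NULL
  emb <- matrix(rnorm(nrow(rec) * d), ncol = d)
  facebase(rec, emb)
}

# Independent O(N) oracle: per-candidate cosine similarity computed one dot
# product at a time, sorted with the same deterministic tie-break.
brute_rank_ids <- function(fb, test_id) {
  rec <- fb$records
  ti <- which(rec$image_id == test_id)
  keep <- which(rec$individual_id != rec$individual_id[ti])
  a <- fb$embeddings[ti, ]
  sims <- vapply(keep, function(j) {
    b <- fb$embeddings[j, ]
    sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }, numeric(1))
  ids <- rec$image_id[keep]
  ids[order(-sims, ids, method = "radix")]
}

# Brute-force observed top-k match counts for a cohort.
brute_counts <- function(fb, cohort, k_set = c(1, 5, 10)) {
  test_ids <- fb$records$image_id[fb$records$cohort == cohort]
  hits <- vapply(test_ids, function(id) {
    ranked <- brute_rank_ids(fb, id)
    co <- fb$records$cohort[match(ranked, fb$records$image_id)]
    vapply(k_set, function(k) any(co[seq_len(min(k, length(co)))] ==
                                    cohort), logical(1))
  }, logical(length(k_set)))
  rowSums(matrix(hits, nrow = length(k_set)))
}

# Enumeration oracle for the random-ranking match probability: fraction of
# all size-k candidate subsets containing at least one of the m successes.
enumerate_match_probability <- function(m, M, k) {
  sets <- utils::combn(M, k)
  mean(apply(sets, 2, function(s) any(s <= m)))
}
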