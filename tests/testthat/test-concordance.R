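test_that("clinician panel rules count definite votes", {
  expect_true(clinician_call(c(1, 1, 2), "two_of_three_definite"))
  expect_false(clinician_call(c(1, 3, 3), "two_of_three_definite"))
  expect_true(clinician_call(c(1, 1, 1), "all_three_definite"))
  expect_false(clinician_call(c(1, 1, 3), "all_three_definite"))
  # optional looser reading: "possibly" counts as a vote
  expect_true(clinician_call(c(1, 3, 3), "two_of_three_definite",
                             definite_scores = c(1L, 3L)))
  expect_error(clinician_call(c(1, 4, 2), "two_of_three_definite"),
               "scores must be")
  m <- rbind(c(1, 1, 2), c(2, 2, 3), c(1, 1, 1))
  expect_equal(clinician_call(m, "two_of_three_definite"),
               c(TRUE, FALSE, TRUE))
})

test_that("software calls read the right top-k flag", {
  flags <- c(k1 = TRUE, k5 = TRUE, k10 = TRUE)
  expect_true(software_call(flags, 1))
  expect_false(software_call(c(k1 = FALSE, k5 = TRUE, k10 = TRUE), 1))
  expect_true(software_call(c(k1 = FALSE, k5 = FALSE, k10 = TRUE), 10))
  expect_error(software_call(flags, 3), "no flag")
  df <- data.frame(k1 = c(TRUE, FALSE), k5 = c(TRUE, TRUE))
  expect_equal(software_call(df, 5), c(TRUE, TRUE))
  expect_error(software_call(df, 10), "no flags")
})

test_that("paired tables count the four outcome cells", {
  t1 <- paired_table(rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(unlist(t1[c("neither", "both", "software_only",
                           "clinician_only")]),
               c(neither = 0L, both = 7L, software_only = 0L,
                 clinician_only = 0L))
  t2 <- paired_table(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(c(t2$neither, t2$both, t2$software_only, t2$clinician_only),
               c(1L, 1L, 1L, 0L))
  expect_error(paired_table(c(TRUE), c(TRUE, FALSE)), "different lengths")
  set.seed(2)
  for (i in 1:5) {
    sw <- runif(200) < 0.5; cl <- runif(200) < 0.3
    t <- paired_table(sw, cl)
    expect_equal(t$neither + t$both + t$software_only + t$clinician_only,
                 200L)
  }
})

test_that("McNemar reproduces published discordant-cell statistics", {
  cl <- mcnemar_stat(as_paired_table(42, 41, 47, 24))  # Coffin Lowry top-1
  expect_lt(abs(cl$statistic - 7.45), 0.005)
  expect_lt(abs(cl$p_value - 0.00634), 5e-6)
  pacs <- mcnemar_stat(as_paired_table(33, 2, 4, 0))   # no correction: 4.00
  expect_equal(pacs$statistic, 4.00)
  expect_lt(abs(pacs$p_value - 0.0455), 5e-5)
  eq <- mcnemar_stat(as_paired_table(10, 10, 6, 6))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  undef <- mcnemar_stat(as_paired_table(10, 10, 0, 0))
  expect_false(undef$defined)
  expect_true(is.na(undef$statistic) && is.na(undef$p_value))
  # depends only on the discordant cells
  expect_equal(mcnemar_stat(as_paired_table(0, 0, 47, 24))$statistic,
               mcnemar_stat(as_paired_table(99, 99, 47, 24))$statistic)
})

test_that("Cohen's kappa reproduces published values and its bounds", {
  expect_lt(abs(cohen_kappa(as_paired_table(33, 2, 4, 0)) - 0.46), 0.005)
  expect_lt(abs(cohen_kappa(as_paired_table(2, 103, 73, 5)) + 0.02), 0.005)
  # degenerate software marginal: p_o = p_e, kappa 0
  expect_equal(cohen_kappa(as_paired_table(0, 96, 59, 0)), 0)
  expect_equal(cohen_kappa(as_paired_table(50, 50, 0, 0)), 1)
  expect_error(cohen_kappa(as_paired_table(0, 0, 0, 0)), "empty")
  set.seed(9)
  for (i in 1:20) {
    cells <- sample(0:30, 4, replace = TRUE)
    if (sum(cells) == 0) next
    t <- as_paired_table(cells[1], cells[2], cells[3], cells[4])
    k <- cohen_kappa(t)
    expect_true(k >= -1 && k <= 1)
    # simultaneous relabelling of the positive class for both raters
    t2 <- as_paired_table(cells[2], cells[1], cells[4], cells[3])
    expect_equal(cohen_kappa(t2), k)
  }
})

test_that("all defined published McNemar statistics and kappas recompute
           from printed cells", {
  v <- verify_paper()
  expect_equal(nrow(v$concordance), 30L)
  expect_true(all(v$concordance$mcnemar_diff <= 0.005 + 1e-9, na.rm = TRUE))
  expect_true(all(v$concordance$kappa_diff <= 0.005 + 1e-9))
  # the one known inconsistency: a computable statistic printed as "."
  expect_equal(v$discrepancies$syndrome, "Rubinstein-Taybi")
  expect_equal(v$discrepancies$k, 10)
  expect_equal(v$discrepancies$mcnemar, 59.00)
})

test_that("cohort concordance tables follow degenerate rating regimes", {
  cfg <- generator_config(
    cohorts = data.frame(name = "A", n_images = 15),
    n_controls = 30, d = 8, sigma_b = 50, sigma_w = 0.1, sigma_e = 0.05,
    dup_frac = 0, seed = 12)
  fb <- generate_embedding_facebase(cfg)   # retrieval is perfect here
  flags <- evaluate_all(fb)$flags
  r_all <- generate_clinician_scores(fb, rating_model(1, 0), seed = 1)
  t_all <- concordance_table(fb, flags, r_all, k = 1)
  expect_equal(t_all$both, 15L)
  expect_equal(t_all$neither + t_all$software_only + t_all$clinician_only,
               0L)
  r_none <- generate_clinician_scores(fb, rating_model(0, 0), seed = 1)
  t_none <- concordance_table(fb, flags, r_none, k = 1)
  expect_equal(t_none$software_only, 15L)
  expect_equal(t_none$kappa, 0)
  expect_error(concordance_table(fb, flags, r_all[-1, ], k = 1),
               "missing ratings")
  # six variants, cells conserving cohort size
  conc <- concordance_all(fb, flags, r_all)
  expect_equal(length(conc), 6L)
  for (tab in conc)
    expect_equal(tab$neither + tab$both + tab$software_only +
                   tab$clinician_only, tab$n)
})
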