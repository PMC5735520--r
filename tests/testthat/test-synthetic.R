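small_cfg <- function(...) {
  generator_config(
    cohorts = data.frame(name = c("A", "B"), n_images = c(5, 5)),
    n_controls = 10, d = 16, dup_frac = 0, seed = 42, ...)
}

test_that("generator produces the configured counts with unit-norm rows", {
  fb <- generate_embedding_facebase(small_cfg())
  expect_equal(n_images(fb), 20L)
  expect_equal(unname(sqrt(rowSums(fb$embeddings^2))), rep(1, 20),
               tolerance = 1e-12)
  cs <- cohort_sizes(fb)
  expect_equal(cs$n_images, c(5L, 5L, 10L))
})

test_that("generator is deterministic per seed and varies across seeds", {
  fb1 <- generate_embedding_facebase(small_cfg())
  fb2 <- generate_embedding_facebase(small_cfg())
  expect_identical(fb1$records, fb2$records)
  expect_identical(fb1$embeddings, fb2$embeddings)
  fb3 <- generate_embedding_facebase(
    generator_config(cohorts = data.frame(name = c("A", "B"),
                                          n_images = c(5, 5)),
                     n_controls = 10, d = 16, dup_frac = 0, seed = 43))
  expect_false(identical(fb1$embeddings, fb3$embeddings))
})

test_that("duplicate individuals carry dotted ids and shared identity", {
  cfg <- generator_config(
    cohorts = data.frame(name = "A", n_images = 40),
    n_controls = 0, d = 4, dup_frac = 0.5, seed = 3)
  fb <- generate_embedding_facebase(cfg)
  cs <- cohort_sizes(fb)
  expect_lt(cs$n_individuals, cs$n_images)   # some individuals duplicated
  dup_ind <- names(which(table(fb$records$individual_id) > 1))[1]
  ids <- fb$records$image_id[fb$records$individual_id == dup_ind]
  expect_true(all(grepl("\\.\\d+$", ids)))
})

test_that("clinician score generator honours degenerate rating models", {
  fb <- generate_embedding_facebase(small_cfg())
  r1 <- generate_clinician_scores(fb, rating_model(1, 0), seed = 1)
  expect_true(all(as.matrix(r1[, 2:4]) == 1L))
  expect_equal(nrow(r1), 10L)   # controls are never scored
  r2 <- generate_clinician_scores(fb, rating_model(0, 0), seed = 1)
  expect_true(all(as.matrix(r2[, 2:4]) == 2L))
  expect_error(
    generate_clinician_scores(fb, rating_model(c(A = 0.5), 0.1), seed = 1),
    "no p_definite for cohort")
})

test_that("score-1 marginal converges to p_definite", {
  cfg <- generator_config(
    cohorts = data.frame(name = "A", n_images = 1000),
    n_controls = 0, d = 2, dup_frac = 0, seed = 5)
  fb <- generate_embedding_facebase(cfg, embeddings = FALSE)
  r <- generate_clinician_scores(fb, rating_model(0.6, 0.2), seed = 9)
  rate <- mean(r$rater1 == 1L)
  se <- sqrt(0.6 * 0.4 / 1000)
  expect_lt(abs(rate - 0.6), 3 * se)
  # raters are positively correlated through the shared latent
  agree <- mean((r$rater1 == 1L) == (r$rater2 == 1L))
  expect_gt(agree, 0.6 * 0.6 + 0.4 * 0.4)
})

test_that("sketch faces are deterministic and stay inside the canvas", {
  p <- random_individual_params(1, seed = 2)[1, ]
  img1 <- generate_face_image(p, 1.0, noise_seed = 7)
  img2 <- generate_face_image(p, 1.0, noise_seed = 7)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  # midpoint params, largest age scale used in tests: border stays background
  mid <- rep(0, 8)
  img <- generate_face_image(mid, 1.2, noise_seed = 1, noise_sd = 0)
  border <- c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)])
  expect_true(all(border == 0.05))
  expect_error(generate_face_image(p, size = 16), "size")
})

test_that("same individual at different ages beats other individuals in
           descriptor similarity", {
  params <- random_individual_params(20, seed = 31)
  p <- descriptor_params()
  base <- embed_images(lapply(seq_len(20), function(i)
    generate_face_image(params[i, ], 1.0, noise_seed = 100 + i)), p)
  aged <- embed_images(lapply(seq_len(20), function(i)
    generate_face_image(params[i, ], 1.2, noise_seed = 200 + i)), p)
  for (i in 1:5) {
    own <- cosine_similarity(base[i, ], aged[i, ])
    others <- vapply(setdiff(1:20, i), function(j)
      cosine_similarity(base[i, ], aged[j, ]), numeric(1))
    expect_gt(own, stats::median(others))
  }
})

test_that("top-1 match rate is non-decreasing in sigma_b (seed-averaged)", {
  rate_at <- function(sb) {
    mean(vapply(1:6, function(s) {
      cfg <- generator_config(
        cohorts = data.frame(name = paste0("S", 1:4),
                             n_images = rep(10, 4)),
        n_controls = 40, d = 8, sigma_b = sb, sigma_w = 0.5,
        sigma_e = 0.3, dup_frac = 0, seed = 1000 + s)
      fb <- generate_embedding_facebase(cfg)
      ev <- evaluate_all(fb, rank_config(1L))
      sum(ev$counts$match) / sum(ev$counts$n_images)
    }, numeric(1)))
  }
  rates <- vapply(c(0, 1, 3, 8), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
})
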