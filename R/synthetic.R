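#' Published database composition at the three analysis stages
#'
#' Cohort layout of the reference image database: ten syndrome cohorts with
#' their image counts and the analysis stage at which each cohort's images
#' were complete. Cornelia de Lange is split across stages: 192 images were
#' present from the start but the cohort was analysed only after a further
#' 249 images arrived at stage 3 (`n_early` records the early tranche).
#' With 2081 controls this yields database sizes 3145, 3432 and 3681 at
#' stages 1-3.
#'
#' @return data.frame with columns `name`, `n_images`, `stage`, `n_early`.
#' @export
reference_cohorts <- function() {
  data.frame(
    name = c("Williams", "Rubinstein-Taybi", "Floating Harbor",
             "Coffin Lowry", "Kabuki", "Smith Magenis", "PACS1",
             "Kleefstra", "Koolen-de Vries", "Cornelia de Lange"),
    n_images = c(183L, 155L, 61L, 154L, 195L, 124L, 39L, 128L, 120L, 441L),
    stage = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L),
    n_early = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 192L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic facebase generator
#'
#' The generator draws embeddings from a three-level Gaussian hierarchy on
#' the sphere: a syndrome prototype (scale `sigma_b`), an individual centre
#' around it (scale `sigma_w`), and per-image noise (scale `sigma_e`),
#' followed by L2 normalisation. Controls are heterogeneous unaffected faces
#' and are drawn from the zero-centred mixture marginal with total variance
#' `sigma_b^2 + sigma_w^2 + sigma_e^2` per coordinate.
#'
#' @param cohorts data.frame with columns `name`, `n_images` and optionally
#'   `stage` (default 1) and `n_early` (images already present at stage 1
#'   for a cohort analysed later; default 0). Defaults to
#'   [reference_cohorts()].
#' @param n_controls number of control images (default 2081, the published
#'   control count).
#' @param d embedding dimension (>= 2).
#' @param sigma_b between-syndrome prototype scale (>= 0).
#' @param sigma_w within-syndrome, between-individual scale (>= 0).
#' @param sigma_e within-individual, between-image scale (>= 0).
#' @param dup_frac fraction of syndrome individuals contributing 2-3 images
#'   (same face at different ages); controls always contribute one image.
#' @param dup_images integer choices for the image count of a duplicated
#'   individual.
#' @param seed integer seed; a fixed config + seed is fully deterministic.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(cohorts = reference_cohorts(),
                             n_controls = 2081L,
                             d = 64L,
                             sigma_b = 1, sigma_w = 0.6, sigma_e = 0.3,
                             dup_frac = 0.05, dup_images = 2:3,
                             seed = 1L) {
  stopifnot(is.data.frame(cohorts),
            all(c("name", "n_images") %in% names(cohorts)))
  if (!"stage" %in% names(cohorts)) cohorts$stage <- 1L
  if (!"n_early" %in% names(cohorts)) cohorts$n_early <- 0L
  cohorts$n_images <- as.integer(cohorts$n_images)
  cohorts$stage <- as.integer(cohorts$stage)
  cohorts$n_early <- as.integer(cohorts$n_early)
  if (any(cohorts$n_images < 0L) || n_controls < 0L)
    stop("counts must be >= 0")
  if (any(cohorts$n_early > cohorts$n_images))
    stop("n_early cannot exceed n_images")
  if (anyDuplicated(cohorts$name)) stop("duplicate cohort names")
  if (CONTROL_COHORT %in% cohorts$name)
    stop("'", CONTROL_COHORT, "' is a reserved cohort name")
  if (d < 2) stop("embedding dimension d must be >= 2")
  if (min(sigma_b, sigma_w, sigma_e) < 0) stop("scales must be >= 0")
  if (dup_frac < 0 || dup_frac > 1) stop("dup_frac must be in [0, 1]")
  structure(list(cohorts = cohorts, n_controls = as.integer(n_controls),
                 d = as.integer(d), sigma_b = sigma_b, sigma_w = sigma_w,
                 sigma_e = sigma_e, dup_frac = dup_frac,
                 dup_images = as.integer(dup_images),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Partition n_images of one cohort into per-individual image counts:
# each individual has 1 image except a dup_frac fraction with 2-3.
allocate_individuals <- function(n_images, dup_frac, dup_images) {
  counts <- integer(0)
  remaining <- n_images
  while (remaining > 0L) {
    k <- if (remaining >= 2L && runif(1) < dup_frac)
      dup_images[sample.int(length(dup_images), 1L)] else 1L
    k <- min(k, remaining)
    counts <- c(counts, k)
    remaining <- remaining - k
  }
  counts
}

#' Generate a synthetic facebase of clustered embeddings
#'
#' Emulates the statistical structure the evaluation assumes: images of the
#' same syndrome are more similar than images of different syndromes or of
#' controls, and occasional individuals contribute several images (which the
#' leave-one-out protocol must exclude together). Image ids carry the
#' field's dotted numbering for same-individual duplicates ("Williams-007.2")
#' but identity is carried solely by `individual_id`.
#'
#' @param cfg a [generator_config()].
#' @param embeddings if FALSE, generate the manifest only (no embedding
#'   matrix); useful when only the database structure is needed.
#' @return a [facebase] with `sum(n_images) + n_controls` records, unit-norm
#'   embedding rows, deterministic for a fixed config.
#' @export
generate_embedding_facebase <- function(cfg = generator_config(),
                                        embeddings = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    recs <- vector("list", nrow(cfg$cohorts) + 1L)
    embs <- vector("list", nrow(cfg$cohorts) + 1L)
    for (i in seq_len(nrow(cfg$cohorts))) {
      co <- cfg$cohorts[i, ]
      slug <- gsub("[^A-Za-z0-9]+", "", co$name)
      counts <- allocate_individuals(co$n_images, cfg$dup_frac,
                                     cfg$dup_images)
      ind_idx <- rep(seq_along(counts), counts)
      img_no <- sequence(counts)
      individual_id <- sprintf("%s-%03d", slug, ind_idx)
      image_id <- ifelse(counts[ind_idx] == 1L,
                         sprintf("%s-%03d", slug, ind_idx),
                         sprintf("%s-%03d.%d", slug, ind_idx, img_no))
      # entry stage: the first n_early images predate stage 1
      stage <- rep(co$stage, co$n_images)
      if (co$n_early > 0L) stage[seq_len(co$n_early)] <- 1L
      recs[[i]] <- data.frame(image_id = image_id,
                              individual_id = individual_id,
                              cohort = co$name, stage = stage,
                              stringsAsFactors = FALSE)
      if (embeddings) {
        mu <- rnorm(cfg$d, 0, cfg$sigma_b)
        centres <- matrix(rnorm(length(counts) * cfg$d, 0, cfg$sigma_w),
                          ncol = cfg$d, byrow = TRUE) +
          matrix(mu, length(counts), cfg$d, byrow = TRUE)
        x <- centres[ind_idx, , drop = FALSE] +
          matrix(rnorm(co$n_images * cfg$d, 0, cfg$sigma_e),
                 ncol = cfg$d)
        embs[[i]] <- x
      }
    }
    nc <- cfg$n_controls
    if (nc > 0L) {
      recs[[length(recs)]] <- data.frame(
        image_id = sprintf("%s-%04d", CONTROL_COHORT, seq_len(nc)),
        individual_id = sprintf("%s-%04d", CONTROL_COHORT, seq_len(nc)),
        cohort = CONTROL_COHORT, stage = 1L,
        stringsAsFactors = FALSE)
      if (embeddings) {
        s_tot <- sqrt(cfg$sigma_b^2 + cfg$sigma_w^2 + cfg$sigma_e^2)
        embs[[length(embs)]] <- matrix(rnorm(nc * cfg$d, 0, s_tot),
                                       ncol = cfg$d)
      }
    }
    rec <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    emb <- if (embeddings)
      do.call(rbind, embs[!vapply(embs, is.null, logical(1))]) else NULL
    facebase(rec, emb)
  })
}

#' Clinician rating model
#'
#' Each non-control image receives three scores in \{1, 2, 3\}
#' (1 = definitely would have considered the diagnosis, 2 = unlikely,
#' 3 = possibly). Per cohort, a rater scores 1 with probability `p_definite`
#' and 3 with probability `p_possible`; the residual mass is score 2.
#' Rater agreement beyond chance is induced by a per-image latent
#' "recognisability" draw shared across the three raters (Gaussian copula
#' with correlation `rater_correlation`), which leaves the per-rater
#' marginals exact.
#'
#' @param p_definite named numeric vector (per cohort) or scalar probability
#'   of score 1.
#' @param p_possible probability of score 3 (scalar or named per cohort);
#'   `p_definite + p_possible <= 1` per cohort.
#' @param rater_correlation latent correlation in \[0, 1\].
#' @return an object of class `rating_model`.
#' @export
rating_model <- function(p_definite, p_possible = 0.2,
                         rater_correlation = 0.5) {
  if (any(p_definite < 0 | p_definite > 1) ||
      any(p_possible < 0 | p_possible > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(p_definite + p_possible > 1 + 1e-12))
    stop("p_definite + p_possible must be <= 1 per cohort")
  if (rater_correlation < 0 || rater_correlation > 1)
    stop("rater_correlation must lie in [0, 1]")
  structure(list(p_definite = p_definite, p_possible = p_possible,
                 rater_correlation = rater_correlation),
            class = "rating_model")
}

# Published per-syndrome clinician panel rates: fraction of images for which
# at least two of three clinicians would definitely have considered the
# diagnosis ((both + clinician-only) / n from the top-match concordance
# table).
panel_positive_rates <- function() {
  c("Williams" = 108 / 183, "Rubinstein-Taybi" = 96 / 155,
    "Floating Harbor" = 45 / 61, "Coffin Lowry" = 65 / 154,
    "Kabuki" = 154 / 195, "Smith Magenis" = 56 / 124,
    "PACS1" = 2 / 39, "Kleefstra" = 13 / 128,
    "Koolen-de Vries" = 61 / 120, "Cornelia de Lange" = 324 / 441)
}

# Invert q = P(Binomial(3, p) >= 2) = 3p^2 - 2p^3 for p in [0, 1].
solve_rater_p <- function(q) {
  vapply(q, function(qi) {
    if (qi <= 0) return(0)
    if (qi >= 1) return(1)
    uniroot(function(p) 3 * p^2 - 2 * p^3 - qi, c(0, 1),
            tol = 1e-12)$root
  }, numeric(1))
}

#' Default rating model matched to published recognition rates
#'
#' Per-cohort per-rater probabilities of a "definitely" score are back-solved
#' so that, under independent raters, the probability that at least two of
#' three raters score 1 equals the published per-syndrome clinician panel
#' rate.
#'
#' @param p_possible probability of score 3 (default 0.2).
#' @param rater_correlation latent correlation (default 0.5).
#' @return a [rating_model()] with named per-cohort `p_definite`.
#' @export
default_rating_model <- function(p_possible = 0.2,
                                 rater_correlation = 0.5) {
  p1 <- solve_rater_p(panel_positive_rates())
  names(p1) <- names(panel_positive_rates())
  rating_model(p_definite = p1,
               p_possible = setNames(pmin(p_possible, 1 - p1), names(p1)),
               rater_correlation = rater_correlation)
}

#' Generate clinician scores for the syndrome images of a facebase
#'
#' Controls are never scored (clinicians were not asked to rate control
#' images), so the rating table contains only syndrome images.
#'
#' @param fb a non-empty [facebase].
#' @param model a [rating_model()]; if `p_definite` is named, every syndrome
#'   cohort of `fb` must be present.
#' @param seed integer seed.
#' @return data.frame (`rating_table`) with columns `image_id`, `rater1`,
#'   `rater2`, `rater3`, scores in \{1, 2, 3\}.
#' @export
generate_clinician_scores <- function(fb, model, seed = 1L) {
  stopifnot(inherits(fb, "facebase"), inherits(model, "rating_model"))
  if (n_images(fb) == 0L) stop("facebase is empty")
  rec <- fb$records[fb$records$cohort != CONTROL_COHORT, , drop = FALSE]
  cohorts <- unique(rec$cohort)
  expand_prob <- function(p, what) {
    if (!is.null(names(p))) {
      absent <- setdiff(cohorts, names(p))
      if (length(absent))
        stop("rating model has no ", what, " for cohort(s): ",
             paste(absent, collapse = ", "))
      unname(p[rec$cohort])
    } else if (length(p) == 1L) rep(p, nrow(rec))
    else stop(what, " must be a scalar or a named per-cohort vector")
  }
  p1 <- expand_prob(model$p_definite, "p_definite")
  p3 <- expand_prob(model$p_possible, "p_possible")

  rho <- model$rater_correlation
  n <- nrow(rec)
  with_seed(seed, {
    z <- rnorm(n)                       # shared per-image recognisability
    scores <- matrix(2L, n, 3)
    for (r in 1:3) {
      u <- pnorm(sqrt(rho) * z + sqrt(1 - rho) * rnorm(n))
      s <- rep(2L, n)
      s[u < p1] <- 1L
      s[u > 1 - p3] <- 3L
      scores[, r] <- s
    }
    out <- data.frame(image_id = rec$image_id, rater1 = scores[, 1],
                      rater2 = scores[, 2], rater3 = scores[, 3],
                      stringsAsFactors = FALSE)
    class(out) <- c("rating_table", "data.frame")
    out
  })
}

#' Random latent parameters for sketch-face individuals
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @return n x 8 matrix of parameters in \[-1, 1\], one row per individual.
#' @export
random_individual_params <- function(n, seed = 1L) {
  with_seed(seed, matrix(runif(n * 8, -1, 1), nrow = n))
}

#' Render a parametric sketch face
#'
#' Draws a grayscale face sketch (head ellipse, two eyes, nose, mouth) whose
#' geometry is a deterministic function of the individual's latent parameter
#' vector; `age_scale` scales the whole geometry about the canvas centre, so
#' the same individual at different "ages" differs globally but not in
#' proportions. Seeded pixel noise emulates capture conditions.
#'
#' @param individual_params numeric vector of length 8 in \[-1, 1\]
#'   (a row of [random_individual_params()]).
#' @param age_scale global geometry scale (default 1).
#' @param noise_seed seed for the additive pixel noise.
#' @param size canvas side in pixels (>= 32).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @return `size` x `size` numeric matrix with values in \[0, 1\].
#' @export
generate_face_image <- function(individual_params, age_scale = 1,
                                noise_seed = 1L, size = 64L,
                                noise_sd = 0.02) {
  if (size < 32L) stop("canvas size must be >= 32")
  p <- as.numeric(individual_params)
  if (length(p) < 8) stop("individual_params must have length 8")
  g <- age_scale
  ax <- seq(-1, 1, length.out = size)
  X <- matrix(ax, size, size, byrow = TRUE)   # column coordinate
  Y <- matrix(ax, size, size)                 # row coordinate (top = -1)

  # amplitudes sized so identity differences survive a 20% age rescale
  # while the largest face (all params +1, age 1.2) stays inside the canvas
  head_a <- (0.60 + 0.12 * p[1]) * g          # head half-width
  head_b <- (0.72 + 0.09 * p[2]) * g          # head half-height
  eye_x  <- (0.26 + 0.09 * p[3]) * g
  eye_y  <- (-0.22 + 0.08 * p[4]) * g
  eye_r  <- (0.055 + 0.025 * p[5]) * g
  nose_l <- (0.18 + 0.08 * p[6]) * g
  mouth_w <- (0.18 + 0.09 * p[7]) * g
  mouth_t <- (0.035 + 0.018 * p[8]) * g

  img <- matrix(0.05, size, size)
  head <- (X / head_a)^2 + (Y / head_b)^2 <= 1
  img[head] <- 0.75
  eyes <- ((X - eye_x)^2 + (Y - eye_y)^2 <= eye_r^2) |
    ((X + eye_x)^2 + (Y - eye_y)^2 <= eye_r^2)
  img[eyes] <- 0.10
  nose <- abs(X) <= 0.02 * g & Y >= eye_y + 0.08 * g &
    Y <= eye_y + 0.08 * g + nose_l
  img[nose] <- 0.35
  mouth <- abs(X) <= mouth_w & abs(Y - 0.42 * g) <= mouth_t
  img[mouth] <- 0.20

  with_seed(noise_seed, {
    img <- img + matrix(rnorm(size * size, 0, noise_sd), size, size)
  })
  pmin(pmax(img, 0), 1)
}

#' Write a grayscale image as plain-text PGM (P2)
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param path output path.
#' @param maxval maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  v <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(v, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#'
#' @param path PGM file path.
#' @return numeric matrix with values in \[0, 1\].
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("not a plain (P2) PGM file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}
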