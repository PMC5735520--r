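---
title: "Evaluating face-matching for syndromic intellectual disability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating face-matching for syndromic intellectual disability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facematchr)
```

## Scope and design

`facematchr` evaluates whether a face matcher retrieves images of
unrelated individuals with the same syndromic diagnosis better than
chance, and how its calls compare with clinical geneticists' recognition
of the same faces. The proprietary matcher and the original photographs
behind the published evaluation cannot be redistributed, so the package
separates three concerns:

1. **exact statistics** (null model, goodness-of-fit, concordance) that
   recompute the published summary tables from their printed inputs;
2. **a reusable leave-one-out retrieval engine** over any labelled
   embedding database; and
3. **synthetic generators** that emulate the statistical structure the
   evaluation assumes, so the whole pipeline is testable end to end.

## The facebase and the leave-one-out protocol

A *facebase* is an ordered collection of image records — image id,
individual id, cohort (one of ten syndrome names or `CONTROL`), entry
stage — optionally paired with one unit-norm embedding row per record.
The reference layout (`reference_cohorts()`) reproduces the published
database composition: 1600 syndrome images across ten cohorts plus 2081
controls, growing over three analysis stages (3145, 3432 and 3681 images);
Cornelia de Lange contributes 192 images from the start but is analysed
only at stage 3 after a further 249 arrive, which the generator encodes by
record-level entry stages.

Each syndrome image in turn is the test case. All images of the *same
individual* (including the test image) are removed from the candidate
pool — some individuals appear at several ages, and a face must never
"match" itself — and the remainder are ranked by cosine similarity,
descending, with ties broken by ascending image id so runs are
deterministic. A top-k success is at least one same-cohort candidate among
the first k (k = 1, 5, 10 by default). Controls are candidates but never
test cases. Same-individual removal applies only while that individual is
the test case; the images return to the pool for every other test case
(the protocol description supports either reading; this one keeps the
candidate pool maximal and identical for all other test images).

## The random-ranking null

If a test image has `M` candidates of which `m` are same-syndrome, and
the matcher carried no signal, the top k would be a uniform size-k subset
of the candidates, so

\[ P(\text{top-}k\ \text{hit}) \;=\; 1 - \binom{M-m}{k}\Big/\binom{M}{k}, \]

computed in log space (`lchoose`) for stability at database scale; at
`k = 1` this is `m/M`. Summing over a cohort's test images — with `m` and
`M` adjusted per image for its own same-individual exclusions — gives the
expected match count. The published expected counts were obtained by
simulation; the hypergeometric tail is that simulation's exact
expectation, and under the duplicate-free stage-1 layout (N = 3145,
n = 183) it reproduces the published Williams expectations 11, 47 and 82
at k = 1, 5, 10 exactly after rounding. Some other published expected
counts (e.g. Rubinstein-Taybi top-1, printed 7 vs closed form ≈ 7.6)
imply duplicate structure that cannot be recovered without the original
manifest; the package does not guess it, and its tests assert only the
reproducible Williams row plus exact recomputation of the printed
chi-squares from the printed integer expectations.

`simulate_expected_counts()` retains the simulation route. Its default
method draws the number of same-syndrome images in the random top-k from
the hypergeometric distribution (`rhyper`), which is distributionally
identical to permuting the ranking but orders of magnitude faster; the
literal permutation (`method = "ranking"`) is kept as a cross-check and
both are verified against the closed form to within three Monte-Carlo
standard errors.

## Goodness-of-fit and concordance

Observed vs expected (match, no-match) pairs are compared with the
Yates-corrected chi-square on 1 df,
`X² = Σ (max(|O−E| − 0.5, 0))² / E`, the correction clamped so `O = E`
gives exactly 0; p-values come from the closed form
`p = erfc(√(x/2))`, tested against `pchisq` as an independent route.
Expected counts enter in two modes: `"exact"` (real-valued, the default —
always defined) and `"rounded"` (integer expectations, mirroring the
published arithmetic, which recomputes all 30 printed statistics to 2 dp;
note a rounded expectation of 0 makes the statistic undefined, as happens
for very small cohorts at k = 1).

For concordance, each image's clinician panel call is "at least two of
three raters scored 1" or "all three scored 1". "Definitely would have
considered" is read as score exactly 1 for both rules, symmetric with the
published two-of-three wording; counting score 3 ("possibly") as a vote is
available behind `definite_scores = c(1, 3)` because the supplementary
captions drop "definitely". The software call at cutoff k is the top-k
retrieval flag. Pairing the two calls gives the 2×2 cells (neither / both
/ software-only / clinician-only); McNemar's statistic `(b−c)²/(b+c)` is
used *without* continuity correction — forced by the printed values
(b = 4, c = 0 prints 4.00; with correction it would be 2.25) — and is
reported as undefined (rendered ".") when `b + c = 0`. Cohen's kappa uses
the standard marginal-product chance agreement; when a degenerate marginal
forces `p_e = 1`, observed agreement is necessarily perfect as well and
kappa is reported as 0, matching the published convention for the
degenerate Rubinstein-Taybi top-10 row. One published row is internally
inconsistent (that same row has `b + c = 59` yet prints its McNemar as not
calculable): the fixtures store the printed cells verbatim and
`verify_paper()` computes 59.00 and flags the discrepancy rather than
hiding either value. Another printed row's cells total 153 where the
cohort has 154 images; the fixture again stores the printed cells.

## The synthetic generators: what they emulate

`generate_embedding_facebase()` draws embeddings from a three-level
Gaussian hierarchy on the sphere: syndrome prototype
`μ_s ~ N(0, σ_b² I)`, individual centre `c_i ~ N(μ_s, σ_w² I)`, image
`x ~ N(c_i, σ_e² I)`, all rows L2-normalised. Controls are heterogeneous
unaffected faces, drawn from the zero-centred mixture marginal with total
variance `σ_b² + σ_w² + σ_e²` rather than forming their own cluster. A
configurable fraction of syndrome individuals (default 5%, a value chosen
once as plausible for a literature-curated collection; the true count is
unpublished) contributes 2–3 images with dotted ids, exercising the
same-individual exclusion.

Parameters that matter:

* `d` (default 64): embedding dimension; dimensionless. High enough that
  random cosines concentrate near 0, small enough to be fast.
* `σ_b, σ_w, σ_e` (defaults 1, 0.6, 0.3): between-syndrome,
  between-individual and within-individual scales, in embedding-space
  units. The defaults were fixed once to give a moderately separable
  world — clear syndrome structure with visible errors — and are *not*
  calibrated to reproduce any published accuracy; with `σ_b = 0` the
  generator provably carries no cohort signal (every syndrome and control
  image is exchangeable), which is the basis of the calibration test.

With no signal the per-cohort observed top-k count is exactly
Binomial(n, p_k) under the duplicate-free layout, so the acceptance
calibration run checks that observed counts sit inside the 99% binomial
envelope of the analytic expectation in ≥ 95% of 100 seeded signal-free
facebases (observed coverage ≈ 0.97). The strong-signal run
(`σ_b/σ_w = 10`) recovers ≥ 90% top-1 retrieval with all goodness-of-fit
p-values far below 0.001 — the qualitative regime of the original study.
A green calibration or recovery test establishes that the *pipeline
arithmetic* is correct under its stated model; it says nothing about real
photographs, pose, illumination, ethnicity or age structure, none of which
the generator models.

Clinician scores are generated per cohort with probability `p_definite`
of score 1 and `p_possible` of score 3 per rater. The default model
back-solves the per-rater `p_definite` (by inverting
`q = 3p² − 2p³` on [0, 1]) so that the independent-rater two-of-three
panel rate equals the published per-syndrome clinician recognition rate —
e.g. high for Kabuki (clinicians know its gestalt well), very low for
PACS1. Rater agreement beyond chance comes from a per-image latent
"recognisability" draw shared across raters (Gaussian copula, correlation
0.5 by default), which leaves per-rater marginals exact; under
independent raters the panel rate would match exactly, and the copula
shifts it only mildly. Controls are never scored, matching the original
protocol.

## The baseline descriptor

The published matcher's feature set is proprietary ("low-resolution
structural and frequency domain" features); the package provides an
explicitly modest stand-in: crop to content, resize to 64×64 bilinearly,
histogram-equalise, 2-D orthonormal DCT, keep the top-left 8×8
low-frequency block, drop the DC coefficient, L2-normalise (63
dimensions). Dropping DC makes it exactly invariant to uniform brightness
shifts; a constant image has no non-DC energy and is rejected as
"featureless" rather than silently normalised. The crop-to-content step
(bounding box of above-midrange pixels) was a deliberate addition to the
minimal DCT pipeline: without it a global scale change — the sketch
generator's model of age — dominates identity, and the same individual at
age scales 1.0 vs 1.2 fails to beat other individuals for a large
minority of cases; with it, all fixture individuals pass. The midrange
threshold shifts with the image, so brightness invariance is preserved
exactly. No claim of pose, expression or occlusion invariance is made or
tested — those belong to the proprietary matcher, not this baseline.

Sketch faces themselves are parametric: head ellipse, two eyes, nose and
mouth, with geometry a deterministic function of an 8-vector of latent
individual parameters, a global `age_scale`, and seeded pixel noise.
Amplitudes were sized once so that identity differences survive both the
capture noise and a 20% age rescale while the extreme face stays inside
the canvas.

## Numerical choices and degenerate inputs

* Hypergeometric tails via `-expm1(lchoose(M−m,k) − lchoose(M,k))`:
  stable for N in the thousands; `k > M − m` naturally yields 1.
* Similarity ties broken by ascending image id (radix order, C locale):
  the original protocol is silent, determinism wins.
* Expected-count rounding uses `round()` (banker's at .5 — never hit by
  the published values).
* p-values render as "<.00001" below 1e-5 and "." when undefined,
  matching the published display.
* Embedding rows are renormalised on load rather than rejected, tolerating
  serialisation rounding; zero rows are an error.
* `k` larger than the candidate pool evaluates over the available
  candidates with a warning (only reachable on tiny toy databases).
* All randomness flows through per-call seeds via an RNG-state-preserving
  wrapper, so library calls never perturb the caller's random stream, and
  rerunning a pipeline config writes byte-identical reports.

## Known limitations

* The synthetic embedding space is an isotropic Gaussian mixture; real
  face-embedding manifolds are anisotropic and syndrome clusters overlap
  unevenly. Absolute synthetic accuracies are therefore not comparable to
  published ones — only the statistical machinery is.
* The published observed match counts depend on the proprietary matcher
  and the original photographs and are deliberately out of reach; the
  package verifies the published *statistics* from the published *inputs*
  instead.
* The duplicate structure of the original database is unpublished, so
  expected counts for cohorts with many repeat individuals cannot be
  reproduced exactly (flagged, not guessed).
* The number of times a syndrome appears within the top 10 (beyond
  presence/absence) is not used, mirroring the original analysis.
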