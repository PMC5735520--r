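#' Construct a facebase
#'
#' A facebase is the labelled database of face images over which the
#' leave-one-out matching evaluation runs: one record per image, carrying the
#' individual's identity, a cohort label (a syndrome name or `"CONTROL"`) and
#' the analysis stage at which the image entered the database. Multiple images
#' of the same individual (e.g. at different ages) are distinct records
#' sharing `individual_id`.
#'
#' @param records data.frame with columns `image_id`, `individual_id`,
#'   `cohort`, and optionally `stage` (defaults to 1) and `image_path`.
#' @param embeddings optional numeric matrix with one row per record, in
#'   record order (or with rownames matching `image_id`). Rows are
#'   renormalised to unit L2 norm on construction; exact unit norm is not
#'   required of the input, but zero rows are an error.
#' @return an object of class `facebase`: a list with elements `records`
#'   (validated data.frame) and `embeddings` (unit-row-norm matrix or NULL).
#' @details Invariants enforced: `image_id` unique; each `individual_id`
#'   belongs to exactly one cohort; embedding row count equals record count.
#' @examples
#' rec <- data.frame(image_id = c("a1", "a2", "c1"),
#'                   individual_id = c("a", "a", "c"),
#'                   cohort = c("W", "W", "CONTROL"))
#' fb <- facebase(rec)
#' cohort_sizes(fb)
#' @export
facebase <- function(records, embeddings = NULL) {
  if (!is.data.frame(records))
    stop("`records` must be a data.frame")
  required <- c("image_id", "individual_id", "cohort")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  records$image_id <- as.character(records$image_id)
  records$individual_id <- as.character(records$individual_id)
  records$cohort <- as.character(records$cohort)
  if (!"stage" %in% names(records)) records$stage <- rep(1L, nrow(records))
  records$stage <- as.integer(records$stage)
  if (!"image_path" %in% names(records))
    records$image_path <- rep(NA_character_, nrow(records))
  records$image_path <- as.character(records$image_path)
  records$image_path[!is.na(records$image_path) &
                       records$image_path == ""] <- NA_character_
  records <- records[, c("image_id", "individual_id", "cohort", "stage",
                         "image_path")]
  rownames(records) <- NULL

  if (anyNA(records$image_id) || anyNA(records$individual_id) ||
      anyNA(records$cohort))
    stop("image_id, individual_id and cohort must not contain NA")
  dup <- records$image_id[duplicated(records$image_id)]
  if (length(dup))
    stop("duplicate image_id in manifest: ",
         paste(unique(dup), collapse = ", "))
  tab <- unique(records[, c("individual_id", "cohort")])
  bad <- tab$individual_id[duplicated(tab$individual_id)]
  if (length(bad))
    stop("individual_id appears under more than one cohort: ",
         paste(unique(bad), collapse = ", "))
  if (anyNA(records$stage) || any(records$stage < 1L))
    stop("stage must be a positive integer")

  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    storage.mode(embeddings) <- "double"
    if (nrow(embeddings) != nrow(records))
      stop("embedding row count (", nrow(embeddings),
           ") does not match record count (", nrow(records), ")")
    if (!is.null(rownames(embeddings))) {
      if (!setequal(rownames(embeddings), records$image_id))
        stop("embedding rownames do not match manifest image_ids")
      embeddings <- embeddings[records$image_id, , drop = FALSE]
    }
    norms <- sqrt(rowSums(embeddings^2))
    if (any(norms < 1e-12))
      stop("embedding row(s) with zero norm: ",
           paste(records$image_id[norms < 1e-12], collapse = ", "))
    embeddings <- embeddings / norms
    rownames(embeddings) <- records$image_id
  }
  structure(list(records = records, embeddings = embeddings),
            class = "facebase")
}

#' @export
print.facebase <- function(x, ...) {
  n <- nrow(x$records)
  syn <- setdiff(unique(x$records$cohort), CONTROL_COHORT)
  cat("facebase: ", n, " images, ",
      length(unique(x$records$individual_id)), " individuals, ",
      length(syn), " syndrome cohort(s), ",
      sum(x$records$cohort == CONTROL_COHORT), " controls\n", sep = "")
  if (is.null(x$embeddings)) cat("embeddings: none\n")
  else cat("embeddings: ", ncol(x$embeddings), "-dimensional, unit norm\n",
           sep = "")
  invisible(x)
}

#' Number of images in a facebase
#' @param fb a [facebase].
#' @return integer count N.
#' @export
n_images <- function(fb) nrow(fb$records)

#' Syndrome cohort names present in a facebase
#' @param fb a [facebase].
#' @return character vector of cohort names, excluding `"CONTROL"`, in order
#'   of first appearance.
#' @export
syndrome_cohorts <- function(fb) {
  setdiff(unique(fb$records$cohort), CONTROL_COHORT)
}

#' Per-cohort image and individual counts
#'
#' @param fb a [facebase].
#' @return data.frame with one row per cohort (including `"CONTROL"` if
#'   present, in order of first appearance) and columns `cohort`, `n_images`,
#'   `n_individuals`. Image counts sum to `n_images(fb)`.
#' @export
cohort_sizes <- function(fb) {
  rec <- fb$records
  cohorts <- unique(rec$cohort)
  out <- data.frame(
    cohort = cohorts,
    n_images = vapply(cohorts, function(co) sum(rec$cohort == co),
                      integer(1)),
    n_individuals = vapply(cohorts, function(co)
      length(unique(rec$individual_id[rec$cohort == co])), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Restrict a facebase to the database composition of one analysis stage
#'
#' Keeps the records (and embedding rows) whose entry stage is at most
#' `stage`, reproducing the staged growth of the database.
#'
#' @param fb a [facebase].
#' @param stage integer analysis stage.
#' @return a [facebase] with the subset of records.
#' @export
stage_facebase <- function(fb, stage) {
  keep <- fb$records$stage <= as.integer(stage)
  emb <- if (is.null(fb$embeddings)) NULL else
    fb$embeddings[keep, , drop = FALSE]
  facebase(fb$records[keep, , drop = FALSE], emb)
}

#' Analysis stage of a cohort
#'
#' The stage at which a cohort is analysed is the latest entry stage among its
#' images (a cohort whose images finish arriving at stage 3 is analysed
#' against the stage-3 database).
#'
#' @param fb a [facebase].
#' @param cohort cohort name.
#' @return integer stage.
#' @export
analysis_stage <- function(fb, cohort) {
  idx <- fb$records$cohort == cohort
  if (!any(idx)) stop("unknown cohort: ", cohort)
  max(fb$records$stage[idx])
}

#' Load a facebase from a CSV manifest
#'
#' The manifest is a UTF-8 CSV with header
#' `image_id,individual_id,cohort,stage,image_path` (`stage` and `image_path`
#' optional). The embedding file, if given, is a CSV whose first column is
#' `image_id` and remaining columns are the embedding coordinates; rows are
#' matched to the manifest by id and renormalised to unit length.
#'
#' @param path manifest CSV path.
#' @param embeddings_path optional embedding CSV path.
#' @return a validated [facebase].
#' @export
load_manifest <- function(path, embeddings_path = NULL) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  rec <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  required <- c("image_id", "individual_id", "cohort")
  if (!all(required %in% names(rec)))
    stop("manifest header must contain: ", paste(required, collapse = ", "))
  emb <- NULL
  if (!is.null(embeddings_path)) {
    if (!file.exists(embeddings_path))
      stop("embedding file not found: ", embeddings_path)
    etab <- read.csv(embeddings_path, stringsAsFactors = FALSE,
                     check.names = FALSE)
    if (names(etab)[1] != "image_id")
      stop("embedding file must have image_id as its first column")
    emb <- as.matrix(etab[, -1, drop = FALSE])
    rownames(emb) <- as.character(etab$image_id)
  }
  facebase(rec, emb)
}

#' Write a facebase to a CSV manifest (and optional embedding CSV)
#'
#' Inverse of [load_manifest()]: record fields round-trip bit-identically.
#'
#' @param fb a [facebase].
#' @param path manifest CSV path to write.
#' @param embeddings_path optional embedding CSV path to write.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fb, path, embeddings_path = NULL) {
  write.csv(fb$records, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(embeddings_path)) {
    if (is.null(fb$embeddings)) stop("facebase has no embeddings to write")
    etab <- data.frame(image_id = fb$records$image_id,
                       fb$embeddings, check.names = FALSE,
                       stringsAsFactors = FALSE)
    colnames(etab) <- c("image_id", paste0("e", seq_len(ncol(fb$embeddings))))
    write.csv(etab, embeddings_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
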