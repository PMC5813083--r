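#' Write / read epochs in the package's array container
#'
#' Epochs are stored as an Arrow Feather (IPC) file: one row per
#' `(trial, sample)` with a float64 column per ROI, plus `fs`, `t0` and
#' `roi_labels` carried in the file metadata. Feather stores IEEE doubles
#' natively, so the round-trip is bit-exact and the files are readable from
#' other languages.
#'
#' @param epochs An [epoch_set()].
#' @param path Output file path (conventionally `.feather`).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   an [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  df <- tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1])
  )
  for (k in seq_len(d[2])) {
    df[[paste0("roi", k)]] <- as.vector(epochs$data[, k, ])
  }
  attr(df, "fs") <- epochs$fs
  attr(df, "t0") <- epochs$t0
  attr(df, "roi_labels") <- epochs$roi_labels
  attr(df, "n_trials") <- d[1]
  attr(df, "n_samples") <- d[3]
  arrow::write_feather(df, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(arrow::read_feather(path))
  for (field in c("fs", "t0", "roi_labels", "n_trials", "n_samples")) {
    if (is.null(attr(df, field))) {
      stop(sprintf("epoch file '%s' is missing metadata field '%s'.",
                   path, field), call. = FALSE)
    }
  }
  nt <- attr(df, "n_trials")
  ns <- attr(df, "n_samples")
  labs <- attr(df, "roi_labels")
  r <- length(labs)
  if (nrow(df) != nt * ns || !all(paste0("roi", seq_len(r)) %in% names(df))) {
    stop(sprintf("epoch file '%s' has an inconsistent layout.", path),
         call. = FALSE)
  }
  if (nt < 1) stop("epoch file has zero trials.", call. = FALSE)
  data <- array(0, dim = c(nt, r, ns))
  for (k in seq_len(r)) {
    data[, k, ] <- matrix(df[[paste0("roi", k)]], nrow = nt)
  }
  epoch_set(data, labs, fs = attr(df, "fs"), t0 = attr(df, "t0"))
}

#' Write / read behavioral report counts (TSV)
#'
#' Tab-separated table with header `subject, RE, LE, ERR, total`. On read,
#' the count invariant `RE + LE + ERR = total` (and non-negativity) is
#' enforced per row, naming the offending subject.
#'
#' @param behavior Tibble with columns `subject`, `RE`, `LE`, `ERR`,
#'   `total`.
#' @param path File path.
#' @return `write_behavior` returns `path` invisibly; `read_behavior`
#'   returns the validated tibble.
#' @export
write_behavior <- function(behavior, path) {
  req <- c("subject", "RE", "LE", "ERR", "total")
  stopifnot(is.data.frame(behavior), all(req %in% names(behavior)))
  readr::write_tsv(behavior[req], path)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_character(), RE = readr::col_double(),
    LE = readr::col_double(), ERR = readr::col_double(),
    total = readr::col_double()
  ))
  req <- c("subject", "RE", "LE", "ERR", "total")
  if (!all(req %in% names(df))) {
    stop("behavior file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("behavior file is empty.", call. = FALSE)
  bad_sum <- which(df$RE + df$LE + df$ERR != df$total)
  if (length(bad_sum) > 0) {
    stop("RE + LE + ERR != total for subject(s): ",
         paste(df$subject[bad_sum], collapse = ", "), call. = FALSE)
  }
  if (any(df$RE < 0 | df$LE < 0 | df$ERR < 0)) {
    stop("negative report counts in behavior file.", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write / read a study manifest (JSON)
#'
#' The manifest lists each subject's per-condition epoch file (paths
#' relative to the manifest) and the behavior TSV.
#'
#' @param manifest Tibble with columns `subject`, `condition`, `path`.
#' @param behavior_path Path of the behavior TSV, relative to the manifest.
#' @param path Manifest file path.
#' @return `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, behavior_path, path) {
  stopifnot(all(c("subject", "condition", "path") %in% names(manifest)))
  subjects <- lapply(split(manifest, manifest$subject), function(d) {
    list(id = d$subject[1],
         epochs = stats::setNames(as.list(d$path), d$condition))
  })
  obj <- list(schema_version = 1L, behavior = behavior_path,
              subjects = unname(subjects))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a study from a manifest
#'
#' Reads a manifest JSON, validates that every referenced file exists and
#' that subject ids are unique, and returns a `study_data` object whose
#' epochs are loaded lazily from disk by [run_study()].
#'
#' @param path Path to a manifest JSON written by [write_manifest()] or
#'   [simulate_study()].
#' @return A `study_data` object.
#' @export
read_study <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$subjects) || length(obj$subjects) == 0) {
    stop("manifest has no subjects.", call. = FALSE)
  }
  root <- dirname(path)
  ids <- vapply(obj$subjects, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids in manifest.", call. = FALSE)
  }
  manifest <- purrr::map_dfr(obj$subjects, function(s) {
    tibble::tibble(subject = s$id, condition = names(s$epochs),
                   path = unlist(s$epochs, use.names = FALSE))
  })
  missing <- manifest$path[!file.exists(file.path(root, manifest$path))]
  if (length(missing) > 0) {
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  behavior <- NULL
  if (!is.null(obj$behavior)) {
    bp <- file.path(root, obj$behavior)
    if (!file.exists(bp)) {
      stop("manifest references missing behavior file: ", obj$behavior,
           call. = FALSE)
    }
    behavior <- read_behavior(bp)
  }
  structure(
    list(epochs = NULL, behavior = behavior, manifest = manifest,
         config = NULL, seed = NA_integer_, root = root),
    class = "study_data"
  )
}

#' Export study tables
#'
#' Writes the group statistics as JSON and the per-subject band-averaged
#' scalars as a TSV with columns `subject`, `condition`, `source_roi`,
#' `target_roi`, `measure`, `value`.
#'
#' @param result A `study_result` from [run_study()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_study_result <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sr <- result$subject_results
  readr::write_tsv(
    tibble::tibble(subject = sr$subject, condition = sr$condition,
                   source_roi = sr$source, target_roi = sr$target,
                   measure = sr$measure, value = sr$value),
    file.path(dir, "subject_connectivity.tsv")
  )
  stats_obj <- list(
    log = result$log,
    laterality = if (is.null(result$laterality)) NULL else list(
      summary = result$laterality$summary,
      rea_test = result$laterality$rea_test
    ),
    lps_tests = result$lps_tests,
    anova = result$anova,
    posthoc = result$posthoc
  )
  jsonlite::write_json(stats_obj, file.path(dir, "study_result.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(dir)
}
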