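#' Read a study CSV with schema validation
#'
#' All study tables are UTF-8 comma-separated files with a mandatory header;
#' CRLF line endings and a UTF-8 byte-order mark are tolerated.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @keywords internal
read_study_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Load and validate a study bundle
#'
#' Assembles the manifest and whichever response tables are supplied, and
#' enforces referential integrity: every response row refers to a manifest
#' image, no duplicated (subject, image) observations, and every subject is
#' confined to a single batch.
#'
#' @param manifest Manifest data frame or CSV path (`image_id`, `category`,
#'   `batch_id`).
#' @param grouping Grouping responses (`subject_id`, `batch_id`, `image_id`,
#'   `group_id`), data frame or path; optional.
#' @param labels Labeling responses (`subject_id`, `batch_id`, `image_id`,
#'   `label_text`); optional.
#' @param classification Forced-choice responses (`subject_id`, `batch_id`,
#'   `image_id`, `chosen_label`); optional.
#' @param predictions Classifier predictions (`model`, `image_id`,
#'   `predicted_label`); optional.
#' @param crt Optional [crt_transform()] or crt.json path.
#' @return A validated `study_bundle` list.
#' @export
load_bundle <- function(manifest, grouping = NULL, labels = NULL,
                        classification = NULL, predictions = NULL,
                        crt = NULL) {
  as_table <- function(x, required) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) x <- read_study_csv(x, required)
    missing <- setdiff(required, names(x))
    if (length(missing)) {
      stop("missing required columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x
  }
  manifest <- as_table(manifest, c("image_id", "category", "batch_id"))
  if (anyDuplicated(manifest$image_id)) {
    stop("manifest has duplicated image ids", call. = FALSE)
  }
  grouping <- as_table(grouping,
                       c("subject_id", "batch_id", "image_id", "group_id"))
  labels <- as_table(labels,
                     c("subject_id", "batch_id", "image_id", "label_text"))
  classification <- as_table(
    classification, c("subject_id", "batch_id", "image_id", "chosen_label"))
  predictions <- as_table(predictions,
                          c("model", "image_id", "predicted_label"))
  if (is.character(crt)) crt <- load_crt(crt)

  check_responses <- function(df, what) {
    if (is.null(df)) return(invisible())
    stray <- setdiff(df$image_id, manifest$image_id)
    if (length(stray)) {
      stop(sprintf("%s: image ids absent from manifest: %s", what,
                   paste(utils::head(stray, 5L), collapse = ", ")),
           call. = FALSE)
    }
    dup <- duplicated(df[, c("subject_id", "image_id")])
    if (any(dup)) {
      stop(sprintf("%s: duplicated (subject, image) rows, e.g. row %d",
                   what, which(dup)[[1L]]), call. = FALSE)
    }
    nb <- tapply(df$batch_id, df$subject_id, function(b) length(unique(b)))
    if (any(nb > 1)) {
      stop(sprintf("%s: subjects appear in multiple batches: %s", what,
                   paste(names(nb)[nb > 1], collapse = ", ")),
           call. = FALSE)
    }
    mb <- stats::setNames(manifest$batch_id, manifest$image_id)
    bad <- df$batch_id != mb[df$image_id]
    if (any(bad)) {
      stop(sprintf("%s: batch_id disagrees with manifest at row %d", what,
                   which(bad)[[1L]]), call. = FALSE)
    }
    invisible()
  }
  check_responses(grouping, "grouping")
  check_responses(labels, "labels")
  check_responses(classification, "classification")
  if (!is.null(predictions)) {
    stray <- setdiff(predictions$image_id, manifest$image_id)
    if (length(stray)) {
      stop("predictions: image ids absent from manifest: ",
           paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(manifest = manifest, grouping = grouping, labels = labels,
                 classification = classification, predictions = predictions,
                 crt = crt),
            class = "study_bundle")
}

#' Wide response matrices from long response tables
#'
#' `grouping_matrix()` pivots grouping responses to an images x subjects
#' character matrix of group ids (`NA` where a subject did not see an
#' image); group ids are made globally unique by prefixing the subject id if
#' the same id string appears under two subjects. `label_matrix()` does the
#' same for raw label text.
#'
#' @param responses Long data frame (`subject_id`, `image_id`, plus
#'   `group_id` or `label_text`).
#' @param manifest Manifest data frame; fixes the row order.
#' @return Character matrix, rownames = image ids, colnames = subject ids.
#' @export
grouping_matrix <- function(responses, manifest) {
  pivot_responses(responses, manifest, "group_id", uniquify = TRUE)
}

#' @rdname grouping_matrix
#' @export
label_matrix <- function(responses, manifest) {
  pivot_responses(responses, manifest, "label_text", uniquify = FALSE)
}

pivot_responses <- function(responses, manifest, value_col, uniquify) {
  stopifnot(all(c("subject_id", "image_id", value_col) %in% names(responses)))
  val <- as.character(responses[[value_col]])
  if (uniquify) {
    # group ids must be globally unique across subjects
    by_gid <- tapply(responses$subject_id, val,
                     function(s) length(unique(s)))
    shared <- names(by_gid)[by_gid > 1]
    if (length(shared)) {
      hit <- val %in% shared
      val[hit] <- paste(responses$subject_id[hit], val[hit], sep = "::")
    }
  }
  imgs <- manifest$image_id
  subs <- sort(unique(responses$subject_id))
  M <- matrix(NA_character_, length(imgs), length(subs),
              dimnames = list(imgs, subs))
  M[cbind(match(responses$image_id, imgs),
          match(responses$subject_id, subs))] <- val
  M
}

#' Serialize / deserialize a transform as JSON
#'
#' The JSON carries the new categories (name, image ids, source
#' frequencies), the prediction map, the unknown sentinel, the provenance
#' block and a format version. Loading re-validates the partition; a version
#' mismatch loads best-effort with a warning.
#'
#' @param crt A [crt_transform()].
#' @param path Output / input file path.
#' @return `load_crt()` returns the [crt_transform()]; `save_crt()` returns
#'   `path` invisibly.
#' @export
save_crt <- function(crt, path) {
  stopifnot(inherits(crt, "crt_transform"))
  payload <- list(
    format_version = crt_format_version(),
    unknown_label = crt$unknown_label,
    new_categories = lapply(crt$new_categories, function(nc) {
      list(name = nc$name, image_ids = as.list(nc$image_ids),
           sources = as.list(nc$sources))
    }),
    prediction_map = as.list(crt$prediction_map),
    provenance = crt$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_crt
#' @export
load_crt <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- payload$format_version
  if (is.null(ver) || !identical(ver, crt_format_version())) {
    warning(sprintf(
      "crt format version %s differs from %s; loading best-effort",
      if (is.null(ver)) "<absent>" else ver, crt_format_version()),
      call. = FALSE)
  }
  new_categories <- lapply(payload$new_categories, function(nc) {
    list(name = nc$name,
         image_ids = vapply(nc$image_ids, as.character, character(1)),
         sources = vapply(nc$sources, as.numeric, numeric(1)))
  })
  pred_map <- unlist(payload$prediction_map)
  crt_transform(new_categories, pred_map,
                unknown_label = payload$unknown_label %||% unknown_sentinel(),
                provenance = payload$provenance %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

crt_format_version <- function() "1.0"

#' Write a synthetic study to a directory of CSVs
#'
#' Emits `manifest.csv`, `responses_grouping.csv`, `responses_labels.csv`,
#' `responses_classification.csv`, `predictions.csv` and
#' `ground_truth.json` (the planted transform).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  }
  w(study$manifest, "manifest.csv")
  w(study$grouping, "responses_grouping.csv")
  w(study$labels, "responses_labels.csv")
  w(study$classification, "responses_classification.csv")
  w(study$predictions, "predictions.csv")
  save_crt(study$ground_truth$crt, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a directory written by [write_study()] back into a bundle
#'
#' @param dir Directory containing the study CSVs.
#' @return A [load_bundle()] result (with the planted transform attached
#'   when `ground_truth.json` is present).
#' @export
read_study <- function(dir) {
  gt <- file.path(dir, "ground_truth.json")
  load_bundle(manifest = file.path(dir, "manifest.csv"),
              grouping = file.path(dir, "responses_grouping.csv"),
              labels = file.path(dir, "responses_labels.csv"),
              classification = file.path(dir, "responses_classification.csv"),
              predictions = file.path(dir, "predictions.csv"),
              crt = if (file.exists(gt)) gt)
}
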