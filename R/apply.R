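#' Translate true labels through a transform, image by image
#'
#' The true label of an image after the transform is the name of the new
#' category that contains the image. Separations are image-level: the same
#' original category can send different images to different new categories,
#' which is why the mapping keys on the image, not the label.
#'
#' @param image_id Character vector of image ids.
#' @param crt A [crt_transform()].
#' @return Character vector of new-category names.
#' @export
transform_truth <- function(image_id, crt) {
  stopifnot(inherits(crt, "crt_transform"))
  map <- crt_image_map(crt)
  missing <- setdiff(unique(image_id), names(map))
  if (length(missing)) {
    stop("images absent from the transform: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  unname(map[as.character(image_id)])
}

#' Translate predicted labels through a transform
#'
#' A predicted label inside the study's category subset follows the
#' prediction map (its category's dominant new category); any label outside
#' the subset — typically a classifier trained on the full original label
#' space answering off-subset — maps to the unknown sentinel. The sentinel
#' itself is a fixed point.
#'
#' @param label Character vector of predicted labels.
#' @param crt A [crt_transform()].
#' @return Character vector of new-category names or the unknown sentinel.
#' @export
transform_prediction <- function(label, crt) {
  stopifnot(inherits(crt, "crt_transform"))
  label <- as.character(label)
  out <- crt$prediction_map[label]
  out[is.na(out)] <- crt$unknown_label
  out[label == crt$unknown_label] <- crt$unknown_label
  unname(out)
}

#' Tabulate classification records into a confusion matrix
#'
#' @param records Data frame with columns `image_id`, `true_label`,
#'   `predicted_label`.
#' @param labels Optional ordered label set; defaults to the sorted union of
#'   observed labels. Predicted labels outside the declared set are routed to
#'   an `"unknown"` column with a warning.
#' @return A `confusion_matrix` object: `labels` plus a square `counts`
#'   matrix (rows = true, columns = predicted).
#' @export
confusion_matrix <- function(records, labels = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("true_label", "predicted_label") %in% names(records)))
  truth <- as.character(records$true_label)
  pred <- as.character(records$predicted_label)
  if (is.null(labels)) {
    labels <- sort(unique(c(truth, pred)))
  } else {
    stray <- setdiff(unique(pred), labels)
    if (length(stray)) {
      warning("predicted labels outside the declared set routed to ",
              "\"unknown\": ", paste(stray, collapse = ", "), call. = FALSE)
      if (!("unknown" %in% labels)) labels <- c(labels, "unknown")
      pred[pred %in% stray] <- "unknown"
    }
    if (!all(truth %in% labels)) {
      stop("true labels outside the declared label set", call. = FALSE)
    }
  }
  f <- function(x) factor(x, levels = labels)
  counts <- unclass(table(f(truth), f(pred)))
  dimnames(counts) <- list(labels, labels)
  structure(list(labels = labels, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix over %d labels, %d records\n",
              length(x$labels), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Transform classification records and tabulate the new confusion matrix
#'
#' Applies [transform_truth()] to true labels and [transform_prediction()]
#' to predicted labels, then tabulates. The operation works on per-image
#' records, never on a pre-aggregated matrix: separations assign images of
#' one original category to different new categories, information an
#' aggregated matrix no longer carries.
#'
#' @inheritParams confusion_matrix
#' @param crt A [crt_transform()].
#' @return A `confusion_matrix` over the new category names (plus the
#'   unknown sentinel when predicted).
#' @export
transform_cfm <- function(records, crt) {
  stopifnot(all(c("image_id", "true_label", "predicted_label") %in%
                  names(records)))
  new_truth <- transform_truth(records$image_id, crt)
  new_pred <- transform_prediction(records$predicted_label, crt)
  labels <- sort(unique(c(new_truth, new_pred)))
  confusion_matrix(
    data.frame(image_id = records$image_id, true_label = new_truth,
               predicted_label = new_pred, stringsAsFactors = FALSE),
    labels = labels)
}

#' Top-1 accuracy and macro precision/recall/F1 from a confusion matrix
#'
#' Top-1 accuracy is trace over total. Macro metrics average per-class values
#' over the classes that occur as true classes (non-empty rows); a class
#' never predicted has precision 0 by convention, and F1 is 0 where
#' precision + recall is 0. A predicted-only column (e.g. the unknown
#' sentinel when no true image is unknown) contributes misclassifications
#' but is not itself averaged. Micro averaging collapses precision, recall
#' and F1 to accuracy in single-label classification and is provided for
#' completeness.
#'
#' @param cfm A [confusion_matrix()].
#' @param averaging `"macro"` (default) or `"micro"`.
#' @return A `metric_report`: `top1_acc`, `precision`, `recall`, `f1` (all
#'   percentages) and the `averaging` tag.
#' @export
compute_metrics <- function(cfm, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(cfm, "confusion_matrix"))
  m <- cfm$counts
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  acc <- sum(diag(m)) / total
  if (averaging == "micro") {
    rep <- list(top1_acc = 100 * acc, precision = 100 * acc,
                recall = 100 * acc, f1 = 100 * acc, averaging = "micro")
    return(structure(rep, class = "metric_report"))
  }
  true_classes <- which(rowSums(m) > 0)
  tp <- diag(m)[true_classes]
  colsum <- colSums(m)[true_classes]
  rowsum <- rowSums(m)[true_classes]
  prec <- ifelse(colsum > 0, tp / colsum, 0)
  rec <- tp / rowsum
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(top1_acc = 100 * acc,
                 precision = 100 * mean(prec),
                 recall = 100 * mean(rec),
                 f1 = 100 * mean(f1),
                 averaging = "macro"),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Top-1 ACC %.1f%%  Precision %.1f%%  Recall %.1f%%  F1 %.1f%%  (%s)\n",
    x$top1_acc, x$precision, x$recall, x$f1, x$averaging))
  invisible(x)
}

#' Difference of two metric reports, in percentage points
#'
#' @param a,b [compute_metrics()] reports with the same averaging tag.
#' @return Named numeric vector `a - b` per metric.
#' @export
compare_reports <- function(a, b) {
  stopifnot(inherits(a, "metric_report"), inherits(b, "metric_report"))
  if (!identical(a$averaging, b$averaging)) {
    stop("cannot compare reports with different averaging", call. = FALSE)
  }
  c(top1_acc = a$top1_acc - b$top1_acc,
    precision = a$precision - b$precision,
    recall = a$recall - b$recall,
    f1 = a$f1 - b$f1)
}
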