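#' Construct and validate a cognitive relevance transform
#'
#' A CRT re-targets a dataset's category system to the one a human population
#' actually uses: it is a set of new categories, each realized by a merge of
#' image sets (possibly separating an original category across several new
#' ones), a record of where each new category's images came from (relative
#' source frequencies), a name, and a map telling how classifier output
#' labels translate.
#'
#' @param new_categories List of `list(name, image_ids, sources)` where
#'   `sources` is a named numeric vector (original category -> relative
#'   frequency of that category's images landing in this new category, after
#'   thresholding).
#' @param prediction_map Named character vector: original category (the study
#'   subset label space) -> new category name.
#' @param unknown_label Sentinel for out-of-vocabulary predictions and
#'   human "don't know" answers.
#' @param provenance Free-form list recording how the transform was derived
#'   (k, cost curve, threshold, seeds).
#' @return A validated `crt_transform` object.
#' @export
crt_transform <- function(new_categories, prediction_map,
                          unknown_label = unknown_sentinel(),
                          provenance = list()) {
  x <- structure(list(new_categories = new_categories,
                      prediction_map = prediction_map,
                      unknown_label = unknown_label,
                      provenance = provenance),
                 class = "crt_transform")
  validate_crt(x)
  x
}

validate_crt <- function(x) {
  stopifnot(inherits(x, "crt_transform"), length(x$new_categories) >= 1L)
  nm <- vapply(x$new_categories, function(nc) nc$name, character(1))
  if (any(!nzchar(nm))) stop("every new category needs a non-empty name",
                             call. = FALSE)
  if (anyDuplicated(nm)) stop("new category names must be unique",
                              call. = FALSE)
  ids <- unlist(lapply(x$new_categories, function(nc) nc$image_ids))
  if (anyDuplicated(ids)) {
    stop("new-category image sets overlap: image assigned twice",
         call. = FALSE)
  }
  if (!is.character(x$prediction_map) || is.null(names(x$prediction_map))) {
    stop("prediction_map must be a named character vector", call. = FALSE)
  }
  bad <- setdiff(unname(x$prediction_map),
                 c(nm, x$unknown_label))
  if (length(bad)) {
    stop("prediction_map targets unknown categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.crt_transform <- function(x, ...) {
  cat(sprintf("Cognitive relevance transform: %d new categories, %d images\n",
              length(x$new_categories),
              length(unlist(lapply(x$new_categories, `[[`, "image_ids")))))
  for (nc in x$new_categories) {
    src <- paste(sprintf("%s (%.2f)", names(nc$sources), nc$sources),
                 collapse = ", ")
    cat(sprintf("  <%s>: %d images from %s\n", nc$name,
                length(nc$image_ids), src))
  }
  invisible(x)
}

crt_image_map <- function(crt) {
  maps <- lapply(crt$new_categories, function(nc) {
    stats::setNames(rep(nc$name, length(nc$image_ids)), nc$image_ids)
  })
  do.call(c, maps)
}

#' Relative frequency of each original category across clusters
#'
#' For cluster `i` and original category `j`, `n[j, i]` is the fraction of
#' category `j`'s images assigned to cluster `i`. Rows sum to 1 when the
#' partition covers the manifest.
#'
#' @param partition A [kmodes_cluster()] partition, or any named vector /
#'   factor image -> cluster id.
#' @param manifest Data frame with columns `image_id`, `category`.
#' @return Numeric matrix, rows = original categories, columns = clusters.
#' @export
category_cluster_frequencies <- function(partition, manifest) {
  assign <- if (inherits(partition, "cluster_partition")) {
    partition$assignment
  } else partition
  stopifnot(!is.null(names(assign)),
            all(c("image_id", "category") %in% names(manifest)))
  if (!setequal(names(assign), manifest$image_id)) {
    stop("partition and manifest cover different image sets", call. = FALSE)
  }
  cl <- as.character(assign[manifest$image_id])
  tab <- table(manifest$category, cl)
  n <- as.matrix(tab)
  sweep(n, 1L, rowSums(n), "/")
}

#' Merge and separation operations from a frequency matrix
#'
#' Each cluster becomes a merge of the original categories whose relative
#' frequency in it exceeds the inclusion threshold `tau`; a category
#' appearing above threshold in several clusters is thereby separated.
#' Thresholding edits the recorded provenance only — image membership stays
#' the full cluster so no image is lost.
#'
#' @param n_ji Frequency matrix from [category_cluster_frequencies()].
#' @param tau Inclusion threshold in `[0, 1)`.
#' @return List with `sources` (per cluster, the named thresholded
#'   frequencies), `separations` (per original category, the clusters it
#'   splits into), and `subthreshold_clusters` (clusters retained with no
#'   above-threshold source, flagged).
#' @export
derive_merge_separation <- function(n_ji, tau = 0.1) {
  stopifnot(is.matrix(n_ji), tau >= 0, tau < 1)
  if (max(abs(rowSums(n_ji) - 1)) > 1e-8) {
    stop("frequency rows must sum to 1", call. = FALSE)
  }
  clusters <- colnames(n_ji)
  if (is.null(clusters)) clusters <- as.character(seq_len(ncol(n_ji)))
  sources <- lapply(seq_len(ncol(n_ji)), function(i) {
    col <- n_ji[, i]
    col[col > tau]
  })
  names(sources) <- clusters
  flagged <- clusters[vapply(sources, length, integer(1)) == 0L]
  for (i in which(clusters %in% flagged)) {
    col <- n_ji[, i]
    sources[[i]] <- col[col > 0]  # sub-threshold provenance, kept but flagged
  }
  separations <- lapply(rownames(n_ji), function(j) {
    clusters[n_ji[j, ] > tau]
  })
  names(separations) <- rownames(n_ji)
  list(sources = sources, separations = separations,
       subthreshold_clusters = flagged)
}

#' Name clusters from cleaned labels and merge same-named clusters
#'
#' Each cluster is named by the most frequent cleaned label among all
#' responses for its images (lexicographic tie-break). Clusters that end up
#' with the same name are merged into a single new category — crowds often
#' keep two visually distinct groups apart yet give them the same word, which
#' is evidence the groups belong to one named category.
#'
#' @param partition A [kmodes_cluster()] partition or named image -> cluster
#'   vector.
#' @param Y Cleaned label matrix from [clean_labels()], rows = images
#'   (rownames = image ids), columns = subjects, `NA` for unseen pairs.
#' @return List with `names` (cluster id -> name), `merged_assignment`
#'   (image -> merged new-category name), `merge_groups` (name -> original
#'   cluster ids).
#' @export
assign_names <- function(partition, Y) {
  assign <- if (inherits(partition, "cluster_partition")) {
    partition$assignment
  } else partition
  stopifnot(!is.null(names(assign)), is.matrix(Y), !is.null(rownames(Y)))
  if (!all(names(assign) %in% rownames(Y))) {
    stop("label matrix does not cover all partition images", call. = FALSE)
  }
  cl_ids <- sort(unique(as.character(assign)))
  nms <- vapply(cl_ids, function(ci) {
    imgs <- names(assign)[as.character(assign) == ci]
    labs <- as.character(Y[imgs, , drop = FALSE])
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0L) return(unknown_sentinel())
    tb <- table(labs)
    names(tb)[order(-as.integer(tb), names(tb))][1L]
  }, character(1))
  merged <- stats::setNames(nms[as.character(assign)], names(assign))
  merge_groups <- split(cl_ids, nms[cl_ids])
  list(names = nms, merged_assignment = merged, merge_groups = merge_groups)
}

#' Derive a cognitive relevance transform from crowd responses
#'
#' End-to-end derivation: cluster the grouping matrix with k-modes (elbow
#' scan when `k = "auto"`), clean the free-text labels, name each cluster by
#' its modal cleaned label, merge same-named clusters, record merge and
#' separation operations via thresholded category-cluster frequencies, and
#' build the prediction map (each original category follows its dominant
#' cluster).
#'
#' The label matrix is aligned with the grouping matrix row-for-row, so the
#' naming clusters correspond exactly to the grouping clusters (grouping and
#' labeling responses come from the same subjects viewing the same images
#' and are statistically dependent). Independent clustering of the label
#' matrix is available via `cluster_labels_independently` for comparison;
#' names are still read off per grouping cluster.
#'
#' @param X Grouping matrix (images x subjects, group-id tokens, `NA` for
#'   unseen pairs), e.g. from [grouping_matrix()].
#' @param A Raw label matrix of the same shape.
#' @param manifest Data frame `image_id`, `category` (and optionally
#'   `batch_id`).
#' @param k Cluster count, or `"auto"` for the elbow suggestion.
#' @param tau Separation inclusion threshold, see
#'   [derive_merge_separation()].
#' @param n_init,seed k-modes restarts and seed.
#' @param k_max Upper end of the elbow scan when `k = "auto"`; defaults to
#'   `min(nrow(X) - 1, 3 * number of original categories)`.
#' @param lexicon,abbreviations,extra_words Passed to [clean_labels()].
#' @param cluster_labels_independently If `TRUE`, additionally cluster the
#'   cleaned-label matrix and store its partition in the provenance.
#' @return A [crt_transform()] with provenance (`k`, `cost_curve`, `tau`,
#'   `seed`, `cluster_names`, flags).
#' @export
derive_crt <- function(X, A, manifest, k = "auto", tau = 0.1, n_init = 10L,
                       seed = 1L, k_max = NULL,
                       lexicon = default_lexicon(),
                       abbreviations = default_abbreviations(),
                       extra_words = NULL,
                       cluster_labels_independently = FALSE) {
  X <- as_grouping_matrix(X)
  stopifnot(all(c("image_id", "category") %in% names(manifest)))
  if (!setequal(rownames(X), manifest$image_id)) {
    stop("grouping matrix rows and manifest image ids differ", call. = FALSE)
  }
  scan <- NULL
  if (identical(k, "auto")) {
    if (is.null(k_max)) {
      k_max <- min(nrow(X) - 1L, 3L * length(unique(manifest$category)))
    }
    scan <- elbow_scan(X, k_min = 2L, k_max = k_max, n_init = n_init,
                       seed = seed)
    k <- scan$suggested_k
  }
  part <- kmodes_cluster(X, k, n_init = n_init, seed = seed)
  Y <- clean_labels(A, lexicon = lexicon, abbreviations = abbreviations,
                    extra_words = extra_words)
  naming <- assign_names(part, Y)
  merged <- naming$merged_assignment
  n_ji <- category_cluster_frequencies(merged, manifest)
  ops <- derive_merge_separation(n_ji, tau)
  new_categories <- lapply(colnames(n_ji), function(nm) {
    list(name = nm,
         image_ids = sort(names(merged)[merged == nm]),
         sources = ops$sources[[nm]])
  })
  pred_map <- stats::setNames(
    colnames(n_ji)[max.col(n_ji, ties.method = "first")],
    rownames(n_ji))
  prov <- list(k = part$k, cost = part$cost, tau = tau,
               seed = as.integer(seed), n_init = as.integer(n_init),
               cluster_names = as.list(naming$names),
               merge_groups = naming$merge_groups,
               subthreshold_clusters = ops$subthreshold_clusters,
               cost_curve = if (!is.null(scan)) {
                 list(k = scan$k, cost = scan$cost,
                      suggested_k = scan$suggested_k,
                      low_confidence = scan$low_confidence)
               })
  if (cluster_labels_independently) {
    prov$label_partition <- kmodes_cluster(Y, k, n_init = n_init,
                                           seed = seed)$assignment
  }
  crt_transform(new_categories, pred_map, provenance = prov)
}
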