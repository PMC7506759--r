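#' k-modes clustering of categorical grouping vectors
#'
#' Huang-style k-modes over a categorical matrix with rows as objects
#' (images) and columns as attributes (subjects' group assignments). The
#' dissimilarity is the Hamming mismatch count with a strict missing-value
#' rule: a missing attribute never matches anything, including another
#' missing value. Because each crowd subject sees only one batch of images,
#' two images from different batches share no observed attributes and are
#' maximally dissimilar — clusters are therefore effectively batch-local, and
#' cross-batch unification happens later through same-name merging.
#'
#' Initialization: the first restart uses Cao-style density initialization
#' (deterministic); remaining restarts sample distinct rows as initial modes.
#' The best-cost run wins.
#'
#' @param X Character matrix (or data frame), rows = images with rownames as
#'   ids, columns = subjects; `NA` marks an unseen image/subject pair.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param n_init Number of restarts (first is Cao, rest random).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param max_iter Iteration cap per restart.
#' @return A `cluster_partition` list: `k`, `assignment` (named integer
#'   vector image -> cluster), `modes` (k x p character matrix), `cost`
#'   (total mismatch count `P(W, Q)`), `n_init`, `seed`.
#' @export
#' @examples
#' X <- rbind(a = c("g1", "g1"), b = c("g1", "g1"), c = c("g2", "g2"))
#' kmodes_cluster(X, k = 2, seed = 1)
kmodes_cluster <- function(X, k, n_init = 10L, seed = 1L, max_iter = 100L) {
  X <- as_grouping_matrix(X)
  n <- nrow(X)
  if (k > n) stop(sprintf("k = %d exceeds number of images (%d)", k, n),
                  call. = FALSE)
  stopifnot(k >= 1, n_init >= 1)
  best <- NULL
  rng <- make_rng_stream(seed)
  for (r in seq_len(n_init)) {
    modes0 <- if (r == 1L) {
      cao_init(X, k)
    } else {
      X[sample_distinct_rows(X, k, rng), , drop = FALSE]
    }
    fit <- kmodes_once(X, modes0, max_iter)
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  structure(list(k = as.integer(k),
                 assignment = best$assignment,
                 modes = best$modes,
                 cost = best$cost,
                 n_init = as.integer(n_init),
                 seed = as.integer(seed)),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("k-modes partition: k = %d, %d images, cost P(W,Q) = %d\n",
              x$k, length(x$assignment), x$cost))
  cat("  cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

as_grouping_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  storage.mode(X) <- "character"
  if (is.null(rownames(X))) rownames(X) <- paste0("img", seq_len(nrow(X)))
  X
}

# mismatch counts of every row of X against one mode vector
row_dissim <- function(X, mode) {
  M <- matrix(mode, nrow(X), ncol(X), byrow = TRUE)
  match <- !is.na(X) & !is.na(M) & X == M
  ncol(X) - rowSums(match)
}

dissim_to_modes <- function(X, modes) {
  D <- vapply(seq_len(nrow(modes)), function(i) row_dissim(X, modes[i, ]),
              numeric(nrow(X)))
  matrix(D, nrow = nrow(X))
}

# columnwise mode of a categorical submatrix; most frequent non-missing
# value, lexicographic tie-break; all-missing attribute stays NA
matrix_mode <- function(Xc) {
  apply(Xc, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(NA_character_)
    tb <- table(col)
    names(tb)[order(-as.integer(tb), names(tb))][1L]
  })
}

kmodes_once <- function(X, modes, max_iter) {
  n <- nrow(X)
  k <- nrow(modes)
  assign_old <- rep.int(0L, n)
  for (it in seq_len(max_iter)) {
    D <- dissim_to_modes(X, modes)
    assignment <- max.col(-D, ties.method = "first")
    # empty-cluster repair: move the globally farthest point there
    for (ci in which(tabulate(assignment, k) == 0L)) {
      far <- which.max(D[cbind(seq_len(n), assignment)])
      assignment[far] <- ci
    }
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
    for (ci in seq_len(k)) {
      modes[ci, ] <- matrix_mode(X[assignment == ci, , drop = FALSE])
    }
  }
  D <- dissim_to_modes(X, modes)
  cost <- sum(D[cbind(seq_len(n), assignment)])
  names(assignment) <- rownames(X)
  list(assignment = assignment, modes = modes, cost = as.integer(cost))
}

# Density-seeded farthest-point initialization (Cao-style): the first mode
# is the densest point; each later mode maximizes the minimum distance to
# the chosen modes, with density breaking ties. Pure maximin keeps every
# well-separated group covered before any group gets a second seed — under
# the missing-never-matches rule batch-local groups sit at a common maximal
# distance, so a density-weighted product would double-seed large groups.
# Deterministic.
cao_init <- function(X, k) {
  n <- nrow(X); p <- ncol(X)
  dens <- numeric(n)
  for (j in seq_len(p)) {
    tb <- table(X[, j], useNA = "no")
    freq <- ifelse(is.na(X[, j]), 0, as.integer(tb[X[, j]]))
    dens <- dens + freq / n
  }
  dens <- dens / p
  chosen <- which.max(dens)
  while (length(chosen) < k) {
    D <- dissim_to_modes(X, X[chosen, , drop = FALSE])
    mind <- apply(D, 1L, min)
    mind[chosen] <- -Inf
    # maximin, density tie-break, then lowest index
    best <- which(mind == max(mind))
    chosen <- c(chosen, best[[which.max(dens[best])]])
  }
  X[chosen, , drop = FALSE]
}

# distinct-row sampling for random restarts (falls back to arbitrary rows if
# fewer than k distinct rows exist)
sample_distinct_rows <- function(X, k, rng) {
  keys <- apply(X, 1L, paste, collapse = "\r")
  distinct <- !duplicated(keys)
  pool <- which(distinct)
  if (length(pool) < k) pool <- seq_len(nrow(X))
  rng$sample(pool, k)
}

# small closure-based RNG stream so package functions never disturb the
# caller's .Random.seed
make_rng_stream <- function(seed) {
  env <- new.env()
  local_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(env$state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    res <- expr()
    env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    sample = function(x, size) local_seed(function() sample(x, size)),
    runif = function(n) local_seed(function() stats::runif(n)),
    with = function(f) local_seed(f)
  )
}

#' Cost-curve scan and elbow suggestion for the cluster count
#'
#' Runs [kmodes_cluster()] over a range of `k` and suggests the elbow as the
#' point of maximal perpendicular distance of the cost curve from the chord
#' joining its endpoints. The suggestion is advisory — cluster-count choice
#' on real crowd data is a judgement call and the suggestion is meant to be
#' overridable.
#'
#' @inheritParams kmodes_cluster
#' @param k_min,k_max Scan range, `1 <= k_min < k_max <= nrow(X)`.
#' @return An `elbow_scan` list: `k` (scanned values), `cost`, `suggested_k`,
#'   `low_confidence` (TRUE when the curve is essentially flat or linear so
#'   no elbow stands out), `seed`.
#' @export
elbow_scan <- function(X, k_min = 1L, k_max, n_init = 10L, seed = 1L) {
  X <- as_grouping_matrix(X)
  stopifnot(k_min >= 1, k_min < k_max, k_max <= nrow(X))
  ks <- seq.int(k_min, k_max)
  costs <- vapply(ks, function(k) {
    kmodes_cluster(X, k, n_init = n_init, seed = seed)$cost
  }, numeric(1))
  if (any(diff(costs) > 0)) {
    warning("cost curve is not monotone non-increasing; ",
            "consider more restarts", call. = FALSE)
  }
  elbow <- chord_elbow(ks, costs)
  structure(list(k = ks, cost = costs, suggested_k = elbow$k,
                 low_confidence = elbow$low_confidence,
                 seed = as.integer(seed)),
            class = "elbow_scan")
}

#' @export
print.elbow_scan <- function(x, ...) {
  cat("k-modes cost curve\n")
  print(stats::setNames(x$cost, paste0("k=", x$k)))
  cat(sprintf("suggested k = %d%s\n", x$suggested_k,
              if (x$low_confidence) " (low confidence: no clear elbow)" else ""))
  invisible(x)
}

# maximal perpendicular distance from the chord (k_min, cost_min) ->
# (k_max, cost_max), on axes normalized to [0, 1]
chord_elbow <- function(ks, costs) {
  if (length(ks) < 3L || diff(range(costs)) == 0) {
    return(list(k = ks[[1L]], low_confidence = TRUE))
  }
  x <- (ks - ks[[1L]]) / (ks[[length(ks)]] - ks[[1L]])
  y <- (costs - costs[[length(costs)]]) / (costs[[1L]] - costs[[length(costs)]])
  # chord runs from (0, 1) to (1, 0); distance to line x + y - 1 = 0
  d <- abs(x + y - 1) / sqrt(2)
  list(k = ks[[which.max(d)]], low_confidence = max(d) < 0.05)
}
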