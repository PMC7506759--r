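#' Uniformly random image-level category transform
#'
#' Draws a surjective assignment of the manifest's images to `n_final` new
#' categories, uniform over assignments, mirroring the image-level structure
#' of a derived transform. The prediction map sends each original category to
#' the new category holding the largest share of its images. Used as the
#' null model when asking whether a derived transform's metric gains are a
#' statistical fluke.
#'
#' @param manifest Data frame with `image_id`, `category`.
#' @param n_final Number of new categories, `1 <= n_final <= images`.
#' @param crt_names Optional names for the new categories (length
#'   `n_final`); defaults to `"r1" ... "rn"`.
#' @param seed Integer seed; the draw is deterministic given it.
#' @param level `"image"` (default, uniform over image assignments) or
#'   `"category"` (whole original categories are assigned to new categories,
#'   a coarser randomization).
#' @return A [crt_transform()].
#' @export
random_crt <- function(manifest, n_final, crt_names = NULL, seed = 1L,
                       level = c("image", "category")) {
  level <- match.arg(level)
  stopifnot(all(c("image_id", "category") %in% names(manifest)))
  n_img <- nrow(manifest)
  if (n_final < 1 || n_final > n_img) {
    stop(sprintf("n_final = %d infeasible for %d images", n_final, n_img),
         call. = FALSE)
  }
  if (is.null(crt_names)) crt_names <- paste0("r", seq_len(n_final))
  stopifnot(length(crt_names) == n_final, !anyDuplicated(crt_names))
  rng <- make_rng_stream(seed)
  assign_idx <- rng$with(function() {
    if (level == "category") {
      cats <- sort(unique(manifest$category))
      if (n_final > length(cats)) {
        stop("category-level randomization needs n_final <= original ",
             "categories", call. = FALSE)
      }
      ci <- sample_surjection(length(cats), n_final)
      stats::setNames(ci, cats)[manifest$category]
    } else {
      sample_surjection(n_img, n_final)
    }
  })
  assignment <- stats::setNames(crt_names[assign_idx], manifest$image_id)
  n_ji <- category_cluster_frequencies(assignment, manifest)
  new_categories <- lapply(colnames(n_ji), function(nm) {
    src <- n_ji[, nm]
    list(name = nm,
         image_ids = sort(names(assignment)[assignment == nm]),
         sources = src[src > 0])
  })
  pred_map <- stats::setNames(
    colnames(n_ji)[max.col(n_ji, ties.method = "first")], rownames(n_ji))
  crt_transform(new_categories, pred_map,
                provenance = list(random = TRUE, level = level,
                                  n_final = as.integer(n_final),
                                  seed = as.integer(seed)))
}

# log Stirling numbers of the second kind, ls[i+1, j+1] = log S(i, j)
log_stirling2 <- function(n, k) {
  ls <- matrix(-Inf, n + 1L, k + 1L)
  ls[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      a <- log(j) + ls[i, j + 1L]      # element i joins one of j blocks
      b <- ls[i, j]                    # element i opens a new block
      m <- max(a, b)
      ls[i + 1L, j + 1L] <- if (is.finite(m)) {
        m + log(exp(a - m) + exp(b - m))
      } else -Inf
    }
  }
  ls
}

# exactly uniform surjection [n] -> [k]: sample a uniform set partition into
# k blocks by the Stirling recurrence, then permute block labels. Rejection
# sampling is hopeless when k is close to n (acceptance ~ k!/k^n).
sample_surjection <- function(n, k) {
  stopifnot(k >= 1, k <= n)
  ls <- log_stirling2(n, k)
  new_block <- logical(n)
  j <- k
  for (i in n:1) {
    if (i == j) {
      new_block[seq_len(i)] <- TRUE
      break
    }
    p_join <- exp(log(j) + ls[i, j + 1L] - ls[i + 1L, j + 1L])
    if (stats::runif(1) < p_join) {
      new_block[i] <- FALSE
    } else {
      new_block[i] <- TRUE
      j <- j - 1L
    }
  }
  block_of <- integer(n)
  n_blocks <- 0L
  for (i in seq_len(n)) {
    if (new_block[i]) {
      n_blocks <- n_blocks + 1L
      block_of[i] <- n_blocks
    } else {
      block_of[i] <- sample.int(n_blocks, 1L)
    }
  }
  perm <- sample.int(k)
  perm[block_of]
}

#' Null distribution of metrics under random transforms
#'
#' Applies `n_reps` independent random transforms (all with `n_final` new
#' categories) to the same classification records and collects the metric
#' reports — the reference distribution against which a derived transform's
#' metrics are judged.
#'
#' @param records Classification records (`image_id`, `true_label`,
#'   `predicted_label`).
#' @param manifest Data frame with `image_id`, `category`.
#' @param n_final Number of new categories per random transform.
#' @param n_reps Number of random transforms.
#' @param seed Root seed; per-replicate seeds are drawn from it.
#' @param level Passed to [random_crt()].
#' @return A `null_distribution` object: `samples` (data frame, one row per
#'   replicate with the four metrics), `n_reps`, `n_final`, `seed`.
#' @export
null_metric_distribution <- function(records, manifest, n_final,
                                     n_reps = 10000L, seed = 1L,
                                     level = "image") {
  stopifnot(n_reps >= 1)
  rng <- make_rng_stream(seed)
  rep_seeds <- rng$with(function() sample.int(.Machine$integer.max - 1L,
                                              n_reps))
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    crt <- random_crt(manifest, n_final, seed = rep_seeds[[i]], level = level)
    rep_i <- compute_metrics(transform_cfm(records, crt))
    rows[[i]] <- data.frame(top1_acc = rep_i$top1_acc,
                            precision = rep_i$precision,
                            recall = rep_i$recall, f1 = rep_i$f1)
  }
  structure(list(samples = do.call(rbind, rows),
                 n_reps = as.integer(n_reps),
                 n_final = as.integer(n_final),
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Random-transform null: %d replicates, %d final categories\n",
              x$n_reps, x$n_final))
  print(round(apply(x$samples, 2L, stats::quantile,
                    c(0.025, 0.5, 0.975)), 2))
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether the distribution of `samples` is symmetric about `mu`.
#' Values equal to `mu` are dropped; for `n <= exact_n` remaining values the
#' null distribution of the positive-rank sum is enumerated exactly (dynamic
#' programming over doubled midranks, so ties are handled exactly too);
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param samples Numeric vector.
#' @param mu Hypothesized center of symmetry.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (direction of
#'   the location of `samples` relative to `mu`).
#' @param exact_n Largest n for the exact branch.
#' @return List: `statistic` (positive-rank sum V), `n` (after zero
#'   removal), `p_value`, `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1.1, 1.2, 1.3), mu = 0, alternative = "greater")
wilcoxon_signed_rank <- function(samples, mu = 0,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_n = 15L) {
  alternative <- match.arg(alternative)
  d <- samples - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all samples equal mu: signed-rank test undefined", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_n) {
    # doubled midranks are integers even with ties
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1L)  # f[w+1] = #sign assignments with 2*V = w
    f[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), f[seq_len(tot + 1L - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(tot + 1L)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact enumeration"
  } else {
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z_g <- (v - mu_v - 0.5) / sqrt(sigma2)
    z_l <- (v - mu_v + 0.5) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l),
                two.sided = min(1, 2 * min(
                  stats::pnorm(z_g, lower.tail = FALSE),
                  stats::pnorm(z_l))))
    method <- "normal approximation with tie correction"
  }
  list(statistic = v, n = n, p_value = p, method = method)
}

#' Two-alternative label preference test
#'
#' For each original category, the proportion of respondents preferring the
#' transformed label over the original one, with an exact two-sided binomial
#' test against indifference (p = 0.5).
#'
#' @param votes Data frame with columns `category`, `votes_original`,
#'   `votes_transformed`.
#' @param alpha Significance level used for the `significant` flag.
#' @return Data frame: `category`, `n`, `prop_transformed`, `p_value`,
#'   `significant`. Zero-vote categories are skipped with a warning.
#' @export
preference_test <- function(votes, alpha = 0.05) {
  stopifnot(all(c("category", "votes_original", "votes_transformed") %in%
                  names(votes)),
            all(votes$votes_original >= 0), all(votes$votes_transformed >= 0))
  n <- votes$votes_original + votes$votes_transformed
  if (any(n == 0)) {
    warning("categories with zero votes skipped: ",
            paste(votes$category[n == 0], collapse = ", "), call. = FALSE)
    votes <- votes[n > 0, , drop = FALSE]
    n <- n[n > 0]
  }
  p <- mapply(function(x, nn) stats::binom.test(x, nn, 0.5)$p.value,
              votes$votes_transformed, n)
  data.frame(category = votes$category, n = n,
             prop_transformed = votes$votes_transformed / n,
             p_value = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test of independence on a contingency table
#'
#' @param table Non-negative count matrix, at least 2 x 2.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
contingency_chisq <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(res$expected < 1)) {
    warning("expected cell count below 1; chi-squared approximation is ",
            "unreliable", call. = FALSE)
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}
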