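#' Exact binomial tail probability
#'
#' Tail sum of the Binomial(trials, p0) pmf: `greater` gives
#' `P(X >= successes)`, `less` gives `P(X <= successes)`.
#'
#' @param successes,trials Non-negative counts with
#'   `0 <= successes <= trials`, `trials >= 1`.
#' @param p0 Null success probability in \[0, 1\].
#' @param alternative `"greater"` or `"less"`.
#' @return Exact tail probability.
#' @export
#' @examples
#' binomial_tail(22, 23, 0.75, "greater")
binomial_tail <- function(successes, trials, p0,
                          alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!(trials >= 1 && successes >= 0 && successes <= trials &&
        successes == round(successes) && trials == round(trials))) {
    stop("need integer counts with 0 <= successes <= trials, trials >= 1",
         call. = FALSE)
  }
  stopifnot(p0 >= 0, p0 <= 1)
  if (alternative == "greater") {
    stats::pbinom(successes - 1, trials, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(successes, trials, p0)
  }
}

#' Per-image vote tally
#'
#' @param image_id Image identifier.
#' @param votes Named integer vector, label -> count; all counts >= 0 and at
#'   least one positive.
#' @param original_label The dataset-provided label for this image.
#' @return A `label_votes` object.
#' @export
label_votes <- function(image_id, votes, original_label) {
  stopifnot(length(image_id) == 1L, length(original_label) == 1L,
            is.numeric(votes), !is.null(names(votes)), all(votes >= 0))
  n <- sum(votes)
  if (n <= 0) stop("each image needs at least one vote", call. = FALSE)
  structure(list(image_id = as.character(image_id),
                 votes = votes, n_trials = as.integer(n),
                 original_label = as.character(original_label)),
            class = "label_votes")
}

# Most frequent label; ties broken in favor of the original, else
# lexicographically.
top_vote_label <- function(votes, original_label) {
  m <- max(votes)
  cand <- sort(names(votes)[votes == m])
  if (original_label %in% cand) original_label else cand[[1L]]
}

#' Population consensus labels from per-subject forced-choice answers
#'
#' Reduces each image's votes to a two-class problem — the positive class is
#' the most frequent answer, everything else is negative — and replaces the
#' dataset-provided label only when the positive class's support significantly
#' exceeds the expected human success probability `pe` (one-sided exact
#' binomial test). Otherwise the original label is kept, reflecting the
#' assumption that dataset labels are correct though not necessarily optimal.
#'
#' The `"literal"` mode instead counts agreement with the original label as
#' success and tests the lower tail; it is kept for audit and is not the
#' default because it does not yield the documented keep/replace behaviour.
#'
#' @param votes A list of [label_votes()] objects (or a data frame with
#'   columns `image_id`, `label`, `original_label`, one row per vote).
#' @param pe Expected probability of successful human classification; the
#'   consensus threshold, in (0, 1).
#' @param alpha Significance level for the one-sided binomial test.
#' @param mode `"prose"` (default) or `"literal"`.
#' @param min_trials Images with fewer votes than this are flagged and kept at
#'   the original label (the test is powerless there).
#' @return A data frame with one row per image: `image_id`, `original_label`,
#'   `top_label`, `p_value`, `consensus_label`, `mode`, `flagged_low_n`.
#' @export
#' @examples
#' v <- label_votes("img1", c(fox = 22, dhole = 1), "dhole")
#' consensus_labels(list(v), pe = 0.75)
consensus_labels <- function(votes, pe = 0.75, alpha = 0.05,
                             mode = c("prose", "literal"), min_trials = 5L) {
  mode <- match.arg(mode)
  stopifnot(pe > 0, pe < 1, alpha > 0, alpha < 1)
  if (is.data.frame(votes)) votes <- votes_from_long(votes)
  stopifnot(length(votes) >= 1L,
            all(vapply(votes, inherits, logical(1), "label_votes")))
  rows <- lapply(votes, function(v) {
    top <- top_vote_label(v$votes, v$original_label)
    if (mode == "prose") {
      succ <- v$votes[[top]]
      p <- binomial_tail(succ, v$n_trials, pe, "greater")
      replace <- p < alpha
    } else {
      succ <- if (v$original_label %in% names(v$votes)) {
        v$votes[[v$original_label]]
      } else 0L
      p <- binomial_tail(succ, v$n_trials, pe, "less")
      replace <- p < alpha
    }
    low_n <- v$n_trials < min_trials
    cons <- if (!low_n && replace) top else v$original_label
    data.frame(image_id = v$image_id, original_label = v$original_label,
               top_label = top, p_value = p, consensus_label = cons,
               mode = mode, flagged_low_n = low_n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# long-format data frame (image_id, label, original_label) -> list of
# label_votes
votes_from_long <- function(df) {
  stopifnot(all(c("image_id", "label", "original_label") %in% names(df)))
  lapply(split(df, df$image_id), function(d) {
    orig <- unique(d$original_label)
    if (length(orig) != 1L) {
      stop(sprintf("image %s has conflicting original labels",
                   d$image_id[[1L]]), call. = FALSE)
    }
    label_votes(d$image_id[[1L]], table_to_counts(d$label), orig)
  })
}

table_to_counts <- function(x) {
  tb <- table(as.character(x))
  counts <- as.integer(tb)
  names(counts) <- names(tb)
  counts
}
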