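# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (exhaustive enumeration, direct
# tabulation) and share no code with the implementation paths they check.

# all set partitions of n items into at most k_max blocks, as restricted
# growth strings
all_partitions <- function(n, k_max) {
  out <- list()
  grow <- function(assign) {
    i <- length(assign) + 1L
    if (i > n) {
      if (max(assign) <= k_max) out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (b in seq_len(min(max(assign) + 1L, k_max))) grow(c(assign, b))
  }
  grow(1L)
  out
}

# mismatch cost of a partition under the missing-never-matches rule, with
# per-attribute most-frequent-value modes (recomputed from scratch)
oracle_partition_cost <- function(X, assign) {
  total <- 0L
  for (b in unique(assign)) {
    rows <- which(assign == b)
    for (j in seq_len(ncol(X))) {
      col <- X[rows, j]
      obs <- col[!is.na(col)]
      matched <- if (length(obs)) max(table(obs)) else 0L
      total <- total + length(rows) - matched
    }
  }
  total
}

oracle_best_cost <- function(X, k) {
  parts <- all_partitions(nrow(X), k)
  min(vapply(parts, function(a) oracle_partition_cost(X, a), numeric(1)))
}

# adjusted Rand index by explicit pair enumeration
oracle_ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[[i]] == a[[j]]
      sb <- b[[i]] == b[[j]]
      s_a <- s_a + sa
      s_b <- s_b + sb
      s_both <- s_both + (sa && sb)
    }
  }
  npairs <- n * (n - 1) / 2
  expected <- s_a * s_b / npairs
  maxi <- (s_a + s_b) / 2
  if (maxi == expected) return(1)
  (s_both - expected) / (maxi - expected)
}

# exact signed-rank p-value by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  switch(alternative,
         greater = mean(vs >= v_obs - 1e-12),
         less = mean(vs <= v_obs + 1e-12),
         two.sided = min(1, 2 * min(mean(vs >= v_obs - 1e-12),
                                    mean(vs <= v_obs + 1e-12))))
}

# direct confusion tabulation, one record at a time
oracle_confusion <- function(truth, pred, labels) {
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_along(truth)) {
    m[truth[[i]], pred[[i]]] <- m[truth[[i]], pred[[i]]] + 1L
  }
  m
}

# small single-batch study where every subject sees every image (no missing
# entries, cost floor 0), handy for elbow and recovery checks
small_single_batch_config <- function(seed = 1L, ...) {
  simulation_config(n_categories = 6L, images_per_category = 4L,
                    task_categories = 6L, task_images = 4L,
                    subjects_per_batch = 10L, seed = seed, ...)
}

study_records <- function(study) {
  truth <- with(study$manifest, stats::setNames(category, image_id))
  data.frame(image_id = study$predictions$image_id,
             true_label = unname(truth[study$predictions$image_id]),
             predicted_label = study$predictions$predicted_label,
             stringsAsFactors = FALSE)
}

local_cluster_count <- function(study) {
  ic <- study$ground_truth$image_cluster
  length(unique(paste(study$manifest$batch_id,
                      ic[study$manifest$image_id])))
}

crt_image_map_for_test <- function(crt) {
  maps <- lapply(crt$new_categories, function(nc) {
    setNames(rep(nc$name, length(nc$image_ids)), nc$image_ids)
  })
  do.call(c, maps)
}
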