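#' Configuration for a synthetic crowd-categorization study
#'
#' Describes a study with planted structure: a batch-partitioned manifest, a
#' planted partition of images into perceptual clusters (the "true"
#' transform a perfect crowd would reveal), per-cluster label vocabularies
#' with synonym/typo/plural corruption, per-subject grouping noise,
#' forced-choice answer kernels, and classifier confusion kernels with
#' out-of-subset mass.
#'
#' Default sizes follow the powered design for a large-scale image dataset
#' study: 10 categories, 16 images per category, 5 categories x 8 images per
#' task, and 23 subjects per batch (the solved number of observations per
#' image). The default planted structure merges consecutive category pairs;
#' pass `cluster_map` and/or `splits` for other structures.
#'
#' @param n_categories,images_per_category Manifest shape.
#' @param task_categories,task_images Batch shape (nu_c, nu_i); must divide
#'   the manifest shape.
#' @param subjects_per_batch Subjects (= observations per image) per batch.
#' @param cluster_map Named character vector original category -> planted
#'   cluster name; `NULL` merges consecutive pairs of categories under
#'   default names.
#' @param splits Optional list: original category -> named numeric vector of
#'   fractions over cluster names (image-level separation; fractions must
#'   sum to 1). Overrides `cluster_map` for that category.
#' @param vocab Optional named list cluster name -> `list(canonical,
#'   synonyms, canonical_weight)`; defaults to canonical = cluster name, no
#'   synonyms.
#' @param grouping_noise Probability a subject misassigns an image to a
#'   random other group within their batch.
#' @param typo_rate,plural_rate,label_offtopic_rate Label corruption rates:
#'   random single-letter substitution, appended plural "s", and replacement
#'   by an off-topic string.
#' @param subject_accuracy,subject_within_cluster_rate Forced-choice kernel:
#'   probability of the correct category, probability of another category in
#'   the same planted cluster; the remainder goes to `"unknown"`.
#' @param classifier_accuracy,classifier_within_cluster_rate Classifier
#'   kernel, analogous; the remainder goes to out-of-subset labels.
#' @param n_out_of_subset_labels Size of the classifier's out-of-subset
#'   label pool.
#' @param category_names Optional category names; defaults to a pool of
#'   common nouns so that identity studies survive label cleaning.
#' @param seed Root seed; everything downstream is deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_categories = 10L, images_per_category = 16L,
                              task_categories = 5L, task_images = 8L,
                              subjects_per_batch = 23L,
                              cluster_map = NULL, splits = NULL, vocab = NULL,
                              grouping_noise = 0, typo_rate = 0,
                              plural_rate = 0, label_offtopic_rate = 0,
                              subject_accuracy = 0.75,
                              subject_within_cluster_rate = 0.15,
                              classifier_accuracy = 0.7,
                              classifier_within_cluster_rate = 0.2,
                              n_out_of_subset_labels = 5L,
                              category_names = NULL, seed = 1L) {
  if (n_categories %% task_categories != 0) {
    stop("task_categories must divide n_categories", call. = FALSE)
  }
  if (images_per_category %% task_images != 0) {
    stop("task_images must divide images_per_category", call. = FALSE)
  }
  rates <- c(grouping_noise, typo_rate, plural_rate, label_offtopic_rate,
             subject_accuracy, subject_within_cluster_rate,
             classifier_accuracy, classifier_within_cluster_rate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            subject_accuracy + subject_within_cluster_rate <= 1,
            classifier_accuracy + classifier_within_cluster_rate <= 1,
            subjects_per_batch >= 1)
  if (is.null(category_names)) {
    pool <- c("dunlin", "jacamar", "cockatoo", "toadstool", "truffle",
              "siamang", "dhole", "library", "website", "meatball",
              "dumpling", "cabbage", "intestine", "snail", "noodle",
              "shrimp", "parrot", "gibbon", "jackal", "squirrel",
              "penguin", "ostrich", "peacock", "swan")
    category_names <- if (n_categories <= length(pool)) {
      pool[seq_len(n_categories)]
    } else {
      c(pool, sprintf("cat%02d", seq_len(n_categories - length(pool))))
    }
  }
  stopifnot(length(category_names) == n_categories,
            !anyDuplicated(category_names))
  if (is.null(cluster_map)) {
    defaults <- c("bird", "mushroom", "monkey", "fox", "book", "meat",
                  "vegetable", "soup", "fish", "tree", "flower", "house")
    grp <- ceiling(seq_len(n_categories) / 2)
    cl_names <- if (max(grp) <= length(defaults)) defaults[seq_len(max(grp))]
    else sprintf("cluster%02d", seq_len(max(grp)))
    cluster_map <- stats::setNames(cl_names[grp], category_names)
  }
  stopifnot(setequal(names(cluster_map), category_names) ||
              all(names(cluster_map) %in% category_names))
  if (!is.null(splits)) {
    stopifnot(all(names(splits) %in% category_names))
    for (s in splits) {
      stopifnot(abs(sum(s) - 1) < 1e-8, !is.null(names(s)))
    }
  }
  cluster_names <- sort(unique(c(unname(cluster_map),
                                 unlist(lapply(splits, names)))))
  if (is.null(vocab)) {
    vocab <- lapply(cluster_names, function(cn) {
      list(canonical = cn, synonyms = character(0), canonical_weight = 1)
    })
    names(vocab) <- cluster_names
  }
  stopifnot(all(cluster_names %in% names(vocab)))
  structure(list(
    n_categories = as.integer(n_categories),
    images_per_category = as.integer(images_per_category),
    task_categories = as.integer(task_categories),
    task_images = as.integer(task_images),
    subjects_per_batch = as.integer(subjects_per_batch),
    category_names = category_names, cluster_map = cluster_map,
    splits = splits, vocab = vocab, cluster_names = cluster_names,
    grouping_noise = grouping_noise, typo_rate = typo_rate,
    plural_rate = plural_rate, label_offtopic_rate = label_offtopic_rate,
    subject_accuracy = subject_accuracy,
    subject_within_cluster_rate = subject_within_cluster_rate,
    classifier_accuracy = classifier_accuracy,
    classifier_within_cluster_rate = classifier_within_cluster_rate,
    n_out_of_subset_labels = as.integer(n_out_of_subset_labels),
    seed = as.integer(seed)), class = "simulation_config")
}

#' Generate a synthetic crowd study
#'
#' Builds the manifest (categories shuffled then chunked round-robin into
#' batches), plants the perceptual clusters, and simulates every response
#' table the pipeline consumes: grouping (planted clusters restricted to the
#' batch, perturbed at `grouping_noise`), free-text labels (cluster
#' vocabulary with typo/plural/off-topic corruption), forced-choice
#' classification answers, and classifier predictions (with out-of-subset
#' mass). Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_study` list: `manifest`, `grouping`, `labels`,
#'   `classification`, `predictions` (data frames in the package's CSV
#'   schemas), and `ground_truth` (`crt`: the planted [crt_transform()];
#'   `image_cluster`: image -> planted cluster).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  rng <- make_rng_stream(cfg$seed)
  rng$with(function() {
    n_img <- cfg$n_categories * cfg$images_per_category
    manifest <- data.frame(
      image_id = sprintf("i%04d", seq_len(n_img)),
      category = rep(cfg$category_names, each = cfg$images_per_category),
      stringsAsFactors = FALSE)

    # batch assignment: seeded category shuffle, chunk categories by nu_c
    # and each category's images by nu_i
    cat_order <- sample(cfg$category_names)
    cat_block <- stats::setNames(
      ceiling(seq_along(cat_order) / cfg$task_categories), cat_order)
    img_block_per_cat <- cfg$images_per_category / cfg$task_images
    img_index <- stats::setNames(
      unlist(lapply(seq_len(cfg$n_categories),
                    function(i) seq_len(cfg$images_per_category))),
      manifest$image_id)
    img_block <- ceiling(img_index / cfg$task_images)
    manifest$batch_id <- sprintf(
      "b%02d",
      (cat_block[manifest$category] - 1L) * img_block_per_cat +
        img_block[manifest$image_id])

    # planted image-level cluster assignment
    image_cluster <- stats::setNames(
      unname(cfg$cluster_map[manifest$category]), manifest$image_id)
    for (cat in names(cfg$splits)) {
      imgs <- manifest$image_id[manifest$category == cat]
      frac <- cfg$splits[[cat]]
      sizes <- diff(round(cumsum(c(0, frac)) * length(imgs)))
      image_cluster[imgs] <- rep(names(frac), sizes)
    }

    batches <- sort(unique(manifest$batch_id))
    subj_ids <- sprintf("s%04d", seq_len(length(batches) *
                                           cfg$subjects_per_batch))
    subj_batch <- rep(batches, each = cfg$subjects_per_batch)

    grouping <- list(); labels <- list(); classif <- list()
    oos_pool <- sprintf("offsubset%02d", seq_len(cfg$n_out_of_subset_labels))
    offtopic_pool <- c("zxqvvb", "qqwxyz", "vvkkzz", "jjqqxx")

    for (si in seq_along(subj_ids)) {
      s <- subj_ids[[si]]
      b <- subj_batch[[si]]
      imgs <- manifest$image_id[manifest$batch_id == b]
      cats <- stats::setNames(manifest$category[manifest$batch_id == b], imgs)
      local_clusters <- image_cluster[imgs]
      present <- unique(local_clusters)
      gid <- stats::setNames(paste0(s, "_g", seq_along(present)), present)
      grp <- unname(gid[local_clusters])
      if (cfg$grouping_noise > 0 && length(present) > 1L) {
        flip <- stats::runif(length(imgs)) < cfg$grouping_noise
        for (ii in which(flip)) {
          others <- setdiff(gid, grp[[ii]])
          grp[[ii]] <- others[[sample.int(length(others), 1L)]]
        }
      }
      grouping[[si]] <- data.frame(subject_id = s, batch_id = b,
                                   image_id = imgs, group_id = grp,
                                   stringsAsFactors = FALSE)

      lab <- vapply(local_clusters, function(cl) {
        v <- cfg$vocab[[cl]]
        words <- c(v$canonical, v$synonyms)
        w <- if (length(v$synonyms)) {
          c(v$canonical_weight,
            rep((1 - v$canonical_weight) / length(v$synonyms),
                length(v$synonyms)))
        } else 1
        words[[sample.int(length(words), 1L, prob = w)]]
      }, character(1))
      off <- stats::runif(length(imgs)) < cfg$label_offtopic_rate
      lab[off] <- sample(offtopic_pool, sum(off), replace = TRUE)
      plur <- stats::runif(length(imgs)) < cfg$plural_rate
      lab[plur] <- paste0(lab[plur], "s")
      typo <- stats::runif(length(imgs)) < cfg$typo_rate
      lab[typo] <- vapply(lab[typo], corrupt_letter, character(1))
      labels[[si]] <- data.frame(subject_id = s, batch_id = b,
                                 image_id = imgs, label_text = unname(lab),
                                 stringsAsFactors = FALSE)

      ans <- vapply(imgs, function(im) {
        u <- stats::runif(1)
        if (u < cfg$subject_accuracy) return(cats[[im]])
        peers <- setdiff(
          cfg$category_names[cfg$cluster_map[cfg$category_names] ==
                               image_cluster[[im]]],
          cats[[im]])
        if (u < cfg$subject_accuracy + cfg$subject_within_cluster_rate &&
            length(peers)) {
          return(peers[[sample.int(length(peers), 1L)]])
        }
        "unknown"
      }, character(1))
      classif[[si]] <- data.frame(subject_id = s, batch_id = b,
                                  image_id = imgs, chosen_label = unname(ans),
                                  stringsAsFactors = FALSE)
    }

    pred <- vapply(manifest$image_id, function(im) {
      tc <- manifest$category[manifest$image_id == im]
      u <- stats::runif(1)
      if (u < cfg$classifier_accuracy) return(tc)
      peers <- setdiff(
        cfg$category_names[cfg$cluster_map[cfg$category_names] ==
                             image_cluster[[im]]], tc)
      if (u < cfg$classifier_accuracy + cfg$classifier_within_cluster_rate &&
          length(peers)) {
        return(peers[[sample.int(length(peers), 1L)]])
      }
      oos_pool[[sample.int(length(oos_pool), 1L)]]
    }, character(1))
    predictions <- data.frame(model = "cnn1", image_id = manifest$image_id,
                              predicted_label = unname(pred),
                              stringsAsFactors = FALSE)

    gt_crt <- planted_crt(manifest, image_cluster, cfg)
    structure(list(manifest = manifest,
                   grouping = do.call(rbind, grouping),
                   labels = do.call(rbind, labels),
                   classification = do.call(rbind, classif),
                   predictions = predictions,
                   ground_truth = list(crt = gt_crt,
                                       image_cluster = image_cluster),
                   config = cfg),
              class = "synthetic_study")
  })
}

# planted transform: cluster partition + canonical names + dominant-cluster
# prediction map
planted_crt <- function(manifest, image_cluster, cfg) {
  assignment <- stats::setNames(as.character(image_cluster),
                                names(image_cluster))
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
                provenance = list(planted = TRUE, seed = cfg$seed))
}

corrupt_letter <- function(w) {
  if (nchar(w) < 2) return(w)
  i <- sample.int(nchar(w), 1L)
  substr(w, i, i) <- sample(letters, 1L)
  w
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d images, %d categories, %d batches, %d subjects\n",
    nrow(x$manifest), length(unique(x$manifest$category)),
    length(unique(x$manifest$batch_id)),
    length(unique(x$grouping$subject_id))))
  cat(sprintf("  planted clusters: %s\n",
              paste(x$config$cluster_names, collapse = ", ")))
  invisible(x)
}

#' Recovery of a planted transform by a derived one
#'
#' Compares image partitions by the adjusted Rand index and planted names by
#' the fraction recovered among the derived names.
#'
#' @param derived,planted [crt_transform()] objects over the same images.
#' @return List: `ari`, `name_accuracy`.
#' @export
recovery_score <- function(derived, planted) {
  md <- crt_image_map(derived)
  mp <- crt_image_map(planted)
  if (!setequal(names(md), names(mp))) {
    stop("transforms cover different image universes", call. = FALSE)
  }
  ids <- names(mp)
  ari <- mclust::adjustedRandIndex(md[ids], mp[ids])
  planted_names <- vapply(planted$new_categories, `[[`, character(1), "name")
  derived_names <- vapply(derived$new_categories, `[[`, character(1), "name")
  list(ari = unname(ari),
       name_accuracy = mean(planted_names %in% derived_names))
}
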