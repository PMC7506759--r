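make_merge_crt <- function() {
  # <bird> merges two categories; <library> splits into book/library
  crt_transform(
    new_categories = list(
      list(name = "bird", image_ids = c("i1", "i2", "i3", "i4"),
           sources = c(dunlin = 1, jacamar = 1)),
      list(name = "book", image_ids = c("i5"),
           sources = c(library = 0.5)),
      list(name = "library", image_ids = c("i6"),
           sources = c(library = 0.5))),
    prediction_map = c(dunlin = "bird", jacamar = "bird",
                       library = "library"))
}

test_that("truth transforms by image membership, resolving splits", {
  crt <- make_merge_crt()
  expect_identical(transform_truth(c("i1", "i4"), crt), c("bird", "bird"))
  expect_identical(transform_truth("i5", crt), "book")
  expect_identical(transform_truth("i6", crt), "library")
  expect_error(transform_truth("i99", crt), "absent")
})

test_that("predictions transform by dominant cluster, off-subset to unknown", {
  crt <- make_merge_crt()
  expect_identical(transform_prediction(c("dunlin", "jacamar"), crt),
                   c("bird", "bird"))
  expect_identical(transform_prediction("library", crt), "library")
  expect_identical(transform_prediction("shredded cabbage", crt), "unknown")
  expect_identical(transform_prediction("unknown", crt), "unknown")
})

test_that("confusion matrices match one-at-a-time tabulation", {
  set.seed(21)
  labels <- c("ant", "bee", "cow")
  rec <- data.frame(image_id = paste0("i", 1:50),
                    true_label = sample(labels, 50, replace = TRUE),
                    predicted_label = sample(labels, 50, replace = TRUE))
  cfm <- confusion_matrix(rec, labels = labels)
  expect_identical(unclass(cfm$counts),
                   unclass(oracle_confusion(rec$true_label,
                                            rec$predicted_label, labels)))
  expect_identical(sum(cfm$counts), 50L)
  # order invariance
  cfm2 <- confusion_matrix(rec[sample(50), ], labels = labels)
  expect_identical(cfm$counts, cfm2$counts)
  # single record
  one <- confusion_matrix(data.frame(image_id = "i", true_label = "ant",
                                     predicted_label = "bee"))
  expect_identical(sum(one$counts), 1L)
  expect_identical(one$counts["ant", "bee"], 1L)
  # undeclared predicted labels route to unknown with a warning
  expect_warning(
    cfm3 <- confusion_matrix(data.frame(image_id = "i", true_label = "ant",
                                        predicted_label = "zebra"),
                             labels = labels),
    "unknown")
  expect_identical(cfm3$counts["ant", "unknown"], 1L)
})

test_that("record transformation preserves counts and handles identity and
           all-merge degenerate transforms", {
  st <- simulate_study(small_single_batch_config(seed = 3))
  rec <- study_records(st)
  crt <- st$ground_truth$crt
  tc <- transform_cfm(rec, crt)
  expect_identical(sum(tc$counts), nrow(rec))

  # identity transform: per-image new category == original category
  manifest <- st$manifest
  ident <- crt_transform(
    lapply(sort(unique(manifest$category)), function(cat) {
      list(name = cat,
           image_ids = manifest$image_id[manifest$category == cat],
           sources = setNames(1, cat))
    }),
    prediction_map = setNames(sort(unique(manifest$category)),
                              sort(unique(manifest$category))))
  ti <- transform_cfm(rec, ident)
  # direct tabulation routes the classifier's off-subset labels the same way
  expect_warning(plain <- confusion_matrix(rec, labels = ti$labels),
                 "unknown")
  expect_identical(ti$counts, plain$counts)

  # all-merge transform: single category, accuracy 100%
  allm <- crt_transform(
    list(list(name = "everything", image_ids = manifest$image_id,
              sources = setNames(rep(1, length(unique(manifest$category))),
                                 unique(manifest$category)))),
    prediction_map = setNames(rep("everything",
                                  length(unique(manifest$category))),
                              unique(manifest$category)))
  rec_in <- rec[rec$predicted_label %in% manifest$category, ]
  ta <- transform_cfm(rec_in, allm)
  expect_identical(compute_metrics(ta)$top1_acc, 100)
})

test_that("macro metrics match hand computation", {
  cfm <- structure(list(labels = c("a", "b"),
                        counts = matrix(c(8L, 3L, 2L, 7L), 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b")))),
                   class = "confusion_matrix")
  m <- compute_metrics(cfm)
  expect_equal(m$top1_acc, 75)
  expect_equal(m$precision, 100 * (8 / 11 + 7 / 9) / 2, tolerance = 1e-10)
  expect_equal(m$recall, 75)
  f1a <- 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8)
  f1b <- 2 * (7 / 9) * 0.7 / (7 / 9 + 0.7)
  expect_equal(m$f1, 100 * (f1a + f1b) / 2, tolerance = 1e-10)
  expect_equal(round(c(m$precision, m$f1), 2), c(75.25, 74.94))
})

test_that("diagonal and single-class matrices score 100 everywhere", {
  diag_cfm <- confusion_matrix(data.frame(
    image_id = 1:9, true_label = rep(c("a", "b", "c"), 3),
    predicted_label = rep(c("a", "b", "c"), 3)))
  m <- compute_metrics(diag_cfm)
  expect_equal(unlist(m[c("top1_acc", "precision", "recall", "f1")]),
               c(top1_acc = 100, precision = 100, recall = 100, f1 = 100))
  one <- confusion_matrix(data.frame(image_id = 1:3, true_label = "a",
                                     predicted_label = "a"))
  expect_equal(compute_metrics(one)$f1, 100)
})

test_that("never-predicted true classes get precision zero; predicted-only
           columns are not averaged", {
  # true classes a, b; b never predicted; stray predictions go to unknown
  rec <- data.frame(image_id = 1:4,
                    true_label = c("a", "a", "b", "b"),
                    predicted_label = c("a", "a", "unknown", "unknown"))
  m <- compute_metrics(confusion_matrix(rec))
  # per-class: a -> P 1, R 1; b -> P 0 (never predicted), R 0
  expect_equal(m$precision, 50)
  expect_equal(m$recall, 50)
  expect_equal(m$f1, 50)
  expect_equal(m$top1_acc, 50)
})

test_that("micro averaging collapses to accuracy", {
  set.seed(5)
  rec <- data.frame(image_id = 1:30,
                    true_label = sample(c("a", "b", "c"), 30, TRUE),
                    predicted_label = sample(c("a", "b", "c"), 30, TRUE))
  m <- compute_metrics(confusion_matrix(rec), averaging = "micro")
  expect_equal(m$precision, m$top1_acc)
  expect_equal(m$f1, m$top1_acc)
})

test_that("report comparison subtracts per metric and is antisymmetric", {
  a <- structure(list(top1_acc = 90, precision = 96.88, recall = 96.88,
                      f1 = 95, averaging = "macro"), class = "metric_report")
  b <- structure(list(top1_acc = 90, precision = 90.34, recall = 90.34,
                      f1 = 93, averaging = "macro"), class = "metric_report")
  d <- compare_reports(a, b)
  expect_equal(unname(d["recall"]), 6.54)
  expect_equal(compare_reports(a, a),
               c(top1_acc = 0, precision = 0, recall = 0, f1 = 0))
  expect_equal(compare_reports(b, a), -d)
  mm <- structure(c(b, list()), class = "metric_report")
  mm$averaging <- "micro"
  expect_error(compare_reports(a, mm), "averaging")
})

test_that("split-free transforms never decrease top-1 accuracy", {
  # coarsening consistent truth/prediction maps cannot turn a correct
  # answer wrong
  for (seed in c(2, 4, 6)) {
    st <- simulate_study(simulation_config(seed = seed))
    rec <- study_records(st)
    crt <- st$ground_truth$crt  # whole-category merges only (no splits)
    before <- compute_metrics(
      confusion_matrix(rec, labels = sort(unique(c(rec$true_label,
                                                   rec$predicted_label)))))
    after <- compute_metrics(transform_cfm(rec, crt))
    expect_gte(after$top1_acc, before$top1_acc)
  }
})
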