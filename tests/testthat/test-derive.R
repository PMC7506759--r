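test_that("category-cluster frequencies are hand-countable row distributions", {
  manifest <- data.frame(
    image_id = paste0("i", 1:16),
    category = rep("jacamar", 16))
  part <- setNames(rep(c(1L, 2L, 3L), c(9, 4, 3)), manifest$image_id)
  n <- category_cluster_frequencies(part, manifest)
  expect_equal(unname(n["jacamar", c("1", "2", "3")]),
               c(0.5625, 0.25, 0.1875))
  expect_equal(unname(rowSums(n)), 1)

  # a category entirely inside one cluster is a one-hot row
  manifest2 <- data.frame(image_id = paste0("j", 1:8),
                          category = rep(c("ant", "bee"), each = 4))
  part2 <- setNames(rep(c("c1", "c2"), each = 4), manifest2$image_id)
  n2 <- category_cluster_frequencies(part2, manifest2)
  expect_equal(unname(n2["ant", ]), c(1, 0))
  expect_equal(unname(n2["bee", ]), c(0, 1))
  expect_error(category_cluster_frequencies(part2[-1], manifest2),
               "different image sets")
})

test_that("threshold arithmetic separates categories as expected", {
  n <- matrix(c(0.5625, 0.25, 0.1875), 1,
              dimnames = list("cat", c("c1", "c2", "c3")))
  expect_length(derive_merge_separation(n, tau = 0.1)$separations$cat, 3)
  expect_length(derive_merge_separation(n, tau = 0.3)$separations$cat, 1)
  one_hot <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                    dimnames = list(c("a", "b"), c("c1", "c2")))
  ops <- derive_merge_separation(one_hot, tau = 0)
  expect_identical(unname(lengths(ops$separations)), c(1L, 1L))
  expect_length(ops$subthreshold_clusters, 0)
  # a cluster whose every source is sub-threshold is retained and flagged
  thin <- matrix(c(0.95, 0.05, 0.97, 0.03), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("c1", "c2")))
  ops2 <- derive_merge_separation(thin, tau = 0.1)
  expect_identical(ops2$subthreshold_clusters, "c2")
  expect_true(length(ops2$sources$c2) > 0)
  expect_error(derive_merge_separation(thin * 2, tau = 0.1), "sum to 1")
})

test_that("clusters are named by modal label and same names merge", {
  part <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), paste0("i", 1:6))
  Y <- rbind(
    i1 = c("bird", "bird"), i2 = c("bird", "dunlin"),
    i3 = c("bird", "bird"), i4 = c("bird", "bird"),
    i5 = c("mushroom", "mushroom"), i6 = c("mushroom", NA))
  nm <- assign_names(part, Y)
  expect_identical(unname(nm$names[c("1", "2", "3")]),
                   c("bird", "bird", "mushroom"))
  expect_identical(sort(unique(nm$merged_assignment)),
                   c("bird", "mushroom"))
  expect_identical(nm$merge_groups$bird, c("1", "2"))
  # unanimous labels name directly; a cluster of unknowns stays unknown
  Yu <- rbind(i1 = c("unknown", NA), i2 = c("unknown", "unknown"))
  expect_identical(unname(assign_names(setNames(c(1L, 1L), c("i1", "i2")),
                                       Yu)$names), "unknown")
})

test_that("name ties break lexicographically", {
  part <- setNames(c(1L, 1L), c("i1", "i2"))
  Y <- rbind(i1 = c("fox", "dog"), i2 = c("dog", "fox"))
  expect_identical(unname(assign_names(part, Y)$names), "dog")
})

test_that("zero-noise simulated studies yield the planted transform exactly", {
  st <- simulate_study(small_single_batch_config(seed = 5))
  X <- grouping_matrix(st$grouping, st$manifest)
  A <- label_matrix(st$labels, st$manifest)
  crt <- derive_crt(X, A, st$manifest, k = "auto", n_init = 3, seed = 2,
                    k_max = 10)
  score <- recovery_score(crt, st$ground_truth$crt)
  expect_equal(score$ari, 1)
  expect_equal(score$name_accuracy, 1)
  expect_identical(sort(names(crt$prediction_map)),
                   sort(names(st$ground_truth$crt$prediction_map)))
  expect_identical(crt$prediction_map[names(st$ground_truth$crt$prediction_map)],
                   st$ground_truth$crt$prediction_map)
})

test_that("multi-batch studies recover the planted transform through
           same-name merging of batch-local clusters", {
  st <- simulate_study(simulation_config(seed = 7))
  X <- grouping_matrix(st$grouping, st$manifest)
  A <- label_matrix(st$labels, st$manifest)
  crt <- derive_crt(X, A, st$manifest, k = local_cluster_count(st),
                    n_init = 3, seed = 3)
  score <- recovery_score(crt, st$ground_truth$crt)
  expect_equal(score$ari, 1)
  expect_equal(score$name_accuracy, 1)
})

test_that("grouping by original category with original names is an identity
           transform", {
  manifest <- data.frame(image_id = paste0("i", 1:12),
                         category = rep(c("fox", "bird", "mushroom"),
                                        each = 4))
  # three subjects all grouping exactly by category, labels = category names
  X <- matrix(paste0(rep(c("s1", "s2", "s3"), each = 12), "_",
                     rep(manifest$category, 3)), 12, 3,
              dimnames = list(manifest$image_id, c("s1", "s2", "s3")))
  A <- matrix(rep(manifest$category, 3), 12, 3,
              dimnames = dimnames(X))
  crt <- derive_crt(X, A, manifest, k = 3, n_init = 3, seed = 1)
  nm <- vapply(crt$new_categories, `[[`, character(1), "name")
  expect_setequal(nm, c("fox", "bird", "mushroom"))
  for (nc in crt$new_categories) {
    expect_setequal(nc$image_ids,
                    manifest$image_id[manifest$category == nc$name])
  }
  expect_identical(crt$prediction_map[c("fox", "bird", "mushroom")],
                   c(fox = "fox", bird = "bird", mushroom = "mushroom"))
})

test_that("derived transforms conserve images and survive column permutation
           and group-id relabeling", {
  st <- simulate_study(small_single_batch_config(seed = 9,
                                                 grouping_noise = 0.1))
  X <- grouping_matrix(st$grouping, st$manifest)
  A <- label_matrix(st$labels, st$manifest)
  crt <- derive_crt(X, A, st$manifest, k = 3, n_init = 5, seed = 4)
  ids <- unlist(lapply(crt$new_categories, `[[`, "image_ids"))
  expect_setequal(ids, st$manifest$image_id)
  expect_false(anyDuplicated(ids) > 0)

  # permute subjects and relabel one subject's group ids
  set.seed(1)
  perm <- sample(ncol(X))
  X2 <- X[, perm]
  A2 <- A[, perm]
  X2[, 1] <- paste0("relabelled_", X2[, 1])
  crt2 <- derive_crt(X2, A2, st$manifest, k = 3, n_init = 5, seed = 4)
  m1 <- crt_image_map_for_test(crt)
  m2 <- crt_image_map_for_test(crt2)
  expect_equal(oracle_ari(m1[st$manifest$image_id],
                          m2[st$manifest$image_id]), 1)
})

test_that("a planted merge-and-split structure is reproduced", {
  # three bird-like categories merge, three fungi merge, one category splits
  # between its own name and another cluster
  cfg <- simulation_config(
    n_categories = 8L, images_per_category = 4L,
    task_categories = 8L, task_images = 4L, subjects_per_batch = 12L,
    category_names = c("dunlin", "jacamar", "cockatoo", "toadstool",
                       "truffle", "dhole", "library", "website"),
    cluster_map = c(dunlin = "bird", jacamar = "bird", cockatoo = "bird",
                    toadstool = "mushroom", truffle = "mushroom",
                    dhole = "fox", library = "library", website = "website"),
    splits = list(library = c(book = 0.5, library = 0.5)),
    seed = 13)
  st <- simulate_study(cfg)
  X <- grouping_matrix(st$grouping, st$manifest)
  A <- label_matrix(st$labels, st$manifest)
  crt <- derive_crt(X, A, st$manifest,
                    k = length(unique(st$ground_truth$image_cluster)),
                    n_init = 5, seed = 2)
  nm <- vapply(crt$new_categories, `[[`, character(1), "name")
  expect_setequal(nm, c("bird", "mushroom", "fox", "library", "website",
                        "book"))
  bird <- crt$new_categories[[which(nm == "bird")]]
  expect_setequal(names(bird$sources), c("dunlin", "jacamar", "cockatoo"))
  expect_equal(unname(bird$sources), rep(1, 3))
  # the split category appears above threshold in two new categories
  lib_clusters <- names(Filter(function(nc) "library" %in% names(nc$sources),
                               setNames(crt$new_categories, nm)))
  expect_setequal(lib_clusters, c("book", "library"))
})
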