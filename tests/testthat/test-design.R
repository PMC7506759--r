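test_that("Cohen's h matches the arcsine-square-root form and keeps sign", {
  expect_equal(as.numeric(cohen_h(0.5, 0.5)), 0)
  expect_equal(as.numeric(cohen_h(0, 1)), pi)
  expect_equal(as.numeric(cohen_h(0.5, 0.75)), 0.5235988, tolerance = 1e-6)
  expect_equal(attr(cohen_h(0.5, 0.75), "signed"), -0.5235988,
               tolerance = 1e-6)
  expect_error(cohen_h(-0.1, 0.5), "proportions")
  expect_error(cohen_h(0.5, 1.2), "proportions")
})

test_that("two-proportion n2 solver matches its closed form and limits", {
  expect_equal(solve_n2_two_proportions(1000, 0.9), 9.784789,
               tolerance = 1e-6)
  expect_equal(solve_n2_two_proportions(172, 0.8), 13.205444,
               tolerance = 1e-6)
  # n1 -> infinity limit is the one-sample constant K
  K <- ((qnorm(0.975) + qnorm(0.8)) / 0.9)^2
  expect_equal(solve_n2_two_proportions(1e9, 0.9), K, tolerance = 1e-6)
  # infeasible when n1 does not exceed K
  expect_error(solve_n2_two_proportions(9, 0.9), "unattainable")
})

test_that("chi-squared independence solver inverts noncentral power", {
  spec <- power_spec()
  N <- solve_N_chisq_independence(81, 0.5, spec)
  expect_equal(N, 148.1024, tolerance = 1e-4)
  expect_equal(solve_N_chisq_independence(225, 0.5, spec), 232.7262,
               tolerance = 1e-4)
  # minimality: power >= target at N, < target at 0.99 N
  pw <- function(N, df, w) {
    pchisq(qchisq(0.95, df), df, ncp = N * w^2, lower.tail = FALSE)
  }
  expect_gte(pw(N, 81, 0.5), 0.8 - 1e-9)
  expect_lt(pw(0.99 * N, 81, 0.5), 0.8)
  # quadratic scaling in the effect size, up to critical-value effects
  ratio <- solve_N_chisq_independence(81, 0.25, spec) / N
  expect_equal(ratio, 4, tolerance = 0.01)
})

test_that("one-proportion solver matches the arcsine normal approximation", {
  h <- 0.5235988
  expect_equal(solve_n_one_proportion(h, power_spec(sides = "one")),
               22.55126, tolerance = 1e-4)
  expect_equal(solve_n_one_proportion(h, power_spec(sides = "two")),
               28.62928, tolerance = 1e-4)
  # degenerate limit: power just above alpha needs almost no samples
  expect_lt(solve_n_one_proportion(1, power_spec(0.05, 0.051, "one")), 0.01)
  expect_error(solve_n_one_proportion(0), "h must be > 0")
})

test_that("to_integer rounds up to a divisible count", {
  expect_identical(to_integer(9.78, 5), 10L)
  expect_identical(to_integer(40, 8), 40L)
  expect_identical(to_integer(14.8, 8), 16L)
  for (n in c(0.3, 1, 7.2, 100.01)) {
    for (nu in c(1L, 2L, 5L, 8L)) {
      r <- to_integer(n, nu)
      expect_gte(r, n)
      expect_identical(r %% nu, 0L)
    }
  }
  expect_identical(to_integer(7.2, 1), 8L)
  expect_error(to_integer(5, 0), "positive integer")
})

test_that("subsample_design reproduces both published study sizes", {
  d1 <- subsample_design(1000, 5, 8, 0.9, 0.5)
  expect_identical(d1$n_categories, 10L)
  expect_identical(d1$images_per_category, 16L)
  expect_identical(d1$n_batches, 4L)
  d2 <- subsample_design(172, 8, 6, 0.8, 0.5)
  expect_identical(d2$n_categories, 16L)
  expect_identical(d2$images_per_category, 18L)
  expect_identical(d2$n_batches, 6L)
  # batch count closes the accounting identity
  for (d in list(d1, d2)) {
    expect_equal(d$n_batches * d$params$task_categories *
                   d$params$task_images,
                 d$n_categories * d$images_per_category)
  }
  # rounded-df variant gives the same final counts for both parameter sets
  expect_identical(subsample_design(1000, 5, 8, 0.9, 0.5,
                                    round_df_nc = TRUE)$images_per_category,
                   16L)
  expect_identical(subsample_design(172, 8, 6, 0.8, 0.5,
                                    round_df_nc = TRUE)$images_per_category,
                   18L)
  # a huge category effect floors the design at one task's worth
  expect_identical(subsample_design(1000, 5, 8, 50, 0.5)$n_categories, 5L)
})

test_that("population_design reproduces observations per image and subjects", {
  p <- population_design(4, 0.5, 0.75)
  expect_identical(p$observations_per_image, 23L)
  expect_identical(p$n_subjects, 92L)
  expect_identical(population_design(1, 0.5, 0.75)$n_subjects, 23L)
  expect_identical(population_design(6, 0.5, 0.75)$n_subjects, 138L)
  expect_equal(p$effect_h, 0.5235988, tolerance = 1e-6)
  expect_error(population_design(4, 0.5, 0.5), "must differ")
  # literal no-sqrt variant is exposed but differs
  expect_false(population_design(4, 0.5, 0.75,
                                 literal_h = TRUE)$effect_h ==
                 p$effect_h)
})

test_that("ANOVA solver and power evaluation match the noncentral F", {
  expect_identical(solve_n_anova(4, 0.4), 76L)
  expect_equal(anova_power(4, 36, 0.4), 0.9866, tolerance = 1e-3)
  # minimality at the per-group level
  expect_gte(anova_power(4, 19, 0.4), 0.8)
  expect_lt(anova_power(4, 18, 0.4), 0.8)
  # power monotone in the effect size
  expect_lt(solve_n_anova(4, 0.6), solve_n_anova(4, 0.4))
})

test_that("solver outputs are minimal real solutions", {
  spec <- power_spec()
  # two-proportion: power function evaluated directly at (n1, n2)
  pw2 <- function(n1, n2, h) {
    pnorm(h / sqrt(1 / n1 + 1 / n2) - qnorm(0.975)) +
      pnorm(-h / sqrt(1 / n1 + 1 / n2) - qnorm(0.975))
  }
  for (case in list(c(1000, 0.9), c(172, 0.8), c(500, 0.5))) {
    n2 <- solve_n2_two_proportions(case[[1]], case[[2]], spec)
    expect_gte(pw2(case[[1]], n2, case[[2]]), 0.8 - 1e-9)
    expect_lt(pw2(case[[1]], 0.99 * n2, case[[2]]), 0.8)
  }
  # one-proportion
  pw1 <- function(n, h) pnorm(h * sqrt(n) - qnorm(0.95))
  n <- solve_n_one_proportion(0.5236, power_spec(sides = "one"))
  expect_gte(pw1(n, 0.5236), 0.8 - 1e-9)
  expect_lt(pw1(0.99 * n, 0.5236), 0.8)
})

test_that("power_spec validates its invariants", {
  expect_error(power_spec(0.9, 0.8), "alpha < power")
  expect_error(power_spec(0, 0.8), "alpha < power")
  expect_error(power_spec(0.05, 1), "alpha < power")
})
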