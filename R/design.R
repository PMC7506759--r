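#' Power specification for a study-design solver
#'
#' Bundles the significance level, the target power and the sidedness of the
#' test whose power is being solved for.
#'
#' @param alpha Significance level, in (0, 1).
#' @param power Target power 1 - beta, in (0, 1). Must exceed `alpha`.
#' @param sides `"one"` or `"two"`.
#' @return A `power_spec` object (a named list).
#' @export
#' @examples
#' power_spec(0.05, 0.8, "two")
power_spec <- function(alpha = 0.05, power = 0.8, sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(power), length(power) == 1L)
  if (!(alpha > 0 && alpha < power && power < 1)) {
    stop("power_spec requires 0 < alpha < power < 1", call. = FALSE)
  }
  structure(list(alpha = alpha, power = power, sides = sides),
            class = "power_spec")
}

n_sides <- function(spec) if (spec$sides == "two") 2 else 1

#' Cohen's h effect size for two proportions
#'
#' Arcsine-square-root variance-stabilized difference
#' `2*asin(sqrt(p1)) - 2*asin(sqrt(p2))`. The magnitude is returned, with the
#' signed value kept in the `"sign"` attribute so direction is not lost.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @return Non-negative effect size; `attr(, "signed")` holds the signed value.
#' @export
#' @examples
#' cohen_h(0.5, 0.75)
cohen_h <- function(p1, p2) {
  stopifnot(is.numeric(p1), is.numeric(p2), length(p1) == 1L, length(p2) == 1L)
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  signed <- 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
  structure(abs(signed), signed = signed)
}

#' Second sample size for a two-proportion test at fixed first sample size
#'
#' Smallest real `n2` such that the normal-approximation (arcsine) power of
#' the two-sample proportions test with effect size `h` and sample sizes
#' `(n1, n2)` reaches the target. Closed form `n2 = K*n1/(n1 - K)` with
#' `K = ((z_{1-alpha/s} + z_{power}) / h)^2`.
#'
#' @param n1 First (fixed) sample size, > 0.
#' @param h Effect size (Cohen's h), > 0.
#' @param spec A [power_spec()].
#' @return Real minimal `n2`.
#' @export
#' @examples
#' solve_n2_two_proportions(1000, 0.9, power_spec())
solve_n2_two_proportions <- function(n1, h, spec = power_spec()) {
  stopifnot(n1 > 0, h > 0)
  K <- ((stats::qnorm(1 - spec$alpha / n_sides(spec)) +
           stats::qnorm(spec$power)) / h)^2
  if (n1 <= K) {
    stop(sprintf(
      "target power unattainable: n1 = %g must exceed K = %.4g", n1, K),
      call. = FALSE)
  }
  K * n1 / (n1 - K)
}

#' Total sample size for a chi-squared test of independence
#'
#' Smallest real `N` such that the noncentral chi-squared power
#' `P(X >= qchisq(1-alpha, df))` with `X ~ chisq(df, ncp = N*w^2)` reaches the
#' target, found by root-finding (power is strictly increasing in `N`).
#'
#' @param df Degrees of freedom, > 0 (need not be integral).
#' @param w Cohen's w effect size, > 0.
#' @param spec A [power_spec()]. Sidedness is ignored: the chi-squared test is
#'   inherently one-tailed.
#' @return Real minimal total sample size `N`.
#' @export
#' @examples
#' solve_N_chisq_independence(81, 0.5, power_spec())
solve_N_chisq_independence <- function(df, w, spec = power_spec()) {
  stopifnot(df > 0, w > 0)
  crit <- stats::qchisq(1 - spec$alpha, df)
  f <- function(N) {
    stats::pchisq(crit, df, ncp = N * w^2, lower.tail = FALSE) - spec$power
  }
  lo <- 1; hi <- 1e9
  if (f(hi) < 0) {
    stop(sprintf("chi-squared power root not bracketed in [%g, %g]: f(hi) = %.3g",
                 lo, hi, f(hi)), call. = FALSE)
  }
  if (f(lo) >= 0) return(lo)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Sample size for a one-sample proportion (binomial) test
#'
#' Arcsine normal approximation: `n = ((z_{1-alpha/s} + z_{power}) / h)^2`.
#'
#' @param h Effect size (Cohen's h), > 0.
#' @param spec A [power_spec()].
#' @return Real minimal sample size.
#' @export
#' @examples
#' solve_n_one_proportion(cohen_h(0.5, 0.75), power_spec(sides = "one"))
solve_n_one_proportion <- function(h, spec = power_spec(sides = "one")) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    stop("effect size h must be > 0", call. = FALSE)
  }
  ((stats::qnorm(1 - spec$alpha / n_sides(spec)) +
      stats::qnorm(spec$power)) / h)^2
}

#' Round a real count up to a multiple of a block size
#'
#' Returns the smallest multiple of `nu` that is at least `n`, so that the
#' rounded count divides evenly into task-sized blocks.
#'
#' @param n Real count, > 0.
#' @param nu Block size, positive integer.
#' @return Integer multiple of `nu`, >= `n`.
#' @export
#' @examples
#' to_integer(9.78, 5)  # 10
to_integer <- function(n, nu) {
  stopifnot(n > 0)
  if (!is.numeric(nu) || length(nu) != 1L || nu < 1 || nu != round(nu)) {
    stop("block size nu must be a positive integer", call. = FALSE)
  }
  as.integer(ceiling(n / nu) * nu)
}

#' Powered subsample design: categories, images per category, batches
#'
#' Sizes the representative subset of a large categorized image dataset for a
#' crowd study. The minimal number of categories comes from the power of the
#' two-sample proportions test (no detectable size-proportion difference
#' between dataset and subset at effect `effect_categories`); the minimal
#' number of images per category from the power of the chi-squared
#' independence test on the eventual human confusion matrix (df `(nc-1)^2`,
#' effect `effect_images`). Both are rounded up to task-divisible counts and
#' the batch count follows.
#'
#' @param total_categories Number of categories in the full dataset, >= 2.
#' @param task_categories Categories shown per task (nu_c), >= 1.
#' @param task_images Images per category per task (nu_i), >= 1.
#' @param effect_categories Cohen's h for the category-count test, > 0.
#' @param effect_images Cohen's w for the image-count test, > 0.
#' @param spec A [power_spec()]; the default two-sided alpha = 0.05,
#'   power = 0.8 matches standard practice.
#' @param round_df_nc If `TRUE`, use the rounded category count when forming
#'   the chi-squared degrees of freedom instead of the raw real solution.
#' @return A `subsample_design` list: `raw_nc`, `raw_ni`, `n_categories`,
#'   `images_per_category`, `n_batches`, plus the resolved parameters.
#' @export
#' @examples
#' subsample_design(1000, 5, 8, 0.9, 0.5)
subsample_design <- function(total_categories, task_categories, task_images,
                             effect_categories, effect_images,
                             spec = power_spec(), round_df_nc = FALSE) {
  stopifnot(total_categories >= 2, task_categories >= 1, task_images >= 1,
            task_categories <= total_categories,
            effect_categories > 0, effect_images > 0)
  nc <- solve_n2_two_proportions(total_categories, effect_categories, spec)
  nc_df <- if (round_df_nc) to_integer(nc, task_categories) else nc
  N <- solve_N_chisq_independence((nc_df - 1)^2, effect_images, spec)
  ni <- N / nc_df
  n_cat <- to_integer(nc, task_categories)
  n_img <- to_integer(ni, task_images)
  n_batches <- n_cat * n_img / (task_categories * task_images)
  stopifnot(abs(n_batches - round(n_batches)) < 1e-9)
  structure(list(
    raw_nc = nc, raw_ni = ni,
    n_categories = n_cat, images_per_category = n_img,
    n_batches = as.integer(round(n_batches)),
    params = list(total_categories = total_categories,
                  task_categories = task_categories,
                  task_images = task_images,
                  effect_categories = effect_categories,
                  effect_images = effect_images,
                  alpha = spec$alpha, power = spec$power, sides = spec$sides,
                  round_df_nc = round_df_nc)
  ), class = "subsample_design")
}

#' @export
print.subsample_design <- function(x, ...) {
  cat("Powered subsample design\n")
  cat(sprintf("  raw minimal categories nc : %.4f\n", x$raw_nc))
  cat(sprintf("  raw images per category ni: %.4f\n", x$raw_ni))
  cat(sprintf("  categories |C'|           : %d\n", x$n_categories))
  cat(sprintf("  images per category |H'|  : %d\n", x$images_per_category))
  cat(sprintf("  batches |B|               : %d\n", x$n_batches))
  invisible(x)
}

#' Powered population design: observations per image and total subjects
#'
#' Converts the minimum acceptable and expected human classification success
#' probabilities into Cohen's h, solves the binomial-test sample size for the
#' number of observations each image needs, and multiplies by the batch count
#' (each subject works one batch, every image in a batch is seen by every
#' subject assigned to it).
#'
#' @param n_batches Number of batches from [subsample_design()], >= 1.
#' @param p_min Minimum probability of successful human classification that
#'   the study must be able to distinguish, in (0, 1).
#' @param p_est Estimated (expected) probability of successful human
#'   classification, in (0, 1). Must differ from `p_min`.
#' @param spec A [power_spec()]; default one-sided (the binomial consensus
#'   question is directional).
#' @param literal_h If `TRUE`, use `2*asin(p) - 2*asin(p)` without the square
#'   root (a non-standard variant kept for audit); default is Cohen's h.
#' @return A `population_design` list: `effect_h`, `observations_per_image`,
#'   `n_subjects`, plus resolved parameters.
#' @export
#' @examples
#' population_design(4, 0.5, 0.75)
population_design <- function(n_batches, p_min, p_est,
                              spec = power_spec(sides = "one"),
                              literal_h = FALSE) {
  stopifnot(n_batches >= 1, n_batches == round(n_batches))
  if (!(p_min > 0 && p_min < 1 && p_est > 0 && p_est < 1)) {
    stop("p_min and p_est must lie in (0, 1)", call. = FALSE)
  }
  if (p_min == p_est) stop("p_min and p_est must differ", call. = FALSE)
  h <- if (literal_h) {
    structure(abs(2 * asin(p_min) - 2 * asin(p_est)),
              signed = 2 * asin(p_min) - 2 * asin(p_est))
  } else {
    cohen_h(p_min, p_est)
  }
  no <- as.integer(ceiling(solve_n_one_proportion(as.numeric(h), spec)))
  structure(list(
    effect_h = as.numeric(h), effect_h_signed = attr(h, "signed"),
    observations_per_image = no,
    n_subjects = as.integer(n_batches * no),
    params = list(n_batches = as.integer(n_batches), p_min = p_min,
                  p_est = p_est, alpha = spec$alpha, power = spec$power,
                  sides = spec$sides, literal_h = literal_h)
  ), class = "population_design")
}

#' @export
print.population_design <- function(x, ...) {
  cat("Powered population design\n")
  cat(sprintf("  effect size h             : %.4f\n", x$effect_h))
  cat(sprintf("  observations per image no : %d\n", x$observations_per_image))
  cat(sprintf("  total subjects |P|        : %d\n", x$n_subjects))
  invisible(x)
}

#' One-way ANOVA power and total sample size
#'
#' `solve_n_anova()` returns the smallest total sample size `k*n` (balanced
#' design, `n` per group) whose noncentral-F power at effect size `f`
#' (noncentrality `k*n*f^2`) reaches the target. `anova_power()` evaluates
#' the power at a given per-group size.
#'
#' @param k Number of groups, >= 2.
#' @param f Cohen's f effect size, > 0.
#' @param spec A [power_spec()]; sidedness ignored (F test is one-tailed).
#' @return `solve_n_anova()`: integer total sample size.
#' @export
#' @examples
#' solve_n_anova(4, 0.4)            # total subjects needed
#' anova_power(4, 36, 0.4)          # power at 36 per group
solve_n_anova <- function(k, f, spec = power_spec()) {
  stopifnot(k >= 2, f > 0)
  n <- 2L
  repeat {
    if (anova_power(k, n, f, spec) >= spec$power) break
    n <- n + 1L
    if (n > 1e7) stop("ANOVA sample-size search did not converge", call. = FALSE)
  }
  as.integer(k * n)
}

#' @rdname solve_n_anova
#' @param n Per-group sample size, >= 2.
#' @return `anova_power()`: power in \[0, 1\].
#' @export
anova_power <- function(k, n, f, spec = power_spec()) {
  stopifnot(k >= 2, n >= 2, f > 0)
  df1 <- k - 1
  df2 <- k * (n - 1)
  stats::pf(stats::qf(1 - spec$alpha, df1, df2), df1, df2,
            ncp = k * n * f^2, lower.tail = FALSE)
}
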