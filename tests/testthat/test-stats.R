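test_that("spearman matches hand-computed rank correlations", {
  s <- spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(s$estimate, 0.6)   # 1 - 6*sum(d^2)/(n(n^2-1)), d^2 = 4
  expect_equal(spearman(1:10, 2 * (1:10) + 1)$estimate, 1.0)
  expect_equal(spearman(1:10, -(1:10))$estimate, -1.0)
})

test_that("spearman is symmetric and invariant to monotone transforms", {
  set.seed(5)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(spearman(x, y)$estimate, spearman(y, x)$estimate)
  expect_equal(spearman(exp(x), y)$estimate, spearman(x, y)$estimate)
  expect_equal(spearman(x, y^3 + 5)$estimate,
               spearman(x, y)$estimate)
})

test_that("small-sample p-value equals the exact permutation distribution", {
  set.seed(8)
  x <- c(0.3, 1.9, 0.7, 2.5, 1.1, 0.2)
  y <- c(0.5, 1.2, 2.2, 2.0, 0.9, 0.4)
  s <- spearman(x, y)
  # brute-force enumeration over all 720 permutations of y
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  r_null <- vapply(perms(y), function(p) cor(rank(x), rank(p)), 0)
  p_exact <- mean(abs(r_null) >= abs(s$estimate) - 1e-12)
  expect_equal(s$p_value, p_exact, tolerance = 1e-10)
})

test_that("degenerate spearman inputs error", {
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 1:2), "at least 3")
  expect_error(spearman(1:4, 1:5), "lengths")
})

test_that("missing values are handled pairwise-complete", {
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, 4, 5, NA, 7, 9)
  s <- spearman(x, y)
  expect_equal(s$n, 4)
  expect_equal(s$estimate, 1.0)
})

test_that("adjusted model recovers a planted standardized effect", {
  set.seed(42)
  betas <- replicate(400, {
    n <- 26
    x <- rnorm(n)
    d <- data.frame(
      x = x, age_death = rnorm(n, 60, 10),
      sex = sample(c("M", "F"), n, TRUE), pm_interval = rnorm(n, 20, 5))
    d$y <- 0.5 * x + rnorm(n, 0, sqrt(1 - 0.25))
    fit_adjusted_model(d, "y", "x", transform = "none")$estimate
  })
  expect_lt(abs(mean(betas) - 0.5), 0.05)
})

test_that("omitting a planted confounder biases the estimate in the planted direction", {
  set.seed(13)
  n <- 200
  u <- rnorm(n)                      # confounder raises both x and y
  d <- data.frame(x = u + rnorm(n), age_death = 10 * u + rnorm(n),
                  sex = sample(c("M", "F"), n, TRUE),
                  pm_interval = rnorm(n))
  d$y <- 0.8 * u + rnorm(n)          # no direct x effect
  b_adj <- fit_adjusted_model(d, "y", "x", c("age_death"),
                              transform = "none")$estimate
  b_raw <- fit_adjusted_model(d, "y", "x", "pm_interval",
                              transform = "none")$estimate
  expect_gt(b_raw, b_adj + 0.1)
})

test_that("collinear designs raise an error naming aliased terms", {
  set.seed(2)
  d <- data.frame(x = rnorm(30), age_death = rnorm(30),
                  sex = sample(c("M", "F"), 30, TRUE),
                  pm_interval = rnorm(30))
  d$dup <- d$age_death
  d$y <- rnorm(30)
  expect_error(
    fit_adjusted_model(d, "y", "x", c("age_death", "dup"),
                       transform = "none"),
    "collinear")
})

test_that("log transform triggers on skewed outcomes and is recorded", {
  set.seed(3)
  d <- data.frame(x = rnorm(80), age_death = rnorm(80, 60, 8),
                  sex = sample(c("M", "F"), 80, TRUE),
                  pm_interval = rnorm(80, 20, 4))
  d$y <- exp(2 + 1.5 * rnorm(80))
  fit <- fit_adjusted_model(d, "y", "x")
  expect_identical(fit$transform, "log")
  d$y2 <- rnorm(80)
  expect_identical(fit_adjusted_model(d, "y2", "x")$transform, "none")
})

test_that("stratified correlations separate planted genotype-specific structure", {
  make_two_strata <- function(seed) {
    st <- default_strata()[c("DRB15_pos", "DRB15_neg")]
    st$DRB15_pos$spearman["iba1"] <- 0
    st$DRB15_neg$spearman["iba1"] <- 0.74
    simulate_cohort(cohort_config(strata = st), seed = seed)
  }
  gaps <- sapply(1:60, function(s) {
    co <- make_two_strata(s)
    sc <- stratified_correlations(co, "iba1")
    sc$estimate[sc$stratum == "DRB15_neg"] -
      sc$estimate[sc$stratum == "DRB15_pos"]
  })
  expect_gt(mean(gaps), 0.4)
})

test_that("single-level stratifier reproduces the unstratified estimate", {
  co <- simulate_cohort(seed = 21)
  ms_neg <- co[co$genotype == "DRB15_neg", ]
  sc <- stratified_correlations(ms_neg, c("iba1", "cd68"))
  expect_equal(nrow(sc), 2)
  expect_equal(sc$estimate[1],
               spearman(ms_neg$iba1, ms_neg$neuron_density)$estimate)
  expect_equal(nrow(stratified_correlations(co, character(0))), 0)
})

test_that("tiny strata are skipped with a warning", {
  co <- simulate_cohort(seed = 22)
  co$genotype[1:2] <- "rare"
  co <- co[c(1:2, which(co$genotype == "DRB15_neg")), ]
  expect_warning(sc <- stratified_correlations(co, "iba1"), "rare")
  expect_true(all(sc$stratum == "DRB15_neg"))
})

test_that("group contrasts reproduce printed percent differences", {
  mk <- function(means, labels) {
    data.frame(group = rep(labels, each = 4),
               y = c(means[1] + c(-0.01, 0.01, -0.02, 0.02),
                     means[2] + c(-0.01, 0.01, -0.02, 0.02)))
  }
  gc1 <- group_contrast(mk(c(0.348, 0.299), c("control", "MS")), "y",
                        "control", "MS", covariates = NULL)
  expect_equal(gc1$percent_difference, 100 * (0.348 - 0.299) / 0.348)
  expect_equal(round(gc1$percent_difference), 14)
  gc2 <- group_contrast(mk(c(531, 403), c("control", "MS")), "y",
                        "control", "MS", covariates = NULL)
  expect_equal(round(gc2$percent_difference), 24)
  gc3 <- group_contrast(mk(c(432, 376), c("DRB15_neg", "DRB15_pos")), "y",
                        "DRB15_neg", "DRB15_pos", covariates = NULL)
  expect_equal(round(gc3$percent_difference), 13)
})

test_that("identical groups give zero percent difference and p near 1", {
  d <- data.frame(group = rep(c("a", "b"), each = 5), y = rep(1:5, 2))
  gc <- group_contrast(d, "y", "a", "b", covariates = NULL)
  expect_equal(gc$percent_difference, 0)
  expect_gt(gc$adjusted_p, 0.99)
  expect_error(group_contrast(d[d$group == "a", ], "y", "a", "b",
                              covariates = NULL), "absent")
})

test_that("OLS residuals are orthogonal to the design", {
  set.seed(99)
  d <- data.frame(x = rnorm(40), age_death = rnorm(40, 60, 9),
                  sex = sample(c("M", "F"), 40, TRUE),
                  pm_interval = rnorm(40, 20, 6))
  d$y <- 1 + 0.3 * d$x + 0.1 * d$age_death + rnorm(40)
  fit <- lm(scale(y) ~ scale(x) + age_death + (sex == "F") + pm_interval,
            data = d)
  expect_lt(max(abs(crossprod(model.matrix(fit), resid(fit)))), 1e-8)
})
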