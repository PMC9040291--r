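test_that("post hoc families have the right size and adjusted >= raw p", {
  set.seed(101)
  v <- rnorm(60)
  g <- rep(c("CN", "MCI", "AD"), each = 20)
  dn <- anova_posthoc(v, g, correction = "dunnett", reference = "CN")
  expect_identical(nrow(dn$comparisons), 2L)  # k - 1 against reference
  tk <- anova_posthoc(v, g, correction = "tukey")
  expect_identical(nrow(tk$comparisons), 3L)  # k(k-1)/2 pairs
  sk <- anova_posthoc(v, g, correction = "sidak")
  for (r in list(dn, tk, sk)) {
    expect_true(all(r$comparisons$p_adj >= r$comparisons$p_raw - 1e-12))
    expect_true(all(r$comparisons$p_adj >= 0 & r$comparisons$p_adj <= 1))
  }
  expect_error(anova_posthoc(c(rnorm(5), 1), c(rep("a", 5), "b")),
               "singleton group")
})

test_that("zero within-group variance with distinct means is handled", {
  v <- rep(c(1, 2, 3), each = 6)
  g <- rep(c("a", "b", "c"), each = 6)
  res <- suppressWarnings(anova_posthoc(v, g, correction = "tukey"))
  expect_true(all(res$comparisons$p_adj < 1e-6))
})

test_that("two-way ANOVA with Tukey runs on a factorial design", {
  set.seed(7)
  d <- expand.grid(virus = c("null", "M1", "M23"), comp = c("endfoot", "neuropil"),
                   rep = 1:10)
  d$y <- rnorm(nrow(d)) + (d$virus == "M1") * 2.5
  res <- anova_posthoc(d$y, d$virus, d$comp, design = "two_way",
                       correction = "tukey")
  expect_true("group:group2" %in% trimws(rownames(res$f_table)))
  expect_lt(res$comparisons$p_adj[res$comparisons$contrast == "null - M1"],
            0.01)
})

test_that("mixed model needs clusters and reduces to ANOVA without them", {
  expect_error(mixed_model(rnorm(10), data.frame(group = rep(c("a", "b"), 5)),
                           rep("one", 10)), "one cluster")
  # balanced design, no cluster variance: fixed effects match OLS
  set.seed(33)
  d <- data.frame(group = rep(c("wt", "ko"), each = 24),
                  animal = rep(sprintf("a%02d", 1:8), each = 6))
  d$y <- rnorm(48, ifelse(d$group == "ko", 10, 12), 1)
  mm <- suppressMessages(mixed_model(d$y, d["group"], d$animal))
  ols <- stats::lm(y ~ group, data = d)
  expect_equal(unname(lme4::fixef(mm$fit)), unname(stats::coef(ols)),
               tolerance = 1e-6)
  expect_true(all(mm$comparisons$p_adj >= mm$comparisons$p_raw - 1e-12))
})

test_that("mixed model recovers planted variance components", {
  errs <- t(vapply(1:20, function(r) {
    set.seed(500 + r)
    a <- rep(sprintf("c%02d", 1:12), each = 10)
    u <- rnorm(12, 0, 1.0)[as.integer(factor(a))]
    g <- rep(rep(c("x", "y"), 6), each = 10)
    y <- 5 + u + rnorm(120, 0, 0.5)
    mm <- mixed_model(y, data.frame(group = g), a)
    abs(mm$variance_components - c(1.0, 0.5)) / c(1.0, 0.5)
  }, c(cluster_sd = 0, residual_sd = 0)))
  expect_lt(median(errs[, "cluster_sd"]), 0.25)
  expect_lt(median(errs[, "residual_sd"]), 0.25)
})

test_that("regression reports exact fits and the Frisch-Waugh identity", {
  x <- seq(-3, 3, length.out = 25)
  r <- regression_partial(2 * x, x)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  set.seed(55)
  for (rep in 1:5) {
    n <- 40
    z1 <- rnorm(n); z2 <- rnorm(n)
    x <- 0.7 * z1 + rnorm(n)
    y <- 0.5 * x + z1 - 0.3 * z2 + rnorm(n)
    r2 <- regression_partial(y, x, data.frame(z1 = z1, z2 = z2))
    fw <- stats::coef(stats::lm(y_resid ~ x_resid, data = r2$partial))[[2]]
    expect_equal(fw, r2$slope, tolerance = 1e-10)
  }
  expect_error(regression_partial(rnorm(20), rnorm(20),
                                  data.frame(z = rep(1, 20), z2 = rep(2, 20))),
               "collinear|aliased")
})

test_that("controlling for a confounder recovers the planted partial slope", {
  set.seed(66)
  n <- 500
  z <- rnorm(n)
  x <- 0.7 * z + rnorm(n, 0, sqrt(1 - 0.7^2))
  y <- 0.5 * x + 1.2 * z + rnorm(n, 0, 0.5)
  marginal <- regression_partial(y, x)
  partial <- regression_partial(y, x, data.frame(z = z))
  expect_gt(abs(marginal$slope - 0.5), 0.2)   # confounded estimate is biased
  se <- summary(partial$fit)$coefficients["x", 2]
  expect_lt(abs(partial$slope - 0.5), 2.5 * se)
})

test_that("unpaired t handles identical samples and matches the Welch formula", {
  res <- suppressMessages(unpaired_t(c(1, 1, 1), c(1, 1, 1)))
  expect_identical(res$t, 0)
  expect_identical(res$p_value, 1)
  set.seed(77)
  a <- rnorm(15); b <- rnorm(12, 0.4)
  got <- unpaired_t(a, b)
  se <- sqrt(var(a) / 15 + var(b) / 12)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 15)^2 / 14 + (var(b) / 12)^2 / 11)
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$df, df_hand, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-10)
})
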