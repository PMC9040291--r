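#' One- or two-way ANOVA with named post hoc correction
#'
#' Fits the requested ANOVA and computes pairwise post hoc comparisons
#' with the named multiplicity correction: Dunnett (each group against a
#' reference), Tukey (all pairs), or Sidak (all pairs, Sidak-adjusted).
#' Adjusted p-values are never smaller than raw ones. Degenerate inputs
#' with zero within-group variance and distinct means are handled without
#' error (p-values collapse to 0).
#'
#' @param values numeric response.
#' @param groups primary grouping factor.
#' @param groups2 second factor for the two-way design.
#' @param design `"one_way"` or `"two_way"`.
#' @param correction `"dunnett"`, `"tukey"` or `"sidak"`.
#' @param reference reference group label for Dunnett (default: first
#'   factor level).
#' @param na_action missing values are dropped listwise with a message.
#' @return a `StatsResult` list: `model`, `f_table`, `comparisons`
#'   (data.frame `contrast`, `estimate`, `p_raw`, `p_adj`), `group_n`.
#' @export
anova_posthoc <- function(values, groups, groups2 = NULL,
                          design = c("one_way", "two_way"),
                          correction = c("dunnett", "tukey", "sidak"),
                          reference = NULL) {
  design <- match.arg(design)
  correction <- match.arg(correction)
  df <- data.frame(value = values, group = factor(groups))
  if (design == "two_way") {
    stopifnot(!is.null(groups2))
    df$group2 <- factor(groups2)
  }
  n0 <- nrow(df)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < n0) message(sprintf("dropped %d incomplete rows", n0 - nrow(df)))
  tab <- table(df$group)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) {
    stop(sprintf("singleton group(s): %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (!is.null(reference)) {
    df$group <- stats::relevel(df$group, ref = as.character(reference))
  }
  fit <- if (design == "one_way") {
    stats::aov(value ~ group, data = df)
  } else {
    stats::aov(value ~ group * group2, data = df)
  }
  f_table <- summary(fit)[[1L]]

  emm <- emmeans::emmeans(fit, "group")
  raw_method <- if (correction == "dunnett") "trt.vs.ctrl" else "pairwise"
  raw <- as.data.frame(emmeans::contrast(emm, method = raw_method,
                                         adjust = "none"))
  adj <- switch(correction,
    dunnett = {
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
      sm <- summary(gl)
      data.frame(contrast = names(sm$test$coefficients),
                 p_adj = as.numeric(sm$test$pvalues))
    },
    tukey = {
      tk <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                            adjust = "tukey"))
      data.frame(contrast = tk$contrast, p_adj = tk$p.value)
    },
    sidak = {
      sd_ <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                             adjust = "sidak"))
      data.frame(contrast = sd_$contrast, p_adj = sd_$p.value)
    })
  comparisons <- data.frame(contrast = as.character(raw$contrast),
                            estimate = raw$estimate,
                            p_raw = raw$p.value)
  # align by order (glht Dunnett names use " - " like emmeans trt.vs.ctrl)
  comparisons$p_adj <- pmin(pmax(adj$p_adj[
    match(gsub("\\s", "", comparisons$contrast),
          gsub("\\s", "", adj$contrast))], 0), 1)
  comparisons$p_adj <- ifelse(is.na(comparisons$p_adj) & length(adj$p_adj) ==
                                nrow(comparisons),
                              adj$p_adj, comparisons$p_adj)
  comparisons$p_adj <- pmax(comparisons$p_adj, comparisons$p_raw, na.rm = TRUE)
  structure(list(model = sprintf("%s ANOVA, %s post hoc", design, correction),
                 fit = fit, f_table = f_table, comparisons = comparisons,
                 group_n = as.vector(tab), groups = names(tab)),
            class = "StatsResult")
}

#' Mixed-effects model with per-cluster random intercept
#'
#' Fits `value ~ fixed effects + (1 | cluster)` by restricted maximum
#' likelihood, with Satterthwaite denominator degrees of freedom for the
#' fixed-effect tests — the standard treatment for unbalanced nested
#' imaging designs (vessels or ROIs nested in animals or subjects).
#' Post hoc contrasts of the first fixed factor are Sidak-adjusted.
#' Missing values are dropped listwise with a message.
#'
#' @param values numeric response.
#' @param fixed data.frame (or named list) of fixed-effect factors.
#' @param cluster cluster identifier (animal/subject).
#' @return a `StatsResult` list: `fit`, `fixed_tests` (ANOVA table with
#'   Satterthwaite df), `comparisons` (Sidak), `variance_components`
#'   (`cluster_sd`, `residual_sd`), `n_clusters`.
#' @export
mixed_model <- function(values, fixed, cluster) {
  fixed <- as.data.frame(fixed)
  df <- cbind(data.frame(value = values,
                         cluster = factor(cluster)), fixed)
  n0 <- nrow(df)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < n0) message(sprintf("dropped %d incomplete rows", n0 - nrow(df)))
  if (nlevels(droplevels(df$cluster)) < 2) {
    stop("only one cluster: fit a fixed-effects model instead")
  }
  fixed_terms <- paste(names(fixed), collapse = " * ")
  form <- stats::as.formula(sprintf("value ~ %s + (1 | cluster)", fixed_terms))
  fit <- lmerTest::lmer(form, data = df, REML = TRUE)
  fixed_tests <- stats::anova(fit, type = 2, ddf = "Satterthwaite")
  vc <- as.data.frame(lme4::VarCorr(fit))
  cluster_sd <- vc$sdcor[vc$grp == "cluster"][1L]
  residual_sd <- vc$sdcor[vc$grp == "Residual"][1L]
  emm <- emmeans::emmeans(fit, names(fixed)[1L], lmer.df = "satterthwaite")
  cmp <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "sidak"))
  raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  comparisons <- data.frame(contrast = as.character(cmp$contrast),
                            estimate = cmp$estimate,
                            p_raw = raw$p.value,
                            p_adj = pmax(cmp$p.value, raw$p.value))
  structure(list(model = "linear mixed model (REML, Satterthwaite df), Sidak post hoc",
                 fit = fit, fixed_tests = fixed_tests,
                 comparisons = comparisons,
                 variance_components = c(cluster_sd = cluster_sd,
                                         residual_sd = residual_sd),
                 n_clusters = nlevels(droplevels(df$cluster))),
            class = "StatsResult")
}

#' Linear regression with covariate control and partial-regression pairs
#'
#' Ordinary least squares of the response on the predictor plus covariates.
#' Reports the predictor's slope, p-value, the model R-squared and adjusted
#' R-squared, and the partial-regression coordinate pairs (residuals of
#' response ~ covariates against residuals of predictor ~ covariates),
#' whose slope equals the multiple-regression coefficient exactly
#' (Frisch-Waugh).
#'
#' @param response numeric response.
#' @param predictor numeric predictor of interest.
#' @param covariates optional data.frame of covariates to control for.
#' @return a `StatsResult` list: `fit`, `slope`, `p_value`, `r_squared`,
#'   `adj_r_squared`, `partial` (data.frame `x_resid`, `y_resid`), `n`.
#' @export
regression_partial <- function(response, predictor, covariates = NULL) {
  df <- data.frame(y = response, x = predictor)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  n0 <- nrow(df)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < n0) message(sprintf("dropped %d incomplete rows", n0 - nrow(df)))
  p_terms <- ncol(df) - 1L
  if (nrow(df) <= p_terms + 1L) stop("n must exceed number of predictors + 1")
  rhs <- paste(setdiff(names(df), "y"), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
  ali <- stats::alias(fit)
  if (!is.null(ali$Complete)) {
    stop(sprintf("collinear design: %s is aliased",
                 paste(rownames(ali$Complete), collapse = ", ")))
  }
  sm <- summary(fit)
  if (is.null(covariates)) {
    partial <- data.frame(x_resid = df$x - mean(df$x),
                          y_resid = stats::residuals(
                            stats::lm(y ~ 1, data = df)))
  } else {
    cov_rhs <- paste(names(covariates), collapse = " + ")
    ry <- stats::residuals(stats::lm(stats::as.formula(paste("y ~", cov_rhs)),
                                     data = df))
    rx <- stats::residuals(stats::lm(stats::as.formula(paste("x ~", cov_rhs)),
                                     data = df))
    partial <- data.frame(x_resid = rx, y_resid = ry)
  }
  structure(list(model = "OLS with partial-regression output",
                 fit = fit,
                 slope = stats::coef(fit)[["x"]],
                 p_value = sm$coefficients["x", 4L],
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 partial = partial, n = nrow(df)),
            class = "StatsResult")
}

#' Two-sample t-test (Welch by default)
#'
#' Welch's unequal-variance t-test unless `pooled = TRUE`. When both
#' samples have zero variance and equal means the comparison carries no
#' evidence of a difference; by convention t = 0 and p = 1 are returned
#' with a message.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param pooled use the pooled-variance (Student) test.
#' @return a `StatsResult` list: `t`, `df`, `p_value`, `estimate`
#'   (mean difference a - b), `conf_int`, `n`.
#' @export
unpaired_t <- function(a, b, pooled = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      message("both samples constant and equal: returning t = 0, p = 1")
      return(structure(list(model = "unpaired t (degenerate)", t = 0,
                            df = length(a) + length(b) - 2, p_value = 1,
                            estimate = 0, conf_int = c(0, 0),
                            n = c(length(a), length(b))),
                       class = "StatsResult"))
    }
    stop("both samples constant with different means: t is infinite")
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  structure(list(model = if (pooled) "unpaired t (pooled)" else "unpaired t (Welch)",
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 estimate = unname(diff(rev(ht$estimate))),
                 conf_int = as.numeric(ht$conf.int),
                 n = c(length(a), length(b))),
            class = "StatsResult")
}

#' @export
print.StatsResult <- function(x, ...) {
  cat("<StatsResult>", x$model, "\n")
  if (!is.null(x$comparisons)) print(x$comparisons)
  if (!is.null(x$p_value)) cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}
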