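#' Press-level vigor versus dopamine regression
#'
#' Ordinary least squares of a per-press vigor metric on the instantaneous
#' DA signal, with the Pearson correlation coefficient and the F-test
#' p-value for the slope differing from zero.
#'
#' @param x per-press DA values.
#' @param y per-press vigor values (peak velocity or amplitude).
#' @return List: `slope`, `intercept`, `r`, `p_slope`, `n`.
#' @export
vigor_da_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop_pv("pressvigor_error_input", "need >= 3 paired finite observations")
  if (sd(x) == 0)
    stop_pv("pressvigor_error_degenerate",
            "x is constant; correlation undefined")
  fit <- lm(y ~ x)
  a <- anova(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(x, y), p_slope = a$`Pr(>F)`[1], n = length(x))
}

#' Mixed-effects contrast of manipulation versus sham sessions
#'
#' Fits `value ~ 1 + session_type + (1 | mouse) + (1 | mouse:session)` by
#' REML, where `session` is the within-mouse session number pairing the k-th
#' manipulation session with the k-th sham session. The manipulation effect
#' is the fixed-effect coefficient, with a Satterthwaite-approximation
#' p-value. Singular fits (a variance component at zero) are flagged but the
#' estimate is still returned.
#'
#' @param table data frame with columns `mouse_id`, `session_number`,
#'   `session_type` (2 levels; the second level is the manipulation) and
#'   `value`.
#' @return List: `estimate`, `se`, `df`, `p`, `singular`, `levels`.
#' @export
mixed_effect_contrast <- function(table) {
  req <- c("mouse_id", "session_number", "session_type", "value")
  if (!all(req %in% names(table)))
    stop_pv("pressvigor_error_input",
            paste("table needs columns:", paste(req, collapse = ", ")))
  table$mouse_id <- factor(table$mouse_id)
  table$session_number <- factor(table$session_number)
  table$session_type <- factor(table$session_type)
  ref <- intersect(c("sham", "control"), levels(table$session_type))
  if (length(ref))
    table$session_type <- stats::relevel(table$session_type, ref[1])
  if (nlevels(table$mouse_id) < 2 || nlevels(table$session_type) < 2)
    stop_pv("pressvigor_error_input",
            "need >= 2 mice and >= 2 session types")
  fit <- suppressWarnings(suppressMessages(lmerTest::lmer(
    value ~ session_type + (1 | mouse_id) + (1 | mouse_id:session_number),
    data = table, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))))
  co <- summary(fit)$coefficients
  list(estimate = co[2, "Estimate"], se = co[2, "Std. Error"],
       df = co[2, "df"], p = co[2, "Pr(>|t|)"],
       singular = lme4::isSingular(fit),
       levels = levels(table$session_type))
}

#' Normality-gated two-group comparison
#'
#' Implements the test-selection policy: normality is assessed with the
#' Shapiro-Wilk test at alpha = 0.05 (on the paired differences, or on each
#' group for unpaired data). Normal data are compared with a t-test (paired,
#' or Welch-corrected two-sample); non-normal data with the Wilcoxon
#' signed-rank (paired) or Mann-Whitney (unpaired) test. All tests two-sided.
#'
#' @param x first sample.
#' @param y second sample (same length as `x` if `paired`).
#' @param paired paired comparison?
#' @param alpha_normality Shapiro-Wilk gate level.
#' @return List: `branch` ("parametric"/"nonparametric"), `test`, `p`,
#'   `estimate` (mean difference / difference of means), `normality_p`.
#' @export
choose_test <- function(x, y, paired = FALSE, alpha_normality = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3)
    stop_pv("pressvigor_error_input", "group sizes must be >= 3")
  if (paired && length(x) != length(y))
    stop_pv("pressvigor_error_input", "paired samples must have equal length")
  est <- if (paired) mean(x - y) else mean(x) - mean(y)
  degenerate <- if (paired) sd(x - y) == 0 else (sd(x) == 0 && sd(y) == 0)
  if (degenerate) {
    return(list(branch = "degenerate", test = "none",
                p = if (est == 0) 1 else 0, estimate = est,
                normality_p = NA_real_))
  }
  shapiro_ok <- function(v) {
    if (sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value
  }
  if (paired) {
    np <- shapiro.test(x - y)$p.value
    normal <- np >= alpha_normality
  } else {
    p1 <- shapiro_ok(x); p2 <- shapiro_ok(y)
    np <- min(as.numeric(p1), as.numeric(p2))
    normal <- !isFALSE(p1) && !isFALSE(p2) && np >= alpha_normality
  }
  if (normal) {
    tt <- t.test(x, y, paired = paired, var.equal = FALSE)
    list(branch = "parametric",
         test = if (paired) "paired t-test" else "Welch two-sample t-test",
         p = tt$p.value, estimate = est, normality_p = np)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, paired = paired, exact = FALSE))
    list(branch = "nonparametric",
         test = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney",
         p = wt$p.value, estimate = est, normality_p = np)
  }
}

#' Repeated-measures omnibus test with many-to-one comparisons
#'
#' Omnibus test across >= 3 conditions measured repeatedly in the same mice,
#' followed by Dunnett-style comparisons of every condition against a
#' designated reference with familywise-error control (single-step
#' multivariate-t adjustment on the mixed-model fit, which also covers
#' unbalanced designs with missing cells).
#'
#' @param df data frame with columns `mouse_id`, `condition`, `value`.
#' @param reference reference condition label.
#' @return List: `omnibus_p`, `omnibus_method` ("rm_anova" for balanced
#'   designs, "mixed_model" otherwise), `comparisons` (data frame of
#'   condition, estimate, p_adjusted), `balanced`.
#' @export
multi_group_contrast <- function(df, reference) {
  req <- c("mouse_id", "condition", "value")
  if (!all(req %in% names(df)))
    stop_pv("pressvigor_error_input",
            paste("df needs columns:", paste(req, collapse = ", ")))
  df <- df[is.finite(df$value), ]
  df$mouse_id <- factor(df$mouse_id)
  conds <- unique(as.character(df$condition))
  if (length(conds) < 3)
    stop_pv("pressvigor_error_input", "need >= 3 conditions")
  if (!reference %in% conds)
    stop_pv("pressvigor_error_input", "reference condition not present")
  df$condition <- factor(df$condition,
                         levels = c(reference, setdiff(conds, reference)))
  tab <- table(df$mouse_id, df$condition)
  balanced <- all(tab == 1)
  if (balanced) {
    fit_aov <- aov(value ~ condition + Error(mouse_id), data = df)
    s <- summary(fit_aov)
    omnibus_p <- s[["Error: Within"]][[1]][["Pr(>F)"]][1]
    method <- "rm_anova"
  } else {
    fit_l <- suppressMessages(lmerTest::lmer(
      value ~ condition + (1 | mouse_id), data = df,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    omnibus_p <- anova(fit_l)[["Pr(>F)"]][1]
    method <- "mixed_model"
  }
  fit_mm <- suppressMessages(lme4::lmer(
    value ~ condition + (1 | mouse_id), data = df,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  gl <- multcomp::glht(fit_mm, linfct = multcomp::mcp(condition = "Dunnett"))
  sgl <- summary(gl)
  comparisons <- data.frame(
    condition = sub(" - .*$", "", names(sgl$test$coefficients)),
    estimate = as.numeric(sgl$test$coefficients),
    p_adjusted = as.numeric(sgl$test$pvalues))
  list(omnibus_p = omnibus_p, omnibus_method = method,
       comparisons = comparisons, balanced = balanced)
}
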