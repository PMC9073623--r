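## Group-comparison statistics: normality-gated two- and three-group tests,
## the three-condition linear mixed model with FDR-adjusted post hocs, and
## gated correlations. The normality gate (Shapiro-Wilk per sample) and the
## Welch t default are recorded in every result so the chosen path is
## auditable.

sample_is_normal <- function(x, alpha) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(unique(x)) < 3) return(FALSE)
  p <- tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  p > alpha
}

#' Two-group comparison with a normality gate
#'
#' Welch two-sample t test when both samples pass a Shapiro-Wilk check at
#' `normality_alpha`, otherwise a two-sided Wilcoxon rank-sum test.
#'
#' @param x,y Numeric samples (NAs dropped; each needs >= 3 values).
#' @param normality_alpha Gate level.
#' @param variable Optional label carried into the result.
#' @return One-row tibble: test used, statistic, p, per-group mean/SD/n, and
#'   whether the normal path fired.
#' @export
compare_two_groups <- function(x, y, normality_alpha = 0.05,
                               variable = NA_character_) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    gm_log("info", "two-group comparison skipped: fewer than 3 values")
    return(tibble::tibble(variable = variable, test = NA_character_,
                          statistic = NA_real_, p = NA_real_,
                          mean_x = NA_real_, sd_x = NA_real_,
                          mean_y = NA_real_, sd_y = NA_real_,
                          n_x = length(x), n_y = length(y),
                          normal_gate = NA))
  }
  normal <- sample_is_normal(x, normality_alpha) &&
    sample_is_normal(y, normality_alpha)
  if (normal) {
    ht <- t.test(x, y)
    test <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y))
    test <- "wilcoxon"
  }
  tibble::tibble(variable = variable, test = test,
                 statistic = unname(ht$statistic), p = ht$p.value,
                 mean_x = mean(x), sd_x = sd(x),
                 mean_y = mean(y), sd_y = sd(y),
                 n_x = length(x), n_y = length(y),
                 normal_gate = normal)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving and
#' idempotent.
#'
#' @param p Vector of p values between 0 and 1.
#' @return Adjusted p values.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Three-group comparison with a normality gate and post hocs
#'
#' One-way ANOVA when every group passes the Shapiro-Wilk check, otherwise
#' Kruskal-Wallis. When the omnibus test is significant at `alpha`, pairwise
#' post hocs in the matching family (Welch t / Wilcoxon rank-sum) are run and
#' FDR-adjusted.
#'
#' @param samples Named list of >= 3-value numeric vectors (3 groups).
#' @param alpha Omnibus significance level gating the post hocs.
#' @param normality_alpha Gate level.
#' @param variable Optional label.
#' @return List: `omnibus` (one-row tibble) and `posthoc` (tibble, possibly
#'   empty). Groups of fewer than 3 values skip the comparison with a reason.
#' @export
compare_three_groups <- function(samples, alpha = 0.05,
                                 normality_alpha = 0.05,
                                 variable = NA_character_) {
  samples <- lapply(samples, function(v) v[!is.na(v)])
  sizes <- vapply(samples, length, 0L)
  if (any(sizes < 3)) {
    gm_log("info", sprintf("three-group comparison skipped (%s): group < 3",
                           variable))
    return(list(omnibus = tibble::tibble(
      variable = variable, test = NA_character_, statistic = NA_real_,
      p = NA_real_, normal_gate = NA,
      note = "skipped: group with fewer than 3 values"),
      posthoc = tibble::tibble()))
  }
  normal <- all(vapply(samples, sample_is_normal, TRUE,
                       alpha = normality_alpha))
  long <- data.frame(
    value = unlist(samples, use.names = FALSE),
    group = factor(rep(names(samples), sizes), levels = names(samples)))
  if (normal) {
    fit <- aov(value ~ group, data = long)
    an <- anova(fit)
    omnibus <- tibble::tibble(variable = variable, test = "anova",
                              statistic = an$`F value`[1],
                              p = an$`Pr(>F)`[1], normal_gate = TRUE,
                              note = NA_character_)
  } else {
    kw <- kruskal.test(value ~ group, data = long)
    omnibus <- tibble::tibble(variable = variable, test = "kruskal_wallis",
                              statistic = unname(kw$statistic),
                              p = kw$p.value, normal_gate = FALSE,
                              note = NA_character_)
  }
  posthoc <- tibble::tibble()
  if (!is.na(omnibus$p) && omnibus$p < alpha) {
    prs <- utils::combn(names(samples), 2, simplify = FALSE)
    rows <- lapply(prs, function(pr) {
      a <- samples[[pr[1]]]; b <- samples[[pr[2]]]
      ht <- if (normal) t.test(a, b)
        else suppressWarnings(wilcox.test(a, b))
      tibble::tibble(variable = variable,
                     contrast = paste(pr, collapse = " - "),
                     test = if (normal) "t" else "wilcoxon",
                     statistic = unname(ht$statistic), p_raw = ht$p.value)
    })
    posthoc <- dplyr::bind_rows(rows)
    posthoc$p_adj <- fdr_adjust(posthoc$p_raw)
  }
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Three-condition linear mixed model with FDR post hocs
#'
#' Fits `value ~ condition + (1 | participant)` by REML: condition is the
#' fixed between/within factor (control all / patient accompanied / patient
#' alone) and the participant random intercept carries the dependence between
#' the two patient conditions. The omnibus test is the Satterthwaite F test
#' on the condition term; the three pairwise contrasts (estimated marginal
#' means) are FDR-adjusted. A singular fit (zero between-participant
#' variance) falls back to ordinary least squares with a logged warning.
#'
#' @param data Data frame with `participant`, `condition`, `value`.
#' @param variable Optional label.
#' @return List: `omnibus` (one-row tibble with F, df, p, method) and
#'   `pairwise` (tibble of contrasts with raw and adjusted p).
#' @export
fit_three_condition_mixed_model <- function(data, variable = NA_character_) {
  data <- data[!is.na(data$value), , drop = FALSE]
  data$condition <- factor(data$condition)
  data$participant <- factor(data$participant)
  tab <- table(data$condition)
  if (sum(tab >= 3) < 2)
    stop("need at least 2 conditions with 3 or more rows", call. = FALSE)
  if (sd(data$value) < 1e-12) {
    # constant response: nothing to explain
    omnibus <- tibble::tibble(variable = variable, method = "degenerate",
                              f_value = 0, df1 = nlevels(data$condition) - 1L,
                              df2 = NA_real_, p = 1)
    pairwise <- tibble::tibble(
      variable = variable,
      contrast = apply(utils::combn(levels(data$condition), 2), 2,
                       paste, collapse = " - "),
      estimate = 0, p_raw = 1, p_adj = 1)
    return(list(omnibus = omnibus, pairwise = pairwise))
  }
  fit <- withCallingHandlers(
    lmerTest::lmer(value ~ condition + (1 | participant), data = data,
                   REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = lme4::.makeCC(
                       action = "ignore", tol = 1e-4))),
    warning = function(w) {
      # small-sample convergence chatter; the singular/degenerate paths below
      # handle the cases that matter
      gm_log("debug", sprintf("lmer (%s): %s", variable,
                              conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    gm_log("warning", sprintf(
      "mixed model singular (%s): falling back to ordinary least squares",
      variable))
    fit_ols <- lm(value ~ condition, data = data)
    an <- anova(fit_ols)
    omnibus <- tibble::tibble(variable = variable, method = "ols_fallback",
                              f_value = an$`F value`[1],
                              df1 = an$Df[1], df2 = an$Df[2],
                              p = an$`Pr(>F)`[1])
    emm <- emmeans::emmeans(fit_ols, "condition")
  } else {
    an <- anova(fit) # Satterthwaite by default in lmerTest
    omnibus <- tibble::tibble(variable = variable, method = "mixed_model_F",
                              f_value = an$`F value`[1],
                              df1 = an$NumDF[1], df2 = an$DenDF[1],
                              p = an$`Pr(>F)`[1])
    emm <- emmeans::emmeans(fit, "condition")
  }
  prs <- summary(emmeans::contrast(emm, "pairwise"), adjust = "none")
  pairwise <- tibble::tibble(variable = variable,
                             contrast = as.character(prs$contrast),
                             estimate = prs$estimate,
                             p_raw = prs$p.value,
                             p_adj = fdr_adjust(prs$p.value))
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Correlation with a normality gate
#'
#' Pearson when both variables pass the Shapiro-Wilk check at
#' `normality_alpha`, else Spearman; two-sided.
#'
#' @param x,y Paired numeric vectors (pairwise-complete; n >= 4).
#' @param normality_alpha Gate level.
#' @param variable Optional label.
#' @return One-row tibble: method, coefficient, p, n.
#' @export
correlate <- function(x, y, normality_alpha = 0.05,
                      variable = NA_character_) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined for constant input", call. = FALSE)
  normal <- sample_is_normal(x, normality_alpha) &&
    sample_is_normal(y, normality_alpha)
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(variable = variable, method = method,
                 coefficient = unname(ct$estimate), p = ct$p.value,
                 n = length(x))
}
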