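# Group-level inference: one-way ANOVA, pooled t-tests with Cohen's d,
# ANCOVA, 2x2 mixed ANOVA, and the JZS / unit-information Bayes-factor
# t-test. Every function returns a one-row (or few-row) "inference_result"
# data.frame: name, statistic, df1, df2, p, effect_size, bf01.

inference_result <- function(name, statistic, df1, df2 = NA_real_, p = NA_real_,
                             effect_size = NA_real_, bf01 = NA_real_) {
  structure(data.frame(name = name, statistic = statistic, df1 = df1,
                       df2 = df2, p = p, effect_size = effect_size,
                       bf01 = bf01, stringsAsFactors = FALSE),
            class = c("inference_result", "data.frame"))
}

#' @export
print.inference_result <- function(x, digits = 3, ...) {
  for (i in seq_len(nrow(x))) {
    df <- if (is.na(x$df2[i])) sprintf("%g", x$df1[i])
          else sprintf("%g,%g", x$df1[i], x$df2[i])
    extra <- character(0)
    if (!is.na(x$effect_size[i]))
      extra <- c(extra, sprintf("effect = %.*f", digits, x$effect_size[i]))
    if (!is.na(x$bf01[i]))
      extra <- c(extra, sprintf("BF01 = %.*f", digits, x$bf01[i]))
    cat(sprintf("%s: stat(%s) = %.*f, p = %.4g%s\n", x$name[i], df,
                digits, x$statistic[i], x$p[i],
                if (length(extra)) paste0(", ", paste(extra, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' One-way between-subjects ANOVA
#'
#' Classical fixed-effects F-test of a group difference in a per-subject
#' metric, with eta-squared = SS_between / SS_total as effect size.
#'
#' @param values Numeric vector of per-subject values.
#' @param group Group labels (coerced to factor). Missing values are dropped
#'   pairwise.
#' @param name Label for the comparison.
#' @return An \code{"inference_result"} row.
#' @export
one_way_anova <- function(values, group, name = "one-way ANOVA") {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- factor(group[keep])
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 subjects")
  fit <- stats::lm(values ~ group)
  a <- stats::anova(fit)
  ss_b <- a$`Sum Sq`[1]; ss_tot <- sum(a$`Sum Sq`)
  inference_result(name, statistic = a$`F value`[1],
                   df1 = a$Df[1], df2 = a$Df[2], p = a$`Pr(>F)`[1],
                   effect_size = ss_b / ss_tot)
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Student's t with pooled variance (df = n1 + n2 - 2), two-sided, and
#' Cohen's d = mean difference / pooled SD.
#'
#' @param a,b Numeric samples (each n >= 2; NAs dropped).
#' @param name Label for the comparison.
#' @return An \code{"inference_result"} row.
#' @export
two_sample_t <- function(a, b, name = "two-sample t") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled variance: t-test degenerate")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  inference_result(name, statistic = unname(tt$statistic),
                   df1 = unname(tt$parameter), p = tt$p.value,
                   effect_size = (mean(a) - mean(b)) / sqrt(sp2))
}

#' ANCOVA: adjusted group effect with continuous covariates
#'
#' Fits \code{values ~ group + covariates} and reports the partial F for the
#' group factor (full model vs. the model without group, covariates
#' retained), with eta-squared = SS_group / SS_total.
#'
#' @param values Numeric per-subject outcome.
#' @param group Group labels.
#' @param covariates Named list or data.frame of numeric covariate columns
#'   (complete cases required).
#' @param name Label for the comparison.
#' @return An \code{"inference_result"} row.
#' @export
ancova_group_effect <- function(values, group, covariates,
                                name = "ANCOVA group effect") {
  covariates <- as.data.frame(covariates)
  dat <- data.frame(.y = values, .g = factor(group), covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= nlevels(dat$.g) + ncol(covariates))
    stop("not enough complete cases for the ANCOVA design")
  full <- stats::lm(.y ~ ., data = dat[, c(".y", ".g", names(covariates))])
  if (full$rank < length(stats::coef(full))) {
    bad <- names(which(is.na(stats::coef(full))))
    stop("rank-deficient ANCOVA design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  reduced <- stats::lm(.y ~ ., data = dat[, c(".y", names(covariates)),
                                          drop = FALSE])
  cmp <- stats::anova(reduced, full)
  ss_group <- cmp$`Sum of Sq`[2]
  ss_total <- sum((dat$.y - mean(dat$.y))^2)
  inference_result(name, statistic = cmp$F[2], df1 = cmp$Df[2],
                   df2 = cmp$Res.Df[2], p = cmp$`Pr(>F)`[2],
                   effect_size = ss_group / ss_total)
}

#' 2 x 2 mixed ANOVA on conditional confidence
#'
#' Two groups (between-subjects) by correctness (within-subjects) ANOVA on
#' per-subject median confidence for correct and error trials, computed from
#' the sums-of-squares decomposition: the group effect is tested against
#' subjects-within-groups, the correctness effect and the interaction
#' against the correctness-by-subject residual. Eta-squared for each effect
#' is SS_effect / SS_total.
#'
#' @param conf_correct,conf_error Per-subject median confidence on correct
#'   and on error trials (same subject order; complete cases required).
#' @param group Group labels, exactly two levels.
#' @return An \code{"inference_result"} with three rows: group main effect,
#'   correctness main effect, group-by-correctness interaction.
#' @export
mixed_anova_confidence <- function(conf_correct, conf_error, group) {
  keep <- !is.na(conf_correct) & !is.na(conf_error) & !is.na(group)
  conf_correct <- conf_correct[keep]; conf_error <- conf_error[keep]
  group <- factor(group[keep])
  if (nlevels(group) != 2) stop("exactly two groups required")
  n <- length(conf_correct)
  if (n < 4) stop("too few subjects for the mixed design")

  subj <- factor(seq_len(n))
  long <- data.frame(
    y = c(conf_correct, conf_error),
    subject = rep(subj, 2),
    g = rep(group, 2),
    w = factor(rep(c("correct", "error"), each = n)))

  grand <- mean(long$y)
  ss_total <- sum((long$y - grand)^2)
  subj_mean <- (conf_correct + conf_error) / 2
  g_mean <- tapply(subj_mean, group, mean)
  n_g <- table(group)
  ss_between_subj <- 2 * sum((subj_mean - grand)^2)
  ss_group <- 2 * sum(n_g * (g_mean - grand)^2)
  ss_subj_in_g <- ss_between_subj - ss_group

  w_mean <- tapply(long$y, long$w, mean)
  ss_w <- n * sum((w_mean - grand)^2)
  cell_mean <- tapply(long$y, list(long$g, long$w), mean)
  ss_cells <- sum(rep(n_g, 2) * (as.vector(cell_mean) - grand)^2)
  ss_gw <- ss_cells - ss_group - ss_w
  ss_w_resid <- ss_total - ss_between_subj - ss_w - ss_gw

  df_g <- 1; df_subj <- n - 2; df_w <- 1; df_gw <- 1; df_wr <- n - 2
  f_g <- (ss_group / df_g) / (ss_subj_in_g / df_subj)
  f_w <- (ss_w / df_w) / (ss_w_resid / df_wr)
  f_gw <- (ss_gw / df_gw) / (ss_w_resid / df_wr)

  rbind(
    inference_result("group main effect", f_g, df_g, df_subj,
                     stats::pf(f_g, df_g, df_subj, lower.tail = FALSE),
                     ss_group / ss_total),
    inference_result("correctness main effect", f_w, df_w, df_wr,
                     stats::pf(f_w, df_w, df_wr, lower.tail = FALSE),
                     ss_w / ss_total),
    inference_result("group x correctness interaction", f_gw, df_gw, df_wr,
                     stats::pf(f_gw, df_gw, df_wr, lower.tail = FALSE),
                     ss_gw / ss_total))
}

# JZS two-sample BF10 for a given t statistic: marginal likelihood ratio of
# the alternative (Cauchy(0, r) prior on the standardized effect, i.e. an
# inverse-gamma(1/2, r^2/2) mixture over the scaling g) to the point null.
jzs_bf10_t <- function(t, n1, n2, r_scale, rel.tol = 1e-10) {
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  null_lik <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  # substitute g = r^2 q so the prior becomes scale-free in q and the
  # integrand keeps its mass near q ~ 1 for any prior scale
  integrand <- function(q) {
    ng <- n_eff * r_scale^2 * q
    (1 + ng)^(-0.5) *
      (1 + t^2 / ((1 + ng) * nu))^(-(nu + 1) / 2) *
      q^(-1.5) * exp(-1 / (2 * q)) / sqrt(2 * pi)
  }
  alt_lik <- stats::integrate(integrand, 0, Inf, rel.tol = rel.tol,
                              abs.tol = 0)$value
  alt_lik / null_lik
}

# normal unit-information variant: effect-size prior delta ~ N(0, r^2)
# (g fixed at r^2 rather than mixed over)
normal_bf10_t <- function(t, n1, n2, r_scale) {
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  g <- r_scale^2
  ((1 + n_eff * g)^(-0.5) *
     (1 + t^2 / ((1 + n_eff * g) * nu))^(-(nu + 1) / 2)) /
    (1 + t^2 / nu)^(-(nu + 1) / 2)
}

#' Bayes-factor two-sample t-test (JZS / unit-information)
#'
#' Computes the evidence for the null hypothesis of no group difference,
#' BF01, from the two-sample t statistic. The default prior on the
#' standardized effect size is the JZS Cauchy with scale \code{r_scale}
#' (the scale-1 setting is the classical unit-information choice); the
#' marginal likelihood under the alternative is evaluated by adaptive
#' quadrature of the t-statistic integral over the variance-scaling mixture
#' (relative tolerance 1e-10). BF01 > 3 is conventionally read as moderate
#' evidence for the null.
#'
#' @param a,b Numeric samples (each n >= 2; NAs dropped).
#' @param r_scale Prior scale on the standardized effect (default 1).
#' @param prior \code{"cauchy"} (JZS, default) or \code{"normal"}
#'   (unit-information normal with SD \code{r_scale}).
#' @param name Label for the comparison.
#' @return An \code{"inference_result"} row; \code{statistic} is the pooled
#'   t, \code{bf01} the evidence for the null.
#' @export
bayes_factor_t <- function(a, b, r_scale = 1,
                           prior = c("cauchy", "normal"),
                           name = "Bayesian two-sample t") {
  prior <- match.arg(prior)
  if (r_scale <= 0) stop("r_scale must be positive")
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  tt <- two_sample_t(a, b, name = name)
  bf10 <- switch(prior,
                 cauchy = jzs_bf10_t(tt$statistic, length(a), length(b),
                                     r_scale),
                 normal = normal_bf10_t(tt$statistic, length(a), length(b),
                                        r_scale))
  tt$bf01 <- 1 / bf10
  tt
}
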