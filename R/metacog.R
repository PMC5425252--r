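# Main analysis entry point: trial table in, classed analysis object out.

#' Metacognition analysis of a confidence-rating discrimination task
#'
#' Runs the full analysis on a per-trial table: trial-level exclusions
#' (first block, anticipatory/late/missing responses), boxplot-based
#' exclusion of low-accuracy outlier subjects, per-subject equal-count
#' confidence binning, per-subject type-I (d', criterion c) and type-II
#' (AUROC2) signal-detection metrics, and the group-level test battery —
#' one-way ANOVAs on AUROC2 and on the perceptual-control measures
#' (accuracy, signal strength, RT, d', c, median confidence), pairwise
#' pooled t-tests with Cohen's d on AUROC2, an ANCOVA adjusting the AUROC2
#' group effect for d', c and signal strength, a 2 x 2 group-by-correctness
#' mixed ANOVA on conditional median confidence, and a Bayes-factor t-test
#' quantifying evidence for no group difference.
#'
#' @param trials Per-trial data.frame (see [read_trial_table()] for the
#'   schema; [simulate_cohort()] produces it directly).
#' @param n_bins Confidence bins per subject (default 6).
#' @param rt_bounds Inclusive RT window, ms (default \code{c(100, 1500)}).
#' @param drop_first_block Drop block-1 trials before analysis
#'   (default TRUE).
#' @param outlier_rule \code{"lower_fence_1p5"} (flag subjects with accuracy
#'   below Q1 - 1.5 IQR, default) or \code{"none"}.
#' @param mixed_pair Two group labels contrasted in the group-by-correctness
#'   mixed ANOVA and in the conditional-confidence t-tests; skipped when
#'   absent from the data.
#' @param bf_pair Two group labels contrasted in the Bayes-factor t-test on
#'   AUROC2; skipped when absent.
#' @param bf_r_scale Prior scale for the Bayes factor (default 1).
#' @return Object of class \code{"metacog"} with components \code{subjects}
#'   (per-subject summary table), \code{tests} (inference results),
#'   \code{trials} (filtered trials with \code{confidence_bin}),
#'   \code{exclusions} (trial/subject exclusion report), and \code{config}.
#' @examples
#' trials <- simulate_cohort(cohort_spec(n_per_group = 8, seed = 42))
#' fit <- metacog(trials)
#' summary(fit)
#' @export
metacog <- function(trials, n_bins = 6, rt_bounds = c(100, 1500),
                    drop_first_block = TRUE,
                    outlier_rule = c("lower_fence_1p5", "none"),
                    mixed_pair = c("placebo", "propranolol"),
                    bf_pair = c("placebo", "amisulpride"),
                    bf_r_scale = 1) {
  outlier_rule <- match.arg(outlier_rule)
  cl <- match.call()
  need <- c("subject_id", "group", "block", "mean_orientation_deg",
            "stimulus_direction", "response", "correct", "rt_ms",
            "confidence")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))

  excl <- exclude_trials(trials, rt_bounds, drop_first_block)
  filtered <- excl$trials
  if (nrow(filtered) == 0) stop("no trials remain after exclusion")

  # subject-level outlier pass on accuracy, before any metric computation
  acc <- tapply(filtered$correct, filtered$subject_id, mean)
  if (outlier_rule == "lower_fence_1p5" && length(acc) >= 4) {
    out_ids <- detect_outlier_subjects(acc)
    if (length(out_ids)) {
      excl$report$excluded_subjects <-
        stats::setNames(as.list(rep("accuracy below lower Tukey fence",
                                    length(out_ids))), out_ids)
      filtered <- filtered[!(filtered$subject_id %in% out_ids), ,
                           drop = FALSE]
    }
  }

  # per-subject binning + summaries
  parts <- split(filtered, filtered$subject_id)
  parts <- lapply(parts, function(tt) {
    tt$confidence_bin <- bin_confidence(tt$confidence, n_bins)
    tt
  })
  filtered <- do.call(rbind, parts)
  rownames(filtered) <- NULL
  subjects <- do.call(rbind, lapply(parts, summarise_subject))
  rownames(subjects) <- NULL
  subjects <- subjects[order(subjects$group, subjects$subject_id), ,
                       drop = FALSE]

  tests <- group_inference(subjects, mixed_pair, bf_pair, bf_r_scale)

  structure(list(subjects = subjects, tests = tests, trials = filtered,
                 exclusions = excl$report,
                 config = list(n_bins = n_bins, rt_bounds = rt_bounds,
                               drop_first_block = drop_first_block,
                               outlier_rule = outlier_rule,
                               mixed_pair = mixed_pair, bf_pair = bf_pair,
                               bf_r_scale = bf_r_scale),
                 call = cl),
            class = "metacog")
}

# the group-level test battery; skips contrasts whose groups are absent
group_inference <- function(subjects, mixed_pair, bf_pair, bf_r_scale) {
  groups <- unique(subjects$group)
  res <- list()
  if (length(groups) >= 2 && all(table(subjects$group) >= 2)) {
    res <- c(res, list(
      one_way_anova(subjects$auroc2, subjects$group, "AUROC2 ~ group"),
      one_way_anova(subjects$accuracy, subjects$group, "accuracy ~ group"),
      one_way_anova(subjects$mean_orientation_deg, subjects$group,
                    "mean orientation ~ group"),
      one_way_anova(subjects$median_rt_ms, subjects$group,
                    "median RT ~ group"),
      one_way_anova(subjects$dprime, subjects$group, "d' ~ group"),
      one_way_anova(subjects$c, subjects$group, "criterion c ~ group"),
      one_way_anova(subjects$median_confidence, subjects$group,
                    "median confidence ~ group")))
    ok <- stats::complete.cases(subjects[, c("auroc2", "dprime", "c",
                                             "mean_orientation_deg")])
    res <- c(res, list(ancova_group_effect(
      subjects$auroc2[ok], subjects$group[ok],
      list(dprime = subjects$dprime[ok], c = subjects$c[ok],
           mean_orientation = subjects$mean_orientation_deg[ok]),
      "AUROC2 ~ group + d' + c + orientation (ANCOVA)")))
    for (pair in utils::combn(sort(groups), 2, simplify = FALSE)) {
      sel <- function(g) subjects$auroc2[subjects$group == g]
      res <- c(res, list(two_sample_t(
        sel(pair[1]), sel(pair[2]),
        sprintf("AUROC2: %s vs %s", pair[1], pair[2]))))
    }
  }
  pair_n <- function(pair) {
    if (!all(pair %in% groups)) return(0L)
    min(table(factor(subjects$group[subjects$group %in% pair])))
  }
  if (pair_n(mixed_pair) >= 2) {
    sub2 <- subjects[subjects$group %in% mixed_pair, , drop = FALSE]
    res <- c(res, list(
      within_pair(mixed_anova_confidence(sub2$median_confidence_correct,
                                         sub2$median_confidence_error,
                                         sub2$group),
                  "median confidence [%s vs %s]", mixed_pair)))
    sel <- function(g, col) sub2[[col]][sub2$group == g]
    res <- c(res, list(
      two_sample_t(sel(mixed_pair[1], "median_confidence_correct"),
                   sel(mixed_pair[2], "median_confidence_correct"),
                   sprintf("correct-trial confidence: %s vs %s",
                           mixed_pair[1], mixed_pair[2])),
      two_sample_t(sel(mixed_pair[1], "median_confidence_error"),
                   sel(mixed_pair[2], "median_confidence_error"),
                   sprintf("error-trial confidence: %s vs %s",
                           mixed_pair[1], mixed_pair[2]))))
  }
  if (pair_n(bf_pair) >= 2) {
    sel <- function(g) subjects$auroc2[subjects$group == g]
    res <- c(res, list(bayes_factor_t(
      sel(bf_pair[1]), sel(bf_pair[2]), r_scale = bf_r_scale,
      name = sprintf("AUROC2 Bayes factor: %s vs %s",
                     bf_pair[1], bf_pair[2]))))
  }
  if (!length(res)) {
    empty <- data.frame(name = character(0), statistic = numeric(0),
                        df1 = numeric(0), df2 = numeric(0), p = numeric(0),
                        effect_size = numeric(0), bf01 = numeric(0),
                        stringsAsFactors = FALSE)
    class(empty) <- c("inference_result", "data.frame")
    return(empty)
  }
  out <- do.call(rbind, res)
  class(out) <- c("inference_result", "data.frame")
  out
}

within_pair <- function(res, fmt, pair) {
  res$name <- paste0(res$name, " — ",
                     sprintf(fmt, pair[1], pair[2]))
  res
}

#' @export
print.metacog <- function(x, ...) {
  cat("Metacognition analysis\n")
  cat(sprintf("  subjects: %d in %d group(s); trials analysed: %d\n",
              nrow(x$subjects), length(unique(x$subjects$group)),
              nrow(x$trials)))
  print(x$exclusions)
  cat("Group AUROC2 means:\n")
  m <- tapply(x$subjects$auroc2, x$subjects$group, mean, na.rm = TRUE)
  for (g in names(m)) cat(sprintf("  %-12s %.3f\n", g, m[[g]]))
  invisible(x)
}

#' @describeIn metacog Full results: subject summaries and every
#'   group-level test.
#' @param object,x A \code{"metacog"} object.
#' @param ... Unused.
#' @export
summary.metacog <- function(object, ...) {
  print(object)
  cat("\nGroup-level tests:\n")
  print(object$tests)
  invisible(object)
}

#' @describeIn metacog Per-subject metric table (subject summaries).
#' @export
coef.metacog <- function(object, ...) object$subjects

#' @describeIn metacog Boxplots of AUROC2 and the perceptual-control
#'   metrics by group (base graphics).
#' @export
plot.metacog <- function(x, ...) {
  s <- x$subjects
  op <- graphics::par(mfrow = c(2, 2), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (col in c("auroc2", "accuracy", "dprime", "median_confidence")) {
    graphics::boxplot(s[[col]] ~ factor(s$group), ylab = col, xlab = "",
                      main = col, ...)
  }
  invisible(x)
}
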