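# Per-subject type-I (d', c) and type-II (AUROC2) signal-detection metrics.

#' Type-II ROC and AUROC2 from binned confidence
#'
#' Builds the type-II receiver-operating-characteristic curve from confidence
#' ratings conditioned on correctness. Sweeping the bins from most to least
#' confident gives cumulative rate pairs \eqn{(f_k, h_k)} with
#' \eqn{h_k = P(\mathrm{conf} \ge k \mid \mathrm{correct})} and
#' \eqn{f_k} its counterpart for errors; AUROC2 is the trapezoidal area under
#' the (f, h) polyline with endpoints (0,0) and (1,1). This equals the
#' tie-corrected rank statistic
#' \eqn{P(\mathrm{conf}_{correct} > \mathrm{conf}_{error}) +
#' \tfrac12 P(\mathrm{tie})}: 0.5 is chance, 1 perfect metacognitive insight.
#'
#' @param confidence_bin Integer vector of bin indices in \code{1:n_bins}.
#' @param correct Logical vector, same length.
#' @param n_bins Number of confidence bins (default 6).
#' @return Object of class \code{"type2_roc"}: cumulative hit/false-alarm
#'   vectors \code{h} and \code{f} (length \code{n_bins + 1}, from 0 to 1),
#'   \code{auroc2}, and the correct/error trial counts.
#' @export
type2_roc <- function(confidence_bin, correct, n_bins = 6) {
  stopifnot(length(confidence_bin) == length(correct))
  if (anyNA(confidence_bin) || anyNA(correct))
    stop("missing values in confidence_bin or correct")
  if (any(confidence_bin < 1 | confidence_bin > n_bins))
    stop("confidence_bin outside 1..", n_bins)
  n_c <- sum(correct)
  n_i <- sum(!correct)
  if (n_c == 0 || n_i == 0)
    stop("AUROC2 undefined: need at least one correct and one incorrect trial")

  # counts per bin, highest-confidence bin first
  tab_c <- tabulate(confidence_bin[correct], nbins = n_bins)
  tab_i <- tabulate(confidence_bin[!correct], nbins = n_bins)
  h <- c(0, cumsum(rev(tab_c)) / n_c)
  f <- c(0, cumsum(rev(tab_i)) / n_i)
  auroc2 <- sum(diff(f) * (h[-length(h)] + h[-1]) / 2)
  structure(list(h = h, f = f, auroc2 = auroc2,
                 n_correct = n_c, n_incorrect = n_i),
            class = "type2_roc")
}

#' @export
print.type2_roc <- function(x, ...) {
  cat(sprintf("Type-II ROC: AUROC2 = %.4f (%d correct, %d incorrect)\n",
              x$auroc2, x$n_correct, x$n_incorrect))
  invisible(x)
}

#' Type-I sensitivity and bias for the 2AFC discrimination
#'
#' Designating left-motion stimuli as the signal class: H = P(respond left |
#' stimulus left) and FA = P(respond left | stimulus right). Sensitivity is
#' \deqn{d' = (z(H) - z(FA)) / \sqrt{2}} (the \eqn{\sqrt 2} correcting for
#' the two-alternative forced-choice design) and the criterion is
#' \deqn{c = -\tfrac12 (z(H) + z(FA)),} with z the inverse cumulative normal.
#' Positive c means a conservative bias against the signal ("left") response.
#' Rates of exactly 0 or 1 are nudged by 1/(2N) of the relevant class before
#' the z-transform so both remain finite.
#'
#' @param stimulus_direction Character vector, \code{"left"}/\code{"right"}.
#' @param response Character vector, same length, no missing values.
#' @param correction \code{"loglinear-cells"} (default; 1/(2N) nudge of
#'   empty/full cells) or \code{"none"}.
#' @param strict_printed_c If TRUE, compute the criterion as
#'   \code{-0.5 * (z(H) - z(FA))} instead of the standard form — a
#'   rescaling of d' kept only for comparison with reports using that
#'   convention.
#' @return Object of class \code{"sdt_type1"}: \code{H}, \code{FA},
#'   \code{dprime}, \code{c}, and per-class counts.
#' @export
type1_sdt <- function(stimulus_direction, response,
                      correction = c("loglinear-cells", "none"),
                      strict_printed_c = FALSE) {
  correction <- match.arg(correction)
  stopifnot(length(stimulus_direction) == length(response))
  if (anyNA(stimulus_direction) || anyNA(response))
    stop("missing values in stimulus_direction or response")
  n_sig <- sum(stimulus_direction == "left")
  n_noise <- sum(stimulus_direction == "right")
  if (n_sig == 0 || n_noise == 0)
    stop("both stimulus classes must be present")
  H <- sum(stimulus_direction == "left" & response == "left") / n_sig
  FA <- sum(stimulus_direction == "right" & response == "left") / n_noise
  if (correction == "loglinear-cells") {
    H <- min(max(H, 1 / (2 * n_sig)), 1 - 1 / (2 * n_sig))
    FA <- min(max(FA, 1 / (2 * n_noise)), 1 - 1 / (2 * n_noise))
  }
  zH <- stats::qnorm(H); zFA <- stats::qnorm(FA)
  dprime <- (zH - zFA) / sqrt(2)
  crit <- if (strict_printed_c) -0.5 * (zH - zFA) else -0.5 * (zH + zFA)
  structure(list(H = H, FA = FA, dprime = dprime, c = crit,
                 n_signal = n_sig, n_noise = n_noise),
            class = "sdt_type1")
}

#' @export
print.sdt_type1 <- function(x, ...) {
  cat(sprintf("Type-I SDT: d' = %.3f, c = %.3f (H = %.3f, FA = %.3f)\n",
              x$dprime, x$c, x$H, x$FA))
  invisible(x)
}

#' Summarise one subject's filtered trials
#'
#' Computes the per-subject quantities that enter the group analyses:
#' accuracy, mean staircased orientation (signal strength), median RT,
#' median confidence (overall / correct-only / error-only), d', c, and
#' AUROC2 from the binned ratings. AUROC2 (and the conditional confidence
#' medians) are NA when the subject has no error (or no correct) trials
#' after exclusion; such subjects drop out of AUROC2 analyses rather than
#' being imputed.
#'
#' @param trials Filtered trial data.frame for a single subject with a
#'   \code{confidence_bin} column (see [bin_confidence()]).
#' @return One-row data.frame (subject summary).
#' @export
summarise_subject <- function(trials) {
  stopifnot(nrow(trials) > 0, "confidence_bin" %in% names(trials))
  correct <- trials$correct
  both_classes <- sum(correct) > 0 && sum(!correct) > 0
  auroc2 <- if (both_classes)
    type2_roc(trials$confidence_bin, correct)$auroc2 else NA_real_
  sdt <- type1_sdt(trials$stimulus_direction, trials$response)
  data.frame(
    subject_id = trials$subject_id[1],
    group = trials$group[1],
    n_trials = nrow(trials),
    accuracy = mean(correct),
    mean_orientation_deg = mean(trials$mean_orientation_deg),
    median_rt_ms = stats::median(trials$rt_ms),
    median_confidence = stats::median(trials$confidence),
    median_confidence_correct = if (any(correct))
      stats::median(trials$confidence[correct]) else NA_real_,
    median_confidence_error = if (any(!correct))
      stats::median(trials$confidence[!correct]) else NA_real_,
    dprime = sdt$dprime,
    c = sdt$c,
    auroc2 = auroc2,
    stringsAsFactors = FALSE)
}

#' Summarise every subject in a filtered cohort
#'
#' Bins confidence per subject (quantile bins computed within subject, so
#' each subject's ratings are spread over their own scale use) and returns
#' the stacked subject summary table — the direct input to the group-level
#' inference.
#'
#' @param trials Filtered trial data.frame for all subjects.
#' @param n_bins Confidence bins per subject (default 6).
#' @return data.frame, one row per subject.
#' @export
summarise_subjects <- function(trials, n_bins = 6) {
  stopifnot(nrow(trials) > 0)
  parts <- split(trials, trials$subject_id)
  out <- do.call(rbind, lapply(parts, function(tt) {
    tt$confidence_bin <- bin_confidence(tt$confidence, n_bins)
    summarise_subject(tt)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$subject_id), , drop = FALSE]
}
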