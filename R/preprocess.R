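# Trial- and subject-level exclusions and equal-count confidence binning.

#' Apply trial-level exclusion rules
#'
#' Removes all first-block trials (staircase stabilisation burn-in), then
#' trials with anticipatory (< 100 ms), late (> 1500 ms) or missing
#' responses, and trials without a confidence rating. Low- and high-variance
#' trials are retained and pooled. For the standard 144-trial session with no
#' response-time violations this leaves 108 trials per subject.
#'
#' @param trials Trial data.frame with at least \code{block}, \code{rt_ms},
#'   \code{response} and \code{confidence} columns.
#' @param rt_bounds Numeric pair: inclusive RT window in ms (default
#'   \code{c(100, 1500)}).
#' @param drop_first_block Drop block-1 trials (default TRUE).
#' @return List with \code{trials} (the filtered table) and \code{report}
#'   (class \code{"exclusion_report"}): counts removed per rule, balancing
#'   \code{n_trials_in = n_trials_out + removals}.
#' @export
exclude_trials <- function(trials, rt_bounds = c(100, 1500),
                           drop_first_block = TRUE) {
  need <- c("block", "rt_ms", "response", "confidence")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  stopifnot(length(rt_bounds) == 2, rt_bounds[1] < rt_bounds[2])

  n_in <- nrow(trials)
  is_block1 <- if (drop_first_block) trials$block == 1 else rep(FALSE, n_in)
  rest <- trials[!is_block1, , drop = FALSE]
  missing_resp <- is.na(rest$response) | is.na(rest$confidence)
  fast <- !missing_resp & !is.na(rest$rt_ms) & rest$rt_ms < rt_bounds[1]
  late <- !missing_resp & !fast & !is.na(rest$rt_ms) & rest$rt_ms > rt_bounds[2]
  keep <- !(missing_resp | fast | late)
  out <- rest[keep, , drop = FALSE]

  report <- structure(list(
    n_trials_in = n_in,
    n_removed_block1 = sum(is_block1),
    n_removed_fast = sum(fast),
    n_removed_late_or_missing = sum(late) + sum(missing_resp),
    n_trials_out = nrow(out),
    excluded_subjects = list()), class = "exclusion_report")
  stopifnot(report$n_trials_in == report$n_trials_out +
              report$n_removed_block1 + report$n_removed_fast +
              report$n_removed_late_or_missing)
  list(trials = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Trial exclusions:\n")
  cat(sprintf("  in: %d, block 1: %d, fast: %d, late/missing: %d, out: %d\n",
              x$n_trials_in, x$n_removed_block1, x$n_removed_fast,
              x$n_removed_late_or_missing, x$n_trials_out))
  if (length(x$excluded_subjects)) {
    cat("Excluded subjects:\n")
    for (s in names(x$excluded_subjects))
      cat(sprintf("  %s: %s\n", s, x$excluded_subjects[[s]]))
  }
  invisible(x)
}

#' Flag low-accuracy outlier subjects by the lower Tukey fence
#'
#' Boxplot-style outlier rule applied to per-subject accuracy: subjects whose
#' accuracy falls strictly below Q1 - 1.5 IQR are flagged. Only the lower
#' fence is used, since the exclusion targets poor performers; quartiles are
#' computed by linear interpolation between order statistics
#' (\code{quantile} type 7).
#'
#' @param accuracy Named numeric vector of per-subject accuracies
#'   (names = subject ids).
#' @return Character vector of flagged subject ids (possibly empty).
#' @export
detect_outlier_subjects <- function(accuracy) {
  if (length(accuracy) < 4)
    stop("need at least 4 subjects for a boxplot-based fence")
  if (is.null(names(accuracy)))
    stop("accuracy must be a named vector (subject ids)")
  q <- stats::quantile(accuracy, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[1] - 1.5 * (q[2] - q[1])
  names(accuracy)[accuracy < fence]
}

#' Discretise confidence ratings into equal-count bins
#'
#' Per-subject quantile binning: bin k holds ratings between the (k-1)/6 and
#' k/6 empirical quantiles (linear interpolation, \code{quantile} type 7),
#' so with distinct ratings the bins have equal counts. Values tied with a
#' boundary share the lower bin; the assignment is monotone in confidence and
#' invariant to any strictly increasing rescaling of the confidence scale.
#'
#' @param confidence Numeric vector of ratings in [0, 1] (or any ordered
#'   scale), no missing values.
#' @param n_bins Number of bins (default 6).
#' @return Integer vector of bin indices in \code{1:n_bins}. If all ratings
#'   are identical the ties are unsplittable: every rating is assigned bin 1
#'   and the result carries attribute \code{degenerate = TRUE}.
#' @export
bin_confidence <- function(confidence, n_bins = 6) {
  if (anyNA(confidence)) stop("confidence contains missing values")
  if (length(confidence) < n_bins)
    stop("need at least ", n_bins, " ratings to form ", n_bins, " bins")
  breaks <- stats::quantile(confidence, probs = seq_len(n_bins - 1) / n_bins,
                            names = FALSE, type = 7)
  # (lo, hi] intervals: a rating equal to a boundary goes to the lower bin
  bins <- 1L + findInterval(confidence, breaks, left.open = TRUE)
  if (length(unique(confidence)) == 1L) attr(bins, "degenerate") <- TRUE
  bins
}
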