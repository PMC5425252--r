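# Synthetic global-motion confidence task: stimulus sampling, adaptive
# staircases, and a two-stage signal-detection observer.

#' Observer parameters for the two-stage SDT simulator
#'
#' Defines a generative observer for the global-motion discrimination task.
#' First-order evidence on a trial is drawn as
#' \code{x ~ N(sign * k_signal * mean_orientation * penalty, sigma_perc)} and
#' the left/right choice is \code{sign(x)}. The confidence judgement reads a
#' second, noisier copy of the evidence, \code{x2 = x + N(0, sigma_meta)}, and
#' reports \code{plogis(conf_gain * |x2|)}, so confidence lives in [0.5, 1)
#' with 0.5 the uninformative midpoint. Larger \code{sigma_meta} decouples
#' confidence from accuracy and lowers type-II sensitivity (AUROC2); it is the
#' single knob used to emulate a drug effect on metacognition.
#'
#' @param sigma_perc Perceptual noise SD, evidence units. Must be > 0.
#' @param k_signal Gain from mean orientation (degrees) to mean evidence
#'   (evidence units per degree).
#' @param variance_penalty Named numeric vector of multiplicative attenuations
#'   of \code{k_signal}, one per variance condition (names are the direction
#'   SDs in degrees). Higher stimulus variance weakens the pooled motion
#'   signal, so its staircase settles at a larger orientation.
#' @param sigma_meta Metacognitive noise SD, evidence units. Must be >= 0.
#' @param conf_gain Slope mapping second-order evidence magnitude to
#'   confidence; 0 yields constant confidence at the midpoint.
#' @param p_miss Probability of a missing/late response (response and RT
#'   recorded as missing).
#' @param p_fast Probability of an anticipatory response: a random guess with
#'   RT drawn below 100 ms.
#' @param rt_location_ms Median of the lognormal RT component, ms.
#' @param rt_scale Log-scale SD of the lognormal RT component (unitless).
#'   RTs are shifted lognormal: \code{100 + rlnorm(log(rt_location_ms),
#'   rt_scale)}.
#' @return An object of class \code{"observer_params"}.
#' @seealso [simulate_trial()], [simulate_cohort()]
#' @export
observer_params <- function(sigma_perc = 1,
                            k_signal = 0.055,
                            variance_penalty = c("20" = 1, "30" = 0.75),
                            sigma_meta = 0.5,
                            conf_gain = 1.5,
                            p_miss = 0.02,
                            p_fast = 0.01,
                            rt_location_ms = 550,
                            rt_scale = 0.35) {
  stopifnot(is.numeric(sigma_perc), length(sigma_perc) == 1, sigma_perc > 0)
  stopifnot(is.numeric(sigma_meta), length(sigma_meta) == 1, sigma_meta >= 0)
  stopifnot(is.numeric(k_signal), k_signal > 0)
  stopifnot(is.numeric(conf_gain), conf_gain >= 0)
  if (p_miss < 0 || p_fast < 0 || p_miss + p_fast >= 1)
    stop("p_miss and p_fast must be non-negative with p_miss + p_fast < 1")
  if (is.null(names(variance_penalty)) || any(variance_penalty <= 0))
    stop("variance_penalty must be a named positive vector keyed by direction SD")
  structure(list(sigma_perc = sigma_perc, k_signal = k_signal,
                 variance_penalty = variance_penalty,
                 sigma_meta = sigma_meta, conf_gain = conf_gain,
                 p_miss = p_miss, p_fast = p_fast,
                 rt_location_ms = rt_location_ms, rt_scale = rt_scale),
            class = "observer_params")
}

#' Cohort specification for the simulated study
#'
#' Describes the study layout: three groups of 20 subjects, 144 trials per
#' subject split evenly over four blocks and over two interleaved variance
#' conditions (direction SD 20 and 30 degrees), each condition driven by its
#' own staircase.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param group_params Named list mapping group label to
#'   [observer_params()]. Defaults to placebo/propranolol/amisulpride with a
#'   reduced metacognitive noise for propranolol, the simulated analogue of a
#'   selective metacognitive enhancement.
#' @param n_trials Trials per subject; must be divisible by \code{n_blocks}
#'   and by the number of variance conditions.
#' @param n_blocks Number of blocks.
#' @param variance_conditions Direction SDs (degrees) of the interleaved
#'   staircase conditions.
#' @param start_level_deg Starting mean orientation of each staircase,
#'   standing in for the threshold carried over from training.
#' @param step_deg,floor_deg,ceiling_deg Staircase step size and level bounds,
#'   degrees.
#' @param seed Master RNG seed; per-subject seeds are derived from it
#'   deterministically so that adding subjects never perturbs earlier ones.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_per_group = 20,
                        group_params = default_group_params(),
                        n_trials = 144,
                        n_blocks = 4,
                        variance_conditions = c(20, 30),
                        start_level_deg = 10,
                        step_deg = 0.5,
                        floor_deg = 0.1,
                        ceiling_deg = 45,
                        seed = 1L) {
  stopifnot(n_per_group >= 2, n_trials >= 1, n_blocks >= 1)
  if (n_trials %% n_blocks != 0)
    stop("n_trials must be divisible by n_blocks")
  if (n_trials %% length(variance_conditions) != 0)
    stop("n_trials must be divisible by the number of variance conditions")
  if (anyDuplicated(names(group_params)))
    stop("duplicate group names in group_params")
  if (!all(vapply(group_params, inherits, logical(1), "observer_params")))
    stop("group_params must be a named list of observer_params objects")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_params = group_params,
                 n_trials = as.integer(n_trials),
                 n_blocks = as.integer(n_blocks),
                 variance_conditions = variance_conditions,
                 start_level_deg = start_level_deg, step_deg = step_deg,
                 floor_deg = floor_deg, ceiling_deg = ceiling_deg,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default per-group observer parameters
#'
#' Placebo and amisulpride observers share identical parameters
#' (\code{sigma_meta = 0.5}); the propranolol observer differs only in a
#' reduced metacognitive noise (\code{sigma_meta = 0.1}), emulating a
#' selective improvement in how faithfully confidence tracks the decision
#' evidence, with no change to first-order performance.
#'
#' @return Named list of [observer_params()].
#' @export
default_group_params <- function() {
  list(placebo = observer_params(sigma_meta = 0.5),
       propranolol = observer_params(sigma_meta = 0.1),
       amisulpride = observer_params(sigma_meta = 0.5))
}

#' Sample per-dot motion directions for one stimulus
#'
#' Each of the \code{n_dots} dots moves in direction
#' \code{sign * mean_orientation_deg + N(0, direction_sd_deg)} (degrees from
#' vertical; negative = left), the generative rule of the global-motion
#' stimulus: the mean orientation is the staircased signal and the direction
#' SD sets the stimulus variance condition.
#'
#' @param direction \code{"left"} or \code{"right"}.
#' @param mean_orientation_deg Mean orientation, degrees from vertical (>= 0).
#' @param direction_sd_deg Direction SD, degrees (> 0 unless exactly 0 for
#'   the noiseless limit).
#' @param n_dots Number of dots (default 1100).
#' @return Numeric vector of \code{n_dots} signed dot directions, degrees.
#' @export
sample_dot_directions <- function(direction, mean_orientation_deg,
                                  direction_sd_deg, n_dots = 1100) {
  direction <- match.arg(direction, c("left", "right"))
  if (n_dots < 1) stop("n_dots must be >= 1")
  if (mean_orientation_deg < 0) stop("mean_orientation_deg must be >= 0")
  if (direction_sd_deg < 0) stop("direction_sd_deg must be non-negative")
  sgn <- if (direction == "left") -1 else 1
  sgn * mean_orientation_deg + rnorm(n_dots, 0, direction_sd_deg)
}

#' Initialise a staircase
#'
#' @param level_deg Starting mean orientation, degrees.
#' @param step_deg Step size, degrees.
#' @param floor_deg,ceiling_deg Level bounds, degrees.
#' @return A \code{"staircase_state"} list with a consecutive-correct counter
#'   at 0.
#' @export
staircase_init <- function(level_deg = 10, step_deg = 0.5,
                           floor_deg = 0.1, ceiling_deg = 45) {
  stopifnot(floor_deg <= level_deg, level_deg <= ceiling_deg, step_deg > 0)
  structure(list(level_deg = level_deg, n_correct_pending = 0L,
                 step_deg = step_deg, floor_deg = floor_deg,
                 ceiling_deg = ceiling_deg),
            class = "staircase_state")
}

#' Update a two-consecutive-correct-down / one-error-up staircase
#'
#' One error makes the stimulus easier (level increases by one step); two
#' consecutive correct responses make it harder (level decreases by one
#' step). In the long run this rule holds accuracy at the fixed point
#' sqrt(0.5), about 70.7%. Levels are clamped to the configured bounds.
#'
#' @param state A \code{"staircase_state"} from [staircase_init()].
#' @param correct Logical, was the response correct.
#' @return The updated \code{"staircase_state"}.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1, !is.na(correct))
  if (!correct) {
    state$level_deg <- state$level_deg + state$step_deg
    state$n_correct_pending <- 0L
  } else if (state$n_correct_pending == 0L) {
    state$n_correct_pending <- 1L
  } else {
    state$level_deg <- state$level_deg - state$step_deg
    state$n_correct_pending <- 0L
  }
  state$level_deg <- min(max(state$level_deg, state$floor_deg),
                         state$ceiling_deg)
  state
}

#' Simulate a single trial of the two-stage observer
#'
#' Draws first-order evidence, the left/right choice, second-order evidence
#' and confidence, and a shifted-lognormal response time; with probability
#' \code{p_miss} the response is missing, and with probability \code{p_fast}
#' it is an anticipatory guess with RT below 100 ms. Uses the current RNG
#' stream (seed management belongs to the session/cohort level).
#'
#' @param observer [observer_params()].
#' @param direction Stimulus direction, \code{"left"} or \code{"right"}.
#' @param mean_orientation_deg Current staircase level, degrees.
#' @param direction_sd_deg Variance condition, degrees.
#' @return One-row data.frame with stimulus, response, correctness, RT,
#'   confidence, and the jittered slider start position (kept for realism;
#'   never analysed).
#' @export
simulate_trial <- function(observer, direction, mean_orientation_deg,
                           direction_sd_deg) {
  stopifnot(inherits(observer, "observer_params"))
  tr <- sim_trial_core(observer, direction, mean_orientation_deg,
                       direction_sd_deg)
  data.frame(variance_condition = direction_sd_deg,
             mean_orientation_deg = mean_orientation_deg,
             stimulus_direction = direction, response = tr$response,
             correct = tr$correct, rt_ms = tr$rt, confidence = tr$confidence,
             slider_start = tr$slider_start, stringsAsFactors = FALSE)
}

# trial internals shared by simulate_trial and simulate_session;
# returns a plain list to keep tight simulation loops cheap
sim_trial_core <- function(observer, direction, mean_orientation_deg,
                           direction_sd_deg) {
  sgn <- if (direction == "left") -1 else 1
  pen <- observer$variance_penalty[[as.character(direction_sd_deg)]]
  if (is.null(pen)) pen <- 1
  mu <- sgn * observer$k_signal * mean_orientation_deg * pen
  x <- rnorm(1, mu, observer$sigma_perc)
  x2 <- x + if (observer$sigma_meta > 0) rnorm(1, 0, observer$sigma_meta) else 0
  confidence <- stats::plogis(observer$conf_gain * abs(x2))
  slider_start <- 0.5 + stats::runif(1, -0.12, 0.12)

  u <- stats::runif(1)
  if (u < observer$p_miss) {
    response <- NA_character_; correct <- NA; rt <- NA_real_
    confidence <- NA_real_
  } else if (u < observer$p_miss + observer$p_fast) {
    response <- sample(c("left", "right"), 1)
    correct <- response == direction
    rt <- stats::runif(1, 0, 99)
  } else {
    response <- if (x > 0) "right" else "left"
    correct <- response == direction
    rt <- 100 + stats::rlnorm(1, log(observer$rt_location_ms),
                              observer$rt_scale)
  }
  list(response = response, correct = correct, rt = rt,
       confidence = confidence, slider_start = slider_start)
}

#' Simulate one subject's session
#'
#' Runs \code{n_trials} trials with the variance conditions interleaved in
#' seeded shuffled pairs within each block, each condition under its own
#' independent staircase whose state carries across blocks. Stimulus
#' direction is left/right with equal probability.
#'
#' @param observer [observer_params()].
#' @param cohort [cohort_spec()] supplying layout and staircase settings.
#' @param subject_id Subject identifier.
#' @param group Group label.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @return data.frame of trials with subject, group, block and trial columns.
#' @export
simulate_session <- function(observer, cohort, subject_id, group, seed) {
  stopifnot(inherits(cohort, "cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))

  vcs <- cohort$variance_conditions
  per_block <- cohort$n_trials / cohort$n_blocks
  states <- lapply(vcs, function(v)
    staircase_init(cohort$start_level_deg, cohort$step_deg,
                   cohort$floor_deg, cohort$ceiling_deg))
  names(states) <- as.character(vcs)

  n <- cohort$n_trials
  block <- integer(n); vcond <- numeric(n); level <- numeric(n)
  stim <- character(n); resp <- character(n); correct <- logical(n)
  rt <- numeric(n); conf <- numeric(n); slider <- numeric(n)

  t_idx <- 0L
  for (b in seq_len(cohort$n_blocks)) {
    # equal counts per condition within block, order shuffled
    order_vc <- sample(rep(vcs, per_block / length(vcs)))
    for (vc in order_vc) {
      t_idx <- t_idx + 1L
      key <- as.character(vc)
      direction <- sample(c("left", "right"), 1)
      tr <- sim_trial_core(observer, direction,
                           states[[key]]$level_deg, vc)
      block[t_idx] <- b; vcond[t_idx] <- vc
      level[t_idx] <- states[[key]]$level_deg
      stim[t_idx] <- direction; resp[t_idx] <- tr$response
      correct[t_idx] <- tr$correct; rt[t_idx] <- tr$rt
      conf[t_idx] <- tr$confidence; slider[t_idx] <- tr$slider_start
      if (!is.na(tr$correct))
        states[[key]] <- staircase_update(states[[key]], tr$correct)
    }
  }
  data.frame(subject_id = subject_id, group = group, block = block,
             trial = seq_len(n), variance_condition = vcond,
             mean_orientation_deg = level, stimulus_direction = stim,
             response = resp, correct = correct, rt_ms = rt,
             confidence = conf, slider_start = slider,
             stringsAsFactors = FALSE)
}

# deterministic counter-based split of the master seed: adding subjects
# never perturbs earlier subjects' streams
subject_seed <- function(master_seed, index) {
  (as.double(master_seed) + 1000003 * as.double(index)) %% 2147483629
}

#' Simulate a full cohort
#'
#' Simulates \code{n_per_group} subjects for every group in
#' \code{cohort$group_params}, with per-subject seeds derived
#' deterministically from the master seed.
#'
#' @param cohort [cohort_spec()].
#' @return data.frame of all trials (subjects x trials rows).
#' @examples
#' trials <- simulate_cohort(cohort_spec(n_per_group = 2, seed = 7))
#' nrow(trials)  # 2 subjects x 3 groups x 144 trials
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  groups <- names(cohort$group_params)
  idx <- 0L
  out <- vector("list", length(groups) * cohort$n_per_group)
  for (g in groups) {
    for (s in seq_len(cohort$n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g, s)
      out[[idx]] <- simulate_session(cohort$group_params[[g]], cohort,
                                     sid, g,
                                     subject_seed(cohort$seed, idx))
    }
  }
  do.call(rbind, out)
}

#' Write a trial table as CSV
#'
#' Canonical dialect: comma-separated, UTF-8, header row, columns in the
#' documented fixed order, missing values as empty fields.
#'
#' @param trials Trial data.frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
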