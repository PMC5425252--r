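# Type-II ROC / AUROC2, type-I SDT metrics, and subject summaries.

test_that("AUROC2 hits its anchor points", {
  # perfect separation
  roc <- type2_roc(c(6, 6, 6, 1, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$auroc2, 1)
  # identical confidence distributions -> chance
  roc <- type2_roc(c(3, 4, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$auroc2, 0.5)
  # worked pairwise example: correct {3,3,5}, incorrect {3,2} -> 5/6
  roc <- type2_roc(c(3, 3, 5, 3, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$auroc2, 5 / 6)
  expect_equal(roc$auroc2,
               pairwise_auroc2(c(3, 3, 5), c(3, 2)))
  # cumulative-rate curves are proper ROC curves
  expect_equal(roc$h[1], 0); expect_equal(roc$h[7], 1)
  expect_true(all(diff(roc$h) >= 0) && all(diff(roc$f) >= 0))
})

test_that("trapezoidal AUROC2 equals the exhaustive rank statistic", {
  set.seed(101)
  for (i in 1:300) {
    n_c <- sample(1:12, 1); n_i <- sample(1:12, 1)
    bc <- sample(1:6, n_c, replace = TRUE)
    bi <- sample(1:6, n_i, replace = TRUE)
    roc <- type2_roc(c(bc, bi), rep(c(TRUE, FALSE), c(n_c, n_i)))
    expect_equal(roc$auroc2, pairwise_auroc2(bc, bi), tolerance = 1e-12)
  }
})

test_that("AUROC2 is invariant under increasing bin relabelling", {
  set.seed(5)
  strictly <- c(1, 2, 4, 5, 6)  # strictly increasing relabelling of 1:5
  for (i in 1:50) {
    bins <- sample(1:5, 30, replace = TRUE)  # keep 6 free for relabel room
    correct <- sample(c(TRUE, FALSE), 30, replace = TRUE,
                      prob = c(.7, .3))
    if (!any(correct) || all(correct)) next
    a0 <- type2_roc(bins, correct)$auroc2
    a2 <- type2_roc(strictly[bins], correct)$auroc2
    expect_equal(a0, a2)
  }
})

test_that("AUROC2 errors informatively on degenerate subjects", {
  expect_error(type2_roc(c(3, 4), c(TRUE, TRUE)), "incorrect")
  expect_error(type2_roc(c(3, 7), c(TRUE, FALSE)), "outside")
})

test_that("d-prime and criterion match closed forms", {
  mk <- function(H, FA, n = 100) {
    # n signal (left) and n noise (right) trials with exact rates
    stim <- rep(c("left", "right"), each = n)
    resp <- c(rep(c("left", "right"), c(H * n, n - H * n)),
              rep(c("left", "right"), c(FA * n, n - FA * n)))
    type1_sdt(stim, resp)
  }
  # H = FA: no sensitivity; c = -z(H)
  s <- mk(0.6, 0.6)
  expect_equal(s$dprime, 0)
  expect_equal(s$c, -qnorm(0.6))
  # symmetric rates: d' = 2 z(0.8)/sqrt(2), c = 0
  s <- mk(0.8, 0.2)
  expect_equal(s$dprime, (qnorm(0.8) - qnorm(0.2)) / sqrt(2))
  expect_equal(s$dprime, 1.19023, tolerance = 1e-5)
  expect_equal(s$c, 0)
  # label-swap antisymmetry: exchanging stimulus classes flips d' and c
  stim <- rep(c("left", "right"), each = 50)
  set.seed(3)
  resp <- sample(c("left", "right"), 100, replace = TRUE, prob = c(.6, .4))
  a <- type1_sdt(stim, resp)
  swap <- function(x) ifelse(x == "left", "right", "left")
  b <- type1_sdt(swap(stim), swap(resp))
  expect_equal(b$dprime, a$dprime)   # symmetric swap of both preserves d'
  b2 <- type1_sdt(rev(stim), resp)   # swap stimulus labels only
  expect_equal(b2$dprime, -a$dprime)
  expect_error(type1_sdt(rep("left", 10), rep("left", 10)), "both stimulus")
})

test_that("zero/one rates are corrected before the z-transform", {
  stim <- rep(c("left", "right"), each = 20)
  resp <- stim  # perfect responding: H = 1, FA = 0
  s <- type1_sdt(stim, resp)
  expect_true(is.finite(s$dprime))
  expect_equal(s$H, 1 - 1 / 40)
  expect_equal(s$FA, 1 / 40)
  expect_false(is.finite(
    type1_sdt(stim, resp, correction = "none")$dprime))
})

test_that("the as-printed criterion switch rescales d-prime", {
  stim <- rep(c("left", "right"), each = 50)
  set.seed(8)
  resp <- ifelse(runif(100) < 0.75, stim, rev(stim))
  s <- type1_sdt(stim, resp, strict_printed_c = TRUE)
  expect_equal(s$c, -0.5 * sqrt(2) * s$dprime)
})

test_that("subject summaries match hand computation and handle degeneracy", {
  tt <- data.frame(
    subject_id = "s1", group = "placebo",
    mean_orientation_deg = c(10, 10, 12, 12, 8, 8, 10, 10, 9, 9),
    stimulus_direction = rep(c("left", "right"), 5),
    response = c("left", "right", "left", "left", "right",
                 "right", "left", "right", "left", "right"),
    rt_ms = seq(400, 850, by = 50),
    confidence = c(.9, .8, .7, .2, .1, .85, .95, .75, .6, .65),
    stringsAsFactors = FALSE)
  tt$correct <- tt$response == tt$stimulus_direction
  tt$confidence_bin <- bin_confidence(tt$confidence)
  s <- summarise_subject(tt)
  expect_equal(s$accuracy, 0.8)
  expect_equal(s$mean_orientation_deg, 9.8)
  expect_equal(s$median_rt_ms, 625)
  expect_equal(s$median_confidence, 0.725)
  expect_equal(s$median_confidence_correct,
               median(tt$confidence[tt$correct]))
  expect_equal(s$median_confidence_error, median(c(.2, .1)))
  expect_equal(s$auroc2, pairwise_auroc2(tt$confidence_bin[tt$correct],
                                         tt$confidence_bin[!tt$correct]))
  sdt <- type1_sdt(tt$stimulus_direction, tt$response)
  expect_equal(s$dprime, sdt$dprime)

  # all-correct subject: AUROC2 undefined (NA), everything else present
  tt2 <- tt; tt2$response <- tt2$stimulus_direction
  tt2$correct <- TRUE
  s2 <- summarise_subject(tt2)
  expect_true(is.na(s2$auroc2))
  expect_equal(s2$accuracy, 1)

  # duplicating every trial leaves the summary unchanged
  s3 <- summarise_subject(rbind(tt, tt))
  expect_equal(s3$accuracy, s$accuracy)
  expect_equal(s3$auroc2, s$auroc2)
  expect_equal(s3$median_confidence, s$median_confidence)
})
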