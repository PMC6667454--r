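test_that("Welch ANOVA electrode selection finds responsive channels", {
  set.seed(21)
  n <- 500
  labels <- rep(c("perception", "production", "silence"), each = n)
  x <- matrix(rnorm(3 * n * 4), 3 * n, 4)
  x[labels != "silence", 2] <- x[labels != "silence", 2] + 3
  sel <- select_event_electrodes(x, labels, 1e-3)
  expect_true(2 %in% sel)
  # vacuous threshold selects everything
  expect_equal(select_event_electrodes(x, labels, 1), 1:4)
  expect_error(select_event_electrodes(x, rep("silence", 3 * n), 0.05),
               "three frame classes")
  # agreement with the reference Welch ANOVA on the planted electrode
  p_ref <- stats::oneway.test(x[, 2] ~ factor(labels), var.equal = FALSE)$p.value
  expect_lt(p_ref, 1e-3)
})

test_that("noise electrodes are selected at about the type-I rate", {
  set.seed(22)
  labels <- rep(c("perception", "production", "silence"), each = 60)
  hits <- vapply(1:1000, function(i) {
    x <- matrix(rnorm(180), 180, 1)
    length(select_event_electrodes(x, labels, 0.05)) == 1
  }, TRUE)
  # Monte-Carlo check of the false-selection rate against the threshold
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("spatiotemporal feature vectors match a slice-and-flatten oracle", {
  set.seed(23)
  x <- matrix(rnorm(50 * 5), 50, 5)
  bv <- build_feature_vectors(x, c(2, 4, 5), nu_shift = -2, nu_duration = 4)
  expect_equal(ncol(bv$x), 15)                   # (4 + 1) x 3 electrodes
  # frames whose window leaves the stream are flagged unusable (skipped)
  expect_equal(bv$frame, 3:48)
  i <- which(bv$frame == 10)
  oracle <- as.vector(x[8:12, c(2, 4, 5)])
  expect_equal(unname(bv$x[i, ]), oracle)
  # degenerate window reproduces the single frame
  bv0 <- build_feature_vectors(x, 1:5, 0, 0)
  expect_equal(unname(bv0$x), unname(x))
  # feature metadata maps columns to electrodes and lags
  expect_equal(bv$electrode, rep(c(2, 4, 5), each = 5))
  expect_equal(bv$lag, rep(-2:2, times = 3))
})

test_that("event model posteriors are normalized and separable classes are learned", {
  set.seed(24)
  n <- 150
  x <- rbind(matrix(rnorm(n * 6), n, 6),
             matrix(rnorm(n * 6, mean = 3), n, 6),
             matrix(rnorm(n * 6, mean = -3), n, 6))
  labels <- rep(c("silence", "perception", "production"), each = n)
  m <- fit_event_model(x, labels, 0.95)
  p <- predict(m, x, type = "posterior")
  expect_equal(unname(rowSums(p)), rep(1, nrow(x)), tolerance = 1e-9)
  expect_gt(mean(predict(m, x, type = "class") == labels), 0.99)
})

test_that("the detection state machine segments clean pulses correctly", {
  nf <- 300
  mk_prob <- function(on, off) {
    p <- tibble::tibble(perception = rep(0, nf), production = rep(0, nf))
    p$perception[on:off] <- 1
    p$production <- 0
    p
  }
  cfg <- detector_config(smooth_len = 1, prob_threshold = 0.5,
                         time_threshold = 10, onset_shift = 0,
                         offset_shift = 0)
  # clean pulse longer than the time threshold -> exactly one event at its edges
  ev <- detect_events(mk_prob(100, 180), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$modality, "perception")
  expect_equal(ev$onset_frame, 100L)
  expect_equal(ev$offset_frame, 181L)
  # pulse shorter than the time threshold is debounced away
  expect_equal(nrow(detect_events(mk_prob(100, 105), cfg)), 0)
  # all-silence stream yields no events
  silent <- tibble::tibble(perception = rep(0, nf), production = rep(0, nf))
  expect_equal(nrow(detect_events(silent, cfg)), 0)
  # an event still open at the stream end is closed at the final frame
  ev_open <- detect_events(mk_prob(250, 300), cfg)
  expect_equal(ev_open$offset_frame, nf + 1L)
  # onset/offset shifts move the reported window
  cfg2 <- detector_config(smooth_len = 1, prob_threshold = 0.5,
                          time_threshold = 10, onset_shift = -5,
                          offset_shift = 5)
  ev2 <- detect_events(mk_prob(100, 180), cfg2)
  expect_equal(ev2$onset_frame, 95L)
  expect_equal(ev2$offset_frame, 186L)
  # events whose shifted offset precedes their onset are dropped
  cfg3 <- detector_config(smooth_len = 1, prob_threshold = 0.5,
                          time_threshold = 10, onset_shift = 60,
                          offset_shift = -60)
  expect_equal(nrow(detect_events(mk_prob(100, 180), cfg3)), 0)
})

test_that("smoothing is a trailing average and raises detection latency only", {
  nf <- 200
  p <- tibble::tibble(perception = rep(0, nf), production = rep(0, nf))
  p$perception[50:150] <- 1
  cfg <- detector_config(smooth_len = 11, prob_threshold = 0.5,
                         time_threshold = 5, onset_shift = 0, offset_shift = 0)
  ev <- detect_events(p, cfg)
  expect_equal(nrow(ev), 1)
  # trailing average crosses 0.5 six frames into the pulse (6/11 > 0.5)
  expect_equal(ev$onset_frame, 55L)
})

test_that("raising the probability threshold never increases detected frames", {
  set.seed(25)
  nf <- 400
  raw <- stats::filter(runif(nf), rep(1 / 15, 15), sides = 1)
  raw[is.na(raw)] <- 0.5
  p <- tibble::tibble(perception = as.numeric(raw), production = rep(0, nf))
  frames_detected <- vapply(c(0.3, 0.45, 0.6, 0.75), function(thr) {
    cfg <- detector_config(smooth_len = 5, prob_threshold = thr,
                           time_threshold = 4, onset_shift = 0,
                           offset_shift = 0)
    sum(detect_events(p, cfg)$n_frames)
  }, 0)
  expect_true(all(diff(frames_detected) <= 0))
})

test_that("streaming detection reproduces batch detection exactly", {
  set.seed(26)
  for (rep in 1:5) {
    nf <- 300
    raw <- stats::filter(runif(nf), rep(1 / 10, 10), sides = 1)
    raw[is.na(raw)] <- 0.3
    p <- tibble::tibble(perception = as.numeric(raw),
                        production = as.numeric(rev(raw)))
    cfg <- detector_config(smooth_len = c(perception = 7, production = 4),
                           prob_threshold = 0.5,
                           time_threshold = c(perception = 5, production = 3),
                           onset_shift = -2, offset_shift = 2)
    expect_identical(detect_events(p, cfg), streaming_detect(p, cfg))
  }
})

test_that("a trained detector localizes events on a held-out noiseless block", {
  dec <- test_decoder()
  tb <- test_testing_block()
  det <- detect_speech(dec$detector, tb$features)
  expect_equal(nrow(det$events), 52)
  scores <- evaluate_decoding(test_transcript(), tb)
  det_scores <- scores$value[scores$metric == "detection_score"]
  expect_true(all(det_scores >= 0.95))
})
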