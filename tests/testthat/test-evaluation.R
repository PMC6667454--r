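test_that("utterance error rate is the sequence edit distance", {
  expect_equal(utterance_error_rate(c("A", "B", "C"), c("A", "B", "C"))$error_rate, 0)
  expect_equal(utterance_error_rate(c("A", "B", "C"), c("A", "B", "C"))$accuracy_rate, 1)
  r <- utterance_error_rate(c("A", "B", "C"), c("A", "C"))
  expect_equal(r$edit_distance, 1)
  expect_equal(r$error_rate, 1 / 3)
  # empty prediction: all deletions
  r2 <- utterance_error_rate(c("A", "B"), character())
  expect_equal(r2$error_rate, 1)
  expect_equal(r2$accuracy_rate, 0)
  # more insertions than the sequence length floors accuracy at 0
  r3 <- utterance_error_rate("A", c("B", "C", "D"))
  expect_equal(r3$accuracy_rate, 0)
  expect_error(utterance_error_rate(character(), "A"), "non-empty")
  # cross-check against the reference string edit distance on single chars
  set.seed(51)
  for (i in 1:20) {
    a <- sample(letters[1:4], sample(1:8, 1), replace = TRUE)
    b <- sample(letters[1:4], sample(0:8, 1), replace = TRUE)
    expect_equal(
      utterance_error_rate(a, b)$edit_distance,
      as.integer(utils::adist(paste(a, collapse = ""),
                              paste(b, collapse = "")))
    )
  }
})

test_that("classification accuracy bootstrap behaves like the binomial", {
  set.seed(52)
  all_ok <- classification_accuracy(rep(TRUE, 30), n_boot = 200)
  expect_equal(all_ok$accuracy, 1)
  expect_equal(all_ok$ci_lower, 1)
  expect_equal(all_ok$ci_upper, 1)
  half <- classification_accuracy(rep(c(TRUE, FALSE), 50), n_boot = 4000)
  expect_equal(half$accuracy, 0.5)
  expect_equal(half$boot_mean, 0.5, tolerance = 0.01)
  # binomial closed form: sd = sqrt(p(1-p)/n) = 0.05
  expect_equal(half$boot_sd, 0.05, tolerance = 0.05)
  expect_error(classification_accuracy(logical()), "at least one")
})

test_that("cross entropy is the mean surprisal in bits", {
  # uniform over 24 answers
  ce <- cross_entropy(rep(log(1 / 24), 10), n_boot = 0)
  expect_equal(ce$cross_entropy_bits, log2(24), tolerance = 1e-12)
  # perfect one-hot predictions carry zero surprisal
  expect_equal(cross_entropy(rep(0, 5), n_boot = 0)$cross_entropy_bits, 0)
  # halving the true class probability adds exactly one bit
  p <- 0.4
  d <- cross_entropy(log(p / 2), n_boot = 0)$cross_entropy_bits -
    cross_entropy(log(p), n_boot = 0)$cross_entropy_bits
  expect_equal(d, 1, tolerance = 1e-12)
})

test_that("detection score combines frame and event accuracies per the weights", {
  ev <- tibble::tibble(onset_s = c(10, 40), offset_s = c(20, 50))
  # perfect detection (padding included in the detected windows)
  det <- tibble::tibble(onset_s = ev$onset_s - 0.3, offset_s = ev$offset_s + 0.3)
  s <- detection_score(ev, det, n_frames = 600, frame_rate = 10)
  expect_equal(s$score, 1)
  expect_equal(s$a_frame, 1)
  expect_equal(s$a_event, 1)
  # detecting twice as many events as actual zeroes the event accuracy
  det2 <- tibble::tibble(onset_s = c(10, 15, 40, 45) - 0.3,
                         offset_s = c(14, 20, 44, 50) + 0.3)
  s2 <- detection_score(ev, det2, n_frames = 600, frame_rate = 10)
  expect_equal(s2$a_event, 0)
  # all-positive predictions on a 50/50 stream score a_frame = w_p = 0.75
  half <- tibble::tibble(onset_s = 0, offset_s = 30)
  allpos <- tibble::tibble(onset_s = 0, offset_s = 60)
  s3 <- detection_score(half, allpos, n_frames = 600, frame_rate = 10,
                        pad_s = 0)
  expect_equal(s3$a_frame, 0.75)
  # missing every event zeroes both terms
  s4 <- detection_score(ev, det[0, ], n_frames = 600, frame_rate = 10)
  expect_equal(s4$a_event, 0)
  expect_lt(s4$score, 0.5)
})

test_that("discriminative power isolates the signal-carrying electrode", {
  # Eq.-style arithmetic: equal between and within variance gives 0.5
  set.seed(53)
  n <- 400
  x <- matrix(rnorm(n * 12), n, 12)
  labels <- rep(c("a", "b", "c"), length.out = n)
  x[labels == "a", 7] <- x[labels == "a", 7] + 4
  x[labels == "b", 7] <- x[labels == "b", 7] - 4
  m <- fit_pca_lda(x, labels, 1)
  dp <- discriminative_power(m, electrode_map = 1:12)
  expect_true(all(dp$component$eta >= 0 & dp$component$eta <= 1))
  expect_equal(dp$electrode$electrode[which.max(dp$electrode$power)], 7)
  # per-electrode values never exceed the maximum component value
  expect_lte(max(dp$electrode$power), max(dp$component$eta) + 1e-12)
  # identical class means give zero discriminative power everywhere
  set.seed(54)
  x0 <- matrix(rnorm(600), 200, 3)
  m0 <- fit_pca_lda(x0, rep(c("a", "b"), 100), 1)
  m0$means[2, ] <- m0$means[1, ]
  dp0 <- discriminative_power(m0, electrode_map = 1:3)
  expect_true(all(dp0$component$eta == 0))
})

test_that("finalization times locate the earliest stable decision", {
  phone_set <- c("sp", "s", "ih", "k", "f", "ay", "n")
  # candidates differing in the first phone finalize at that phone
  cands <- list(A = c("s", "ih"), B = c("f", "ay"))
  r <- render_transcription_event(cands$A, phone_set, per = 4, pad = 2)
  hmms <- lapply(cands, build_hmm, p_self = 0.5)
  vit <- lapply(hmms, viterbi_log_likelihood, frame_loglikes = r$emissions)
  scores <- do.call(rbind, lapply(vit, `[[`, "frame_scores"))
  ft <- finalization_time(scores, seq_len(ncol(scores)), "A",
                          r$onset, r$offset)
  expect_equal(ft$finalization_frame, r$onset)   # first frame of /s/
  expect_lt(ft$percent, 100)
  # identical-prefix candidates cannot finalize before the differing phone
  cands2 <- list(Six = c("s", "ih", "k", "s"),
                 Synth = c("s", "ih", "n", "f"))
  phone_set2 <- c("sp", "s", "ih", "k", "n", "f")
  r2 <- render_transcription_event(cands2$Six, phone_set2, per = 3, pad = 2)
  hmms2 <- lapply(cands2, build_hmm, p_self = 0.5)
  vit2 <- lapply(hmms2, viterbi_log_likelihood, frame_loglikes = r2$emissions)
  scores2 <- do.call(rbind, lapply(vit2, `[[`, "frame_scores"))
  ft2 <- finalization_time(scores2, seq_len(ncol(scores2)), "Six",
                           r2$onset, r2$offset)
  diverge_frame <- r2$onset + 2 * 3               # first frame of /k/
  expect_gte(ft2$finalization_frame, diverge_frame)
  expect_lt(ft2$percent, 100)
})

test_that("phone confusions and articulatory mutual information behave", {
  set.seed(55)
  cats <- read_place_categories()
  phones <- c("p", "b", "t", "d", "k", "g", "iy", "aa", "s", "sh")
  actual <- sample(phones, 3000, replace = TRUE)
  # perfect predictions: confusion is the identity, MI equals category entropy
  cm <- phone_confusions(actual, actual)
  expect_equal(unname(diag(cm)), rep(1, length(unique(actual))))
  mi <- place_of_articulation_mi(actual, actual, cats, n_perm = 200)
  cat_freq <- table(cats[actual]) / length(actual)
  expect_equal(mi$mi_bits, -sum(cat_freq * log2(cat_freq)), tolerance = 1e-9)
  # within-category confusions are significant against randomized categories
  confuse <- function(ph) {
    pool <- names(cats)[cats == cats[[ph]] & names(cats) %in% phones]
    pool[sample.int(length(pool), 1)]
  }
  pred_cat <- vapply(actual, confuse, "")
  mi_cat <- place_of_articulation_mi(actual, pred_cat, cats, n_perm = 200)
  expect_lt(mi_cat$p_value, 0.05)
  # independent labels: MI near zero, insignificant
  pred <- sample(phones, 3000, replace = TRUE)
  mi0 <- place_of_articulation_mi(actual, pred, cats, n_perm = 200)
  expect_lt(mi0$mi_bits, 0.02)
  expect_gt(mi0$p_value, 0.05)
  # a phone missing from the category map is an error
  expect_error(place_of_articulation_mi(c("p", "qq"), c("p", "p"),
                                        cats, n_perm = 10),
               "missing phone")
  # row normalization yields rows summing to 1
  cm2 <- phone_confusions(actual, pred)
  expect_equal(unname(rowSums(cm2)), rep(1, nrow(cm2)), tolerance = 1e-12)
})

test_that("Holm-Bonferroni matches the hand-applied step-down procedure", {
  # hand application: sorted p (.005, .01, .03, .04) vs alpha/(m-k+1)
  # (.0125, .0167, .025, .05): the third comparison fails, so only the two
  # smallest are rejected
  res <- holm_bonferroni(c(0.01, 0.04, 0.03, 0.005))
  expect_equal(res$reject, c(TRUE, FALSE, FALSE, TRUE))
  # agreement with the reference adjusted p-values
  expect_equal(res$p_adjusted,
               stats::p.adjust(c(0.01, 0.04, 0.03, 0.005), method = "holm"))
  # m = 1 reduces to a plain comparison
  expect_true(holm_bonferroni(0.04)$reject)
  expect_false(holm_bonferroni(0.06)$reject)
})

test_that("native statistical tests match their closed forms", {
  # exact McNemar: 10 vs 0 discordant pairs -> one-tailed p = 2^-10
  expect_equal(mcnemar_exact(10, 0), 2^-10, tolerance = 1e-12)
  expect_equal(mcnemar_exact(0, 0), 1)
  # symmetric discordance is not significant
  expect_gt(mcnemar_exact(5, 5), 0.5)
  # permutation test recognizes a strong paired difference
  set.seed(56)
  x <- rnorm(30, 1)
  y <- rnorm(30, 0)
  expect_lt(permutation_test_paired(x, y, n_perm = 2000), 0.01)
  expect_gt(permutation_test_paired(y, x, n_perm = 2000), 0.5)
  # bootstrap test against chance
  expect_lt(bootstrap_test(rep(c(1, 1, 1, 0), 25), reference = 0.25,
                           n_boot = 2000), 0.01)
})
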