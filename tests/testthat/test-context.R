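uniform_lik <- function(labels) {
  smooth_normalize(setNames(rep(-1, length(labels)), labels), 1)
}

onehot_lik <- function(labels, at) {
  raw <- setNames(rep(-Inf, length(labels)), labels)
  raw[at] <- 0
  smooth_normalize(raw, 1)
}

test_that("context priors implement flat within-set conditionals", {
  stim <- test_stim()
  pri <- build_context_priors(stim)
  expect_equal(dim(pri), c(24, 9))
  expect_equal(unname(colSums(pri)), rep(1, 9))
  room <- pri[, "How is your room currently?"]
  expect_equal(unname(room[c("Bright", "Dark", "Hot", "Cold", "Fine")]),
               rep(1 / 5, 5))
  # out-of-set pairs have zero prior
  expect_equal(unname(room["Piano"]), 0)
  expect_equal(unname(pri["Fine", "When do you want me to check back on you?"]), 0)
})

test_that("answer priors update as a mixture of context-prior columns", {
  stim <- test_stim()
  pri <- build_context_priors(stim)
  st <- context_state(pri)
  expect_false(st$prior_available)
  # concentrated question likelihoods reproduce that question's column
  q <- "How is your room currently?"
  st1 <- update_answer_priors(st, onehot_lik(stim$questions, q))
  expect_true(st1$prior_available)
  got <- exp(st1$log_prior)
  expect_equal(got[names(got) %in% valid_answers(stim, q)],
               setNames(rep(1 / 5, 5), valid_answers(stim, q)),
               tolerance = 1e-6)
  # zero-prior answers survive as hard (floored) log zeros
  expect_lt(st1$log_prior[["Piano"]], -1e9)
  # uniform question likelihoods give priors proportional to row sums
  st2 <- update_answer_priors(st, uniform_lik(stim$questions))
  manual <- rowSums(pri) / sum(rowSums(pri))
  expect_equal(unname(exp(st2$log_prior)), unname(manual), tolerance = 1e-9)
})

test_that("posterior integration normalizes and honors the scaling factor", {
  stim <- test_stim()
  pri <- build_context_priors(stim)
  set.seed(41)
  raw <- setNames(rnorm(24, -50, 10), stim$answers)
  alik <- smooth_normalize(raw, 1)
  # m = 0 knocks out context: posterior equals the likelihoods
  st <- update_answer_priors(context_state(pri, m = 0),
                             onehot_lik(stim$questions, stim$questions[3]))
  post0 <- integrate_context(st, alik)
  expect_equal(post0$log_posterior, post0$loglik, tolerance = 1e-9)
  expect_equal(predict_utterances(answer_lik = alik,
                                  posterior = post0)$answer_with_context,
               predict_utterances(answer_lik = alik)$answer_no_context)
  # posteriors exponentiate to a distribution
  st1 <- update_answer_priors(context_state(pri, m = 1),
                              onehot_lik(stim$questions,
                                         "How is your room currently?"))
  post1 <- integrate_context(st1, alik)
  expect_equal(sum(exp(post1$log_posterior)), 1, tolerance = 1e-9)
  # with a concentrated question, out-of-set answers are eliminated
  valid <- valid_answers(stim, "How is your room currently?")
  out_of_set <- setdiff(stim$answers, valid)
  expect_true(all(post1$log_posterior[post1$utterance %in% out_of_set] < -1e8))
  best <- post1$utterance[which.max(post1$log_posterior)]
  expect_true(best %in% valid)
  expect_error(context_state(pri, m = -1), "m must be")
})

test_that("posteriors are invariant to constant shifts of the inputs", {
  stim <- test_stim()
  pri <- build_context_priors(stim)
  set.seed(42)
  raw <- setNames(rnorm(24, -50, 10), stim$answers)
  qlik <- onehot_lik(stim$questions, stim$questions[1])
  st <- update_answer_priors(context_state(pri), qlik)
  base <- integrate_context(st, smooth_normalize(raw, 0.7))
  shifted <- integrate_context(st, smooth_normalize(raw + 555, 0.7))
  expect_equal(base$log_posterior, shifted$log_posterior, tolerance = 1e-6)
})

test_that("hand-computed toy example matches the integration arithmetic", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "qa_sets:",
    "  - set: 1",
    "    questions: ['Qa?']",
    "    answers: ['A1', 'A2']",
    "  - set: 2",
    "    questions: ['Qb?']",
    "    answers: ['B1', 'B2', 'B3']",
    "phone_seqs:",
    "  'Qa?': [k, ah]",
    "  'Qb?': [k, iy]",
    "  'A1': [ey]",
    "  'A2': [ah, t]",
    "  'B1': [b, iy]",
    "  'B2': [b, ay]",
    "  'B3': [b, uw]"
  ), f)
  stim <- read_stimulus_set(f)
  pri <- build_context_priors(stim)
  qlik <- onehot_lik(stim$questions, "Qb?")
  st <- update_answer_priors(context_state(pri, m = 1), qlik)
  alik <- smooth_normalize(
    setNames(log(c(0.4, 0.3, 0.1, 0.1, 0.1)), stim$answers), 1)
  post <- integrate_context(st, alik)
  # by hand: prior = (0, 0, 1/3, 1/3, 1/3); posterior proportional to
  # prior * likelihood = (0, 0, .1/3, .1/3, .1/3) -> uniform over B answers
  got <- setNames(exp(post$log_posterior), post$utterance)
  expect_equal(unname(got[c("B1", "B2", "B3")]), rep(1 / 3, 3),
               tolerance = 1e-6)
  expect_lt(got[["A1"]], 1e-8)
})

test_that("an answer before any question yields no context prediction", {
  stim <- test_stim()
  st <- context_state(build_context_priors(stim))
  alik <- uniform_lik(stim$answers)
  expect_null(integrate_context(st, alik))
  pred <- predict_utterances(answer_lik = alik, posterior = NULL)
  expect_false(is.na(pred$answer_no_context))
  expect_true(is.na(pred$answer_with_context))
})

test_that("prior modes transform question likelihoods as specified", {
  stim <- test_stim()
  conc <- onehot_lik(stim$questions, stim$questions[5])
  # hard on concentrated likelihoods is (numerically) idempotent
  hard <- apply_prior_mode(conc, "hard")
  expect_equal(which.max(hard$loglik), 5)
  expect_equal(max(hard$loglik), 0)
  expect_true(all(hard$loglik[-5] < -1e9))
  # true with the correct label matches hard when the argmax is correct
  tru <- apply_prior_mode(conc, "true", true_label = stim$questions[5])
  expect_equal(tru$loglik, hard$loglik)
  # hard on uniform likelihoods one-hots at the tie-broken (first) index
  unif <- uniform_lik(stim$questions)
  hard_u <- apply_prior_mode(unif, "hard")
  expect_equal(which.max(hard_u$loglik), 1)
  expect_identical(apply_prior_mode(unif, "soft"), unif)
  expect_error(apply_prior_mode(unif, "true"), "true_label")
})
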