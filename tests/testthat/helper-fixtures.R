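# Shared fixtures and independent oracles for the test suite. Heavy objects
# (synthetic blocks, the trained decoder) are built once per run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

test_stim <- function() memo("stim", function() read_stimulus_set())

# High-SNR small-scale study configuration used by the integration tests:
# reduced electrode grid and shortened training silences keep the suite fast;
# block structure (10 repetitions per stimulus, 26 testing trials) is fixed by
# the generator.
test_sim_config <- function(noise_sd = 0.05) {
  sim_config(
    n_electrodes = 32, n_perception_electrodes = 12,
    n_production_electrodes = 12, noise_sd = noise_sd,
    phone_duration_range = c(0.06, 0.12),
    inter_trial_silence_range = c(0.8, 1.2), seed = 42
  )
}

test_training_blocks <- function() {
  memo("training_blocks", function() {
    cfg <- test_sim_config()
    list(
      generate_block(cfg, test_stim(), "question_training", seed = 101),
      generate_block(cfg, test_stim(), "answer_training", seed = 102)
    )
  })
}

test_testing_block <- function() {
  memo("testing_block", function() {
    cfg <- test_sim_config()
    cfg$inter_trial_silence_range <- c(2, 3)
    generate_block(cfg, test_stim(), "testing", seed = 103)
  })
}

test_decoder <- function() {
  memo("decoder", function() {
    train_qa_decoder(
      test_training_blocks(), test_stim(),
      detector_config = detector_config(train_stride = 3),
      question_config = classifier_config(train_stride = 2),
      answer_config = classifier_config(train_stride = 2)
    )
  })
}

test_transcript <- function() {
  memo("transcript", function() decode_block(test_decoder(), test_testing_block()))
}

# --- independent oracles -----------------------------------------------------

# Brute-force Viterbi: enumerate every state path allowed by the
# left-to-right transition support (start in state 1, self or +1 moves, end
# in the final state) and maximize the summed transition and scaled emission
# log probabilities.
brute_force_viterbi <- function(hmm, frame_loglikes, w_e = 1) {
  ns <- length(hmm$states)
  nt <- nrow(frame_loglikes)
  if (nt < ns) return(-Inf)
  emit <- frame_loglikes[, hmm$states, drop = FALSE] * w_e
  best <- -Inf
  recurse <- function(t, s, acc) {
    acc <- acc + emit[t, s]
    if (t == nt) {
      if (s == ns) best <<- max(best, acc)
      return()
    }
    # remaining frames must suffice to reach the final state
    stay_tr <- hmm$log_self[s]
    if ((nt - t) >= (ns - s)) recurse(t + 1, s, acc + stay_tr)
    if (s < ns) recurse(t + 1, s + 1, acc + hmm$log_next[s])
  }
  recurse(1, 1, 0)
  best
}

# Full-length FFT-based Hilbert envelope (frequency-domain analytic signal).
fft_hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# O(n * w) sliding z-score: recompute mean/sd per trailing window.
naive_sliding_zscore <- function(x, w, clip = 3.5) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (t in seq_len(n)) {
    lo <- max(1, t - w + 1)
    win <- x[lo:t, , drop = FALSE]
    mu <- colMeans(win)
    sd <- apply(win, 2, stats::sd)
    if (nrow(win) == 1) sd <- rep(0, ncol(x))
    z <- ifelse(sd > 0, (x[t, ] - mu) / sd, 0)
    out[t, ] <- pmin(clip, pmax(-clip, z))
  }
  out
}

# Render one-hot emissions for an utterance: `per` frames per phone plus
# `pad` silence frames on both sides; returns emissions plus the utterance's
# onset/offset frames within the rendering.
render_transcription_event <- function(phones, phone_set, per = 3, pad = 3) {
  seq_phones <- c(rep("sp", pad), rep(phones, each = per), rep("sp", pad))
  list(
    emissions = transcription_emissions(seq_phones, phone_set),
    onset = pad + 1L,
    offset = pad + length(phones) * per + 1L
  )
}
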