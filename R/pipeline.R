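#' Train the full question-and-answer decoder
#'
#' Fits the three model types from training blocks: the speech detector on
#' both block types, the question classifier on perception data and the
#' answer classifier on production data.
#'
#' @param sessions List of `synthetic_session` training blocks (at least one
#'   `question_training` and one `answer_training`).
#' @param stim A [read_stimulus_set()] result.
#' @param detector_config,question_config,answer_config Model configurations.
#' @return A `qa_decoder`: list with `detector`, `question_classifier`,
#'   `answer_classifier`, `priors`, `stim`.
#' @export
train_qa_decoder <- function(sessions, stim,
                             detector_config = qadecoder::detector_config(),
                             question_config = classifier_config(),
                             answer_config = classifier_config()) {
  types <- vapply(sessions, `[[`, "", "block_type")
  q_blocks <- sessions[types == "question_training"]
  a_blocks <- sessions[types == "answer_training"]
  if (!length(q_blocks)) abort("missing question (perception) training blocks: cannot fit the question classifier")
  if (!length(a_blocks)) abort("missing answer (production) training blocks: cannot fit the answer classifier")
  structure(list(
    detector = fit_speech_detector(c(q_blocks, a_blocks), detector_config),
    question_classifier = fit_utterance_classifier(q_blocks, stim, "question",
                                                   question_config),
    answer_classifier = fit_utterance_classifier(a_blocks, stim, "answer",
                                                 answer_config),
    priors = build_context_priors(stim),
    stim = stim
  ), class = "qa_decoder")
}

#' @export
print.qa_decoder <- function(x, ...) {
  cat("<qa_decoder>\n")
  print(x$detector)
  print(x$question_classifier)
  print(x$answer_classifier)
  invisible(x)
}

# Incremental (frame-by-frame) event detection: same smoothing, binarization
# and debouncing as detect_events(), run as a streaming state machine. Used
# by replay mode; batch mode uses the vectorized path. Both are causal and
# produce identical events.
streaming_detect <- function(prob, config, frame_rate = 1, t0 = 0) {
  pr <- as.data.frame(prob)
  nf <- nrow(pr)
  out <- purrr::map_dfr(c("perception", "production"), function(mod) {
    len <- config$smooth_len[[mod]]
    thr <- config$prob_threshold[[mod]]
    tt <- config$time_threshold[[mod]]
    buf <- numeric(0)
    in_event <- FALSE
    run_val <- NA_integer_
    run_start <- 1L
    run_len <- 0L
    cur_on <- NA_integer_
    onsets <- integer(0); offsets <- integer(0)
    flush_run <- function() {
      if (is.na(run_val)) return()
      if (!in_event && run_val == 1L && run_len >= tt) {
        in_event <<- TRUE
        cur_on <<- run_start
      } else if (in_event && run_val == 0L && run_len >= tt) {
        onsets <<- c(onsets, cur_on)
        offsets <<- c(offsets, run_start)
        in_event <<- FALSE
      }
    }
    for (t in seq_len(nf)) {
      buf <- c(buf, pr[[mod]][t])
      if (length(buf) > len) buf <- buf[-1]
      b <- as.integer(mean(buf) > thr)
      if (!is.na(run_val) && b == run_val) {
        run_len <- run_len + 1L
      } else {
        flush_run()
        run_val <- b
        run_start <- t
        run_len <- 1L
      }
      # a run can satisfy the debounce before it ends
      if (run_len == tt) flush_run()
    }
    if (in_event) {
      onsets <- c(onsets, cur_on)
      offsets <- c(offsets, nf + 1L)
    }
    if (!length(onsets)) return(NULL)
    on <- pmax(1L, pmin(nf, onsets + config$onset_shift[[mod]]))
    off <- pmax(1L, pmin(nf + 1L, offsets + config$offset_shift[[mod]]))
    keep <- off > on
    tibble::tibble(modality = mod, onset_frame = on[keep],
                   offset_frame = off[keep])
  })
  if (!nrow(out)) {
    return(tibble::tibble(modality = character(), onset_frame = integer(),
                          offset_frame = integer(), onset_s = numeric(),
                          offset_s = numeric(), n_frames = integer()))
  }
  out |>
    dplyr::mutate(onset_s = t0 + (.data$onset_frame - 1) / frame_rate,
                  offset_s = t0 + (.data$offset_frame - 1) / frame_rate,
                  n_frames = .data$offset_frame - .data$onset_frame) |>
    dplyr::arrange(.data$onset_frame)
}

#' Decode one test block
#'
#' Runs detection over the block, classifies each detected event in temporal
#' order, and maintains the context state across the block: question events
#' update the answer priors; answer events are integrated with the current
#' priors. Priors are reset at the start of every block.
#'
#' @param decoder A [train_qa_decoder()] result.
#' @param session A testing `synthetic_session` (or any session with
#'   `features`).
#' @param m Context prior scaling factor.
#' @param prior_mode Question prior mode: `"soft"`, `"hard"`, or `"true"`
#'   (see [apply_prior_mode()]; `"true"` reads question identities from the
#'   session's trial log).
#' @param mode `"batch"` (vectorized detection) or `"replay"` (frame-by-frame
#'   streaming detection); both are causal and produce identical transcripts.
#' @return A decoding transcript tibble: one row per detected event with
#'   `event_id`, `modality`, `onset_frame`, `offset_frame`, `onset_s`,
#'   `offset_s`, predictions (`question`, `answer_no_context`,
#'   `answer_with_context`), and list columns `likelihoods` /` posterior`.
#' @export
decode_block <- function(decoder, session, m = 1,
                         prior_mode = c("soft", "hard", "true"),
                         mode = c("batch", "replay")) {
  prior_mode <- match.arg(prior_mode)
  mode <- match.arg(mode)
  features <- session$features
  prob <- event_probabilities(decoder$detector, features)
  events <- if (mode == "batch") {
    detect_events(prob, decoder$detector$config, frame_rate(features),
                  attr(features, "t0"))
  } else {
    streaming_detect(prob, decoder$detector$config, frame_rate(features),
                     attr(features, "t0"))
  }
  state <- context_state(decoder$priors, m = m)
  q_seen <- 0L
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$modality == "perception") {
      lik <- classify_event(decoder$question_classifier, features,
                            ev$onset_frame, ev$offset_frame)
      q_seen <- q_seen + 1L
      true_q <- if (!is.null(session$trial_log) &&
                    q_seen <= nrow(session$trial_log)) {
        session$trial_log$question[q_seen]
      } else NULL
      lik_for_prior <- apply_prior_mode(lik, prior_mode, true_label = true_q)
      state <- update_answer_priors(state, lik_for_prior)
      pred <- predict_utterances(question_lik = lik)
      rows[[i]] <- tibble::tibble(
        event_id = i, modality = "perception",
        onset_frame = ev$onset_frame, offset_frame = ev$offset_frame,
        onset_s = ev$onset_s, offset_s = ev$offset_s,
        question = pred$question, answer_no_context = NA_character_,
        answer_with_context = NA_character_,
        likelihoods = list(lik), posterior = list(NULL)
      )
    } else {
      lik <- classify_event(decoder$answer_classifier, features,
                            ev$onset_frame, ev$offset_frame)
      post <- integrate_context(state, lik)
      pred <- predict_utterances(answer_lik = lik, posterior = post)
      rows[[i]] <- tibble::tibble(
        event_id = i, modality = "production",
        onset_frame = ev$onset_frame, offset_frame = ev$offset_frame,
        onset_s = ev$onset_s, offset_s = ev$offset_s,
        question = NA_character_, answer_no_context = pred$answer_no_context,
        answer_with_context = pred$answer_with_context,
        likelihoods = list(lik), posterior = list(post)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Classify test-block events at their true times
#'
#' Classification (as opposed to decoding) uses the transcribed event times:
#' each true event window, padded with `pad_s` seconds of silence on both
#' sides, is passed to the matching classifier, and context integration runs
#' across the block in temporal order.
#'
#' @inheritParams decode_block
#' @param pad_s Silence padding in seconds (default 0.3).
#' @return A transcript tibble as in [decode_block()], plus a `label` column
#'   with the true utterance.
#' @export
classify_block <- function(decoder, session, m = 1,
                           prior_mode = c("soft", "hard", "true"),
                           pad_s = 0.3) {
  prior_mode <- match.arg(prior_mode)
  features <- session$features
  evs <- true_events(session)
  state <- context_state(decoder$priors, m = m)
  rows <- vector("list", nrow(evs))
  for (i in seq_len(nrow(evs))) {
    ev <- evs[i, ]
    on_f <- time_to_frame(features, ev$onset_s)
    off_f <- time_to_frame(features, ev$offset_s)
    if (ev$modality == "perception") {
      lik <- classify_event(decoder$question_classifier, features, on_f, off_f,
                            pad_s = pad_s)
      lik_for_prior <- apply_prior_mode(lik, prior_mode, true_label = ev$label)
      state <- update_answer_priors(state, lik_for_prior)
      pred <- predict_utterances(question_lik = lik)
      rows[[i]] <- tibble::tibble(
        event_id = i, modality = "perception", label = ev$label,
        onset_s = ev$onset_s, offset_s = ev$offset_s,
        question = pred$question, answer_no_context = NA_character_,
        answer_with_context = NA_character_,
        likelihoods = list(lik), posterior = list(NULL)
      )
    } else {
      lik <- classify_event(decoder$answer_classifier, features, on_f, off_f,
                            pad_s = pad_s)
      post <- integrate_context(state, lik)
      pred <- predict_utterances(answer_lik = lik, posterior = post)
      rows[[i]] <- tibble::tibble(
        event_id = i, modality = "production", label = ev$label,
        onset_s = ev$onset_s, offset_s = ev$offset_s,
        question = NA_character_, answer_no_context = pred$answer_no_context,
        answer_with_context = pred$answer_with_context,
        likelihoods = list(lik), posterior = list(post)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Evaluate a decoding transcript against a session
#'
#' Computes decoding accuracy rates (questions, answers without and with
#' context) against the session's trial log, and detection scores per
#' modality against the transcribed events.
#'
#' @param transcript A [decode_block()] transcript.
#' @param session The decoded `synthetic_session` (testing block).
#' @return Tibble with one row per metric: `metric`, `modality`, `value`.
#' @export
evaluate_decoding <- function(transcript, session) {
  tl <- session$trial_log
  if (is.null(tl)) abort("session has no trial log (not a testing block)")
  qs <- transcript$question[transcript$modality == "perception"]
  am <- transcript$answer_no_context[transcript$modality == "production"]
  ap <- transcript$answer_with_context[transcript$modality == "production"]
  acc <- function(actual, pred) {
    utterance_error_rate(actual, pred[!is.na(pred)])$accuracy_rate
  }
  tev <- true_events(session)
  feats <- session$features
  det <- purrr::map_dfr(c("perception", "production"), function(mod) {
    detection_score(
      tev |> dplyr::filter(.data$modality == mod),
      transcript |> dplyr::filter(.data$modality == mod),
      n_frames(feats), frame_rate(feats), attr(feats, "t0")
    ) |> dplyr::mutate(modality = mod)
  })
  dplyr::bind_rows(
    tibble::tibble(metric = "accuracy_rate_question", modality = "perception",
                   value = acc(tl$question, qs)),
    tibble::tibble(metric = "accuracy_rate_answer_no_context",
                   modality = "production", value = acc(tl$answer, am)),
    tibble::tibble(metric = "accuracy_rate_answer_with_context",
                   modality = "production", value = acc(tl$answer, ap)),
    det |> dplyr::transmute(metric = "detection_score", .data$modality,
                            value = .data$score)
  )
}
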