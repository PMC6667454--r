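#' Configuration for synthetic session generation
#'
#' The generator emulates the statistical structure the decoder assumes:
#' frame-rate z-scored high-gamma activity across an electrode grid, with
#' phone-specific spatial response patterns confined to modality-specific
#' electrode subsets (an "auditory" subset active during perception and a
#' "motor" subset active during production), the block/trial structure of the
#' task, inter-trial silences, and additive Gaussian noise.
#'
#' Electrodes `1..n_perception_electrodes` form the auditory subset and the
#' next `n_production_electrodes` the motor subset; the remainder never carry
#' signal.
#'
#' @param n_electrodes Total electrode count (default 128).
#' @param frame_rate Feature frame rate in Hz (default 95.37, the decimated
#'   rate of the acquisition chain).
#' @param n_perception_electrodes,n_production_electrodes Sizes of the
#'   modality-responsive subsets (defaults 32 each).
#' @param template_gain Peak phone-response amplitude in z-score units
#'   (default 2).
#' @param noise_sd Additive noise standard deviation in z-score units
#'   (default 1).
#' @param phone_duration_range Uniform range of synthetic phone durations in
#'   seconds (default 0.06-0.20).
#' @param inter_trial_silence_range Uniform range of silences between events
#'   in seconds (default 2-3).
#' @param ar_coef Optional AR(1) coefficient for temporally correlated noise
#'   (default 0, i.i.d.).
#' @param clip Feature clip bound (default 3.5).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   sessions.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_electrodes = 128, frame_rate = 95.37,
                       n_perception_electrodes = 32,
                       n_production_electrodes = 32,
                       template_gain = 2, noise_sd = 1,
                       phone_duration_range = c(0.06, 0.20),
                       inter_trial_silence_range = c(2, 3),
                       ar_coef = 0, clip = 3.5, seed = 1L) {
  if (n_perception_electrodes + n_production_electrodes > n_electrodes) {
    abort("modality-responsive electrode counts exceed n_electrodes")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (frame_rate <= 0) abort("frame_rate must be positive")
  if (length(phone_duration_range) != 2 || diff(phone_duration_range) < 0 ||
      phone_duration_range[1] <= 0) {
    abort("phone_duration_range must be an increasing positive pair")
  }
  structure(list(
    n_electrodes = as.integer(n_electrodes), frame_rate = frame_rate,
    n_perception_electrodes = as.integer(n_perception_electrodes),
    n_production_electrodes = as.integer(n_production_electrodes),
    template_gain = template_gain, noise_sd = noise_sd,
    phone_duration_range = phone_duration_range,
    inter_trial_silence_range = inter_trial_silence_range,
    ar_coef = ar_coef, clip = clip, seed = as.integer(seed)
  ), class = "sim_config")
}

# Smooth within-phone amplitude profile, nonzero across the whole interval so
# every frame of a phone carries its spatial signature.
phone_kernel <- function(u) 0.7 + 0.3 * sin(pi * u)

#' Generate phone response templates
#'
#' Each non-silence phone receives, per modality, a distinct spatial weight
#' vector supported only on the modality-appropriate electrode subset
#' (auditory for perception, motor for production), with unit L2 norm. The
#' silence token `sp` maps to the zero pattern. Templates are deterministic
#' given the configuration seed.
#'
#' @param config A [sim_config()].
#' @param phone_inventory Character vector of phone labels including `"sp"`
#'   (e.g. `read_stimulus_set()$phone_inventory`).
#' @return List with elements `perception` and `production`, each an
#'   electrodes-by-phones spatial weight matrix (columns named by phone), and
#'   `kernel`, the within-phone temporal profile function of fractional
#'   position.
#' @export
make_phone_templates <- function(config, phone_inventory) {
  if (length(phone_inventory) == 0) abort("phone inventory is empty")
  if (!"sp" %in% phone_inventory) abort("phone inventory must contain the silence token 'sp'")
  n_e <- config$n_electrodes
  idx <- list(
    perception = seq_len(config$n_perception_electrodes),
    production = config$n_perception_electrodes +
      seq_len(config$n_production_electrodes)
  )
  with_seed(config$seed, {
    spat <- lapply(idx, function(rows) {
      m <- matrix(0, n_e, length(phone_inventory),
                  dimnames = list(NULL, phone_inventory))
      for (ph in phone_inventory) {
        if (ph == "sp") next
        w <- runif(length(rows))
        m[rows, ph] <- w / sqrt(sum(w^2))
      }
      m
    })
    list(perception = spat$perception, production = spat$production,
         kernel = phone_kernel)
  })
}

# Build the ordered event list for one block.
block_events <- function(config, stim, block_type, weight_questions) {
  switch(block_type,
    question_training = {
      labels <- sample(rep(stim$questions, each = 10))
      tibble::tibble(label = labels, modality = "perception",
                     question = NA_character_)
    },
    answer_training = {
      labels <- sample(rep(stim$answers, each = 10))
      tibble::tibble(label = labels, modality = "production",
                     question = NA_character_)
    },
    testing = {
      wts <- if (weight_questions) {
        vapply(stim$questions, function(q) length(valid_answers(stim, q)), 0)
      } else rep(1, length(stim$questions))
      qs <- sample(stim$questions, 26, replace = TRUE, prob = wts)
      as_ <- vapply(qs, function(q) {
        va <- valid_answers(stim, q)
        va[sample.int(length(va), 1)]
      }, "")
      tibble::tibble(
        label = as.vector(rbind(qs, as_)),
        modality = rep(c("perception", "production"), times = 26),
        question = rep(qs, each = 2)
      )
    },
    abort(paste0("unknown block_type: ", block_type))
  )
}

#' Generate a synthetic session block
#'
#' Builds one task block: `question_training` (each question presented 10
#' times in random order), `answer_training` (each answer produced 10 times in
#' random order), or `testing` (26 question-and-answer trials, each a question
#' event followed by an answer event drawn from that question's valid
#' answers, separated by inter-trial silences). Features are the sum of
#' per-phone template activations plus Gaussian noise, clipped to
#' `[-clip, clip]`.
#'
#' @param config A [sim_config()].
#' @param stim A [read_stimulus_set()] result.
#' @param block_type One of `"question_training"`, `"answer_training"`,
#'   `"testing"`.
#' @param seed Seed for this block (defaults to `config$seed`, making the
#'   session a pure function of the configuration; pass different seeds to
#'   generate distinct blocks under one configuration).
#' @param weight_questions If `TRUE`, testing-block questions are sampled with
#'   probability proportional to their number of valid answers; default
#'   `FALSE` (uniform).
#'
#' @return A `synthetic_session` list: `features` ([feature_stream()]),
#'   `transcription` (tibble: `utterance_id`, `label`, `phone`, `onset_s`,
#'   `offset_s`, `modality`; half-open intervals), `block_type`, and for
#'   testing blocks `trial_log` (tibble: `question`, `answer`).
#' @export
generate_block <- function(config, stim, block_type, seed = config$seed,
                           weight_questions = FALSE) {
  templates <- make_phone_templates(config, stim$phone_inventory)
  rate <- config$frame_rate
  with_seed(seed, {
    events <- block_events(config, stim, block_type, weight_questions)
    n_ev <- nrow(events)
    gaps <- runif(n_ev + 1, config$inter_trial_silence_range[1],
                  config$inter_trial_silence_range[2])
    trans <- vector("list", n_ev)
    t_cur <- gaps[1]
    for (i in seq_len(n_ev)) {
      phones <- phone_sequence(stim, events$label[i])
      durs <- runif(length(phones), config$phone_duration_range[1],
                    config$phone_duration_range[2])
      offs <- t_cur + cumsum(durs)
      ons <- c(t_cur, head(offs, -1))
      trans[[i]] <- tibble::tibble(
        utterance_id = i, label = events$label[i], phone = phones,
        onset_s = ons, offset_s = offs, modality = events$modality[i]
      )
      t_cur <- offs[length(offs)] + gaps[i + 1]
    }
    transcription <- dplyr::bind_rows(trans)
    total_s <- t_cur
    nf <- as.integer(ceiling(total_s * rate))
    x <- matrix(0, nf, config$n_electrodes)
    frame_t <- (seq_len(nf) - 1) / rate
    for (i in seq_len(nrow(transcription))) {
      row <- transcription[i, ]
      if (row$phone == "sp") next
      fs <- which(frame_t >= row$onset_s & frame_t < row$offset_s)
      if (!length(fs)) next
      u <- (frame_t[fs] - row$onset_s) / (row$offset_s - row$onset_s)
      spat <- templates[[row$modality]][, row$phone]
      x[fs, ] <- x[fs, ] +
        outer(config$template_gain * templates$kernel(u), spat)
    }
    if (config$noise_sd > 0) {
      eps <- matrix(rnorm(nf * config$n_electrodes, sd = config$noise_sd),
                    nf, config$n_electrodes)
      if (config$ar_coef != 0) {
        eps <- apply(eps, 2, function(e)
          as.numeric(stats::filter(e * sqrt(1 - config$ar_coef^2),
                                   config$ar_coef, method = "recursive")))
      }
      x <- x + eps
    }
    x <- pmin(pmax(x, -config$clip), config$clip)
    session <- list(
      features = feature_stream(x, frame_rate = rate, t0 = 0,
                                clip = config$clip),
      transcription = transcription,
      block_type = block_type,
      trial_log = if (block_type == "testing") {
        tibble::tibble(question = events$question[events$modality == "perception"],
                       answer = events$label[events$modality == "production"])
      } else NULL
    )
    structure(session, class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %s: %d frames, %d utterances\n",
              x$block_type, n_frames(x$features),
              length(unique(x$transcription$utterance_id))))
  invisible(x)
}

#' Per-frame modality labels from a transcription
#'
#' Labels each feature frame `perception`, `production`, or `silence` using
#' the half-open frame convention (a frame belongs to the phone interval
#' containing its start time). The silence phone `sp` inside an utterance is
#' labeled by the utterance's modality.
#'
#' @param session A `synthetic_session`, or a list with `features` and
#'   `transcription`.
#' @return Character vector, one label per frame.
#' @export
frame_labels <- function(session) {
  nf <- n_frames(session$features)
  frame_t <- frame_to_time(session$features, seq_len(nf))
  lab <- rep("silence", nf)
  tr <- session$transcription
  for (i in seq_len(nrow(tr))) {
    sel <- frame_t >= tr$onset_s[i] & frame_t < tr$offset_s[i]
    lab[sel] <- tr$modality[i]
  }
  lab
}

#' Per-frame phone labels from a transcription
#'
#' @inheritParams frame_labels
#' @param modality Restrict to one modality; frames outside transcribed
#'   intervals (and frames of the other modality) are labeled `"sp"`.
#' @return Character vector of phone labels, one per frame.
#' @export
frame_phones <- function(session, modality = c("perception", "production")) {
  modality <- match.arg(modality)
  nf <- n_frames(session$features)
  frame_t <- frame_to_time(session$features, seq_len(nf))
  lab <- rep("sp", nf)
  tr <- session$transcription[session$transcription$modality == modality, ]
  for (i in seq_len(nrow(tr))) {
    sel <- frame_t >= tr$onset_s[i] & frame_t < tr$offset_s[i]
    lab[sel] <- tr$phone[i]
  }
  lab
}

#' True utterance events of a session
#'
#' @inheritParams frame_labels
#' @return Tibble with one row per utterance: `utterance_id`, `label`,
#'   `modality`, `onset_s`, `offset_s`.
#' @export
true_events <- function(session) {
  session$transcription |>
    dplyr::group_by(.data$utterance_id, .data$label, .data$modality) |>
    dplyr::summarise(onset_s = min(.data$onset_s),
                     offset_s = max(.data$offset_s), .groups = "drop") |>
    dplyr::arrange(.data$onset_s)
}
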