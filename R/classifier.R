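#' Utterance classifier configuration
#'
#' Hyperparameters of the phone-HMM utterance classifier: the Welch t-test
#' electrode selection threshold, the spatiotemporal feature window and PCA
#' variance fraction of the phone likelihood model, the HMM self-transition
#' probability, the emission scaling factor, and the likelihood smoothing
#' parameter.
#'
#' @param p_threshold Welch t-test p-value threshold for electrode relevance.
#' @param nu_shift,nu_duration Feature window parameters in frames (see
#'   [build_feature_vectors()]).
#' @param pca_variance_fraction PCA variance fraction in (0, 1].
#' @param p_self HMM self-transition probability in (0, 1); the expected
#'   dwell per non-final state is `1/(1 - p_self)` frames.
#' @param w_e Emission probability scaling factor weighting emissions against
#'   transitions in the Viterbi recursion.
#' @param omega Likelihood smoothing parameter in \[0, 1\]; 0 flattens the
#'   normalized likelihoods to uniform, 1 applies a plain log-softmax.
#' @param pad_s Silence padding (seconds) added before and after true event
#'   windows prior to Viterbi decoding (default 0.3).
#' @param train_stride Use every `train_stride`-th frame when fitting the
#'   phone model.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(p_threshold = 1e-3, nu_shift = -4,
                              nu_duration = 8, pca_variance_fraction = 0.8,
                              p_self = 0.9, w_e = 1, omega = 1, pad_s = 0.3,
                              train_stride = 1) {
  if (!(p_self > 0 && p_self < 1)) abort("p_self must lie in (0, 1)")
  if (!(omega >= 0 && omega <= 1)) abort("omega must lie in [0, 1]")
  if (w_e < 0) abort("w_e must be >= 0")
  structure(list(p_threshold = p_threshold, nu_shift = as.integer(nu_shift),
                 nu_duration = as.integer(nu_duration),
                 pca_variance_fraction = pca_variance_fraction,
                 p_self = p_self, w_e = w_e, omega = omega, pad_s = pad_s,
                 train_stride = as.integer(train_stride)),
            class = "classifier_config")
}

#' Build a left-to-right phone HMM for an utterance
#'
#' States are the utterance's representative phone sequence flanked by
#' initial and final silence states (`sp`). Each non-final state
#' self-transitions with probability `p_self` or advances to the next state
#' with probability `1 - p_self`; the final state is absorbing
#' (self-transition probability 1).
#'
#' @param phone_seq Character vector of phone labels (without boundary
#'   silences).
#' @param p_self Self-transition probability in (0, 1).
#' @param label Optional utterance label carried on the object.
#' @return An `utterance_hmm`: list with `states` (length
#'   `length(phone_seq) + 2`), `log_self`, `log_next`, `label`.
#' @export
build_hmm <- function(phone_seq, p_self, label = NULL) {
  if (!length(phone_seq)) abort("phone sequence must be non-empty")
  if (!(p_self > 0 && p_self < 1)) abort("p_self must lie in (0, 1)")
  states <- c("sp", as.character(phone_seq), "sp")
  ns <- length(states)
  log_self <- c(rep(log(p_self), ns - 1), 0)          # final state absorbing
  log_next <- c(rep(log(1 - p_self), ns - 1), -Inf)
  structure(list(states = states, log_self = log_self, log_next = log_next,
                 p_self = p_self, label = label),
            class = "utterance_hmm")
}

#' @export
print.utterance_hmm <- function(x, ...) {
  cat(sprintf("<utterance_hmm>%s %d states: %s\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$states), paste(x$states, collapse = " ")))
  invisible(x)
}

#' @rdname build_hmm
#' @param x An `utterance_hmm`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.utterance_hmm <- function(x, ...) {
  tibble::tibble(state = seq_along(x$states), phone = x$states,
                 p_self = exp(x$log_self), p_next = exp(x$log_next))
}

#' Viterbi log likelihood of an utterance HMM
#'
#' Runs the Viterbi recursion
#' `v(t, s) = w_e * log p(y_t | s) + max_i [v(t-1, i) + log p(s | i)]`
#' over the left-to-right HMM, initialized with path log probability 0 at the
#' first state (the initial silence) and `-Inf` elsewhere, so
#' `v(1, s1) = w_e * log p(y_1 | sp)`. The utterance log likelihood is the
#' final-state value at the final frame. Also returns, per frame, the running
#' best-path log probability (max over states), used for decision
#' finalization analyses.
#'
#' @param hmm An [build_hmm()] object.
#' @param frame_loglikes Frames-by-phones matrix of emission log likelihoods
#'   `log p(y_t | s)`, columns named by phone; must cover every phone the HMM
#'   uses.
#' @param w_e Emission scaling factor.
#' @return List with `loglik` (scalar; `-Inf` when the stream is shorter than
#'   the state count, making the utterance infeasible) and `frame_scores`
#'   (numeric vector, one running score per frame).
#' @export
viterbi_log_likelihood <- function(hmm, frame_loglikes, w_e = 1) {
  ll <- as.matrix(frame_loglikes)
  nt <- nrow(ll)
  if (nt < 1) abort("need at least one frame")
  miss <- setdiff(unique(hmm$states), colnames(ll))
  if (length(miss)) abort(paste0("frame log likelihoods missing phone: ", miss[1]))
  ns <- length(hmm$states)
  emit <- ll[, hmm$states, drop = FALSE] * w_e     # frames x states
  v <- c(emit[1, 1], rep(-Inf, ns - 1))
  scores <- numeric(nt)
  scores[1] <- max(v)
  if (nt >= 2) {
    for (t in 2:nt) {
      stay <- v + hmm$log_self
      move <- c(-Inf, v[-ns] + hmm$log_next[-ns])
      v <- emit[t, ] + pmax(stay, move)
      scores[t] <- max(v)
    }
  }
  loglik <- if (nt < ns) -Inf else unname(v[ns])
  list(loglik = loglik, frame_scores = scores)
}

#' Smooth and normalize utterance log likelihoods
#'
#' Applies `l*_u = omega * l_u - LogSumExp_j(omega * l_j)` with
#' max-subtraction for stability, so that `sum_u exp(l*_u) = 1`. At
#' `omega = 0` the result is uniform (`-log |U|` for every utterance); at
#' `omega = 1` it is a plain log-softmax of the raw values.
#'
#' @param loglik Named numeric vector of raw utterance log likelihoods; at
#'   least one value must be finite.
#' @param omega Smoothing parameter in \[0, 1\].
#' @return A `likelihood_set` tibble with columns `utterance`, `raw`,
#'   `loglik` (the smoothed normalized values) and attribute `omega`.
#' @export
smooth_normalize <- function(loglik, omega = 1) {
  if (!(omega >= 0 && omega <= 1)) abort("omega must lie in [0, 1]")
  if (is.null(names(loglik))) abort("loglik must be named by utterance")
  if (all(!is.finite(loglik))) abort("all utterance log likelihoods are -Inf")
  sm <- omega * loglik
  sm[loglik == -Inf] <- -Inf      # infeasible utterances stay impossible
  out <- sm - logsumexp(sm)
  res <- tibble::tibble(utterance = names(loglik), raw = unname(loglik),
                        loglik = unname(out))
  structure(res, omega = omega,
            class = c("likelihood_set", class(res)))
}

#' Fit an utterance classifier for one modality
#'
#' Selects modality-relevant electrodes with per-electrode Welch t-tests
#' (modality vs. silence), trains a PCA-LDA phone likelihood model on
#' spatiotemporal feature vectors labeled with the transcribed phone at each
#' frame (`sp` elsewhere), and builds one left-to-right HMM per candidate
#' utterance from its representative phone sequence.
#'
#' @param sessions A `synthetic_session` or list of them containing the
#'   modality's training data.
#' @param stim A [read_stimulus_set()] result.
#' @param type `"question"` (perception) or `"answer"` (production).
#' @param config A [classifier_config()].
#' @return An `utterance_classifier`: list with `phone_model`
#'   ([fit_pca_lda()]), `electrodes`, `hmms` (named list), `type`, `modality`,
#'   `phones`, `config`, plus feature-map metadata.
#' @export
fit_utterance_classifier <- function(sessions, stim,
                                     type = c("question", "answer"),
                                     config = classifier_config()) {
  type <- match.arg(type)
  modality <- if (type == "question") "perception" else "production"
  if (inherits(sessions, "synthetic_session")) sessions <- list(sessions)
  feats <- lapply(sessions, function(s) as.matrix(s$features))
  pooled <- do.call(rbind, feats)
  pooled_mod <- unlist(lapply(sessions, frame_labels))
  electrodes <- select_modality_electrodes(pooled, pooled_mod, modality,
                                           config$p_threshold)
  if (!length(electrodes)) abort("no electrodes passed the t-test threshold")

  xs <- list(); ys <- list(); em <- NULL
  for (i in seq_along(sessions)) {
    ph <- frame_phones(sessions[[i]], modality)
    bv <- build_feature_vectors(feats[[i]], electrodes, config$nu_shift,
                                config$nu_duration)
    keep <- seq(1, length(bv$frame), by = config$train_stride)
    xs[[i]] <- bv$x[keep, , drop = FALSE]
    ys[[i]] <- ph[bv$frame[keep]]
    em <- bv
  }
  phone_model <- fit_pca_lda(do.call(rbind, xs), unlist(ys),
                             config$pca_variance_fraction)

  labels <- if (type == "question") stim$questions else stim$answers
  hmms <- setNames(lapply(labels, function(u) {
    build_hmm(phone_sequence(stim, u), config$p_self, label = u)
  }), labels)

  structure(list(phone_model = phone_model, electrodes = electrodes,
                 electrode_map = em$electrode, lag_map = em$lag,
                 hmms = hmms, type = type, modality = modality,
                 phones = phone_model$classes, config = config),
            class = "utterance_classifier")
}

#' @export
print.utterance_classifier <- function(x, ...) {
  cat(sprintf("<utterance_classifier> %s (%s): %d utterances, %d phones, %d electrodes\n",
              x$type, x$modality, length(x$hmms), length(x$phones),
              length(x$electrodes)))
  invisible(x)
}

# Per-frame phone emission log likelihoods for a window of the stream.
# LDA class log posteriors under flat priors serve as likelihood surrogates;
# a log floor keeps rounded-to-zero posteriors finite. Frames whose feature
# window leaves the stream are dropped (can only happen at stream edges).
phone_frame_loglikes <- function(classifier, features, frames) {
  bv <- build_feature_vectors(as.matrix(features), classifier$electrodes,
                              classifier$config$nu_shift,
                              classifier$config$nu_duration, frames = frames)
  if (!length(bv$frame)) abort("empty decoding window")
  lp <- predict(classifier$phone_model, bv$x, type = "logposterior")
  lp <- log_floor(lp)
  list(loglik = lp, frame = bv$frame)
}

#' Classify a detected or transcribed event window
#'
#' Computes each candidate utterance's Viterbi log likelihood over the event's
#' feature window and returns the smoothed normalized likelihood set. When
#' classifying from true (transcribed) event times, `pad_s` seconds of
#' context are prepended/appended before decoding (truncated at stream
#' edges); detector-produced windows are used as-is, their index shifts
#' having already widened the window.
#'
#' @param classifier An [fit_utterance_classifier()] result.
#' @param features A [feature_stream()].
#' @param onset_frame,offset_frame Event window, half-open frame interval.
#' @param pad_s Silence padding in seconds (default 0: detector window).
#' @return A `likelihood_set` tibble (see [smooth_normalize()]) with
#'   attributes `frame_scores` (utterances x frames matrix of running
#'   best-path log probabilities) and `frames` (decoded frame indices).
#' @export
classify_event <- function(classifier, features, onset_frame, offset_frame,
                           pad_s = 0) {
  nf <- nrow(as.matrix(features))
  pad <- as.integer(round(pad_s * frame_rate(features)))
  lo <- max(1L, onset_frame - pad)
  hi <- min(nf, offset_frame - 1L + pad)
  if (hi < lo) abort("empty decoding window")
  fl <- phone_frame_loglikes(classifier, features, frames = lo:hi)
  w_e <- classifier$config$w_e
  vit <- lapply(classifier$hmms, viterbi_log_likelihood,
                frame_loglikes = fl$loglik, w_e = w_e)
  raw <- vapply(vit, `[[`, 0, "loglik")
  scores <- do.call(rbind, lapply(vit, `[[`, "frame_scores"))
  ls <- smooth_normalize(raw, classifier$config$omega)
  attr(ls, "frame_scores") <- scores
  attr(ls, "frames") <- fl$frame
  attr(ls, "w_e") <- w_e
  ls
}

#' Frame-wise phone classification
#'
#' Most likely phone per frame under the classifier's emission model; used for
#' phone confusion analyses.
#'
#' @param classifier An [fit_utterance_classifier()] result.
#' @param features A [feature_stream()].
#' @param frames Frame indices to classify (default all usable frames).
#' @return Tibble with `frame` and `phone` columns (frames with out-of-bounds
#'   feature windows are omitted).
#' @export
phone_frame_classify <- function(classifier, features, frames = NULL) {
  xm <- as.matrix(features)
  if (is.null(frames)) frames <- seq_len(nrow(xm))
  bv <- build_feature_vectors(xm, classifier$electrodes,
                              classifier$config$nu_shift,
                              classifier$config$nu_duration, frames = frames)
  cls <- predict(classifier$phone_model, bv$x, type = "class")
  tibble::tibble(frame = bv$frame, phone = cls)
}
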