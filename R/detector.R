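#' Speech detector configuration
#'
#' Hyperparameters of the frame-wise speech event detector: electrode
#' selection threshold, the spatiotemporal feature window, PCA variance
#' fraction, and the per-modality smoothing/threshold/debounce parameters used
#' to turn frame probabilities into events. Event-stage parameters may be
#' given as a single value (shared by both modalities) or as a named vector
#' `c(perception = ..., production = ...)`.
#'
#' @param anova_p_threshold Welch ANOVA p-value threshold for electrode
#'   relevance.
#' @param nu_shift,nu_duration Feature window onset shift and duration in
#'   frames; the window for frame `t` is the closed interval
#'   `[t + nu_shift, t + nu_shift + nu_duration]`.
#' @param pca_variance_fraction PCA variance fraction in (0, 1].
#' @param smooth_len Trailing probability-averaging window length (frames).
#' @param prob_threshold Probability threshold for binarization, in (0, 1).
#' @param time_threshold Debounce duration (frames) a binarized value must
#'   hold before an onset/offset is accepted.
#' @param onset_shift,offset_shift Integers added to detected onset/offset
#'   frame indices before segmenting the neural data (negative onset shifts
#'   and positive offset shifts widen the window to include silence padding).
#' @param train_stride Use every `train_stride`-th usable frame when fitting
#'   the event model (1 keeps all frames).
#'
#' @return A `detector_config` list.
#' @export
detector_config <- function(anova_p_threshold = 1e-3, nu_shift = -9,
                            nu_duration = 9, pca_variance_fraction = 0.8,
                            smooth_len = 10, prob_threshold = 0.4,
                            time_threshold = 8, onset_shift = -20,
                            offset_shift = 20, train_stride = 1) {
  if (nu_duration < 0) abort("nu_duration must be >= 0")
  if (!(pca_variance_fraction > 0 && pca_variance_fraction <= 1)) {
    abort("pca_variance_fraction must lie in (0, 1]")
  }
  pm <- function(x, name) {
    v <- if (length(x) == 1) c(perception = unname(x), production = unname(x))
         else x[c("perception", "production")]
    if (anyNA(v)) abort(paste0(name, " must name perception and production"))
    v
  }
  prob <- pm(prob_threshold, "prob_threshold")
  if (any(prob <= 0 | prob >= 1)) abort("prob_threshold must lie in (0, 1)")
  tt <- pm(time_threshold, "time_threshold")
  if (any(tt < 1)) abort("time_threshold must be >= 1")
  structure(list(
    anova_p_threshold = anova_p_threshold,
    nu_shift = as.integer(nu_shift), nu_duration = as.integer(nu_duration),
    pca_variance_fraction = pca_variance_fraction,
    smooth_len = pm(smooth_len, "smooth_len"),
    prob_threshold = prob,
    time_threshold = tt,
    onset_shift = pm(onset_shift, "onset_shift"),
    offset_shift = pm(offset_shift, "offset_shift"),
    train_stride = as.integer(train_stride)
  ), class = "detector_config")
}

#' Select event-responsive electrodes by Welch ANOVA
#'
#' Runs Welch's analysis of variance (unequal variances) on each electrode's
#' z-scores across the three frame classes (perception, production, silence)
#' and keeps electrodes with p-value below the threshold. Electrodes whose
#' test fails (e.g. a constant class) are excluded.
#'
#' @param features A [feature_stream()] or frames-by-electrodes matrix.
#' @param labels Per-frame class labels; all three classes must be present.
#' @param p_threshold Inclusion threshold; electrodes with `p < p_threshold`
#'   are selected.
#' @return Integer vector of electrode indices.
#' @export
select_event_electrodes <- function(features, labels, p_threshold) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 3) {
    abort("all three frame classes must be present")
  }
  g <- factor(labels)
  p <- vapply(seq_len(ncol(x)), function(e) {
    tryCatch(oneway.test(x[, e] ~ g, var.equal = FALSE)$p.value,
             error = function(err) NA_real_)
  }, 0)
  which(!is.na(p) & p < p_threshold)
}

#' Per-electrode Welch test electrode selection for one modality
#'
#' Two-tailed Welch t-test per electrode between frames of the given modality
#' and silence frames; electrodes with `p < p_threshold` are selected. Used to
#' pick the channels feeding the question (perception vs. silence) and answer
#' (production vs. silence) phone likelihood models.
#'
#' @inheritParams select_event_electrodes
#' @param modality `"perception"` or `"production"`.
#' @return Integer vector of electrode indices.
#' @export
select_modality_electrodes <- function(features, labels, modality,
                                       p_threshold) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  a <- labels == modality
  b <- labels == "silence"
  if (sum(a) < 2 || sum(b) < 2) abort("both subsets need >= 2 frames")
  p <- vapply(seq_len(ncol(x)), function(e) {
    tryCatch(t.test(x[a, e], x[b, e])$p.value, error = function(err) NA_real_)
  }, 0)
  which(!is.na(p) & p < p_threshold)
}

#' Build spatiotemporal feature vectors
#'
#' For each target frame `t`, concatenates the selected electrodes' z-scores
#' over the closed frame interval `[t + nu_shift, t + nu_shift + nu_duration]`
#' (electrode-major: all lags of electrode 1, then electrode 2, ...). Frames
#' whose window falls outside the stream are flagged unusable and skipped.
#'
#' @param features A [feature_stream()] or frames-by-electrodes matrix.
#' @param electrodes Integer electrode indices to include.
#' @param nu_shift,nu_duration Window parameters in frames (see
#'   [detector_config()]).
#' @param frames Target frame indices (default all frames).
#' @return List with `x` (matrix, usable frames x
#'   `(nu_duration + 1) * length(electrodes)` features) and `frame` (the
#'   usable target frame indices).
#' @export
build_feature_vectors <- function(features, electrodes, nu_shift, nu_duration,
                                  frames = NULL) {
  xm <- as.matrix(features)
  nf <- nrow(xm)
  if (is.null(frames)) frames <- seq_len(nf)
  lo <- frames + nu_shift
  hi <- frames + nu_shift + nu_duration
  ok <- lo >= 1 & hi <= nf
  frames <- frames[ok]
  lags <- 0:nu_duration
  L <- length(lags)
  cols <- matrix(0, length(frames), L * length(electrodes))
  for (j in seq_along(electrodes)) {
    col <- xm[, electrodes[j]]
    for (l in seq_len(L)) {
      cols[, (j - 1) * L + l] <- col[frames + nu_shift + lags[l]]
    }
  }
  list(x = cols, frame = frames,
       electrode = rep(electrodes, each = L),
       lag = rep(nu_shift + lags, times = length(electrodes)))
}

#' Fit the speech event model
#'
#' PCA-LDA over spatiotemporal feature vectors with frame classes
#' perception/production/silence and flat priors.
#'
#' @param vectors Feature matrix from [build_feature_vectors()].
#' @param labels Per-row class labels.
#' @param pca_variance_fraction PCA variance fraction in (0, 1].
#' @return An `event_model` (a [fit_pca_lda()] object).
#' @export
fit_event_model <- function(vectors, labels, pca_variance_fraction) {
  m <- fit_pca_lda(vectors, labels, pca_variance_fraction)
  class(m) <- c("event_model", class(m))
  m
}

#' Train a speech detector on sessions
#'
#' Derives frame labels from each session's transcription, selects relevant
#' electrodes by Welch ANOVA across the pooled frames, builds spatiotemporal
#' feature vectors, and fits the PCA-LDA event model.
#'
#' @param sessions A `synthetic_session` or list of them (training blocks of
#'   both modalities).
#' @param config A [detector_config()].
#' @return A `speech_detector`: list with `model`, `electrodes`, feature
#'   window metadata (`electrode_map`, `lag_map`) and `config`.
#' @export
fit_speech_detector <- function(sessions, config = detector_config()) {
  if (inherits(sessions, "synthetic_session")) sessions <- list(sessions)
  feats <- lapply(sessions, function(s) as.matrix(s$features))
  labs <- lapply(sessions, frame_labels)
  pooled <- do.call(rbind, feats)
  pooled_lab <- unlist(labs)
  electrodes <- select_event_electrodes(pooled, pooled_lab,
                                        config$anova_p_threshold)
  if (!length(electrodes)) abort("no electrodes passed the ANOVA threshold")
  xs <- vector("list", length(sessions))
  ys <- vector("list", length(sessions))
  em <- NULL
  for (i in seq_along(sessions)) {
    bv <- build_feature_vectors(feats[[i]], electrodes, config$nu_shift,
                                config$nu_duration)
    keep <- seq(1, length(bv$frame), by = config$train_stride)
    xs[[i]] <- bv$x[keep, , drop = FALSE]
    ys[[i]] <- labs[[i]][bv$frame[keep]]
    em <- bv
  }
  model <- fit_event_model(do.call(rbind, xs), unlist(ys),
                           config$pca_variance_fraction)
  structure(list(model = model, electrodes = electrodes,
                 electrode_map = em$electrode, lag_map = em$lag,
                 config = config),
            class = "speech_detector")
}

#' @export
print.speech_detector <- function(x, ...) {
  cat(sprintf("<speech_detector> %d electrodes, window [%d, %d], %d components\n",
              length(x$electrodes), x$config$nu_shift,
              x$config$nu_shift + x$config$nu_duration, x$model$ncomp))
  invisible(x)
}

#' Frame-wise speech event probabilities
#'
#' @param detector A [fit_speech_detector()] result.
#' @param features A [feature_stream()].
#' @return Tibble with columns `frame`, `perception`, `production`,
#'   `silence`; frames whose feature window falls outside the stream get
#'   silence probability 1.
#' @export
event_probabilities <- function(detector, features) {
  bv <- build_feature_vectors(as.matrix(features), detector$electrodes,
                              detector$config$nu_shift,
                              detector$config$nu_duration)
  p <- predict(detector$model, bv$x, type = "posterior")
  nf <- nrow(as.matrix(features))
  out <- matrix(0, nf, 3,
                dimnames = list(NULL, c("perception", "production", "silence")))
  out[, "silence"] <- 1
  out[bv$frame, colnames(p)] <- p
  tibble::as_tibble(out) |> dplyr::mutate(frame = dplyr::row_number(),
                                          .before = 1)
}

# Trailing moving average over the most recent `len` values (expanding at the
# start of the stream).
trailing_mean <- function(x, len) {
  if (len <= 1) return(x)
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  idx <- seq_len(n)
  lo <- pmax(0, idx - len)
  out <- (cs - c(0, cs)[lo + 1]) / (idx - lo)
  out
}

# Debouncing state machine over a binary vector; returns half-open
# [onset, offset) frame pairs.
debounce_events <- function(b, time_threshold) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onsets <- integer(0)
  offsets <- integer(0)
  in_event <- FALSE
  cur_on <- NA_integer_
  for (i in seq_along(r$values)) {
    if (!in_event && r$values[i] == 1 && r$lengths[i] >= time_threshold) {
      in_event <- TRUE
      cur_on <- starts[i]
    } else if (in_event && r$values[i] == 0 && r$lengths[i] >= time_threshold) {
      onsets <- c(onsets, cur_on)
      offsets <- c(offsets, starts[i])
      in_event <- FALSE
    }
  }
  n <- length(b)
  if (in_event) {   # open event at end of stream is closed at the final frame
    onsets <- c(onsets, cur_on)
    offsets <- c(offsets, n + 1L)
  }
  list(onset = onsets, offset = offsets)
}

#' Detect speech events from frame probabilities
#'
#' Per modality: (1) trailing average of the event probability over
#' `smooth_len` frames; (2) binarization at `prob_threshold`; (3) debouncing —
#' an onset (offset) is accepted only when the binary value holds for
#' `time_threshold` frames; (4) the configured onset/offset index shifts are
#' added. Events whose shifted offset does not exceed their onset are dropped.
#' An event still open at the end of the stream is closed at the final frame.
#'
#' @param prob Tibble or matrix of frame probabilities with `perception` and
#'   `production` columns (rows normalized over the three classes).
#' @param config A [detector_config()].
#' @param frame_rate Frames per second used to report event times (default 1,
#'   i.e. times in frames).
#' @param t0 Stream time origin in seconds.
#' @return Tibble of detected events: `modality`, `onset_frame`,
#'   `offset_frame` (half-open), `onset_s`, `offset_s`, `n_frames`, ordered by
#'   onset.
#' @export
detect_events <- function(prob, config = detector_config(), frame_rate = 1,
                          t0 = 0) {
  pr <- as.data.frame(prob)
  nf <- nrow(pr)
  out <- purrr::map_dfr(c("perception", "production"), function(mod) {
    s <- trailing_mean(pr[[mod]], config$smooth_len[[mod]])
    b <- as.integer(s > config$prob_threshold[[mod]])
    ev <- debounce_events(b, config$time_threshold[[mod]])
    if (!length(ev$onset)) return(NULL)
    on <- pmax(1L, pmin(nf, ev$onset + config$onset_shift[[mod]]))
    off <- pmax(1L, pmin(nf + 1L, ev$offset + config$offset_shift[[mod]]))
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

#' Run speech detection on a feature stream
#'
#' Convenience wrapper: computes frame probabilities with the detector's event
#' model and segments them into events.
#'
#' @param detector A [fit_speech_detector()] result.
#' @param features A [feature_stream()].
#' @return List with `probabilities` (tibble from [event_probabilities()]) and
#'   `events` (tibble from [detect_events()]).
#' @export
detect_speech <- function(detector, features) {
  prob <- event_probabilities(detector, features)
  events <- detect_events(prob, detector$config,
                          frame_rate = frame_rate(features),
                          t0 = attr(features, "t0"))
  list(probabilities = prob, events = events)
}
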