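#' Utterance error rate and decoding accuracy rate
#'
#' The utterance error rate is the edit (Levenshtein) distance between the
#' actual and predicted utterance label sequences, at utterance granularity,
#' divided by the length of the actual sequence — the utterance-level analog
#' of the word error rate. The decoding accuracy rate is `max(0, 1 - error)`.
#' Sequences spanning several test blocks should be concatenated before
#' calling.
#'
#' @param actual Character vector of actual utterance labels (non-empty).
#' @param predicted Character vector of predicted labels (may differ in
#'   length; an empty prediction scores all deletions).
#' @return Tibble with `edit_distance`, `error_rate`, `accuracy_rate`.
#' @export
utterance_error_rate <- function(actual, predicted) {
  if (!length(actual)) abort("actual sequence must be non-empty")
  d <- levenshtein(as.character(actual), as.character(predicted))
  err <- d / length(actual)
  tibble::tibble(edit_distance = d, error_rate = err,
                 accuracy_rate = max(0, 1 - err))
}

#' Classification accuracy with bootstrap uncertainty
#'
#' Proportion of correctly classified trials, with mean, standard deviation
#' and percentile confidence interval obtained from bootstrap resamples of
#' the trials.
#'
#' @param correct Logical vector, one entry per trial.
#' @param n_boot Number of bootstrap resamples (default 10000; raise to 1e6
#'   for publication-grade intervals).
#' @param conf Confidence level for the percentile interval.
#' @return Tibble with `accuracy`, `boot_mean`, `boot_sd`, `ci_lower`,
#'   `ci_upper`, `n_trials`.
#' @export
classification_accuracy <- function(correct, n_boot = 1e4, conf = 0.95) {
  correct <- as.logical(correct)
  n <- length(correct)
  if (!n) abort("need at least one trial")
  acc <- mean(correct)
  bs <- vapply(seq_len(n_boot), function(i) {
    mean(correct[sample.int(n, n, replace = TRUE)])
  }, 0)
  qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble::tibble(accuracy = acc, boot_mean = mean(bs), boot_sd = stats::sd(bs),
                 ci_lower = qs[1], ci_upper = qs[2], n_trials = n)
}

#' Cross entropy of utterance predictions
#'
#' Mean surprisal in bits: the average over trials of the negative base-2 log
#' probability assigned to the actual utterance. Lower is better; uniform
#' predictions over `K` candidates give `log2(K)` bits.
#'
#' @param log_prob Numeric vector of natural-log predicted probabilities of
#'   the actual utterance, one per trial (e.g. the `loglik` or
#'   `log_posterior` entry at the true label).
#' @param n_boot Bootstrap resamples for the uncertainty estimate (0 skips
#'   the bootstrap).
#' @return Tibble with `cross_entropy_bits`, `boot_sd`, `n_trials`.
#' @export
cross_entropy <- function(log_prob, n_boot = 1e4) {
  if (!length(log_prob)) abort("need at least one trial")
  surprisal <- -log_prob / log(2)
  ce <- mean(surprisal)
  bsd <- if (n_boot > 0) {
    stats::sd(vapply(seq_len(n_boot), function(i) {
      mean(surprisal[sample.int(length(surprisal), replace = TRUE)])
    }, 0))
  } else NA_real_
  tibble::tibble(cross_entropy_bits = ce, boot_sd = bsd,
                 n_trials = length(log_prob))
}

# Frame-wise binary truth for one modality: TRUE inside padded true events.
event_frame_mask <- function(events, n_frames, frame_rate, t0 = 0, pad_s = 0) {
  mask <- rep(FALSE, n_frames)
  frame_t <- t0 + (seq_len(n_frames) - 1) / frame_rate
  for (i in seq_len(nrow(events))) {
    mask <- mask | (frame_t >= events$onset_s[i] - pad_s &
                    frame_t < events$offset_s[i] + pad_s)
  }
  mask
}

#' Speech detection score
#'
#' Combines a weighted frame-by-frame accuracy with an event-count accuracy:
#' `a_frame = (w_P N_TP + (1 - w_P) N_TN) / (w_P N_P + (1 - w_P) N_N)` on
#' true events padded by `pad_s` seconds at both ends,
#' `a_event = 1 - min(1, |N_DE - N_AE| / N_AE)`, and
#' `s = w_F a_frame + (1 - w_F) a_event`. With the default `w_P = 0.75`,
#' correctly detecting positive frames is weighted three times as heavily as
#' negatives. Padding is truncated at block boundaries.
#'
#' @param true_events Tibble of actual events for one modality (`onset_s`,
#'   `offset_s`), e.g. from [true_events()] filtered by modality.
#' @param detected_events Tibble of detected events for the same modality
#'   (`onset_s`, `offset_s`).
#' @param n_frames,frame_rate,t0 Frame grid of the block.
#' @param w_p Positive weight fraction (default 0.75).
#' @param w_f Frame-accuracy weight fraction (default 0.5).
#' @param pad_s Padding applied to true events (default 0.3 s).
#' @return Tibble with `a_frame`, `a_event`, `score`, and the underlying
#'   counts.
#' @export
detection_score <- function(true_events, detected_events, n_frames,
                            frame_rate, t0 = 0, w_p = 0.75, w_f = 0.5,
                            pad_s = 0.3) {
  truth <- event_frame_mask(true_events, n_frames, frame_rate, t0, pad_s)
  det <- event_frame_mask(detected_events, n_frames, frame_rate, t0, 0)
  n_p <- sum(truth)
  n_n <- sum(!truth)
  n_tp <- sum(truth & det)
  n_tn <- sum(!truth & !det)
  a_frame <- (w_p * n_tp + (1 - w_p) * n_tn) / (w_p * n_p + (1 - w_p) * n_n)
  n_ae <- nrow(true_events)
  n_de <- nrow(detected_events)
  a_event <- if (n_ae > 0) 1 - min(1, abs(n_de - n_ae) / n_ae) else NA_real_
  tibble::tibble(a_frame = a_frame, a_event = a_event,
                 score = w_f * a_frame + (1 - w_f) * a_event,
                 n_tp = n_tp, n_tn = n_tn, n_p = n_p, n_n = n_n,
                 n_detected = n_de, n_actual = n_ae)
}

#' Electrode discriminative power of a PCA-LDA model
#'
#' For each LDA feature (principal component) estimates
#' `eta_i = sigma2_between / (sigma2_between + sigma2_within)`, where the
#' between-class variance is the variance of the class means and the
#' within-class variance the corresponding diagonal entry of the shared
#' covariance. The per-component values are projected back to the original
#' spatiotemporal features as a |PCA-weight|-normalized average (keeping each
#' value within `[0, max eta]`), and each electrode is scored by the maximum
#' over its time lags.
#'
#' @param model A `speech_detector` or `utterance_classifier` (or a bare
#'   [fit_pca_lda()] model plus `electrode_map`).
#' @param electrode_map Optional integer vector mapping original features to
#'   electrode indices (taken from the fitted object when available).
#' @return List with `component` (tibble: `component`, `between`, `within`,
#'   `eta`), `feature` (per original feature), and `electrode` (tibble:
#'   `electrode`, `power`).
#' @export
discriminative_power <- function(model, electrode_map = NULL) {
  if (inherits(model, "speech_detector")) {
    electrode_map <- electrode_map %||% model$electrode_map
    model <- model$model
  } else if (inherits(model, "utterance_classifier")) {
    electrode_map <- electrode_map %||% model$electrode_map
    model <- model$phone_model
  }
  between <- apply(model$means, 2, stats::var)
  within <- diag(model$covariance)
  eta <- ifelse(between + within > 0, between / (between + within), 0)
  comp <- tibble::tibble(component = seq_along(eta), between = between,
                         within = within, eta = unname(eta))
  w <- abs(model$rotation)
  denom <- rowSums(w)
  feature <- as.numeric(w %*% eta) / ifelse(denom > 0, denom, 1)
  elec <- NULL
  if (!is.null(electrode_map)) {
    elec <- tibble::tibble(electrode = electrode_map, power = feature) |>
      dplyr::group_by(.data$electrode) |>
      dplyr::summarise(power = max(.data$power), .groups = "drop")
  }
  list(component = comp, feature = feature, electrode = elec)
}

#' Decision finalization time of a classified event
#'
#' The earliest frame after which the eventually-winning utterance is and
#' remains strictly more likely than every competitor, expressed as percent
#' of the way from the true onset to the true offset. Computed from the
#' per-frame running Viterbi path scores attached to a [classify_event()]
#' result (neural variant), or from scores built from one-hot
#' transcription-based emissions (transcription variant).
#'
#' @param frame_scores Utterances x frames matrix of running path log
#'   probabilities (attribute `frame_scores` of a likelihood set).
#' @param frames Frame indices of the columns (attribute `frames`).
#' @param winner Row name of the finally selected utterance.
#' @param onset_frame,offset_frame True utterance bounds (half-open frames).
#' @return Tibble with `finalization_frame` and `percent` (of the utterance
#'   span; can exceed 100 when finalization happens during trailing padding).
#' @export
finalization_time <- function(frame_scores, frames, winner, onset_frame,
                              offset_frame) {
  wi <- match(winner, rownames(frame_scores))
  if (is.na(wi)) abort("winner not among the candidate utterances")
  nt <- ncol(frame_scores)
  lead <- vapply(seq_len(nt), function(t) {
    others <- frame_scores[-wi, t]
    frame_scores[wi, t] > max(others)
  }, TRUE)
  # last frame at which the winner was NOT strictly leading
  last_bad <- if (any(!lead)) max(which(!lead)) else 0L
  fin <- if (last_bad >= nt) NA_integer_ else frames[last_bad + 1L]
  pct <- if (is.na(fin)) NA_real_ else {
    100 * (fin - onset_frame) / (offset_frame - onset_frame)
  }
  tibble::tibble(finalization_frame = fin, percent = pct)
}

#' One-hot emission log likelihoods from a transcription
#'
#' Builds the transcription-based emission matrix used for the
#' transcription-based finalization variant: probability ~1 for the
#' transcribed phone at each frame and the log floor elsewhere.
#'
#' @param phones Character vector of per-frame phone labels (e.g.
#'   [frame_phones()] sliced to the event window).
#' @param phone_set Phone label universe (emission columns).
#' @return Frames x phones matrix of log likelihoods.
#' @export
transcription_emissions <- function(phones, phone_set) {
  miss <- setdiff(unique(phones), phone_set)
  if (length(miss)) abort(paste0("phone not in phone_set: ", miss[1]))
  m <- matrix(LOG_FLOOR, length(phones), length(phone_set),
              dimnames = list(NULL, phone_set))
  m[cbind(seq_along(phones), match(phones, phone_set))] <- 0
  m
}

#' Phone confusion matrix
#'
#' @param actual,predicted Character vectors of per-frame phone labels.
#' @param normalize Row-normalize by actual-phone counts (default `TRUE`).
#' @return A `phone_confusion` matrix (actual x predicted).
#' @export
phone_confusions <- function(actual, predicted, normalize = TRUE) {
  levels <- sort(unique(c(actual, predicted)))
  tab <- table(factor(actual, levels), factor(predicted, levels))
  m <- unclass(as.matrix(tab))
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, 1)
  }
  structure(m, class = c("phone_confusion", "matrix", "array"))
}

# Mutual information (bits) of a joint count table.
mi_bits <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log2(p[idx] / outer(px, py)[idx]))
}

#' Place-of-articulation mutual information
#'
#' Collapses actual and predicted phone labels into disjoint articulatory
#' categories, computes the mutual information (bits) between the collapsed
#' labels, and assesses it against a null of random disjoint categorizations
#' with the same category sizes (one-tailed permutation p-value). Silence
#' frames (`sp`) are excluded.
#'
#' @param actual,predicted Per-frame phone labels.
#' @param categories Named character vector phone -> category (e.g.
#'   [read_place_categories()]); must cover every non-silence phone present.
#' @param n_perm Number of random categorizations (default 1000).
#' @return Tibble with `mi_bits`, `p_value`, `n_frames`, `n_perm`.
#' @export
place_of_articulation_mi <- function(actual, predicted, categories,
                                     n_perm = 1000) {
  keep <- actual != "sp" & predicted != "sp"
  a <- actual[keep]
  p <- predicted[keep]
  phones <- sort(unique(c(a, p)))
  miss <- setdiff(phones, names(categories))
  if (length(miss)) abort(paste0("category map missing phone: ", miss[1]))
  obs <- mi_bits(table(categories[a], categories[p]))
  sizes <- table(categories[phones])
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- setNames(sample(categories[phones]), phones)
    mi_bits(table(perm[a], perm[p]))
  }, 0)
  tibble::tibble(mi_bits = obs, p_value = (1 + sum(null >= obs)) / (1 + n_perm),
                 n_frames = length(a), n_perm = n_perm)
}

#' Holm-Bonferroni step-down correction
#'
#' @param p Numeric vector of p-values.
#' @param alpha Family-wise error level.
#' @return Tibble with `p`, `p_adjusted` (monotone step-down adjusted values)
#'   and `reject`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  tibble::tibble(p = p, p_adjusted = out, reject = out < alpha)
}

#' One-tailed exact McNemar test
#'
#' Exact binomial tail on the discordant pair counts: probability of at least
#' `b` successes in `b + c` trials at rate 1/2, testing whether the first
#' condition wins more often.
#'
#' @param b Count of pairs where the first condition is correct and the
#'   second is not.
#' @param c Count of the reverse discordance.
#' @return One-tailed p-value.
#' @export
mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  sum(stats::dbinom(b:n, n, 0.5))
}

#' One-tailed paired permutation test
#'
#' Sign-flipping permutation test on paired differences, testing whether the
#' mean difference exceeds zero.
#'
#' @param x,y Paired numeric vectors (tests `mean(x - y) > 0`).
#' @param n_perm Number of sign permutations.
#' @return One-tailed p-value.
#' @export
permutation_test_paired <- function(x, y, n_perm = 10000) {
  d <- x - y
  obs <- mean(d)
  null <- vapply(seq_len(n_perm), function(i) {
    mean(d * sample(c(-1, 1), length(d), replace = TRUE))
  }, 0)
  (1 + sum(null >= obs)) / (1 + n_perm)
}

#' One-tailed bootstrap test against a reference value
#'
#' Resamples the statistic's inputs and reports the fraction of bootstrap
#' statistics at or below the reference (testing whether the statistic
#' exceeds it).
#'
#' @param x Numeric vector of per-trial values.
#' @param statistic Function mapping a resample to a scalar (default `mean`).
#' @param reference Null reference value (e.g. chance level).
#' @param n_boot Number of resamples.
#' @return One-tailed p-value.
#' @export
bootstrap_test <- function(x, reference, statistic = mean, n_boot = 10000) {
  bs <- vapply(seq_len(n_boot), function(i) {
    statistic(x[sample.int(length(x), replace = TRUE)])
  }, 0)
  (1 + sum(bs <= reference)) / (1 + n_boot)
}
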