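#' Plot a likelihood set
#'
#' Bar chart of normalized utterance probabilities for one classified event.
#'
#' @param object A `likelihood_set` from [classify_event()] or
#'   [smooth_normalize()].
#' @param top Show only the `top` most likely utterances (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.likelihood_set <- function(object, top = NULL, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(prob = exp(.data$loglik)) |>
    dplyr::arrange(dplyr::desc(.data$prob))
  if (!is.null(top)) df <- head(df, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$utterance, .data$prob), y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized probability") +
    ggplot2::theme_minimal()
}

#' Plot answer posteriors against likelihoods
#'
#' @param object An `answer_posterior` from [integrate_context()].
#' @param top Show only the `top` highest-posterior answers.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.answer_posterior <- function(object, top = NULL, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(likelihood = exp(.data$loglik),
                  posterior = exp(.data$log_posterior)) |>
    dplyr::arrange(dplyr::desc(.data$posterior))
  if (!is.null(top)) df <- head(df, top)
  df <- tidyr::pivot_longer(df, c("likelihood", "posterior"),
                            names_to = "quantity", values_to = "prob")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$utterance, .data$prob), y = .data$prob,
    fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phone confusion matrix
#'
#' @param object A [phone_confusions()] matrix.
#' @param ... Unused.
#' @return A ggplot tile plot (rows: actual phone, columns: predicted).
#' @exportS3Method ggplot2::autoplot
autoplot.phone_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("actual", "predicted", "proportion")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$actual,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted phone", y = "actual phone") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot detector probabilities and detected events
#'
#' Overlays the smoothed-free perception/production probabilities with the
#' detected event intervals.
#'
#' @param prob Tibble from [event_probabilities()].
#' @param events Tibble from [detect_events()].
#' @param frame_rate Frames per second for the time axis (default 1: frames).
#' @return A ggplot object.
#' @export
plot_detection <- function(prob, events, frame_rate = 1) {
  df <- tidyr::pivot_longer(prob, c("perception", "production"),
                            names_to = "modality", values_to = "probability") |>
    dplyr::mutate(time = (.data$frame - 1) / frame_rate)
  ev <- events |>
    dplyr::mutate(t_on = (.data$onset_frame - 1) / frame_rate,
                  t_off = (.data$offset_frame - 1) / frame_rate)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$probability,
                                   color = .data$modality)) +
    ggplot2::geom_rect(data = ev, inherit.aes = FALSE, alpha = 0.2,
                       ggplot2::aes(xmin = .data$t_on, xmax = .data$t_off,
                                    ymin = 0, ymax = 1,
                                    fill = .data$modality)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "event probability") +
    ggplot2::theme_minimal()
}

#' Plot running utterance path probabilities
#'
#' Normalized per-frame Viterbi path probabilities of each candidate
#' utterance across a classified event, visualizing how the decision
#' sharpens as the utterance unfolds.
#'
#' @param likelihood_set A [classify_event()] result (needs the
#'   `frame_scores` attribute).
#' @param top Label only the `top` finally most likely utterances.
#' @return A ggplot object.
#' @export
plot_path_probabilities <- function(likelihood_set, top = 5) {
  scores <- attr(likelihood_set, "frame_scores")
  frames <- attr(likelihood_set, "frames")
  if (is.null(scores)) abort("likelihood set carries no frame scores")
  norm <- apply(scores, 2, function(col) exp(col - logsumexp(col)))
  keep <- rownames(scores)[order(scores[, ncol(scores)],
                                 decreasing = TRUE)][seq_len(top)]
  df <- tibble::as_tibble(norm, .name_repair = "minimal") |>
    stats::setNames(as.character(frames)) |>
    dplyr::mutate(utterance = rownames(scores)) |>
    tidyr::pivot_longer(-"utterance", names_to = "frame",
                        values_to = "probability") |>
    dplyr::mutate(frame = as.integer(.data$frame),
                  shown = ifelse(.data$utterance %in% keep,
                                 .data$utterance, "other"))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$probability,
                                   group = .data$utterance,
                                   color = .data$shown)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "path probability", color = NULL) +
    ggplot2::theme_minimal()
}
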