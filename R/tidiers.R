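#' Tidiers for decoder objects
#'
#' Broom-style `tidy()` and `glance()` methods summarizing fitted decoder
#' components as tibbles.
#'
#' @param x The object to summarize.
#' @param ... Unused.
#' @return A tibble.
#' @name qadecoder-tidiers
NULL

#' @rdname qadecoder-tidiers
#' @exportS3Method generics::glance
glance.speech_detector <- function(x, ...) {
  tibble::tibble(n_electrodes = length(x$electrodes),
                 n_components = x$model$ncomp,
                 shrinkage = x$model$shrinkage,
                 nu_shift = x$config$nu_shift,
                 nu_duration = x$config$nu_duration)
}

#' @rdname qadecoder-tidiers
#' @exportS3Method generics::glance
glance.utterance_classifier <- function(x, ...) {
  tibble::tibble(type = x$type, modality = x$modality,
                 n_utterances = length(x$hmms),
                 n_phones = length(x$phones),
                 n_electrodes = length(x$electrodes),
                 n_components = x$phone_model$ncomp,
                 p_self = x$config$p_self, omega = x$config$omega,
                 w_e = x$config$w_e)
}

#' @rdname qadecoder-tidiers
#' @exportS3Method generics::glance
glance.qa_decoder <- function(x, ...) {
  dplyr::bind_rows(
    glance(x$question_classifier),
    glance(x$answer_classifier)
  )
}

#' @rdname qadecoder-tidiers
#' @exportS3Method generics::tidy
tidy.context_prior_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "answer") |>
    tidyr::pivot_longer(-"answer", names_to = "question", values_to = "prior")
}

#' @rdname qadecoder-tidiers
#' @exportS3Method generics::tidy
tidy.phone_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("actual", "predicted", "proportion")
  tibble::as_tibble(df)
}

#' @rdname qadecoder-tidiers
#' @exportS3Method generics::tidy
tidy.likelihood_set <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x)) |>
    dplyr::mutate(probability = exp(.data$loglik))
}
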