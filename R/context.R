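#' Build the context prior matrix
#'
#' Conditional probabilities `p(u_a | u_q)` relating answers to questions:
#' `1 / N_{A,q}` when the answer belongs to one of the question's QA sets
#' (all valid answers equally likely) and 0 otherwise, where `N_{A,q}` is the
#' number of valid answers to question `u_q`.
#'
#' @param stim A [read_stimulus_set()] result; every question must have at
#'   least one valid answer.
#' @return A `context_prior_matrix`: answers x questions numeric matrix with
#'   columns summing to 1.
#' @export
build_context_priors <- function(stim) {
  m <- matrix(0, length(stim$answers), length(stim$questions),
              dimnames = list(stim$answers, stim$questions))
  for (q in stim$questions) {
    va <- valid_answers(stim, q)
    if (!length(va)) abort(paste0("question has no valid answers: ", q))
    m[va, q] <- 1 / length(va)
  }
  structure(m, class = c("context_prior_matrix", "matrix", "array"))
}

#' Initialize the context integration state
#'
#' The state carries the current answer log priors, which are updated only
#' when a new set of question likelihoods arrives; until then no
#' answers-with-context prediction is produced.
#'
#' @param priors A [build_context_priors()] matrix.
#' @param m Context prior scaling factor (>= 0); larger values weight the
#'   answer priors more heavily against the answer likelihoods.
#' @return A `context_state` list with `log_prior` (`NULL` until the first
#'   question), `prior_available`, `m`, and the prior matrix.
#' @export
context_state <- function(priors, m = 1) {
  if (m < 0) abort("context scaling m must be >= 0")
  structure(list(priors = priors, log_prior = NULL, prior_available = FALSE,
                 m = m),
            class = "context_state")
}

#' Update answer priors from decoded question likelihoods
#'
#' Computes `log p_Q(u_a) = LogSumExp_q [ log p(u_a | u_q) + l*_{u_q} ]` (the
#' additive constant is dropped; the result is renormalized for reporting).
#' Zero context priors contribute at the log floor, so answers outside every
#' decoded question's set keep effectively zero prior.
#'
#' @param state A [context_state()].
#' @param question_lik A `likelihood_set` over the questions (normalized per
#'   [smooth_normalize()]).
#' @return The updated `context_state` with `prior_available = TRUE`.
#' @export
update_answer_priors <- function(state, question_lik) {
  qs <- colnames(state$priors)
  if (!all(qs %in% question_lik$utterance)) {
    abort("question likelihood set does not cover all questions")
  }
  lq <- setNames(question_lik$loglik, question_lik$utterance)[qs]
  lp <- apply(log_floor(log(state$priors)), 1,
              function(row) logsumexp(row + lq))
  lp <- lp - logsumexp(lp)
  state$log_prior <- log_floor(lp)
  state$prior_available <- TRUE
  state
}

#' Integrate answer likelihoods with the current answer priors
#'
#' Computes unnormalized log posteriors `phi_u = m * log p_Q(u_a) + l*_{u_a}`
#' and normalizes them by LogSumExp so that `sum_u exp(phi*_u) = 1`. If no
#' question likelihoods have been received yet, no posterior is produced.
#'
#' @param state A [context_state()].
#' @param answer_lik A `likelihood_set` over the answers.
#' @return An `answer_posterior` tibble: `utterance`, `loglik`, `log_prior`,
#'   `log_posterior`; `NULL` when `state$prior_available` is `FALSE`.
#' @export
integrate_context <- function(state, answer_lik) {
  if (!state$prior_available) return(NULL)
  ans <- rownames(state$priors)
  if (!all(ans %in% answer_lik$utterance)) {
    abort("answer likelihood set does not cover all answers")
  }
  la <- setNames(answer_lik$loglik, answer_lik$utterance)[ans]
  phi <- state$m * state$log_prior + la
  phi_star <- log_floor(phi - logsumexp(phi))
  res <- tibble::tibble(utterance = ans, loglik = unname(la),
                        log_prior = unname(state$log_prior),
                        log_posterior = unname(phi_star))
  structure(res, m = state$m, class = c("answer_posterior", class(res)))
}

#' Predicted utterance identities
#'
#' The system's predictions: the question with the highest normalized
#' likelihood, the answer with the highest likelihood (no context), and the
#' answer with the highest posterior (with context). Ties break to the lowest
#' utterance index.
#'
#' @param question_lik Optional question `likelihood_set`.
#' @param answer_lik Optional answer `likelihood_set`.
#' @param posterior Optional `answer_posterior` from [integrate_context()].
#' @return Named list with `question`, `answer_no_context`,
#'   `answer_with_context` (each `NA` when its input is absent).
#' @export
predict_utterances <- function(question_lik = NULL, answer_lik = NULL,
                               posterior = NULL) {
  pick <- function(tbl, col) {
    if (is.null(tbl)) return(NA_character_)
    tbl$utterance[argmax_first(tbl[[col]])]
  }
  list(question = pick(question_lik, "loglik"),
       answer_no_context = pick(answer_lik, "loglik"),
       answer_with_context = pick(posterior, "log_posterior"))
}

#' Apply a prior mode to question likelihoods
#'
#' `soft` leaves the likelihoods unchanged; `hard` sets the most likely
#' question's probability to 1 and all others to 0; `true` does the same at
#' the actually presented question. Context integration then proceeds
#' normally.
#'
#' @param question_lik A question `likelihood_set`.
#' @param mode One of `"soft"`, `"hard"`, `"true"`.
#' @param true_label Required for `mode = "true"`.
#' @return A `likelihood_set` with the same utterances.
#' @export
apply_prior_mode <- function(question_lik, mode = c("soft", "hard", "true"),
                             true_label = NULL) {
  mode <- match.arg(mode)
  if (mode == "soft") return(question_lik)
  idx <- if (mode == "hard") {
    argmax_first(question_lik$loglik)
  } else {
    if (is.null(true_label)) abort("mode = 'true' requires true_label")
    match(true_label, question_lik$utterance)
  }
  if (is.na(idx)) abort("true_label not among the candidate questions")
  out <- question_lik
  out$loglik <- rep(LOG_FLOOR, nrow(out))
  out$loglik[idx] <- 0
  out
}
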