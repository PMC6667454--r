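#' Read a question-and-answer stimulus set
#'
#' A stimulus set defines the utterance inventory of the task: a small number
#' of QA sets, each pairing one or more spoken questions with the answer
#' choices that are valid responses to them, plus a representative phone
#' sequence for every utterance. The packaged fixture describes the canonical
#' task (4 QA sets, 9 questions, 24 answers).
#'
#' @param path Path to a YAML file with fields `qa_sets` (list of
#'   `set`/`questions`/`answers` entries) and `phone_seqs` (utterance label to
#'   phone-label vector). `NULL` (default) loads the packaged fixture.
#'
#' @return An object of class `qa_stimulus_set`: a list with
#'   \describe{
#'     \item{utterances}{tibble with columns `label`, `type`
#'       (`"question"`/`"answer"`), `qa_sets` (list column of integer set
#'       ids; answers may belong to several sets), `phones` (list column).}
#'     \item{questions, answers}{character vectors of labels, in fixture
#'       order.}
#'     \item{phone_inventory}{sorted unique phone labels including `"sp"`.}
#'   }
#'
#' @examples
#' stim <- read_stimulus_set()
#' length(stim$questions)
#' length(stim$answers)
#' @export
read_stimulus_set <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stimulus_set.yaml", package = "qadecoder")
  }
  if (!file.exists(path)) abort(paste0("stimulus set file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$qa_sets) || is.null(raw$phone_seqs)) {
    abort("stimulus set must define 'qa_sets' and 'phone_seqs'")
  }

  rows <- purrr::map_dfr(raw$qa_sets, function(qs) {
    dplyr::bind_rows(
      tibble::tibble(label = as.character(qs$questions), type = "question",
                     qa_set = as.integer(qs$set)),
      tibble::tibble(label = as.character(qs$answers), type = "answer",
                     qa_set = as.integer(qs$set))
    )
  })
  dup_q <- rows$label[rows$type == "question"][duplicated(rows$label[rows$type == "question"])]
  if (length(dup_q)) abort(paste0("duplicate question label: ", dup_q[1]))
  dup_a <- rows |>
    dplyr::filter(.data$type == "answer") |>
    dplyr::count(.data$label, .data$qa_set) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_a)) abort(paste0("duplicate answer label within a QA set: ", dup_a$label[1]))
  both <- intersect(rows$label[rows$type == "question"], rows$label[rows$type == "answer"])
  if (length(both)) abort(paste0("label used as both question and answer: ", both[1]))

  utterances <- rows |>
    dplyr::group_by(.data$label, .data$type) |>
    dplyr::summarise(qa_sets = list(sort(unique(.data$qa_set))), .groups = "drop") |>
    dplyr::arrange(match(.data$label, rows$label))

  missing_seq <- setdiff(utterances$label, names(raw$phone_seqs))
  if (length(missing_seq)) {
    abort(paste0("no phone sequence for utterance: ", missing_seq[1]))
  }
  utterances$phones <- purrr::map(utterances$label,
                                  ~ as.character(raw$phone_seqs[[.x]]))
  if (any(lengths(utterances$phones) == 0)) abort("empty phone sequence")

  questions <- utterances$label[utterances$type == "question"]
  answers <- utterances$label[utterances$type == "answer"]

  seq_key <- vapply(utterances$phones, paste, "", collapse = " ")
  if (anyDuplicated(seq_key)) {
    warn("two utterances share an identical phone sequence; they will be indistinguishable to the classifier")
  }

  structure(
    list(
      utterances = utterances,
      questions = questions,
      answers = answers,
      phone_inventory = sort(unique(c("sp", unlist(utterances$phones))))
    ),
    class = "qa_stimulus_set"
  )
}

#' @export
print.qa_stimulus_set <- function(x, ...) {
  n_sets <- length(unique(unlist(x$utterances$qa_sets)))
  cat(sprintf(
    "<qa_stimulus_set> %d QA sets, %d questions, %d answers, %d phones (incl. sp)\n",
    n_sets, length(x$questions), length(x$answers), length(x$phone_inventory)
  ))
  invisible(x)
}

#' Phone sequence of one utterance
#'
#' @param stim A `qa_stimulus_set`.
#' @param label Utterance label.
#' @return Character vector of phone labels (without boundary silences).
#' @export
phone_sequence <- function(stim, label) {
  i <- match(label, stim$utterances$label)
  if (is.na(i)) abort(paste0("unknown utterance: ", label))
  stim$utterances$phones[[i]]
}

#' Valid answers for a question
#'
#' @param stim A `qa_stimulus_set`.
#' @param question Question label.
#' @return Character vector of answer labels belonging to the question's QA set.
#' @export
valid_answers <- function(stim, question) {
  i <- match(question, stim$utterances$label)
  if (is.na(i) || stim$utterances$type[i] != "question") {
    abort(paste0("unknown question: ", question))
  }
  sets <- stim$utterances$qa_sets[[i]]
  ans <- stim$utterances |>
    dplyr::filter(.data$type == "answer",
                  purrr::map_lgl(.data$qa_sets, ~ any(.x %in% sets)))
  ans$label
}

#' Read the place-of-articulation category map
#'
#' Returns the mapping from phone labels to nine disjoint place-of-articulation
#' categories used to collapse phone confusions. The silence token is not
#' categorised.
#'
#' @param path YAML file mapping category name to phone vector; `NULL` loads
#'   the packaged map.
#' @return Named character vector: names are phone labels, values category
#'   names.
#' @export
read_place_categories <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "place_of_articulation.yaml",
                        package = "qadecoder")
  }
  raw <- yaml::read_yaml(path)
  phones <- unlist(raw, use.names = FALSE)
  if (anyDuplicated(phones)) abort("place categories must be disjoint")
  setNames(rep(names(raw), lengths(raw)), phones)
}
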