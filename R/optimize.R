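#' Define a hyperparameter search space
#'
#' A space is a named list of parameter priors. Supported kinds:
#' `param_uniform(low, high)`, `param_loguniform(low, high)`,
#' `param_int(low, high)` and `param_choice(values)`.
#'
#' @param low,high Bounds of the prior.
#' @param values Candidate values for a choice parameter.
#' @return A `param_spec` list.
#' @name hyperparameter_space
NULL

#' @rdname hyperparameter_space
#' @export
param_uniform <- function(low, high) {
  structure(list(kind = "uniform", low = low, high = high),
            class = "param_spec")
}

#' @rdname hyperparameter_space
#' @export
param_loguniform <- function(low, high) {
  if (low <= 0) abort("loguniform bounds must be positive")
  structure(list(kind = "loguniform", low = low, high = high),
            class = "param_spec")
}

#' @rdname hyperparameter_space
#' @export
param_int <- function(low, high) {
  structure(list(kind = "int", low = as.integer(low), high = as.integer(high)),
            class = "param_spec")
}

#' @rdname hyperparameter_space
#' @export
param_choice <- function(values) {
  structure(list(kind = "choice", values = values), class = "param_spec")
}

sample_param <- function(spec) {
  switch(spec$kind,
    uniform = runif(1, spec$low, spec$high),
    loguniform = exp(runif(1, log(spec$low), log(spec$high))),
    int = sample(seq.int(spec$low, spec$high), 1),
    choice = spec$values[[sample.int(length(spec$values), 1)]],
    abort(paste0("unknown parameter kind: ", spec$kind))
  )
}

#' Hyperparameter search by best-of-epochs random sampling
#'
#' Samples `n_epochs` configurations from the space's prior distributions,
#' evaluates each with the supplied objective, and returns the configuration
#' with the minimal loss together with the full epoch trace.
#'
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar loss (lower is better).
#' @param space Named list of parameter specs (see
#'   [hyperparameter_space]).
#' @param n_epochs Number of configurations to evaluate (default 50; the
#'   full-scale analyses in this workflow use 250).
#' @param seed Optional seed for reproducible sampling.
#' @return List with `best_params`, `best_loss`, and `trace` (tibble: `epoch`,
#'   `loss`, `params` list column).
#' @export
optimize_hyperparameters <- function(objective, space, n_epochs = 50,
                                     seed = NULL) {
  if (!length(space) || is.null(names(space))) {
    abort("space must be a named list of parameter specs")
  }
  run <- function() {
    params <- vector("list", n_epochs)
    loss <- numeric(n_epochs)
    for (e in seq_len(n_epochs)) {
      p <- lapply(space, sample_param)
      params[[e]] <- p
      loss[e] <- objective(p)
    }
    best <- which.min(loss)
    list(best_params = params[[best]], best_loss = loss[best],
         trace = tibble::tibble(epoch = seq_len(n_epochs), loss = loss,
                                params = params))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Leave-one-block-out hyperparameter optimization
#'
#' For each test block, searches the space on a validation set comprising all
#' the other blocks, mirroring cross-validated hyperparameter selection: the
#' chosen configuration for a block never sees that block during
#' optimization.
#'
#' @param blocks List of test blocks (any objects; passed through to the
#'   objective).
#' @param objective Function `(params, validation_blocks)` returning a scalar
#'   validation loss.
#' @param space Named list of parameter specs.
#' @param n_epochs Epochs per held-out block.
#' @param seed Optional base seed (block `i` uses `seed + i`).
#' @return List, one element per block: `best_params`, `best_loss`, `trace`.
#' @export
optimize_loo <- function(blocks, objective, space, n_epochs = 50,
                         seed = NULL) {
  if (length(blocks) < 2) {
    abort("leave-one-block-out needs >= 2 blocks; use a simple train/validation split instead")
  }
  lapply(seq_along(blocks), function(i) {
    optimize_hyperparameters(
      function(p) objective(p, blocks[-i]),
      space, n_epochs = n_epochs,
      seed = if (is.null(seed)) NULL else seed + i
    )
  })
}
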