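#' Fit a PCA-LDA discriminative model
#'
#' The discriminative workhorse used both for speech event detection and for
#' phone likelihood modeling: features are projected onto the minimum number
#' of principal components explaining at least `variance_fraction` of the
#' training variance, then classified with linear discriminant analysis using
#' a shared within-class covariance estimated with Ledoit-Wolf shrinkage
#' (toward a scaled identity) and flat class priors.
#'
#' @param x Numeric matrix, observations x features.
#' @param labels Character/factor vector of class labels, `nrow(x)` long.
#' @param variance_fraction Fraction of variance the retained principal
#'   components must explain, in (0, 1]. `1` retains the full feature rank.
#'
#' @return A `pca_lda` object (list with PCA center/rotation, class means in
#'   component space, shrunk shared covariance, shrinkage intensity, classes).
#' @export
fit_pca_lda <- function(x, labels, variance_fraction = 0.8) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) abort("labels must match rows of x")
  if (!(variance_fraction > 0 && variance_fraction <= 1)) {
    abort("variance_fraction must lie in (0, 1]")
  }
  counts <- table(labels)
  if (length(counts) < 2) abort("need at least two classes")
  if (any(counts < 2)) {
    abort(paste0("need >= 2 samples per class; too few for: ",
                 names(counts)[counts < 2][1]))
  }

  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  n <- nrow(xc)
  cv <- crossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  tol <- max(eg$values[1], 0) * 1e-9
  rank <- max(1L, sum(eg$values > tol))
  cum <- cumsum(pmax(eg$values, 0)) / sum(pmax(eg$values, 0))
  ncomp <- min(rank, which(cum >= variance_fraction - 1e-12)[1])
  rotation <- eg$vectors[, seq_len(ncomp), drop = FALSE]

  z <- xc %*% rotation
  classes <- sort(names(counts))
  means <- do.call(rbind, lapply(classes, function(k) {
    colMeans(z[labels == k, , drop = FALSE])
  }))
  rownames(means) <- classes
  colnames(means) <- paste0("PC", seq_len(ncomp))
  resid <- z - means[labels, , drop = FALSE]
  lw <- ledoit_wolf(resid)

  structure(list(
    center = center, rotation = rotation, eigenvalues = eg$values,
    ncomp = ncomp, classes = classes, means = means,
    covariance = lw$sigma, shrinkage = lw$shrinkage,
    n_train = n
  ), class = "pca_lda")
}

# Ledoit-Wolf shrinkage of the covariance of `resid` (rows already centered,
# e.g. by their class mean) toward mu * I. Returns the shrunk covariance and
# the shrinkage intensity.
ledoit_wolf <- function(resid) {
  n <- nrow(resid)
  p <- ncol(resid)
  s <- crossprod(resid) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mu, p))^2) / p
  if (d2 < .Machine$double.eps) {
    sigma <- diag(max(mu, 1e-12), p)
    return(list(sigma = sigma, shrinkage = 1))
  }
  norms4 <- rowSums(resid^2)^2
  b2bar <- (sum(norms4) / n - sum(s^2)) / (n * p)
  b2 <- min(b2bar, d2)
  rho <- b2 / d2
  sigma <- rho * diag(mu, p) + (1 - rho) * s
  # guard against exact singularity when rho == 0 and s is rank-deficient
  sigma <- sigma + diag(1e-10 * max(mu, 1), p)
  list(sigma = sigma, shrinkage = rho)
}

#' Predict from a PCA-LDA model
#'
#' @param object A [fit_pca_lda()] model.
#' @param newdata Numeric matrix in the original feature space.
#' @param type `"posterior"` for class posterior probabilities (flat priors),
#'   `"logposterior"` for their logs, or `"class"` for the argmax label.
#' @param ... Unused.
#' @return Matrix (observations x classes) for probability types; character
#'   vector for `"class"`.
#' @export
predict.pca_lda <- function(object, newdata,
                            type = c("posterior", "logposterior", "class"),
                            ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  z <- sweep(x, 2, object$center) %*% object$rotation
  m <- solve(object$covariance, t(object$means))      # ncomp x K
  scores <- z %*% m
  scores <- sweep(scores, 2, 0.5 * colSums(t(object$means) * m))
  colnames(scores) <- object$classes
  if (type == "class") {
    return(object$classes[max.col(scores, ties.method = "first")])
  }
  lp <- scores - apply(scores, 1, logsumexp)
  if (type == "logposterior") lp else exp(lp)
}

#' @export
print.pca_lda <- function(x, ...) {
  cat(sprintf("<pca_lda> %d classes, %d components (shrinkage %.3f, n = %d)\n",
              length(x$classes), x$ncomp, x$shrinkage, x$n_train))
  invisible(x)
}

#' @rdname fit_pca_lda
#' @param x A `pca_lda` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.pca_lda <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), n_components = x$ncomp,
                 shrinkage = x$shrinkage, n_train = x$n_train)
}

#' @rdname fit_pca_lda
#' @exportS3Method generics::tidy
tidy.pca_lda <- function(x, ...) {
  tibble::as_tibble(x$means, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "component",
                        values_to = "mean")
}
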