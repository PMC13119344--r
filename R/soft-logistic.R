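#' Fit a logistic model to soft (continuous) labels
#'
#' Minimizes the cross-entropy between predicted probabilities and
#' continuous targets in `[0, 1]` (optionally plus an L2 penalty on the
#' weights) by a damped Newton iteration. This is how the sequence
#' classifier is trained: the targets are the structure classifier's
#' P(kinked) values rather than hard labels. Features are standardized
#' internally; the standardization means and SDs are recorded in the
#' returned parameter set, so the fitted model slots directly into
#' [standardized_logistic()].
#'
#' The iteration is deterministic (no random initialization); it starts at
#' the zero weight vector and halves the Newton step until the objective
#' does not increase, so cross-entropy is non-increasing over iterations.
#'
#' @param x Numeric matrix or data frame of features (rows = observations).
#' @param targets Numeric vector of target probabilities in `[0, 1]`.
#' @param l2 Ridge penalty on the standardized weights (not the intercept),
#'   default 0.
#' @param tol Convergence threshold on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `nb_softlogit`: a list with `params`
#'   (an [logistic_params()] object), `loss` (final mean cross-entropy),
#'   `loss_trace`, `iterations`, `converged`, `n`.
#' @export
fit_soft_label_logistic <- function(x, targets, l2 = 0, tol = 1e-8,
                                    max_iter = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  t_ <- as.numeric(targets)
  if (nrow(x) != length(t_)) rlang::abort("rows of `x` must match `targets`")
  if (any(!is.finite(t_)) || any(t_ < 0) || any(t_ > 1)) {
    rlang::abort("`targets` must lie in [0, 1]")
  }
  if (l2 < 0) rlang::abort("`l2` must be >= 0")
  p_feat <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("x", seq_len(p_feat))
  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  if (any(!is.finite(sigma)) || any(sigma == 0)) {
    rlang::abort("constant feature column(s): cannot standardize")
  }
  z <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  zz <- cbind(z, 1)  # intercept last
  beta <- rep(0, p_feat + 1L)
  n <- nrow(zz)
  obj <- function(beta) {
    eta <- drop(zz %*% beta)
    # numerically stable cross-entropy: log(1 + e^eta) - t * eta
    ce <- sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - t_ * eta)
    ce + 0.5 * l2 * sum(beta[seq_len(p_feat)]^2)
  }
  loss_trace <- obj(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(zz %*% beta)
    p <- sigmoid(eta)
    grad <- drop(crossprod(zz, p - t_))
    grad[seq_len(p_feat)] <- grad[seq_len(p_feat)] + l2 * beta[seq_len(p_feat)]
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      iter <- iter - 1L
      break
    }
    wdiag <- pmax(p * (1 - p), 1e-10)
    hess <- crossprod(zz * wdiag, zz)
    if (l2 > 0) {
      idx <- cbind(seq_len(p_feat), seq_len(p_feat))
      hess[idx] <- hess[idx] + l2
    }
    step <- tryCatch(solve(hess, grad), error = function(e) {
      solve(hess + diag(1e-8, nrow(hess)), grad)
    })
    f0 <- obj(beta)
    damp <- 1
    repeat {
      cand <- beta - damp * step
      if (obj(cand) <= f0 + 1e-12 || damp < 1e-8) break
      damp <- damp / 2
    }
    if (damp < 1e-8) break
    beta <- cand
    loss_trace <- c(loss_trace, obj(beta))
  }
  if (!converged) {
    eta <- drop(zz %*% beta)
    p <- sigmoid(eta)
    grad <- drop(crossprod(zz, p - t_))
    grad[seq_len(p_feat)] <- grad[seq_len(p_feat)] + l2 * beta[seq_len(p_feat)]
    converged <- max(abs(grad)) < tol
  }
  if (!converged) {
    rlang::abort(sprintf(
      "soft-label logistic fit did not converge in %d iterations (gradient max-norm %.3g)",
      max_iter, max(abs(grad))
    ))
  }
  structure(
    list(
      params = logistic_params(feats, mu, sigma,
                               beta[seq_len(p_feat)], beta[p_feat + 1L]),
      loss = obj(beta) / n,
      loss_trace = loss_trace / n,
      iterations = iter,
      converged = converged,
      l2 = l2,
      n = n
    ),
    class = "nb_softlogit"
  )
}

#' @export
print.nb_softlogit <- function(x, ...) {
  cat(sprintf(
    "<nb_softlogit: %d features, n = %d, mean cross-entropy = %.6g, %d iterations>\n",
    nrow(x$params$coef), x$n, x$loss, x$iterations
  ))
  invisible(x)
}

#' @export
predict.nb_softlogit <- function(object, newdata, ...) {
  standardized_logistic(newdata, object$params)
}

#' Tidy a soft-label logistic fit
#'
#' @param x An `nb_softlogit` object.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `mu`, `sigma`,
#'   `estimate` (the weight on the standardized feature).
#' @method tidy nb_softlogit
#' @export
tidy.nb_softlogit <- function(x, ...) {
  dplyr::rename(x$params$coef, estimate = "w")
}

#' Glance at a soft-label logistic fit
#'
#' @inheritParams tidy.nb_softlogit
#' @return One-row tibble: `n`, `n_features`, `log_loss`, `iterations`,
#'   `converged`, `l2`, `intercept`.
#' @method glance nb_softlogit
#' @export
glance.nb_softlogit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_features = nrow(x$params$coef), log_loss = x$loss,
    iterations = x$iterations, converged = x$converged, l2 = x$l2,
    intercept = x$params$b
  )
}
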