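#' Binarize a pattern set
#'
#' Collapses each pattern to the set of cortical channels that spike in it:
#' entry \eqn{m_{p,n} = 1} iff channel \eqn{n} spikes during pattern
#' \eqn{p}. Timing information and spike multiplicities are discarded.
#'
#' @param patterns a list of `spike_pattern`s.
#' @param P number of cortical channels (defaults to the attached config, or
#'   the largest channel index seen).
#' @return list(M, rewarded): an `N_p x P` binary matrix and the label
#'   vector.
#' @export
binarize_patterns <- function(patterns, P = NULL) {
  if (is.null(P)) {
    cfg <- attr(patterns, "config")
    P <- if (!is.null(cfg)) cfg$P
         else max(unlist(lapply(patterns, `[[`, "channels")), 1L)
  }
  M <- t(vapply(patterns, function(p) {
    row <- numeric(P)
    row[unique(p$channels)] <- 1
    row
  }, numeric(P)))
  list(M = M, rewarded = vapply(patterns, `[[`, logical(1), "rewarded"))
}

#' Logistic regression with nonnegative weights
#'
#' The machine-learning comparator for the spiking network: a logistic
#' classifier on the binarized pattern matrix whose linear coefficients are
#' constrained to be nonnegative — the constraint an excitatory synaptic
#' pathway imposes — while the intercept stays free. Fits by maximising the
#' log-likelihood with a mild L2 penalty on the weights (for a strictly
#' convex, bounded problem on separable data) using box-constrained
#' L-BFGS-B.
#'
#' Like an excitatory neuron, the constrained classifier cannot separate a
#' rewarded pattern from a non-rewarded superpattern: the superpattern always
#' scores at least as high.
#'
#' @param M binary `N_p x P` matrix from [binarize_patterns()].
#' @param rewarded logical (or 0/1) label vector.
#' @param lambda L2 regularization strength on the weights (not the
#'   intercept); set to 0 to disable.
#' @param threshold classification probability threshold.
#' @return list with `weights` (nonnegative), `intercept`, `fitted`
#'   (probabilities), `predicted`, `accuracy` (training accuracy), and
#'   `convergence` diagnostics from [stats::optim()].
#' @export
fit_nonneg_logistic <- function(M, rewarded, lambda = 1e-4,
                                threshold = 0.5) {
  M <- as.matrix(M)
  y <- as.numeric(rewarded)
  stopifnot(nrow(M) == length(y), nrow(M) >= 1)
  P <- ncol(M)
  nll <- function(par) {
    eta <- par[1] + drop(M %*% par[-1])
    # -sum(y*log(p) + (1-y)*log(1-p)) in a numerically stable form
    sum((1 - y) * eta + log1p(exp(-eta))) + lambda * sum(par[-1]^2)
  }
  grad <- function(par) {
    eta <- par[1] + drop(M %*% par[-1])
    p <- stats::plogis(eta)
    d <- p - y
    c(sum(d), drop(crossprod(M, d)) + 2 * lambda * par[-1])
  }
  fit <- stats::optim(c(0, rep(0.1, P)), nll, grad, method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, P)),
                      control = list(maxit = 1000))
  if (fit$convergence != 0)
    warning("constrained logistic fit did not converge (code ",
            fit$convergence, "): ", fit$message)
  eta <- fit$par[1] + drop(M %*% fit$par[-1])
  prob <- stats::plogis(eta)
  pred <- prob >= threshold
  list(weights = fit$par[-1], intercept = fit$par[1], fitted = prob,
       predicted = pred, accuracy = mean(pred == (y == 1)),
       convergence = fit[c("convergence", "message", "value")])
}
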