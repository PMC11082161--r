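#' Network configuration
#'
#' @param model `"m1"` or `"m2"`, or an [m1_params()]/[m2_params()] object.
#' @param kernel a [synapse_kernel()].
#' @param n_msn 1, or 2 for the collateral-inhibition microcircuit (accuracy
#'   is read out on MSN1 only).
#' @param J collateral inhibition weight (nA, `<= 0`; 0 is the uncoupled
#'   control).
#' @param reward_scheme two-MSN reward assignment: `"differential"` rewards
#'   MSN2 exactly on the patterns not rewarded for MSN1; `"same"` rewards
#'   both identically.
#' @param w_init range of the uniform initial weights (nA).
#' @param w_min,w_max synaptic weight bounds (nA).
#' @param dt Euler step (ms).
#' @return An object of class `network_config`.
#' @export
network_config <- function(model = "m1", kernel = synapse_kernel("dirac"),
                           n_msn = 1, J = -0.5,
                           reward_scheme = c("differential", "same"),
                           w_init = c(0, 0.05), w_min = 0, w_max = 2,
                           dt = 0.1) {
  if (is.character(model))
    model <- switch(match.arg(model, c("m1", "m2")),
                    m1 = m1_params(), m2 = m2_params())
  stopifnot(inherits(model, "msn_params"), n_msn %in% c(1, 2), J <= 0,
            length(w_init) == 2, w_init[1] <= w_init[2], dt > 0,
            w_min <= w_max)
  structure(list(model = model, kernel = kernel, n_msn = n_msn, J = J,
                 reward_scheme = match.arg(reward_scheme),
                 w_init = w_init, w_min = w_min, w_max = w_max, dt = dt),
            class = "network_config")
}

#' Training configuration
#'
#' @param n_iterations number of pattern presentations.
#' @param test_every run a frozen-weight, noise-free test session every this
#'   many iterations (defaults to the number of patterns `N_p`).
#' @param T_1 MaxAccuracy half-window, in test sessions.
#' @param n_repetitions repetitions for sweep drivers.
#' @param seed optional RNG seed set at the start of training.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_iterations = 500, test_every = NULL, T_1 = 10,
                         n_repetitions = 250, seed = NULL) {
  stopifnot(n_iterations >= 1, is.null(test_every) || test_every >= 1,
            T_1 >= 0, n_repetitions >= 1)
  structure(list(n_iterations = n_iterations, test_every = test_every,
                 T_1 = T_1, n_repetitions = n_repetitions, seed = seed),
            class = "train_config")
}

#' Classify the MSN response to one pattern presentation
#'
#' A rewarded pattern is learned when the MSN fires at or after the last
#' template spike of the sequence (\eqn{\sigma = 1}); firing strictly before
#' it is a premature type 1 error, and silence is a type 2 error.
#' Non-rewarded patterns must not elicit any spike. The verdict is judged
#' against the last template (correlated) spike, never against background
#' noise spikes.
#'
#' @param pattern the presented `spike_pattern`.
#' @param spikes MSN spike times of the trial (ms).
#' @return One-row data frame: `rewarded`, `spiked`, `spiked_after`,
#'   `first_spike`, `t_last`, `error` (one of `"success"`, `"type1"`,
#'   `"type2"`, `"n/a"`).
#' @export
classify_trial <- function(pattern, spikes) {
  stopifnot(inherits(pattern, "spike_pattern"))
  t_last <- if (length(pattern$times)) max(pattern$times) else 0
  nu <- length(spikes) > 0
  first <- if (nu) min(spikes) else NA_real_
  sigma <- nu && first >= t_last
  err <- if (!pattern$rewarded) "n/a"
         else if (sigma) "success"
         else if (nu) "type1"
         else "type2"
  data.frame(rewarded = pattern$rewarded, spiked = nu, spiked_after = sigma,
             first_spike = first, t_last = t_last, error = err,
             stringsAsFactors = FALSE)
}

run_test_session <- function(patterns, net, W1, W2) {
  out <- lapply(seq_along(patterns), function(k) {
    p <- patterns[[k]]
    res <- simulate_trial(net$model, net$kernel, as_input_spec(p),
                          weights = W1, duration = p$t_duration, dt = net$dt,
                          noise = FALSE, plasticity = NULL,
                          n_msn = net$n_msn, weights2 = W2, J = net$J)
    cbind(pattern = k, classify_trial(p, res$spikes))
  })
  do.call(rbind, out)
}

#' Train an MSN (or two-MSN circuit) on a pattern-classification task
#'
#' The training loop draws a pattern uniformly from the set at each
#' iteration, presents it with plasticity active (rewarded patterns carry
#' `A_reward > 0`, others 0; in two-MSN differential mode MSN2 receives the
#' complementary rewards), resets membrane and plasticity state between
#' presentations, and every `test_every` iterations runs a frozen-weight,
#' noise-free test session over all patterns. Background spikes
#' (`lambda_stim`, `lambda_ext`) and timing jitter (`tau_pattern`) are
#' redrawn at every training presentation from the task configuration.
#'
#' @param patterns a list of `spike_pattern`s (reward flags set), typically
#'   from [gen_task1()], [gen_task2_nested()] or [gen_task4_poisson()].
#' @param net a [network_config()].
#' @param rule an [stdp_rule()].
#' @param A_reward reward amplitude for rewarded patterns (0 reproduces the
#'   unsupervised control).
#' @param train a [train_config()].
#' @param cfg optional [task_config()] overriding the one attached to
#'   `patterns` (noise rates, jitter).
#' @return An object of class `striatal_fit` with components
#'   `accuracy` (data frame: `iteration`, `accuracy`, `max_accuracy`),
#'   `weights` (final MSN1 weights), `weights2`, `weight_trace` (weights at
#'   each test session), `outcomes` (outcome log of the final test session),
#'   `patterns`, and the configuration echo.
#' @seealso [predict.striatal_fit()], [test_subpatterns()]
#' @export
run_training <- function(patterns, net = network_config(),
                         rule = stdp_rule("asymmetric_anti_hebbian"),
                         A_reward = 0.9, train = train_config(),
                         cfg = NULL) {
  if (is.null(cfg)) cfg <- attr(patterns, "config")
  if (is.null(cfg)) cfg <- task_config(P = max(1L, max(unlist(lapply(
    patterns, `[[`, "channels")), 0L)), N_p = length(patterns))
  if (!is.null(train$seed)) set.seed(train$seed)
  N_p <- length(patterns)
  test_every <- if (is.null(train$test_every)) N_p else train$test_every
  P <- cfg$P
  W1 <- stats::runif(P, net$w_init[1], net$w_init[2])
  W2 <- if (net$n_msn == 2) stats::runif(P, net$w_init[1], net$w_init[2])
        else NULL
  rewarded <- vapply(patterns, `[[`, logical(1), "rewarded")
  noisy <- cfg$lambda_stim > 0 || cfg$lambda_ext > 0
  acc_it <- integer(0); acc <- numeric(0)
  wtrace <- list()
  outcomes <- NULL
  for (it in seq_len(train$n_iterations)) {
    k <- sample.int(N_p, 1)
    p <- patterns[[k]]
    if (cfg$tau_pattern > 0) p <- jitter_pattern(p, cfg$tau_pattern)
    inp <- if (noisy) add_noise_spikes(p, cfg) else as_input_spec(p)
    Ar1 <- if (rewarded[k]) A_reward else 0
    Ar2 <- if (net$n_msn == 2) {
      if (net$reward_scheme == "differential") {
        if (rewarded[k]) 0 else A_reward
      } else Ar1
    } else 0
    res <- simulate_trial(net$model, net$kernel, inp, weights = W1,
                          duration = p$t_duration, dt = net$dt,
                          noise = inherits(net$model, "m1_params"),
                          plasticity = rule, A_reward = Ar1,
                          w_min = net$w_min, w_max = net$w_max,
                          n_msn = net$n_msn, weights2 = W2, J = net$J,
                          A_reward2 = Ar2)
    W1 <- res$weights
    if (net$n_msn == 2) W2 <- res$weights2
    if (it %% test_every == 0) {
      outcomes <- run_test_session(patterns, net, W1, W2)
      acc_it <- c(acc_it, it)
      acc <- c(acc, accuracy(outcomes))
      wtrace[[length(wtrace) + 1]] <- W1
    }
  }
  structure(list(
    accuracy = data.frame(iteration = acc_it, accuracy = acc,
                          max_accuracy = max_accuracy(acc, train$T_1)),
    weights = W1, weights2 = W2,
    weight_trace = do.call(rbind, wtrace),
    outcomes = outcomes, patterns = patterns,
    net = net, rule = rule, A_reward = A_reward, train = train, cfg = cfg),
    class = "striatal_fit")
}

#' @export
print.striatal_fit <- function(x, ...) {
  cat(sprintf("<striatal_fit> %s MSN%s, %s STDP, A_reward = %g\n",
              if (inherits(x$net$model, "m1_params")) "M1" else "M2",
              if (x$net$n_msn == 2) " pair (collateral inhibition)" else "",
              x$rule$name, x$A_reward))
  n <- nrow(x$accuracy)
  if (n)
    cat(sprintf("  %d iterations, %d test sessions; final accuracy %.3f, final MaxAccuracy %.3f\n",
                x$train$n_iterations, n, x$accuracy$accuracy[n],
                x$accuracy$max_accuracy[n]))
  invisible(x)
}

#' @export
summary.striatal_fit <- function(object, ...) {
  n <- nrow(object$accuracy)
  out <- list(
    model = if (inherits(object$net$model, "m1_params")) "M1" else "M2",
    rule = object$rule$name,
    n_msn = object$net$n_msn,
    A_reward = object$A_reward,
    n_patterns = length(object$patterns),
    final_accuracy = if (n) object$accuracy$accuracy[n] else NA_real_,
    final_max_accuracy = if (n) object$accuracy$max_accuracy[n] else NA_real_,
    weights = object$weights,
    error_table = if (!is.null(object$outcomes))
      table(object$outcomes$error) else NULL)
  class(out) <- "summary.striatal_fit"
  out
}

#' @export
print.summary.striatal_fit <- function(x, ...) {
  cat(sprintf("Striatal sequence-learning fit (%s, %s, %d MSN)\n",
              x$model, x$rule, x$n_msn))
  cat(sprintf("  patterns: %d   A_reward: %g\n", x$n_patterns, x$A_reward))
  cat(sprintf("  final accuracy:    %.3f\n", x$final_accuracy))
  cat(sprintf("  final MaxAccuracy: %.3f\n", x$final_max_accuracy))
  cat("  final weights (nA):\n")
  print(round(x$weights, 4))
  if (!is.null(x$error_table)) {
    cat("  last test session verdicts:\n")
    print(x$error_table)
  }
  invisible(x)
}

#' @export
coef.striatal_fit <- function(object, ...) object$weights

#' Classify patterns with the trained, frozen network
#'
#' @param object a `striatal_fit`.
#' @param newdata a list of `spike_pattern`s; defaults to the training set.
#' @param ... unused.
#' @return Outcome data frame (one row per pattern) as in [classify_trial()].
#' @export
predict.striatal_fit <- function(object, newdata = NULL, ...) {
  pats <- if (is.null(newdata)) object$patterns else newdata
  run_test_session(pats, object$net, object$weights, object$weights2)
}

#' @export
plot.striatal_fit <- function(x, ...) {
  a <- x$accuracy
  graphics::plot(a$iteration, a$max_accuracy, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "training iteration",
                 ylab = "accuracy", ...)
  graphics::lines(a$iteration, a$accuracy, lty = 2)
  graphics::legend("bottomright", legend = c("MaxAccuracy", "Accuracy"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(x)
}

#' Probe a trained network with proper subpatterns
#'
#' Presents random proper subpatterns of the multi-spike rewarded patterns to
#' the frozen network and reports how often the MSN stays silent — the
#' anti-Hebbian equilibrium is expected to withhold spikes until the whole
#' sequence has been seen.
#'
#' @param fit a `striatal_fit`.
#' @param n_draws subpattern draws per eligible pattern.
#' @return list(fraction_silent, n_probes, outcomes).
#' @export
test_subpatterns <- function(fit, n_draws = 5) {
  eligible <- Filter(function(p) p$rewarded && length(p$times) >= 2,
                     fit$patterns)
  if (!length(eligible))
    return(list(fraction_silent = NA_real_, n_probes = 0L, outcomes = NULL))
  probes <- unlist(lapply(eligible, function(p)
    replicate(n_draws, subpattern(p), simplify = FALSE)), recursive = FALSE)
  out <- predict(fit, newdata = probes)
  list(fraction_silent = mean(!out$spiked), n_probes = nrow(out),
       outcomes = out)
}
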