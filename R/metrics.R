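#' Classification accuracy of a test session
#'
#' \deqn{Accuracy = \frac{1}{N_p} \sum_k r_k \sigma_k + (1 - r_k)(1 - \nu_k)}
#' where \eqn{r_k} flags a rewarded pattern, \eqn{\nu_k} any MSN spike during
#' the trial and \eqn{\sigma_k} a first MSN spike at or after the last
#' template spike of the pattern.
#'
#' @param outcomes a data frame with logical columns `rewarded`, `spiked`,
#'   `spiked_after` (one row per pattern), as produced by [classify_trial()].
#' @return The accuracy in `[0, 1]`.
#' @export
accuracy <- function(outcomes) {
  if (NROW(outcomes) == 0) stop("empty outcome list")
  r <- as.numeric(outcomes$rewarded)
  s <- as.numeric(outcomes$spiked_after)
  v <- as.numeric(outcomes$spiked)
  mean(r * s + (1 - r) * (1 - v))
}

#' Sliding-window maximum of an accuracy series
#'
#' `MaxAccuracy(t) = max over [t - T_1, t + T_1] of Accuracy`, with the
#' window truncated at the series boundaries. Smooths the intrinsic
#' success/failure alternation of the anti-Hebbian equilibrium.
#'
#' @param x numeric accuracy series (one value per test session).
#' @param T_1 half-window in test sessions.
#' @return Numeric series of the same length.
#' @export
max_accuracy <- function(x, T_1 = 10) {
  stopifnot(T_1 >= 0)
  n <- length(x)
  if (n == 0) return(numeric(0))
  vapply(seq_len(n), function(i)
    max(x[max(1, i - T_1):min(n, i + T_1)]), numeric(1))
}

#' Potentiation window of the anti-Hebbian/reward equilibrium
#'
#' When a success terminates a rewarded pattern, synapses of neurons that
#' fired more than \eqn{T_p = \tau_s \log(-A_{pre\mbox{-}post}/A_{reward})}
#' before the MSN spike are net-potentiated (the reward exceeds the pre-post
#' depression); later ones are net-depressed.
#'
#' @param tau_stdp STDP timescale (ms).
#' @param A_pre_post pre-post amplitude, must be negative.
#' @param A_reward reward amplitude, must be positive.
#' @return \eqn{T_p} in ms (returned as-is when non-positive).
#' @export
potentiation_window <- function(tau_stdp = 20, A_pre_post = -1,
                                A_reward = 0.9) {
  if (A_reward == 0) stop("undefined for A_reward = 0")
  if (A_pre_post >= 0) stop("requires pre-post depression (A_pre_post < 0)")
  tau_stdp * log(-A_pre_post / A_reward)
}

#' Ceiling on consecutive successes and the induced accuracy bound
#'
#' Between two missed-spike (type 2) errors the weight budget allows at most
#' \deqn{N = \lceil A_{reward} / |A_{pre\mbox{-}post} + A_{reward}| \rceil}
#' successes: each success drains the last synapse by
#' \eqn{\varepsilon|A_{pre\mbox{-}post} + A_{reward}|} while each type 2
#' error refills every synapse by \eqn{\varepsilon A_{reward}}. The long-run
#' accuracy therefore cannot exceed \eqn{1 - 1/N}.
#'
#' @param A_reward reward amplitude.
#' @param A_pre_post pre-post STDP amplitude.
#' @return list(N, accuracy_bound).
#' @export
success_ceiling <- function(A_reward = 0.9, A_pre_post = -1) {
  s <- A_pre_post + A_reward
  if (s == 0) stop("A_pre_post + A_reward = 0: the number of successes is unbounded")
  # guard the ceiling against floating-point residue in the ratio
  N <- ceiling(A_reward / abs(s) - 1e-9)
  list(N = N, accuracy_bound = 1 - 1 / N)
}

#' Theory inputs for the error-mode conditions
#'
#' @param times template spike times \eqn{t_1 < ... < t_n} (ms).
#' @param w_max_jump maximal per-spike voltage jump (mV); use
#'   [weight_to_jump()] to convert a synaptic bound in nA.
#' @param params an [m1_params()] object supplying \eqn{V_r, V_{th}, \tau}
#'   (and \eqn{V_{eq}} for the alternative baseline).
#' @param baseline `"V_r"` evaluates the conditions exactly as the closed
#'   form states them; `"V_eq"` rebases them on the resting potential, which
#'   matches trials that start from rest.
#' @return An object of class `theory_inputs`.
#' @export
theory_inputs <- function(times, w_max_jump, params = m1_params(),
                          baseline = c("V_r", "V_eq")) {
  stopifnot(!is.unsorted(times, strictly = TRUE), w_max_jump >= 0)
  baseline <- match.arg(baseline)
  structure(list(times = times, w_max_jump = w_max_jump, params = params,
                 baseline = baseline),
            class = "theory_inputs")
}

theory_base <- function(ti)
  if (ti$baseline == "V_r") ti$params$V_r else ti$params$V_eq

#' Convert a synaptic weight to its Dirac voltage jump
#'
#' @param w weight (nA).
#' @param params [m1_params()] or [m2_params()]; the jump is `R * w` or
#'   `R_scale * w` mV respectively.
#' @return Voltage jump (mV).
#' @export
weight_to_jump <- function(w, params) {
  if (inherits(params, "m1_params")) params$R * w else params$R_scale * w
}

#' Necessary condition for a premature (type 1) spike
#'
#' A type 1 error (MSN spike strictly before the last template spike) can
#' only occur if the maximal voltage reachable just before the last spike
#' exceeds threshold:
#' \deqn{base + w_{max} \sum_{k=1}^{n-1} e^{-\delta_k^{n-1}/\tau} \ge V_{th},}
#' with \eqn{\delta_k^l = t_l - t_k}.
#'
#' @param inputs a [theory_inputs()] with at least two spikes.
#' @return Logical flag.
#' @export
type1_possible <- function(inputs) {
  stopifnot(inherits(inputs, "theory_inputs"), length(inputs$times) >= 2)
  tt <- inputs$times
  n <- length(tt)
  del <- tt[n - 1] - tt[seq_len(n - 1)]
  theory_base(inputs) +
    inputs$w_max_jump * sum(exp(-del / inputs$params$tau)) >=
    inputs$params$V_th
}

#' Sufficient condition for systematic missed spikes (type 2)
#'
#' Type 2 errors occur on every presentation if even the maximal voltage
#' after the full pattern stays below threshold:
#' \deqn{base + w_{max} \sum_{k=1}^{n} e^{-\delta_k^{n}/\tau} \le V_{th}.}
#'
#' @param inputs a [theory_inputs()].
#' @return Logical flag.
#' @export
type2_certain <- function(inputs) {
  stopifnot(inherits(inputs, "theory_inputs"), length(inputs$times) >= 1)
  tt <- inputs$times
  del <- tt[length(tt)] - tt
  theory_base(inputs) +
    inputs$w_max_jump * sum(exp(-del / inputs$params$tau)) <=
    inputs$params$V_th
}

#' Per-iteration observables of repeated single-pattern presentations
#'
#' For a log of presentations grouped by iteration across independent
#' repetitions, computes the probability of observing no MSN spike, the mean
#' timing of the first MSN spike relative to the end of the pattern template
#' (among spiking repetitions; `NA` when all are silent), and the
#' classification accuracy.
#'
#' @param log a data frame with columns `iteration`, `rewarded`, `spiked`,
#'   `spiked_after`, `first_spike` (ms, `NA` if silent), `t_last` (time of
#'   the last template spike, ms).
#' @return A data frame with one row per iteration: `iteration`,
#'   `p_no_spike`, `relative_timing`, `accuracy`.
#' @export
presentation_observables <- function(log) {
  stopifnot(all(c("iteration", "rewarded", "spiked", "spiked_after",
                  "first_spike", "t_last") %in% names(log)))
  its <- sort(unique(log$iteration))
  out <- lapply(its, function(i) {
    g <- log[log$iteration == i, ]
    rel <- g$first_spike - g$t_last
    data.frame(iteration = i,
               p_no_spike = mean(!g$spiked),
               relative_timing = if (any(g$spiked))
                 mean(rel[g$spiked], na.rm = TRUE) else NA_real_,
               accuracy = accuracy(g))
  })
  do.call(rbind, out)
}

#' Two-sample comparison between experimental conditions
#'
#' Welch two-sample t-test, the procedure used throughout for comparing
#' accuracy distributions between rules, models or circuits. No
#' multiple-testing correction is applied.
#'
#' @param x,y numeric samples.
#' @param alternative passed to [stats::t.test()].
#' @return The `htest` object.
#' @export
compare_conditions <- function(x, y, alternative = "two.sided") {
  stats::t.test(x, y, alternative = alternative)
}
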