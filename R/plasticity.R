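#' Pair-based STDP rule
#'
#' Defines the exponential spike-timing-dependent plasticity kernel
#' \deqn{\Phi(\Delta t) = A_{post\mbox{-}pre}\, e^{\Delta t/\tau_s}
#'       \;(\Delta t < 0), \qquad
#'       \Phi(\Delta t) = A_{pre\mbox{-}post}\, e^{-\Delta t/\tau_s}
#'       \;(\Delta t > 0),}
#' with \eqn{\Delta t = t_{post} - t_{pre}} and all-to-all pairing. A
#' simultaneous pre/post pair is causally ordered input-before-output by the
#' integration scheme, so \eqn{\Phi(0) = A_{pre\mbox{-}post}} (the
#' \eqn{\Delta t \to 0^+} limit).
#'
#' The four named presets, ordered as (A_post_pre, A_pre_post):
#' \describe{
#'   \item{`"symmetric_ltd"`}{(-1, -1) — symmetric anti-Hebbian (all pairings depress).}
#'   \item{`"asymmetric_hebbian"`}{(-1, +1) — pre-before-post potentiates.}
#'   \item{`"asymmetric_anti_hebbian"`}{(+1, -1) — pre-before-post depresses.}
#'   \item{`"symmetric_ltp"`}{(+1, +1) — symmetric Hebbian (all pairings potentiate).}
#' }
#'
#' @param preset a preset name (hyphens and the short aliases `"sym-ltd"`,
#'   `"hebb"`, `"anti-hebb"`, `"sym-ltp"` are also accepted), or `NULL` to
#'   give amplitudes directly.
#' @param A_post_pre,A_pre_post dimensionless pairing amplitudes.
#' @param tau_stdp kernel timescale (ms).
#' @param epsilon plasticity rate (nA per unit amplitude).
#' @return An object of class `stdp_rule`.
#' @export
stdp_rule <- function(preset = NULL, A_post_pre = NULL, A_pre_post = NULL,
                      tau_stdp = 20, epsilon = 0.02) {
  stopifnot(tau_stdp > 0, epsilon >= 0)
  name <- "custom"
  if (!is.null(preset)) {
    key <- gsub("-", "_", tolower(preset))
    presets <- list(
      symmetric_ltd = c(-1, -1), sym_ltd = c(-1, -1),
      asymmetric_hebbian = c(-1, 1), hebb = c(-1, 1), hebbian = c(-1, 1),
      asymmetric_anti_hebbian = c(1, -1), anti_hebb = c(1, -1),
      anti_hebbian = c(1, -1),
      symmetric_ltp = c(1, 1), sym_ltp = c(1, 1))
    if (is.null(presets[[key]]))
      stop("unknown STDP preset: ", preset)
    A_post_pre <- presets[[key]][1]
    A_pre_post <- presets[[key]][2]
    name <- c(sym_ltd = "symmetric_ltd", hebb = "asymmetric_hebbian",
              hebbian = "asymmetric_hebbian", anti_hebb = "asymmetric_anti_hebbian",
              anti_hebbian = "asymmetric_anti_hebbian",
              sym_ltp = "symmetric_ltp")[key]
    if (is.na(name)) name <- key
  } else if (is.null(A_post_pre) || is.null(A_pre_post)) {
    stop("give either a preset name or both amplitudes")
  }
  structure(list(name = unname(name), A_post_pre = A_post_pre,
                 A_pre_post = A_pre_post, tau_stdp = tau_stdp,
                 epsilon = epsilon),
            class = "stdp_rule")
}

#' @export
print.stdp_rule <- function(x, ...) {
  cat(sprintf("<stdp_rule: %s> A_post_pre = %g, A_pre_post = %g, tau_stdp = %g ms, epsilon = %g nA\n",
              x$name, x$A_post_pre, x$A_pre_post, x$tau_stdp, x$epsilon))
  invisible(x)
}

#' Evaluate the STDP pairing kernel
#'
#' @param delta_t spike-time difference \eqn{t_{post} - t_{pre}} (ms);
#'   vectorised.
#' @param rule an [stdp_rule()] object.
#' @return Dimensionless pairing amplitude \eqn{\Phi(\Delta t)}.
#' @export
stdp_kernel <- function(delta_t, rule) {
  stopifnot(inherits(rule, "stdp_rule"))
  ifelse(delta_t < 0,
         rule$A_post_pre * exp(delta_t / rule$tau_stdp),
         rule$A_pre_post * exp(-delta_t / rule$tau_stdp))
}

#' Non-associative reward potentiation
#'
#' During a rewarded trial every presynaptic spike potentiates its synapse by
#' \eqn{\Delta W = \varepsilon A_{reward}}, independently of postsynaptic
#' activity.
#'
#' @param A_reward dimensionless reward amplitude; 0 disables reward-LTP.
#' @return An object of class `reward_rule`.
#' @export
reward_rule <- function(A_reward = 0.9) {
  stopifnot(is.numeric(A_reward), A_reward >= 0)
  structure(list(A_reward = A_reward), class = "reward_rule")
}

#' Trial-scoped spike history
#'
#' Holds presynaptic spike times per channel and postsynaptic spike times for
#' the all-to-all STDP bookkeeping. Histories are cleared at trial boundaries
#' (membrane and plasticity state are reset between pattern presentations).
#'
#' @param P number of cortical channels.
#' @return An object of class `spike_history`.
#' @export
spike_history <- function(P) {
  stopifnot(P >= 1)
  structure(list(pre = rep(list(numeric(0)), P), post = numeric(0), P = P),
            class = "spike_history")
}

#' Clear a spike history
#'
#' @param hist a [spike_history()].
#' @return The emptied history (idempotent).
#' @export
reset_history <- function(hist) {
  stopifnot(inherits(hist, "spike_history"))
  spike_history(hist$P)
}

clip_weights <- function(W, w_min = 0, w_max = 2) pmin(pmax(W, w_min), w_max)

#' Apply plasticity at a postsynaptic spike
#'
#' Updates every channel by \eqn{\varepsilon \sum_{t_{pre,i} \le t_{post}}
#' \Phi(t_{post} - t_{pre,i})} (all-to-all; a simultaneous pre spike counts
#' through the pre-post branch), clips to the weight bounds, and records the
#' spike in the history.
#'
#' @param weights numeric weight vector (nA).
#' @param hist a [spike_history()].
#' @param t_post postsynaptic spike time (ms), not before any stored time.
#' @param rule an [stdp_rule()].
#' @param w_min,w_max weight bounds (nA).
#' @return list(weights, hist).
#' @export
on_post_spike <- function(weights, hist, t_post, rule, w_min = 0, w_max = 2) {
  stopifnot(inherits(hist, "spike_history"), length(weights) == hist$P)
  dW <- vapply(hist$pre, function(tp) {
    if (!length(tp)) return(0)
    tp <- tp[tp <= t_post]
    if (!length(tp)) return(0)
    sum(rule$A_pre_post * exp(-(t_post - tp) / rule$tau_stdp))
  }, numeric(1))
  weights <- clip_weights(weights + rule$epsilon * dW, w_min, w_max)
  hist$post <- c(hist$post, t_post)
  list(weights = weights, hist = hist)
}

#' Apply plasticity at a presynaptic spike
#'
#' Updates the spiking channel by \eqn{\varepsilon \sum_{t_{post} < t_{pre}}
#' \Phi(t_{post} - t_{pre})}, adds the reward potentiation
#' \eqn{\varepsilon A_{reward}} when the trial is rewarded, clips, and records
#' the spike.
#'
#' @param weights numeric weight vector (nA).
#' @param hist a [spike_history()].
#' @param channel channel index of the presynaptic spike.
#' @param t_pre presynaptic spike time (ms), not before any stored time.
#' @param rule an [stdp_rule()].
#' @param reward a [reward_rule()] (or a bare `A_reward` number).
#' @param rewarded_trial logical; apply the reward potentiation.
#' @param w_min,w_max weight bounds (nA).
#' @return list(weights, hist).
#' @export
on_pre_spike <- function(weights, hist, channel, t_pre, rule,
                         reward = reward_rule(0), rewarded_trial = FALSE,
                         w_min = 0, w_max = 2) {
  stopifnot(inherits(hist, "spike_history"), length(weights) == hist$P,
            channel >= 1, channel <= hist$P)
  A_r <- if (inherits(reward, "reward_rule")) reward$A_reward else reward
  tpost <- hist$post[hist$post < t_pre]
  dW <- if (length(tpost))
    sum(rule$A_post_pre * exp((tpost - t_pre) / rule$tau_stdp)) else 0
  if (isTRUE(rewarded_trial)) dW <- dW + A_r
  weights[channel] <- clip_weights(weights[channel] + rule$epsilon * dW,
                                   w_min, w_max)
  hist$pre[[channel]] <- c(hist$pre[[channel]], t_pre)
  list(weights = weights, hist = hist)
}

#' Replay a trial's plasticity from its event log
#'
#' Applies [on_pre_spike()]/[on_post_spike()] in causal order over a recorded
#' trial (cortical events and MSN spike times) starting from the trial's
#' initial weights. Used to verify that the compiled engine's online updates
#' agree with the history-based definition of the rule.
#'
#' @param W0 initial weight vector (nA).
#' @param channels,times cortical spike events (channel index, ms).
#' @param post_times MSN spike times (ms).
#' @param rule an [stdp_rule()].
#' @param A_reward reward amplitude applied at every presynaptic spike.
#' @param dt Euler step (ms); events are binned to step left edges so
#'   simultaneity matches the engine.
#' @param w_min,w_max weight bounds (nA).
#' @return Final weight vector.
#' @export
replay_plasticity <- function(W0, channels, times, post_times, rule,
                              A_reward = 0, dt = 0.1, w_min = 0, w_max = 2) {
  hist <- spike_history(length(W0))
  W <- W0
  bin <- function(t) floor(t / dt + 1e-9) * dt
  ev <- data.frame(t = c(bin(times), post_times),
                   ch = c(channels, rep(NA_integer_, length(post_times))),
                   pre = c(rep(TRUE, length(times)),
                           rep(FALSE, length(post_times))))
  # stable order: by time, pre events before post events at equal times;
  # the net update of each Euler step is clipped as a whole
  ev <- ev[order(ev$t, !ev$pre), ]
  for (i in seq_len(nrow(ev))) {
    if (ev$pre[i]) {
      r <- on_pre_spike(W, hist, ev$ch[i], ev$t[i], rule,
                        reward_rule(A_reward), rewarded_trial = A_reward > 0,
                        w_min = -Inf, w_max = Inf)
    } else {
      r <- on_post_spike(W, hist, ev$t[i], rule, w_min = -Inf, w_max = Inf)
    }
    W <- r$weights
    hist <- r$hist
    if (i == nrow(ev) || ev$t[i + 1] > ev$t[i])
      W <- clip_weights(W, w_min, w_max)
  }
  W
}
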