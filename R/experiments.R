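#' Stationary Poisson-drive experiment
#'
#' Runs uninterrupted simulations of a single MSN receiving independent
#' Poisson spike trains on each of the `P` cortical channels, with STDP (and
#' optionally reward-LTP on every presynaptic spike) active throughout, and
#' reports the synaptic weight statistics and output firing rates. This is
#' the protocol used to characterise the stationary weight distributions of
#' the four STDP polarities: Hebbian rules saturate the weights while
#' anti-Hebbian rules settle on low, reward-sensitive weights.
#'
#' @param rule an [stdp_rule()].
#' @param A_reward reward amplitude applied at every presynaptic spike
#'   (0 = no reward).
#' @param rate_hz Poisson rate per cortical channel (Hz).
#' @param P number of cortical channels.
#' @param duration_s run length (s).
#' @param n_reps independent repetitions.
#' @param model an [m1_params()] or [m2_params()] object.
#' @param w_init initial weight range (nA).
#' @param w_min,w_max weight bounds (nA).
#' @param dt Euler step (ms).
#' @param snapshot_ms interval for weight snapshots (ms).
#' @return list with `rates` (Hz, one per repetition), `median_rate`,
#'   `final_weights` (`n_reps x P`), and `snapshots` (list of matrices).
#' @export
run_stationary_poisson <- function(rule, A_reward = 0, rate_hz = 10, P = 10,
                                   duration_s = 5, n_reps = 20,
                                   model = m1_params(),
                                   w_init = c(0, 0.05), w_min = 0, w_max = 2,
                                   dt = 0.1, snapshot_ms = 250) {
  dur <- duration_s * 1000
  rates <- numeric(n_reps)
  finw <- matrix(NA_real_, n_reps, P)
  snaps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    n_ev <- stats::rpois(1, rate_hz / 1000 * P * dur)
    tt <- sort(stats::runif(n_ev) * dur)
    ch <- sample.int(P, n_ev, replace = TRUE)
    W0 <- stats::runif(P, w_init[1], w_init[2])
    res <- simulate_trial(model, synapse_kernel("dirac"),
                          input_spec(channels = ch, times = tt),
                          weights = W0, duration = dur, dt = dt,
                          noise = inherits(model, "m1_params"),
                          plasticity = rule, A_reward = A_reward,
                          w_min = w_min, w_max = w_max,
                          record_w_every = snapshot_ms)
    rates[r] <- length(res$spikes) / duration_s
    finw[r, ] <- res$weights
    snaps[[r]] <- res$weight_snapshots
  }
  list(rates = rates, median_rate = stats::median(rates),
       final_weights = finw, snapshots = snaps)
}

#' Repeated-presentation learning dynamics of a single pattern
#'
#' Presents one pattern over and over to independent networks with plasticity
#' active, recording for every iteration the probability of observing no MSN
#' spike, the relative timing of the first spike with respect to the end of
#' the pattern, and the accuracy — the observables that expose how Hebbian
#' rules drift toward premature spiking while anti-Hebbian rules hold the
#' spike at the end of the sequence.
#'
#' @param pattern a `spike_pattern` (its `rewarded` flag selects the reward).
#' @param rule an [stdp_rule()].
#' @param A_reward reward amplitude for rewarded presentations.
#' @param n_iterations presentations per network.
#' @param n_reps independent networks.
#' @param net a [network_config()].
#' @return list with `log` (per presentation) and `observables` (per
#'   iteration, from [presentation_observables()]).
#' @export
run_single_pattern_dynamics <- function(pattern, rule, A_reward = 0.5,
                                        n_iterations = 100, n_reps = 20,
                                        net = network_config()) {
  logs <- vector("list", n_reps * n_iterations)
  idx <- 1
  for (r in seq_len(n_reps)) {
    P <- max(pattern$channels)
    W <- stats::runif(P, net$w_init[1], net$w_init[2])
    Ar <- if (pattern$rewarded) A_reward else 0
    for (it in seq_len(n_iterations)) {
      res <- simulate_trial(net$model, net$kernel, as_input_spec(pattern),
                            weights = W, duration = pattern$t_duration,
                            dt = net$dt,
                            noise = inherits(net$model, "m1_params"),
                            plasticity = rule, A_reward = Ar,
                            w_min = net$w_min, w_max = net$w_max)
      W <- res$weights
      logs[[idx]] <- cbind(iteration = it, rep = r,
                           classify_trial(pattern, res$spikes))
      idx <- idx + 1
    }
  }
  log <- do.call(rbind, logs)
  list(log = log, observables = presentation_observables(log))
}

#' Error-mode experiment: repeated rewarded 4-spike sequences
#'
#' Deterministic (noise-free) driver mapping the success / premature-spike
#' (type 1) / missed-spike (type 2) landscape of an M1 neuron learning a
#' single rewarded pattern of `n_spikes` equally spaced spikes under
#' anti-Hebbian STDP with reward-LTP. For every grid cell (inter-spike
#' interval `T_delay`, synaptic bound `w_max`) the pattern is presented
#' `n_presentations` times with plasticity on; outcomes are classified per
#' presentation and aggregated, and the trace of the last synaptic weight is
#' kept (it shows the characteristic serrated profile: slow decay over a run
#' of successes, upward jump at each type 2 error).
#'
#' @param T_delay_grid inter-spike intervals (ms).
#' @param w_max_grid synaptic weight bounds (nA).
#' @param n_presentations presentations per cell.
#' @param burn_in presentations discarded before aggregating frequencies.
#' @param rule an [stdp_rule()]; the pre-post amplitude must be negative.
#' @param A_reward reward amplitude (every presentation is rewarded).
#' @param model an [m1_params()] object.
#' @param P number of cortical channels (the pattern uses channels
#'   `1..n_spikes`).
#' @param n_spikes spikes per pattern.
#' @param t_offset,t_duration trial geometry (ms).
#' @param dt Euler step (ms).
#' @param w_start initial weight level (nA); `NULL` starts at `w_max/2`.
#' @return A list with `cells` (data frame: `T_delay`, `w_max`, `accuracy`,
#'   `type1_freq`, `type2_freq`) and `detail` (per-cell list with the outcome
#'   sequence, pattern and last-weight trace).
#' @export
run_error_mode_experiment <- function(T_delay_grid, w_max_grid,
                                      n_presentations = 200, burn_in = 0,
                                      rule = stdp_rule("asymmetric_anti_hebbian"),
                                      A_reward = 0.9, model = m1_params(),
                                      P = 10, n_spikes = 4, t_offset = 10,
                                      t_duration = 50, dt = 0.1,
                                      w_start = NULL) {
  stopifnot(rule$A_pre_post < 0)
  cells <- expand.grid(T_delay = T_delay_grid, w_max = w_max_grid)
  detail <- vector("list", nrow(cells))
  res_rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    Td <- cells$T_delay[ci]
    wm <- cells$w_max[ci]
    times <- t_offset + (seq_len(n_spikes) - 1) * Td
    if (max(times) >= t_duration)
      stop("pattern does not fit inside t_duration for T_delay = ", Td)
    pat <- new_pattern(seq_len(n_spikes), times, TRUE, t_offset, t_duration)
    W <- rep(if (is.null(w_start)) wm / 2 else w_start, P)
    err <- character(n_presentations + burn_in)
    wlast <- numeric(n_presentations + burn_in)
    for (it in seq_len(n_presentations + burn_in)) {
      res <- simulate_trial(model, synapse_kernel("dirac"),
                            as_input_spec(pat), weights = W,
                            duration = t_duration, dt = dt, noise = FALSE,
                            plasticity = rule, A_reward = A_reward,
                            w_min = 0, w_max = wm)
      err[it] <- classify_trial(pat, res$spikes)$error
      W <- res$weights
      wlast[it] <- W[n_spikes]
    }
    keep <- err[(burn_in + 1):(burn_in + n_presentations)]
    res_rows[[ci]] <- data.frame(
      T_delay = Td, w_max = wm,
      accuracy = mean(keep == "success"),
      type1_freq = mean(keep == "type1"),
      type2_freq = mean(keep == "type2"))
    detail[[ci]] <- list(pattern = pat, errors = err,
                         last_weight_trace = wlast, w_max = wm)
  }
  list(cells = do.call(rbind, res_rows), detail = detail)
}

#' Export an error-mode grid as a heatmap-shaped CSV
#'
#' @param cells the `cells` data frame from [run_error_mode_experiment()].
#' @param value which frequency to tabulate.
#' @param path output CSV path (rows: `T_delay`, columns: `w_max`).
#' @export
write_error_mode_csv <- function(cells, value = c("accuracy", "type1_freq",
                                                  "type2_freq"), path) {
  value <- match.arg(value)
  M <- stats::xtabs(stats::as.formula(paste(value, "~ T_delay + w_max")),
                    data = cells)
  utils::write.csv(as.data.frame.matrix(M), path)
  invisible(path)
}
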