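#' Trial input specification
#'
#' Assembles the spike input of a single trial: cortical spikes on the `P`
#' plastic channels and external spikes delivered through a fixed weight
#' `W_ext`.
#'
#' @param channels integer channel indices of the cortical spikes.
#' @param times spike times (ms), same length as `channels`.
#' @param ext_times external spike times (ms).
#' @param W_ext external spike weight (nA).
#' @return An object of class `input_spec`.
#' @export
input_spec <- function(channels = integer(0), times = numeric(0),
                       ext_times = numeric(0), W_ext = 1) {
  stopifnot(length(channels) == length(times), all(times >= 0),
            all(ext_times >= 0))
  o <- order(times, channels)
  structure(list(channels = as.integer(channels[o]), times = times[o],
                 ext_times = sort(ext_times), W_ext = W_ext),
            class = "input_spec")
}

#' Convert a pattern to a trial input
#'
#' @param p a `spike_pattern`.
#' @return An [input_spec()] holding only the pattern's template spikes.
#' @export
as_input_spec <- function(p) {
  if (inherits(p, "input_spec")) return(p)
  stopifnot(inherits(p, "spike_pattern"))
  input_spec(channels = p$channels, times = p$times)
}

model_param_vector <- function(p) {
  if (inherits(p, "m1_params"))
    c(p$V_eq, p$V_th, p$V_r, p$R, p$tau, p$tau_refractory, p$eta_noise)
  else
    c(p$C, p$k, p$V_c, p$V_eq, p$V_th, p$V_r, p$a, p$b, p$d, p$R_scale,
      p$eta_noise)
}

kernel_code <- function(k) match(k$kind, c("dirac", "exponential", "alpha")) - 1L

#' Simulate a single trial
#'
#' Euler integration (fixed step `dt`) of one MSN — or two MSNs with
#' collateral inhibition from the second onto the first — driven by the given
#' spike input, starting from rest (`V = V_eq`, `U = 0`). With `plasticity`
#' set, pair-based STDP and reward-LTP act online during the trial; weights
#' are clipped to `[w_min, w_max]` after every individual update. Spike times
#' use the left edge of the Euler step in which threshold is crossed, and
#' simultaneous input and output events are ordered input-before-output.
#'
#' @param model an [m1_params()] or [m2_params()] object.
#' @param kernel a [synapse_kernel()].
#' @param input an [input_spec()] or a `spike_pattern`.
#' @param weights cortical synaptic weight vector (nA); its length sets `P`.
#' @param duration trial duration (ms).
#' @param dt Euler step (ms).
#' @param noise logical; enable the membrane noise term.
#' @param plasticity `NULL` (frozen weights) or an [stdp_rule()].
#' @param A_reward reward amplitude applied at every presynaptic spike of the
#'   trial (0 on non-rewarded trials).
#' @param w_min,w_max weight bounds (nA).
#' @param n_msn 1 or 2.
#' @param weights2 second MSN's weight vector (two-MSN mode).
#' @param J collateral inhibition weight (nA, `<= 0`); each MSN2 spike kicks
#'   MSN1's voltage by `R * J` mV (M1) or `R_scale * J` mV (M2).
#' @param A_reward2 reward amplitude for the second MSN.
#' @param record_voltage logical; return the voltage trace sampled every `dt`.
#' @param record_w_every interval (ms) for weight snapshots; 0 disables.
#' @return list with `spikes` (MSN1 spike times), `weights` (final MSN1
#'   weights), `spikes2`/`weights2` in two-MSN mode, and optionally `voltage`
#'   (+ `times`) and `weight_snapshots`.
#' @export
simulate_trial <- function(model, kernel = synapse_kernel("dirac"),
                           input, weights, duration = 50, dt = 0.1,
                           noise = inherits(model, "m1_params"),
                           plasticity = NULL, A_reward = 0,
                           w_min = 0, w_max = 2,
                           n_msn = 1, weights2 = NULL, J = 0, A_reward2 = 0,
                           record_voltage = FALSE, record_w_every = 0) {
  stopifnot(inherits(model, "msn_params"), inherits(kernel, "synapse_kernel"),
            duration > 0, dt > 0)
  input <- as_input_spec(input)
  if (length(weights) < 1) stop("empty weight vector")
  if (length(input$channels) && max(input$channels) > length(weights))
    stop("input channel index exceeds number of weights")
  if (length(input$times) && max(input$times) > duration)
    stop("input events must lie within [0, duration]")
  if (n_msn == 2 && is.null(weights2))
    stop("two-MSN mode needs weights2")
  plastic <- !is.null(plasticity)
  rule <- if (plastic) plasticity else stdp_rule("symmetric_ltd")
  res <- cpp_sim_trial(
    model = if (inherits(model, "m1_params")) 1L else 2L,
    mp = model_param_vector(model),
    kernel = kernel_code(kernel), Ts = kernel$T_s,
    P = length(weights),
    ev_ch = input$channels, ev_t = input$times,
    ext_t = input$ext_times, W_ext = input$W_ext,
    W0 = as.numeric(weights), duration = duration, dt = dt,
    noise = isTRUE(noise),
    n_msn = as.integer(n_msn),
    W20 = if (is.null(weights2)) numeric(0) else as.numeric(weights2),
    J = J,
    plastic = plastic,
    A_post_pre = rule$A_post_pre, A_pre_post = rule$A_pre_post,
    tau_s = rule$tau_stdp, eps = rule$epsilon,
    A_reward1 = A_reward, A_reward2 = A_reward2,
    w_min = w_min, w_max = w_max,
    record_v = isTRUE(record_voltage), record_w_every = record_w_every)
  if (record_voltage)
    res$times <- seq(0, by = dt, length.out = length(res$voltage))
  res
}

#' Write a voltage trace as CSV
#'
#' @param trace a result of [simulate_trial()] with `record_voltage = TRUE`.
#' @param path output path; columns `time_ms`, `value`.
#' @export
write_voltage_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$times, value = trace$voltage),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a spike train as CSV
#'
#' @param channels,times spike events (channel, ms); scalar `channels` is
#'   recycled.
#' @param path output path; columns `channel`, `time_ms`.
#' @export
write_spikes_csv <- function(channels, times, path) {
  utils::write.csv(data.frame(channel = rep_len(channels, length(times)),
                              time_ms = times),
                   path, row.names = FALSE)
  invisible(path)
}
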