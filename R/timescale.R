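#' Minimal single-spike weight
#'
#' Bisection for the smallest synaptic weight at which one presynaptic spike
#' makes the neuron fire, for a given model and synaptic kernel. Continuous
#' kernels dilute the (unit-normalised) synaptic charge over their timescale,
#' so this threshold grows with `T_s`.
#'
#' @param model an [m1_params()] or [m2_params()] object.
#' @param kernel a [synapse_kernel()].
#' @param duration probe-trial duration (ms).
#' @param bounds search interval (nA).
#' @param tol relative bisection tolerance.
#' @return Threshold weight (nA).
#' @export
min_spiking_weight <- function(model, kernel, duration = 80,
                               bounds = c(0.01, 500), tol = 1e-3) {
  lo <- bounds[1]; hi <- bounds[2]
  fires <- function(w) length(simulate_trial(model, kernel,
                                             input_spec(1L, 10),
                                             weights = w,
                                             duration = duration,
                                             noise = FALSE)$spikes) > 0
  if (!fires(hi)) stop("upper search bound does not elicit a spike")
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Synaptic-timescale sweep of sequence-learning accuracy
#'
#' Trains networks on fixed-delay sequences for every synaptic timescale in
#' `grid` and reports the mean final accuracy per timescale. Because
#' continuous kernels are charge-normalised, a single spike's peak drive
#' shrinks with `T_s`; all weight-dimension quantities (initial weights,
#' bounds and the plasticity rate) are therefore multiplied by one common
#' scale factor, chosen as twice the minimal spiking weight of the slowest
#' kernel in the sweep relative to `w_max` — the same scale for every
#' timescale, so accuracy differences reflect the temporal profile alone.
#'
#' @param grid synaptic timescales to test (ms).
#' @param kind `"alpha"` or `"exponential"`.
#' @param n_reps repetitions (independent pattern draws and trainings) per
#'   timescale.
#' @param cfg a [task_config()] describing the sequence task.
#' @param model neuron model (the spike-latency M2 by default).
#' @param rule an [stdp_rule()].
#' @param A_reward reward amplitude.
#' @param n_iterations training presentations per repetition.
#' @param w_max unscaled weight bound (nA).
#' @param epsilon unscaled plasticity rate.
#' @param w_init unscaled initial weight range (nA).
#' @param seed optional master seed; repetition `r` of timescale `i` derives
#'   a fixed child seed so cells are independent of execution order.
#' @return list with `summary` (data frame: `T_s`, `mean_accuracy`,
#'   `mean_max_accuracy`), `accuracy` (matrix reps x timescales),
#'   `max_accuracy` (same shape), `optimum` (grid value maximising mean
#'   final accuracy) and `weight_scale`.
#' @export
run_timescale_sweep <- function(grid = c(0.5, 1, 3, 5, 10, 15),
                                kind = "alpha", n_reps = 10,
                                cfg = task_config(P = 10, N_p = 5, N_stim = 3),
                                model = m2_params(),
                                rule = stdp_rule("asymmetric_anti_hebbian"),
                                A_reward = 0.9, n_iterations = 500,
                                w_max = 2, epsilon = rule$epsilon,
                                w_init = c(0, 0.05), seed = NULL) {
  kappa <- 2 * min_spiking_weight(model, synapse_kernel(kind, max(grid))) /
    w_max
  rule$epsilon <- epsilon * kappa
  acc <- matrix(NA_real_, n_reps, length(grid))
  macc <- matrix(NA_real_, n_reps, length(grid))
  for (i in seq_along(grid)) {
    net <- network_config(model = model,
                          kernel = synapse_kernel(kind, grid[i]),
                          w_init = w_init * kappa, w_max = w_max * kappa)
    for (r in seq_len(n_reps)) {
      if (!is.null(seed)) set.seed(child_seed(seed, i * 1000 + r))
      pats <- gen_task1(cfg)
      fit <- run_training(pats, net = net, rule = rule, A_reward = A_reward,
                          train = train_config(n_iterations))
      n <- nrow(fit$accuracy)
      acc[r, i] <- fit$accuracy$accuracy[n]
      macc[r, i] <- fit$accuracy$max_accuracy[n]
    }
  }
  colnames(acc) <- colnames(macc) <- grid
  summary <- data.frame(T_s = grid, mean_accuracy = colMeans(acc),
                        mean_max_accuracy = colMeans(macc))
  list(summary = summary, accuracy = acc, max_accuracy = macc,
       optimum = grid[which.max(summary$mean_accuracy)],
       weight_scale = kappa)
}
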