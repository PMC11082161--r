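#' Parameters of the leaky integrate-and-fire MSN (model M1)
#'
#' Constructs the parameter set of the linear leaky integrate-and-fire
#' description of a striatal medium spiny neuron (MSN). Between spikes the
#' membrane potential obeys
#' \deqn{\tau \frac{dV}{dt} = -(V - V_{eq}) + R I(t) + \sqrt{\tau} V_{noise}(t),}
#' a spike is emitted when \eqn{V \ge V_{th}}, after which \eqn{V} is reset to
#' \eqn{V_r} and input integration is suspended for `tau_refractory`
#' milliseconds. The defaults are the values fitted to whole-cell recordings
#' of MSNs in mouse dorsolateral striatum.
#'
#' @param V_eq resting potential (mV).
#' @param V_th spike threshold (mV).
#' @param V_r reset potential (mV).
#' @param R input resistance (MOhm).
#' @param tau membrane time constant (ms).
#' @param C membrane capacitance (nF); informational, `tau/R` by construction.
#' @param tau_refractory absolute refractory period (ms).
#' @param eta_noise standard deviation of the white membrane noise (mV). The
#'   Euler discretisation adds a Gaussian increment of standard deviation
#'   `eta_noise * sqrt(dt)` to the voltage at every step.
#' @return An object of class `m1_params`.
#' @export
m1_params <- function(V_eq = -76.72, V_th = -39.51, V_r = -41.70,
                      R = 118.50, tau = 11.85, C = 0.098,
                      tau_refractory = 10, eta_noise = 0.5) {
  stopifnot(V_eq < V_th, V_r < V_th, R > 0, tau > 0, tau_refractory >= 0,
            eta_noise >= 0)
  structure(list(V_eq = V_eq, V_th = V_th, V_r = V_r, R = R, tau = tau,
                 C = C, tau_refractory = tau_refractory,
                 eta_noise = eta_noise),
            class = c("m1_params", "msn_params"))
}

#' Parameters of the adaptive quadratic MSN (model M2)
#'
#' Constructs the parameter set of the nonlinear adaptive
#' (Izhikevich-type) MSN model,
#' \deqn{C \frac{dV}{dt} = k (V - V_c)(V - V_{eq}) - U + I(t), \qquad
#'       \frac{dU}{dt} = a\,(b (V - V_{eq}) - U),}
#' with a spike detected at \eqn{V \ge V_{th}}, reset \eqn{V \gets V_r} and
#' adaptation jump \eqn{U \gets U + d}. The quadratic nonlinearity gives the
#' model its characteristic spike latency near rheobase. Dirac synaptic input
#' of weight \eqn{W} (nA) is scaled by `R_scale * C`, i.e. produces an
#' instantaneous voltage jump of `R_scale * W` mV.
#'
#' Units are nA/mV/ms/nF; `k` is in nS/mV so the quadratic current
#' \eqn{k (V - V_c)(V - V_{eq})} is in pA and is converted internally.
#'
#' @param C capacitance (nF).
#' @param k quadratic gain (nS/mV).
#' @param V_c instability threshold parameter (mV).
#' @param V_eq resting potential (mV).
#' @param V_th spike-detection cutoff (mV).
#' @param V_r reset potential (mV).
#' @param a adaptation rate (1/ms).
#' @param b adaptation coupling (nA/mV).
#' @param d adaptation jump at spike (nA).
#' @param R_scale current-scaling resistance for synaptic input (MOhm).
#' @param eta_noise optional additive voltage noise std (mV); the model is
#'   noise-free by default.
#' @return An object of class `m2_params`.
#' @export
m2_params <- function(C = 0.05, k = 1, V_c = -25, V_eq = -80, V_th = -20,
                      V_r = -55, a = 0.01, b = -0.02, d = 0.15,
                      R_scale = 100, eta_noise = 0) {
  stopifnot(C > 0, a > 0, V_eq < V_c, V_c < V_th, R_scale > 0)
  structure(list(C = C, k = k, V_c = V_c, V_eq = V_eq, V_th = V_th,
                 V_r = V_r, a = a, b = b, d = d, R_scale = R_scale,
                 eta_noise = eta_noise),
            class = c("m2_params", "msn_params"))
}

#' @export
print.msn_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  for (nm in names(x)) cat(sprintf("  %-15s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Postsynaptic current kernel
#'
#' Defines the shape of the excitatory postsynaptic current elicited by one
#' presynaptic spike. `"dirac"` produces an instantaneous voltage jump;
#' `"exponential"` and `"alpha"` produce continuous currents
#' \deqn{\varphi(t) = \frac{1}{T_s} e^{-t/T_s} \quad\text{and}\quad
#'       \varphi(t) = \frac{t}{T_s^2} e^{-t/T_s},}
#' both normalised so the integrated current equals 1 for any `T_s`.
#'
#' @param kind one of `"dirac"`, `"exponential"`, `"alpha"`.
#' @param T_s synaptic time constant (ms); unused for `"dirac"`.
#' @return An object of class `synapse_kernel`.
#' @export
synapse_kernel <- function(kind = c("dirac", "exponential", "alpha"),
                           T_s = 10) {
  kind <- match.arg(kind)
  if (kind != "dirac" && (!is.numeric(T_s) || T_s <= 0))
    stop("T_s must be positive for ", kind, " synapses")
  structure(list(kind = kind, T_s = T_s), class = "synapse_kernel")
}

#' Evaluate a postsynaptic current kernel
#'
#' @param kernel a [synapse_kernel()] of kind `"exponential"` or `"alpha"`.
#' @param t time since the presynaptic spike (ms); vectorised. Values of `t`
#'   before the spike return 0.
#' @return Current density (1/ms) at each `t`.
#' @export
psc_kernel <- function(kernel, t) {
  stopifnot(inherits(kernel, "synapse_kernel"))
  if (kernel$kind == "dirac")
    stop("the Dirac kernel has no pointwise density; use a continuous kind")
  Ts <- kernel$T_s
  out <- numeric(length(t))
  pos <- t >= 0
  if (kernel$kind == "exponential") {
    out[pos] <- exp(-t[pos] / Ts) / Ts
  } else {
    out[pos] <- t[pos] * exp(-t[pos] / Ts) / Ts^2
  }
  out
}

#' Closed-form M1 voltage between input events
#'
#' Exact solution of the noise-free M1 membrane equation under a constant
#' current, used as the analytic oracle for the Euler integrator:
#' \deqn{V(\Delta t) = V_{eq} + R I + (V_0 - V_{eq} - R I) e^{-\Delta t/\tau}.}
#'
#' @param p an [m1_params()] object.
#' @param V0 voltage at the start of the interval (mV).
#' @param I_const constant input current (nA).
#' @param dt elapsed time (ms); vectorised.
#' @return Voltage (mV).
#' @export
exact_m1_between_events <- function(p, V0, I_const = 0, dt) {
  stopifnot(inherits(p, "m1_params"))
  Vinf <- p$V_eq + p$R * I_const
  Vinf + (V0 - Vinf) * exp(-dt / p$tau)
}

#' Single Euler step of the M1 membrane equation
#'
#' Reference (pure R) integrator step, primarily used to cross-check the
#' compiled engine. Events arriving in the step are applied at its left edge.
#'
#' @param state list with elements `V` (mV) and `refr_until` (ms).
#' @param p an [m1_params()] object.
#' @param t time at the start of the step (ms).
#' @param dt step size (ms).
#' @param I constant current during the step (nA).
#' @param dirac_w summed Dirac weight arriving in this step (nA); produces a
#'   jump of `R * dirac_w` mV (discarded during the refractory period).
#' @param syn_drive summed weighted kernel current (nA/ms) during the step.
#' @param noise logical; add a Gaussian increment of std `eta_noise*sqrt(dt)`.
#' @return list(state, spiked).
#' @export
step_m1 <- function(state, p, t = 0, dt = 0.1, I = 0, dirac_w = 0,
                    syn_drive = 0, noise = FALSE) {
  V <- state$V
  refr <- if (is.null(state$refr_until)) -Inf else state$refr_until
  spiked <- FALSE
  if (t >= refr) {
    V <- V + p$R * dirac_w
    V <- V + dt * (-(V - p$V_eq) + p$R * I) / p$tau + dt * p$R * syn_drive
    if (noise) V <- V + p$eta_noise * sqrt(dt) * stats::rnorm(1)
    if (V >= p$V_th) {
      spiked <- TRUE
      V <- p$V_r
      refr <- t + p$tau_refractory
    }
  } else {
    V <- p$V_r
  }
  list(state = list(V = V, refr_until = refr), spiked = spiked)
}

#' Single Euler step of the M2 membrane equations
#'
#' Reference (pure R) integrator step for the adaptive quadratic model.
#'
#' @param state list with elements `V` (mV) and `U` (nA).
#' @param p an [m2_params()] object.
#' @param dt step size (ms).
#' @param I constant current during the step (nA).
#' @param dirac_w summed Dirac weight arriving in this step (nA); produces a
#'   jump of `R_scale * dirac_w` mV.
#' @param syn_drive summed weighted kernel current (nA/ms).
#' @param noise logical; optional additive voltage noise.
#' @return list(state, spiked).
#' @export
step_m2 <- function(state, p, dt = 0.1, I = 0, dirac_w = 0, syn_drive = 0,
                    noise = FALSE) {
  V <- state$V + p$R_scale * dirac_w
  U <- state$U
  quad <- 1e-3 * p$k * (V - p$V_c) * (V - p$V_eq)
  dV <- dt * (quad - U + I) / p$C + dt * p$R_scale * syn_drive
  U <- U + dt * p$a * (p$b * (V - p$V_eq) - U)
  V <- V + dV
  if (noise) V <- V + p$eta_noise * sqrt(dt) * stats::rnorm(1)
  spiked <- !is.finite(V) || V >= p$V_th
  if (spiked) {
    V <- p$V_r
    U <- U + p$d
  }
  list(state = list(V = V, U = U), spiked = spiked)
}
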