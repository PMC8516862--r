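#' Phase drift of a theta neuron
#'
#' Right-hand side of the theta-neuron equation
#' \eqn{d\theta/dt = 1 - \cos\theta + I (1 + \cos\theta)} where `total_input`
#' is the summed current-like term \eqn{I = b + S_k + N(t)}. Pure function;
#' vectorised over both arguments.
#'
#' @param theta phase (radians).
#' @param total_input summed applied current, synaptic input and noise.
#' @return Phase derivative (1/ms when time is in ms).
#' @examples
#' theta_drift(pi, 123)  # 2: the input term vanishes at the spike phase
#' @export
theta_drift <- function(theta, total_input) {
  if (any(!is.finite(theta)) || any(!is.finite(total_input)))
    stop("non-finite state in theta_drift(): numerical blow-up ",
         "(time step too large?)")
  ct <- cos(theta)
  1 - ct + total_input * (1 + ct)
}

#' Total synaptic input to one cell
#'
#' Signed weighted sum \eqn{S_k = \sum_j \alpha_j g_{jk} s_{jk}} over all
#' presynaptic synapses onto cell k, with \eqn{\alpha_j = +1} for excitatory
#' presynaptic cells (including the pacemaker) and \eqn{-1} for inhibitory
#' ones.
#'
#' @param s gating values of the presynaptic synapses.
#' @param weights synaptic strengths g_jk (non-negative).
#' @param signs +1 / -1 per presynaptic synapse.
#' @return The summed current-like input (scalar).
#' @export
total_synaptic_input <- function(s, weights, signs) {
  if (length(s) != length(weights) || length(s) != length(signs))
    stop("s, weights and signs must have equal length")
  sum(signs * weights * s)
}

#' One forward-Euler step of the synaptic gating ODE
#'
#' Advances \eqn{ds/dt = -s/\tau_j + e^{-\eta(1+\cos\theta_j)}(1-s)/\tau_R}
#' by `dt`. The activation term is ~1 when the presynaptic phase is at the
#' spike phase \eqn{\pi} and exponentially suppressed elsewhere. For valid
#' step sizes (`dt < tau_R`) the update cannot leave [0, 1]; a result
#' outside that interval is an error (the step is too large), never clamped.
#'
#' @param s gating value(s) in [0, 1].
#' @param theta_pre presynaptic phase (radians).
#' @param tau_decay synaptic decay time (ms).
#' @param tau_R synaptic rise time (ms).
#' @param eta gating activation scale.
#' @param dt step size (ms).
#' @return Updated gating value(s).
#' @export
gating_step <- function(s, theta_pre, tau_decay, tau_R, eta, dt) {
  stopifnot(tau_decay > 0, tau_R > 0, dt > 0)
  act <- exp(-eta * (1 + cos(theta_pre)))
  s_new <- s + dt * (-s / tau_decay + act * (1 - s) / tau_R)
  if (any(s_new < 0 | s_new > 1))
    stop("gating variable left [0,1]: dt too large for tau_R")
  s_new
}

#' Noise EPSP kernel
#'
#' Postsynaptic potential elicited by a background noise spike at `t_n`:
#' \deqn{N(t) = H(t - t_n) \, A g_{max}
#'   \frac{e^{-(t-t_n)/\tau_{exc}} - e^{-(t-t_n)/\tau_R}}
#'        {\tau_{exc} - \tau_R}}
#' (zero before the spike, a difference-of-exponentials afterwards).
#' Contributions of multiple noise spikes sum linearly.
#'
#' @param t evaluation time(s) (ms).
#' @param t_n noise spike time (ms).
#' @param Ag_max kernel scale.
#' @param tau_exc decay time (ms).
#' @param tau_R rise time (ms); must differ from `tau_exc`.
#' @return Kernel value(s).
#' @export
noise_epsp <- function(t, t_n, Ag_max, tau_exc, tau_R) {
  if (tau_exc == tau_R)
    stop("tau_exc == tau_R: noise kernel degenerate")
  d <- t - t_n
  out <- numeric(length(d))
  on <- d >= 0
  out[on] <- Ag_max * (exp(-d[on] / tau_exc) - exp(-d[on] / tau_R)) /
    (tau_exc - tau_R)
  out
}

#' Summed noise input series per cell
#'
#' Evaluates the total background input N(t) of every cell on the
#' simulation time grid by summing [noise_epsp()] kernels over the cell's
#' noise spike train.
#'
#' @param noise_spikes list of per-cell noise spike time vectors (ms).
#' @param time sampling grid (ms).
#' @param Ag_max,tau_exc,tau_R kernel parameters, see [noise_epsp()].
#' @return A `length(time) x length(noise_spikes)` matrix.
#' @export
noise_input_series <- function(noise_spikes, time, Ag_max, tau_exc, tau_R) {
  if (tau_exc == tau_R)
    stop("tau_exc == tau_R: noise kernel degenerate")
  n <- length(time)
  out <- matrix(0, n, length(noise_spikes))
  scale <- Ag_max / (tau_exc - tau_R)
  for (k in seq_along(noise_spikes)) {
    for (t_n in noise_spikes[[k]]) {
      i0 <- findInterval(t_n, time) + 1L  # first sample with time >= t_n
      if (t_n <= time[1]) i0 <- 1L
      if (i0 > n) next
      d <- time[i0:n] - t_n
      out[i0:n, k] <- out[i0:n, k] +
        scale * (exp(-d / tau_exc) - exp(-d / tau_R))
    }
  }
  out
}

#' Pacemaker drive cell: constant current and initial phase
#'
#' The rhythmic drive is a single pacemaker theta neuron under the constant
#' suprathreshold current \eqn{I_p = (\pi f / 1000)^2}, whose closed-form
#' inter-spike period \eqn{\pi/\sqrt{I_p}} equals the click-train interval
#' 1000/f ms. `pacemaker_phase0()` returns the initial phase for which the
#' first spike (phase crossing of \eqn{\pi}) occurs at `t0`, using the exact
#' solution \eqn{\tan(\theta/2) = \sqrt{I}\tan(\sqrt{I}t + c)}.
#'
#' @param freq drive frequency (Hz).
#' @param t0 time of the first drive spike (ms), within one period.
#' @return Current (dimensionless) / initial phase in `[0, 2*pi)`.
#' @export
pacemaker_current <- function(freq) {
  stopifnot(freq > 0)
  (pi * freq / 1000)^2
}

#' @rdname pacemaker_current
#' @export
pacemaker_phase0 <- function(freq, t0 = 0) {
  if (t0 == 0) return(pi)
  sq <- sqrt(pacemaker_current(freq))
  u0 <- sq * tan(pi / 2 - sq * t0)
  (2 * atan(u0)) %% (2 * pi)
}

#' Resting phase of a theta neuron
#'
#' Stable fixed point of the theta equation under constant subthreshold
#' input `b < 0`: \eqn{\theta^* = -\arccos((1+b)/(1-b))} (wrapped to
#' `[0, 2*pi)`). For suprathreshold input (`b >= 0`, no fixed point) the
#' convention is 0.
#'
#' @param b applied current.
#' @return Phase in `[0, 2*pi)`; vectorised over `b`.
#' @export
rest_phase <- function(b) {
  ifelse(b < 0, 2 * pi - acos((1 + b) / (1 - b)), 0)
}
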