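#' Simulate one trial of the driven microcircuit
#'
#' Advances all cell phases and all synaptic gating variables jointly with a
#' fixed-step forward Euler scheme at `dt = duration / n_steps`. The
#' pacemaker drive enters every cell as an excitatory synapse of strength
#' `I_factor * g_de` (E cells) or `I_factor * g_di` (I cells); background
#' noise enters as the precomputed summed EPSP series of the stimulus
#' program. All gating variables start at 0. Initial phases default to each
#' cell's resting phase ([rest_phase()] of its applied current), so every
#' trial starts from the same quiescent state and trial-to-trial
#' variability comes from the background noise alone; `init = "random"`
#' instead draws phases uniformly from `[0, 2*pi)` under the trial seed.
#' Deterministic given (network, stimulus, seed, init).
#'
#' @param network an [build_network()] object.
#' @param stimulus an [make_stimulus()] program.
#' @param params an [model_parameters()] object (integration settings).
#' @param seed integer seed for the initial phases (used only when
#'   `init = "random"`).
#' @param engine `"cpp"` (compiled, default) or `"r"` (plain-R reference
#'   integrator, used for cross-checking).
#' @param init `"rest"` (default) starts every cell at its resting phase;
#'   `"random"` draws initial phases uniformly per trial.
#' @param theta0 optional explicit initial phases of the network cells
#'   (length `n_cells`), overriding `init`.
#' @return An object of class `assr_trial`: `time` (ms grid), `theta_trace`
#'   (`n_steps x (n_cells + 1)`, pacemaker last), `s_trace`
#'   (`n_steps x groups`), `meg` (simulated MEG series), `spikes` (per-cell
#'   spike times), `dt`, `seed_used`.
#' @export
simulate_trial <- function(network, stimulus, params = network$params,
                           seed = 1L, engine = c("cpp", "r"),
                           init = c("rest", "random"), theta0 = NULL) {
  engine <- match.arg(engine)
  init <- match.arg(init)
  stopifnot(inherits(network, "assr_network"),
            inherits(stimulus, "assr_stimulus"))
  n <- network$n_cells
  n_steps <- params$n_steps
  dt <- params$duration / n_steps
  time <- (seq_len(n_steps) - 1) * dt

  noise <- noise_input_series(stimulus$noise_spike_times, time,
                              params$Ag_max, params$tau_exc, params$tau_R)
  if (ncol(noise) != n) stop("stimulus/network cell count mismatch")

  if (is.null(theta0)) {
    if (init == "random") {
      set.seed(mix_seed(seed, 999983))
      theta0 <- runif(n, 0, 2 * pi)
    } else {
      theta0 <- rest_phase(network$b_per_cell)
    }
  }
  stopifnot(length(theta0) == n)
  th0 <- c(theta0, pacemaker_phase0(stimulus$drive_freq, stimulus$t0))
  b_pace <- pacemaker_current(stimulus$drive_freq)

  res <- if (engine == "cpp") {
    sim_theta_core(network$W, network$pre, network$tau_decay,
                   params$tau_R, params$eta, network$b_per_cell, b_pace,
                   noise, th0, dt, n_steps)
  } else {
    sim_theta_core_r(network$W, network$pre, network$tau_decay,
                     params$tau_R, params$eta, network$b_per_cell, b_pace,
                     noise, th0, dt, n_steps)
  }

  trial <- structure(list(
    time = time,
    theta_trace = res$theta,
    s_trace = res$s,
    meg = NULL,
    spikes = NULL,
    dt = dt,
    seed_used = seed,
    drive_freq = stimulus$drive_freq
  ), class = "assr_trial")
  trial$meg <- compute_meg(trial, network)
  trial$spikes <- detect_spikes(res$theta[, seq_len(n), drop = FALSE], time)
  trial
}

# Plain-R reference integrator, formula-for-formula identical to the
# compiled core; kept for oracle comparisons in the test suite.
sim_theta_core_r <- function(W, pre, tau_d, tau_R, eta, b, b_pace,
                             noise, theta0, dt, n_steps) {
  G <- nrow(W); n <- ncol(W)
  theta <- theta0
  s <- numeric(G)
  th_tr <- matrix(0, n_steps, n + 1)
  s_tr <- matrix(0, n_steps, G)
  for (i in seq_len(n_steps)) {
    th_tr[i, ] <- theta
    s_tr[i, ] <- s
    cth <- cos(theta)
    S <- drop(crossprod(W, s))
    act <- exp(-eta * (1 + cth[pre]))
    s_new <- s + dt * (-s / tau_d + act * (1 - s) / tau_R)
    if (any(s_new < -1e-12 | s_new > 1 + 1e-12))
      stop("gating variable left [0,1] at step ", i, " (dt too large)")
    inp <- c(b + S + noise[i, ], b_pace)
    theta_new <- theta + dt * (1 - cth + inp * (1 + cth))
    if (any(!is.finite(theta_new)))
      stop("non-finite phase at step ", i, " (numerical blow-up)")
    theta <- theta_new %% (2 * pi)
    s <- s_new
  }
  list(theta = th_tr, s = s_tr)
}

#' Detect spikes as upward phase crossings of pi
#'
#' A theta neuron spikes when its phase crosses \eqn{\pi} from below. Spike
#' times are linearly interpolated between the samples bracketing each
#' crossing; crossings of the 2*pi wrap do not count.
#'
#' @param theta_trace phase matrix (`n_steps x n_cells`) or vector, wrapped
#'   to `[0, 2*pi)`.
#' @param time sampling grid (ms), same length as the trace.
#' @return A list of increasing per-cell spike time vectors (a single
#'   vector input yields a one-element list).
#' @export
detect_spikes <- function(theta_trace, time) {
  if (is.null(dim(theta_trace)))
    theta_trace <- matrix(theta_trace, ncol = 1)
  n <- nrow(theta_trace)
  stopifnot(length(time) == n)
  lapply(seq_len(ncol(theta_trace)), function(k) {
    th <- theta_trace[, k]
    prev <- th[-n]; cur <- th[-1]
    idx <- which(prev < pi & cur >= pi)
    if (!length(idx)) return(numeric(0))
    frac <- (pi - prev[idx]) / (cur[idx] - prev[idx])
    time[idx] + frac * (time[idx + 1] - time[idx])
  })
}
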