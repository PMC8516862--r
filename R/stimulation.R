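#' Periodic click-train drive times
#'
#' Spike times of the rhythmic ASSR drive: `t0, t0 + T, t0 + 2T, ...` with
#' inter-click interval `T = 1000/freq` ms, strictly below `duration`. A
#' 40 Hz train over 500 ms has 20 clicks spaced 25 ms apart.
#'
#' @param freq drive frequency (Hz), > 0.
#' @param duration trial length (ms), > 0.
#' @param t0 onset of the first click (ms), default 0.
#' @return Vector of click times (ms).
#' @examples
#' make_click_train(40, 500)  # 20 clicks, 25 ms apart
#' @export
make_click_train <- function(freq, duration, t0 = 0) {
  stopifnot(freq > 0, duration > 0, t0 >= 0)
  times <- seq(t0, duration, by = 1000 / freq)
  times[times < duration - 1e-9]
}

#' Homogeneous Poisson background spike trains
#'
#' Independent homogeneous Poisson processes per cell, generated from
#' exponential inter-event intervals. Each cell's train is drawn under its
#' own seed `mix_seed(seed, cell)`, so any single train is reproducible in
#' isolation.
#'
#' @param rate event rate (spikes/ms); 0 yields empty trains.
#' @param duration trial length (ms).
#' @param n_cells number of cells.
#' @param seed integer seed of this trial's noise.
#' @return List of `n_cells` increasing spike-time vectors in `[0, duration)`.
#' @export
make_poisson_noise <- function(rate, duration, n_cells, seed) {
  if (rate < 0) stop("noise rate must be non-negative")
  out <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    out[[k]] <- numeric(0)
    if (rate == 0) next
    set.seed(mix_seed(seed, k))
    chunk <- max(16L, ceiling(rate * duration + 6 * sqrt(rate * duration + 1)))
    times <- cumsum(rexp(chunk, rate))
    while (times[length(times)] < duration)
      times <- c(times, times[length(times)] + cumsum(rexp(chunk, rate)))
    out[[k]] <- times[times < duration]
  }
  out
}

#' Stimulus program for one trial
#'
#' Bundles the deterministic click-train drive with one realisation of the
#' per-cell Poisson background for a single simulation trial. Noise is given
#' to the network cells only, not to the pacemaker.
#'
#' @param drive_freq drive frequency (Hz).
#' @param params an [model_parameters()] object.
#' @param seed trial seed governing the noise realisation.
#' @param t0 drive onset (ms).
#' @return An object of class `assr_stimulus`.
#' @export
make_stimulus <- function(drive_freq, params, seed, t0 = 0) {
  n_cells <- params$n_E + params$n_I
  structure(list(
    drive_freq = drive_freq,
    t0 = t0,
    drive_spike_times = make_click_train(drive_freq, params$duration, t0),
    noise_spike_times = make_poisson_noise(params$noise_rate,
                                           params$duration, n_cells, seed),
    duration = params$duration,
    seed = seed
  ), class = "assr_stimulus")
}

#' Write a stimulus program as a plain-text event list
#'
#' One `cell time_ms` row per event; cell 0 is the drive, cells 1..n the
#' network cells' noise trains. For inspection and external tooling.
#'
#' @param stimulus an `assr_stimulus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_events <- function(stimulus, path) {
  rows <- c(
    sprintf("0 %.6f", stimulus$drive_spike_times),
    unlist(lapply(seq_along(stimulus$noise_spike_times), function(k) {
      sprintf("%d %.6f", k, stimulus$noise_spike_times[[k]])
    }))
  )
  writeLines(c("# cell time_ms (cell 0 = drive)", rows), path)
  invisible(path)
}
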