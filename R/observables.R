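#' Simulated MEG signal of one trial
#'
#' The simulated MEG is the sum of all excitatory synaptic gating variables
#' whose postsynaptic cell is a pyramidal cell: the E-to-E recurrent
#' synapses plus (by default) the pacemaker drive synapses onto E cells.
#' Because synapses sharing a presynaptic cell and decay time carry
#' identical gating values, the sum is the gating trace weighted by each
#' group's count of excitatory synapses onto pyramidal cells (stored in the
#' network as `meg_mult`). Noise enters the cells as a current, not a gating
#' variable, and is excluded.
#'
#' @param trial an [simulate_trial()] recording.
#' @param network the network the trial was simulated on.
#' @return Numeric time series, one value per sample.
#' @export
compute_meg <- function(trial, network) {
  stopifnot(ncol(trial$s_trace) == length(network$meg_mult))
  drop(trial$s_trace %*% network$meg_mult)
}

#' Average simulated MEG signals across trials in time
#'
#' Pointwise arithmetic mean of equal-length series. All spectral analyses
#' operate on this time-domain average (average before Fourier transform),
#' so components whose phase flips between trials cancel.
#'
#' @param megs list of equal-length numeric series.
#' @return The mean series.
#' @export
average_trials <- function(megs) {
  stopifnot(length(megs) >= 1)
  len <- lengths(megs)
  if (length(unique(len)) != 1) stop("trial series differ in length")
  rowMeans(do.call(cbind, megs))
}

#' Power spectrum and band powers of a simulated MEG signal
#'
#' Magnitude-squared discrete Fourier transform over the one-sided real
#' spectrum, with no window or detrending (the target frequencies fall on
#' exact bins for the default 500 ms trial, where the resolution is 2 Hz).
#' The normalisation is `|FFT/n|^2`: an on-bin sinusoid of amplitude `a`
#' yields band power `a^2/4` regardless of the sampling resolution, so band
#' powers are invariant under time-step refinement. All comparisons in this
#' package are relative between conditions.
#'
#' @param series uniformly sampled time series.
#' @param dt sampling interval (ms).
#' @param n_trials_averaged bookkeeping: trials averaged into `series`.
#' @return An object of class `assr_power`: `freqs` (Hz), `psd`, `p20` and
#'   `p40` (power at the exact 20 / 40 Hz bins), `n_trials_averaged`.
#' @export
power_spectrum <- function(series, dt, n_trials_averaged = 1L) {
  n <- length(series)
  ft <- stats::fft(series)
  n_half <- floor(n / 2) + 1L
  psd <- (Mod(ft / n)^2)[seq_len(n_half)]
  df <- 1000 / (n * dt)
  freqs <- (seq_len(n_half) - 1) * df
  structure(list(
    freqs = freqs, psd = psd,
    p20 = power_at(freqs, psd, 20),
    p40 = power_at(freqs, psd, 40),
    n_trials_averaged = as.integer(n_trials_averaged)
  ), class = "assr_power")
}

power_at <- function(freqs, psd, f) {
  i <- which.min(abs(freqs - f))
  if (abs(freqs[i] - f) > 1e-6)
    warning(sprintf("%g Hz is not an exact bin (nearest %.4g Hz)",
                    f, freqs[i]))
  psd[i]
}

#' @export
print.assr_power <- function(x, ...) {
  cat(sprintf("power spectrum: %d bins, df=%.3g Hz, p40=%.4g, p20=%.4g (%d trials)\n",
              length(x$freqs), x$freqs[2] - x$freqs[1], x$p40, x$p20,
              x$n_trials_averaged))
  invisible(x)
}

#' Beat-skipping index of the pyramidal population response
#'
#' Quantifies the alternating-cycle ("beat-skipping") firing regime in which
#' the pyramidal population responds strongly only to every other drive
#' cycle. Drive cycles after an onset window are classified into the two
#' alternating parities; the index is `1 - low/high`, where `high` and `low`
#' are the mean spike counts per cycle of the stronger and weaker parity.
#' It is ~0 when every cycle receives the same response and approaches 1
#' under perfect alternation.
#'
#' @param spikes pyramidal spike times pooled over cells (vector, or a list
#'   of per-cell vectors).
#' @param drive an `assr_stimulus` (its click times define the cycles).
#' @param onset_skip initial window excluded from analysis (ms).
#' @return Index in [0, 1], or `NA` when no spikes fall in the analysis
#'   window (undefined, not zero).
#' @export
beat_skipping_index <- function(spikes, drive, onset_skip = 100) {
  if (is.list(spikes)) spikes <- sort(unlist(spikes))
  edges <- drive$drive_spike_times
  keep_cycle <- edges >= onset_skip
  if (sum(keep_cycle) < 2) stop("need at least two drive cycles to analyse")
  spikes <- spikes[spikes >= min(edges[keep_cycle])]
  if (!length(spikes)) return(NA_real_)
  cyc <- findInterval(spikes, edges)
  cyc_ids <- which(keep_cycle)
  counts <- vapply(cyc_ids, function(i) sum(cyc == i), numeric(1))
  parity <- cyc_ids %% 2
  m0 <- mean(counts[parity == 0]); m1 <- mean(counts[parity == 1])
  hi <- max(m0, m1); lo <- min(m0, m1)
  if (hi == 0) return(NA_real_)
  1 - lo / hi
}
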