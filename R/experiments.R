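#' Simulate one experimental condition (trials, average, spectrum)
#'
#' Runs `n_trials` trials of one (variant, drive frequency, input strength,
#' alteration levels) condition, each with its own noise realisation and
#' initial phases under a per-trial seed derived from the condition seed,
#' averages the simulated MEG signals in time, and computes the power
#' spectrum of the average. The beat-skipping index is computed per trial
#' from the pooled pyramidal spikes and averaged over trials (missing
#' values dropped), since the skipped parity can differ between trials.
#'
#' @param variant one of `VARIANTS`.
#' @param drive_freq drive frequency (Hz).
#' @param I_factor input-strength multiplier.
#' @param params an [model_parameters()] object.
#' @param base_seed base seed of the experiment; the condition seed is
#'   derived from it and the condition's content via [condition_seed()].
#' @param gGABA_level,bInh_level alteration levels (see
#'   [build_network()]).
#' @param n_trials trials to run (default `params$n_trials`).
#' @param keep_spectrum attach the full `assr_power` object as a list column.
#' @param ... further arguments passed to [build_network()].
#' @return A one-row [tibble::tibble()] with columns `variant`, `drive_freq`,
#'   `I_factor`, `gGABA_level`, `bInh_level`, `p40`, `p20`, `beat_index`,
#'   `n_trials`, `base_seed` (plus `spectrum` if requested).
#' @export
run_condition <- function(variant, drive_freq, I_factor,
                          params = model_parameters(), base_seed = 1L,
                          gGABA_level = 1, bInh_level = 0,
                          n_trials = params$n_trials,
                          keep_spectrum = FALSE, ...) {
  net <- build_network(variant, params, gGABA_level = gGABA_level,
                       bInh_level = bInh_level, ...)
  net <- scale_input(net, I_factor)
  cseed <- condition_seed(base_seed, variant, drive_freq, I_factor,
                          gGABA_level, bInh_level)
  megs <- vector("list", n_trials)
  beat <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    tseed <- trial_seed(cseed, tr)
    stim <- make_stimulus(drive_freq, params, tseed)
    trial <- tryCatch(
      simulate_trial(net, stim, params, seed = tseed),
      error = function(e) stop(sprintf(
        "condition %s f=%g I=%g gGABA=%g bInh=%g trial %d: %s",
        variant, drive_freq, I_factor, gGABA_level, bInh_level,
        tr, conditionMessage(e)), call. = FALSE))
    megs[[tr]] <- trial$meg
    beat[tr] <- beat_skipping_index(trial$spikes[seq_len(net$n_E)], stim)
  }
  avg <- average_trials(megs)
  ps <- power_spectrum(avg, params$duration / params$n_steps,
                       n_trials_averaged = n_trials)
  out <- tibble::tibble(
    variant = variant, drive_freq = drive_freq, I_factor = I_factor,
    gGABA_level = gGABA_level, bInh_level = bInh_level,
    p40 = ps$p40, p20 = ps$p20,
    beat_index = mean(beat, na.rm = TRUE),
    n_trials = as.integer(n_trials), base_seed = base_seed)
  if (keep_spectrum) out$spectrum <- list(ps)
  out
}

#' Replication experiment: control and IPSC variants at 20/30/40 Hz drive
#'
#' Simulates the control and prolonged-IPSC networks under click-train
#' drive at each of 20, 30 and 40 Hz at default input strength, emitting
#' one row per condition with the full spectrum attached.
#'
#' @param params an [model_parameters()] object.
#' @param base_seed base seed.
#' @param drive_freqs drive frequencies (Hz).
#' @param variants variants to include.
#' @return A `SweepResult` tibble (with `spectrum` list column).
#' @export
run_replication <- function(params = model_parameters(), base_seed = 1L,
                            drive_freqs = c(20, 30, 40),
                            variants = c("control", "IPSC")) {
  grid <- expand.grid(variant = variants, drive_freq = drive_freqs,
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    run_condition(grid$variant[i], grid$drive_freq[i], I_factor = 1,
                  params = params, base_seed = base_seed,
                  keep_spectrum = TRUE)))
}

#' Input-strength sweep of one variant
#'
#' Simulates one network variant under fixed-frequency drive while scaling
#' the drive strength over a grid of factors (default 0.1 to 1.5 in steps
#' of 0.1, as a multiple of the default drive weights).
#'
#' @param variant one of `VARIANTS`.
#' @param drive_freq drive frequency (Hz).
#' @param factors input-strength factors (positive, non-empty).
#' @param params an [model_parameters()] object.
#' @param base_seed base seed.
#' @param gGABA_level,bInh_level alteration levels.
#' @param ... passed to [run_condition()].
#' @return A `SweepResult` tibble, one row per factor.
#' @export
run_input_sweep <- function(variant, drive_freq = 40,
                            factors = seq(0.1, 1.5, by = 0.1),
                            params = model_parameters(), base_seed = 1L,
                            gGABA_level = 1, bInh_level = 0, ...) {
  stopifnot(length(factors) >= 1, all(factors > 0))
  do.call(rbind, lapply(factors, function(f)
    run_condition(variant, drive_freq, f, params = params,
                  base_seed = base_seed, gGABA_level = gGABA_level,
                  bInh_level = bInh_level, ...)))
}

#' Combined-alteration sweep (alteration grid x input strength)
#'
#' Crosses the alteration grid of a combined model family (see
#' [alteration_grid()]) with the input-strength factors at the given drive
#' frequency (40 Hz for the gamma-drive experiments, 20 Hz for the
#' beta-drive experiment).
#'
#' @param variant_family `"IPSC+gGABA"`, `"IPSC+bInh"` or `"Full"`.
#' @param drive_freq drive frequency (Hz).
#' @param params an [model_parameters()] object.
#' @param base_seed base seed.
#' @param grid alteration settings (default the family's published grid).
#' @param factors input-strength factors.
#' @param ... passed to [run_condition()].
#' @return A `SweepResult` tibble, one row per (level, factor).
#' @export
run_combination_sweep <- function(variant_family, drive_freq = 40,
                                  params = model_parameters(),
                                  base_seed = 1L,
                                  grid = alteration_grid(variant_family),
                                  factors = seq(0.1, 1.5, by = 0.1), ...) {
  stopifnot(variant_family %in% c("IPSC+gGABA", "IPSC+bInh", "Full"))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    run_input_sweep(variant_family, drive_freq, factors, params,
                    base_seed,
                    gGABA_level = grid$gGABA_level[i],
                    bInh_level = grid$bInh_level[i], ...)))
}

#' Emergence window of the 20 Hz component over an input sweep
#'
#' Operationalises a "substantial" 20 Hz component: a factor has one when
#' its 20 Hz power exceeds a threshold, by default the midpoint between the
#' sweep's minimum and maximum 20 Hz power (a declared convention; pass
#' `threshold` to override, e.g. with a pooled threshold across a
#' combination family). The window is reported as the first factor above
#' threshold (`lower`) and the first factor after the 20 Hz maximum that
#' has fallen back below it (`upper`).
#'
#' @param sweep a `SweepResult` tibble for a single condition series,
#'   ordered or orderable by `I_factor`.
#' @param threshold emergence threshold on `p20`; default the sweep's
#'   min/max midpoint.
#' @return A list with `lower`, `upper` (factors, `NA` if absent),
#'   `threshold`, `n_above` (count of factors above threshold), and
#'   `peak_factor` (factor of maximal p20).
#' @export
beta_window <- function(sweep, threshold = NULL) {
  sweep <- sweep[order(sweep$I_factor), ]
  p20 <- sweep$p20
  f <- sweep$I_factor
  if (is.null(threshold)) threshold <- (min(p20) + max(p20)) / 2
  above <- p20 > threshold
  lower <- if (any(above)) f[which(above)[1]] else NA_real_
  imax <- which.max(p20)
  after <- which(!above & seq_along(f) > imax)
  upper <- if (any(above) && length(after)) f[after[1]] else NA_real_
  list(lower = lower, upper = upper, threshold = threshold,
       n_above = sum(above), peak_factor = f[imax])
}

#' Beta-window edges by majority vote over base seeds
#'
#' Repeats the input sweep of [beta_window()] under several base seeds and
#' returns the modal lower and upper window edge (ties broken by the
#' median), reflecting that single sweeps are stochastic through the
#' background noise.
#'
#' @param variant,drive_freq,factors,params see [run_input_sweep()].
#' @param base_seeds integer vector of base seeds.
#' @param ... passed to [run_input_sweep()].
#' @return A list with `lower`, `upper` (modal edges), and `per_seed` (a
#'   tibble of the per-seed edges).
#' @export
beta_window_majority <- function(variant = "IPSC", drive_freq = 40,
                                 factors = seq(0.1, 1.5, by = 0.1),
                                 params = model_parameters(),
                                 base_seeds = 1:5, ...) {
  per_seed <- do.call(rbind, lapply(base_seeds, function(s) {
    sweep <- run_input_sweep(variant, drive_freq, factors, params,
                             base_seed = s, ...)
    w <- beta_window(sweep)
    tibble::tibble(base_seed = s, lower = w$lower, upper = w$upper,
                   n_above = w$n_above, peak_factor = w$peak_factor)
  }))
  list(lower = modal_value(per_seed$lower),
       upper = modal_value(per_seed$upper),
       per_seed = per_seed)
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  if (length(modes) == 1) modes else median(x)
}
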