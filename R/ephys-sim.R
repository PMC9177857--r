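#' Parameters of the synthetic spiking population
#'
#' Units belong to four archetypes observed in olfactory tubercle and
#' anterior piriform recordings: `transient` units excited during the odor
#' (0-1 s), `ramping` units whose rate climbs through the waiting period
#' (1-2.5 s) in proportion to cue value, `inhibited` units suppressed
#' throughout the task window, and `sustained` units elevated from odor
#' through wait. Excited archetypes respond at the US on rewarded trials
#' with an amplitude decreasing in cue value, so the unexpected CS50 reward
#' evokes a larger jump than the fully predicted CS100 reward (reward
#' surprise); inhibited units show the inverted pattern. When `history` is
#' on, ramping units carry an additive wait-window modulation by the
#' previous CS50 outcome on CS50 trials.
#'
#' @param mix Named archetype proportions (must sum to 1).
#' @param baseline_rate Mean baseline rate, Hz (unit-wise jittered +/-30%).
#' @param transient_amp Peak added rate at CS for transient units, Hz.
#' @param dominant_fraction Fraction of transient units that are single-CS
#'   dominant rather than monotonically value-tuned.
#' @param dominant_probs Sampling probabilities of the preferred CS for
#'   dominant units; the default recruits more units for higher-value cues
#'   so that the dominant subpopulation is monotonic in aggregate.
#' @param ramp_amp Added rate at end of wait per unit cue value, Hz.
#' @param sustained_amp Added rate for sustained units, Hz.
#' @param history Logical; enable the outcome-history modulation.
#' @param history_amp Additive wait-window rate modulation (Hz) on CS50
#'   trials of ramping units, signed by the previous CS50 outcome.
#' @param us_amp Scale (Hz) of the rewarded-US response of excited units;
#'   realized amplitude is `us_amp * (1.2 - value)`.
#' @param inhibited_factor Multiplicative rate factor of inhibited units
#'   during the task window.
#' @param window Raster window, s relative to odor onset.
#' @return A `population_params` list.
#' @export
population_params <- function(mix = c(transient = 0.4, ramping = 0.3,
                                      inhibited = 0.2, sustained = 0.1),
                              baseline_rate = 3, transient_amp = 8,
                              dominant_fraction = 0.5,
                              dominant_probs = c(CS100 = 0.5, CS50 = 0.3,
                                                 CS0 = 0.2),
                              ramp_amp = 8, sustained_amp = 5,
                              history = TRUE, history_amp = 1.5,
                              us_amp = 8, inhibited_factor = 0.3,
                              window = c(-3, 6)) {
  stopifnot(abs(sum(mix) - 1) < 1e-9, all(mix >= 0),
            baseline_rate >= 0, inhibited_factor >= 0)
  structure(list(mix = mix, baseline_rate = baseline_rate,
                 transient_amp = transient_amp,
                 dominant_fraction = dominant_fraction,
                 dominant_probs = dominant_probs, ramp_amp = ramp_amp,
                 sustained_amp = sustained_amp, history = history,
                 history_amp = history_amp, us_amp = us_amp,
                 inhibited_factor = inhibited_factor, window = window),
            class = "population_params")
}

# Stationary cue values used to scale synthetic responses.
cs_value <- c(CS100 = 1, CS50 = 0.5, CS0 = 0)

# Quota allocation: integer counts proportional to probs summing to n,
# largest-remainder rule.
quota_counts <- function(n, probs) {
  raw <- n * probs / sum(probs)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1L
  }
  k
}

#' Simulate a population of task-responsive units
#'
#' Draws inhomogeneous-Poisson spike trains for `n_units` units over the
#' trials of `seq`, with piecewise-constant within-trial rate profiles per
#' archetype (see [population_params()]). Spike times are stored relative
#' to odor onset of each trial.
#'
#' @param seq Trial sequence.
#' @param n_units Number of units.
#' @param params A [population_params()].
#' @param region Region label attached to every unit (`"Tu"` or `"aPC"`).
#' @param seed Optional seed.
#' @return A `unit_raster_set`: list with `units` (each a list `id`,
#'   `archetype`, `tuning`, `pref_cs`, `spikes` data frame `trial`,
#'   `time`), `seq`, `window`, `region`.
#' @export
simulate_population <- function(seq, n_units = 60,
                                params = population_params(),
                                region = "Tu", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n_arch <- round(p$mix * n_units)
  while (sum(n_arch) < n_units) n_arch[1] <- n_arch[1] + 1L
  while (sum(n_arch) > n_units) n_arch[which.max(n_arch)] <-
      n_arch[which.max(n_arch)] - 1L
  archetypes <- rep(names(p$mix), n_arch)

  # Previous-CS50-outcome sign per trial (+1/-1 on CS50 trials, 0 else).
  hist_sign <- numeric(nrow(seq))
  i50 <- which(seq$cs == "CS50")
  if (length(i50) >= 2L)
    hist_sign[i50[-1L]] <- ifelse(seq$rewarded[i50][-length(i50)], 1, -1)

  # Transient tuning assigned by quota so that the prevalence of dominant
  # units per preferred cue follows dominant_probs deterministically (the
  # fraction, like the cue proportions of the task, is a design property,
  # not a per-unit coin flip).
  tr_idx <- which(archetypes == "transient")
  tunings <- rep("none", n_units)
  prefs <- rep(NA_character_, n_units)
  if (length(tr_idx)) {
    n_dom <- round(p$dominant_fraction * length(tr_idx))
    counts <- quota_counts(n_dom, p$dominant_probs)
    lab <- c(rep(names(p$dominant_probs), counts),
             rep(NA_character_, length(tr_idx) - n_dom))
    lab <- sample(lab)
    tunings[tr_idx] <- ifelse(is.na(lab), "monotonic", "dominant")
    prefs[tr_idx] <- lab
  }

  units <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    arch <- archetypes[u]
    b <- p$baseline_rate * stats::runif(1, 0.7, 1.3)
    tuning <- tunings[u]; pref <- prefs[u]
    spikes <- vector("list", nrow(seq))
    for (i in seq_len(nrow(seq))) {
      v <- cs_value[[seq$cs[i]]]
      segs <- unit_rate_segments(arch, tuning, pref, b, v, seq$cs[i],
                                 seq$rewarded[i], hist_sign[i], p)
      spikes[[i]] <- draw_poisson_segments(segs, trial = i)
    }
    units[[u]] <- list(id = sprintf("u%03d", u), archetype = arch,
                       tuning = tuning, pref_cs = pref, baseline = b,
                       spikes = do.call(rbind, spikes))
  }
  structure(list(units = units, seq = seq, window = p$window,
                 region = region),
            class = "unit_raster_set")
}

# Piecewise-constant rate profile of one unit on one trial. Returns a
# matrix with columns t0, t1, rate (Hz, relative time).
unit_rate_segments <- function(arch, tuning, pref, b, v, cs, rewarded,
                               hist_sign, p) {
  w <- p$window
  add <- NULL
  if (arch == "transient") {
    amp <- if (tuning == "dominant") {
      p$transient_amp * (if (cs == pref) 1 else 0.1)
    } else p$transient_amp * (0.2 + 0.8 * v)
    add <- rbind(add, c(0, 1, amp))
  } else if (arch == "ramping") {
    peak <- p$ramp_amp * v
    if (p$history && cs == "CS50") peak <- peak + p$history_amp * hist_sign
    peak <- max(peak, 0)
    # linear climb approximated by four steps over the wait
    br <- seq(1, 2.5, length.out = 5L)
    frac <- (br[-1] + br[-5]) / 2 - 1
    frac <- frac / 1.5
    add <- rbind(add, cbind(br[-5], br[-1], peak * frac),
                 c(2.5, 2.7, peak))
  } else if (arch == "sustained") {
    add <- rbind(add, c(0, 2.5, p$sustained_amp * (0.2 + 0.8 * v)))
  } else if (arch == "inhibited") {
    add <- rbind(add, c(0, 2.7, -b * (1 - p$inhibited_factor)))
  }
  if (rewarded) {
    if (arch == "inhibited") {
      add <- rbind(add, c(2.7, 3.7,
                          -b * (1 - p$inhibited_factor) - 0.8 * (1.2 - v)))
    } else {
      add <- rbind(add, c(2.7, 3.7, p$us_amp * (1.2 - v)))
    }
  }
  segs <- rbind(c(w[1], w[2], b))
  if (!is.null(add)) segs <- rbind(segs, add)
  segs
}

# Sample an inhomogeneous Poisson train from additive piecewise-constant
# rate segments; the first segment is the base, later rows add to it.
draw_poisson_segments <- function(segs, trial) {
  base <- segs[1, , drop = FALSE]
  cuts <- sort(unique(c(segs[, 1], segs[, 2])))
  times <- numeric(0)
  for (k in seq_len(length(cuts) - 1L)) {
    t0 <- cuts[k]; t1 <- cuts[k + 1L]
    rate <- sum(segs[segs[, 1] <= t0 + 1e-12 & segs[, 2] >= t1 - 1e-12, 3])
    rate <- max(rate, 0)
    if (rate <= 0) next
    n <- stats::rpois(1L, rate * (t1 - t0))
    if (n > 0) times <- c(times, stats::runif(n, t0, t1))
  }
  if (!length(times))
    return(data.frame(trial = integer(0), time = numeric(0)))
  data.frame(trial = trial, time = sort(times))
}

#' Simulate multichannel extracellular voltage
#'
#' Gaussian noise at 30 kHz with biphasic spike templates inserted at the
#' given times, optionally with a common-mode artifact added to every
#' channel. Spike amplitude is expressed in multiples of the raw median
#' absolute deviation of the noise.
#'
#' @param spike_times Numeric vector of spike times (s), or a list of such
#'   vectors, one per channel. A single vector is placed on channel 1.
#' @param n_channels Number of channels.
#' @param duration Trace duration, s.
#' @param fs Sample rate, Hz.
#' @param noise_sd Noise standard deviation (arbitrary units).
#' @param amp_mad Spike peak amplitude in multiples of the noise MAD.
#' @param common_mode Optional numeric vector (length = samples) added to
#'   all channels.
#' @param seed Optional seed.
#' @return List with `samples` (channels x samples matrix), `fs`,
#'   `spike_times` (as inserted), `template`.
#' @export
simulate_voltage <- function(spike_times, n_channels = 4, duration = 10,
                             fs = 30000, noise_sd = 1, amp_mad = 10,
                             common_mode = NULL, seed = NULL) {
  stopifnot(amp_mad > 0, n_channels >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  x <- matrix(stats::rnorm(n_channels * n, 0, noise_sd),
              nrow = n_channels)
  if (!is.list(spike_times)) {
    spike_times <- c(list(spike_times),
                     rep(list(numeric(0)), n_channels - 1L))
  }
  stopifnot(length(spike_times) == n_channels)
  i <- 0:31
  template <- -exp(-((i - 10) / 2.5)^2) + 0.45 * exp(-((i - 17) / 4)^2)
  template <- template / max(abs(template))
  amp <- amp_mad * 0.6745 * noise_sd
  for (ch in seq_len(n_channels)) {
    for (st in spike_times[[ch]]) {
      pk <- round(st * fs) + 1L
      idx <- pk - 10L + i
      keep <- idx >= 1L & idx <= n
      x[ch, idx[keep]] <- x[ch, idx[keep]] + amp * template[keep]
    }
  }
  if (!is.null(common_mode)) {
    stopifnot(length(common_mode) == n)
    x <- sweep(x, 2, common_mode, "+")
  }
  list(samples = x, fs = fs, spike_times = spike_times,
       template = template)
}
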