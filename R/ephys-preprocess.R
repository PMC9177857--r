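#' Common-mode removal by channel-wise median subtraction
#'
#' At every time sample the median across all channels of the recording
#' site is subtracted from each channel, removing noise and movement
#' artifacts shared by the channels.
#'
#' @param x Channels x samples numeric matrix.
#' @return Matrix of the same shape with the per-sample channel median
#'   removed.
#' @export
median_subtract <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  med <- apply(x, 2, stats::median)
  sweep(x, 2, med, "-")
}

#' Band-pass filter for spike detection
#'
#' 4th-order Butterworth band-pass (default 300-5000 Hz at 30 kHz),
#' applied forward-backward (zero phase) so spike timestamps are not
#' shifted.
#'
#' @param x Channels x samples matrix, or a numeric vector.
#' @param low,high Pass-band edges, Hz.
#' @param fs Sample rate, Hz.
#' @param order Filter order.
#' @return Filtered data, same shape as the input.
#' @export
bandpass_filter <- function(x, low = 300, high = 5000, fs = 30000,
                            order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  f1 <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) t(apply(x, 1, f1)) else f1(x)
}

#' Threshold-based spike detection
#'
#' Identifies local maxima of the (absolute, by default) filtered signal
#' crossing `threshold_mad` times the raw median absolute deviation of
#' each channel. Peaks closer than `min_distance` on a channel are merged,
#' keeping the larger; events detected on more than one channel of the
#' same tetrode within `min_distance` are collapsed to the channel with
#' the highest peak, whose timestamp is kept.
#'
#' @param x Filtered channels x samples matrix (or vector for one
#'   channel).
#' @param fs Sample rate, Hz.
#' @param threshold_mad Threshold in multiples of the per-channel MAD.
#' @param min_distance Minimum peak separation, s.
#' @param tetrodes Integer vector assigning each channel to a tetrode
#'   (default: all channels one tetrode).
#' @param polarity `"abs"` detects peaks of |x|; `"neg"` restricts to
#'   negative-going peaks.
#' @return Data frame `time` (s), `channel`, `amplitude` (absolute peak
#'   height), sorted by time.
#' @export
detect_spikes <- function(x, fs = 30000, threshold_mad = 7.5,
                          min_distance = 0.001, tetrodes = NULL,
                          polarity = c("abs", "neg")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n_ch <- nrow(x)
  if (is.null(tetrodes)) tetrodes <- rep(1L, n_ch)
  stopifnot(length(tetrodes) == n_ch)
  min_gap <- round(min_distance * fs)

  per_channel <- lapply(seq_len(n_ch), function(ch) {
    v <- x[ch, ]
    s <- if (polarity == "abs") abs(v) else -v
    thr <- threshold_mad * stats::mad(v, constant = 1)
    n <- length(s)
    if (n < 3) return(NULL)
    core <- 2:(n - 1)
    is_peak <- s[core] >= s[core - 1] & s[core] > s[core + 1] &
      s[core] > thr
    idx <- core[is_peak]
    if (!length(idx)) return(NULL)
    # enforce minimum distance, keeping the larger of close peaks
    keep_idx <- integer(0); keep_amp <- numeric(0)
    for (k in seq_along(idx)) {
      if (length(keep_idx) &&
          idx[k] - keep_idx[length(keep_idx)] < min_gap) {
        if (s[idx[k]] > keep_amp[length(keep_amp)]) {
          keep_idx[length(keep_idx)] <- idx[k]
          keep_amp[length(keep_amp)] <- s[idx[k]]
        }
      } else {
        keep_idx <- c(keep_idx, idx[k])
        keep_amp <- c(keep_amp, s[idx[k]])
      }
    }
    data.frame(time = (keep_idx - 1L) / fs, channel = ch,
               amplitude = keep_amp)
  })
  ev <- do.call(rbind, per_channel)
  if (is.null(ev) || !nrow(ev))
    return(data.frame(time = numeric(0), channel = integer(0),
                      amplitude = numeric(0)))
  # collapse cross-channel duplicates within each tetrode
  out <- list()
  for (tet in unique(tetrodes)) {
    e <- ev[tetrodes[ev$channel] == tet, , drop = FALSE]
    e <- e[order(e$time), , drop = FALSE]
    if (!nrow(e)) next
    grp <- cumsum(c(1, diff(e$time) >= min_distance))
    for (g in unique(grp)) {
      eg <- e[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- eg[which.max(eg$amplitude), ]
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$time), ]
  rownames(res) <- NULL
  res
}

#' Unit quality control
#'
#' A unit is kept only if its refractory-period violation ratio
#' (inter-spike intervals shorter than 2 ms, as a fraction of all spikes)
#' is below 2% and its baseline firing rate is under the region-specific
#' cutoff: 5 Hz in the olfactory tubercle (putative striatal projection
#' neurons; faster units are putative fast-spiking interneurons or ventral
#' pallidal) and 10 Hz in the anterior piriform cortex (putative principal
#' units).
#'
#' @param spike_times Spike times of the unit, s (any reference).
#' @param baseline_rate Baseline firing rate, Hz.
#' @param region `"Tu"` or `"aPC"`.
#' @param refractory_s Refractory period, s.
#' @param max_violation Maximum violation ratio.
#' @return List `include` (logical), `reason` (character), and
#'   `violation_ratio`.
#' @export
unit_qc <- function(spike_times, baseline_rate, region = c("Tu", "aPC"),
                    refractory_s = 0.002, max_violation = 0.02) {
  region <- match.arg(region)
  n <- length(spike_times)
  viol <- if (n >= 2)
    sum(diff(sort(spike_times)) < refractory_s) / n else 0
  rate_cut <- if (region == "Tu") 5 else 10
  if (viol >= max_violation)
    return(list(include = FALSE, reason = "refractory violations >= 2%",
                violation_ratio = viol))
  if (baseline_rate >= rate_cut)
    return(list(include = FALSE,
                reason = sprintf("baseline rate >= %d Hz (%s cutoff)",
                                 rate_cut, region),
                violation_ratio = viol))
  list(include = TRUE, reason = "ok", violation_ratio = viol)
}
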