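#' Build matched, concatenated population vectors from one or more sessions
#'
#' Bins each unit's spikes into sliding firing-rate windows and
#' concatenates units across sessions by matching trials on CS type, trial
#' order and, for CS50, trial outcome. When sessions differ in the number
#' of rewarded (or unrewarded) CS50 trials, the common minimum is kept and
#' supernumerary trials are dropped from the end.
#'
#' @param sessions A `unit_raster_set` or list of them (one per session).
#' @param bin Bin width, s (0.5 for display, 0.25 with `step = bin` for
#'   statistics).
#' @param step Bin step, s.
#' @param range Time range (s relative to odor onset) covered by the bins.
#' @return A `population_vectors` object: list with `rates` (units x
#'   trials x bins array, Hz), `trials` (data frame `cs`, `rewarded`,
#'   `rep`), `bin_centers`, `bin_starts`, `bin_width`, `unit_session`.
#' @export
build_population_vectors <- function(sessions, bin = 0.5, step = 0.125,
                                     range = c(-2.5, 6)) {
  if (inherits(sessions, "unit_raster_set")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1, bin > 0, step > 0)
  starts <- seq(range[1], range[2] - bin + 1e-9, by = step)
  centers <- starts + bin / 2

  # Matched trial table: per (cs, rewarded) group, the minimum count across
  # sessions, trials taken in order of occurrence.
  group_key <- function(seq) paste(seq$cs, seq$rewarded)
  keys <- lapply(sessions, function(s) group_key(s$seq))
  all_groups <- Reduce(intersect, lapply(keys, unique))
  if (!any(grepl("^CS50", all_groups)) &&
      any(vapply(sessions, function(s) any(s$seq$cs == "CS50"), logical(1))))
    stop("no CS50 trial group common to all sessions")
  counts <- sapply(all_groups, function(g)
    min(vapply(keys, function(k) sum(k == g), numeric(1))))
  trials <- do.call(rbind, lapply(all_groups, function(g) {
    parts <- strsplit(g, " ")[[1]]
    data.frame(cs = parts[1], rewarded = as.logical(parts[2]),
               rep = seq_len(counts[[g]]))
  }))
  # per session: index of the matched trials in that session's sequence
  sess_trial_idx <- lapply(keys, function(k) {
    idx <- integer(nrow(trials))
    for (r in seq_len(nrow(trials))) {
      g <- paste(trials$cs[r], trials$rewarded[r])
      idx[r] <- which(k == g)[trials$rep[r]]
    }
    idx
  })

  n_units <- sum(vapply(sessions, function(s) length(s$units), integer(1)))
  rates <- array(0, c(n_units, nrow(trials), length(starts)))
  unit_session <- integer(n_units)
  u0 <- 0L
  for (s in seq_along(sessions)) {
    idx <- sess_trial_idx[[s]]
    for (u in seq_along(sessions[[s]]$units)) {
      sp <- sessions[[s]]$units[[u]]$spikes
      for (r in seq_len(nrow(trials))) {
        tt <- sp$time[sp$trial == idx[r]]
        rates[u0 + u, r, ] <- bin_counts(tt, starts, bin) / bin
      }
      unit_session[u0 + u] <- s
    }
    u0 <- u0 + length(sessions[[s]]$units)
  }
  structure(list(rates = rates, trials = trials, bin_centers = centers,
                 bin_starts = starts, bin_width = bin,
                 unit_session = unit_session),
            class = "population_vectors")
}

# Spike counts per sliding bin (half-open [start, start + width)).
bin_counts <- function(times, starts, width) {
  vapply(starts, function(s0) sum(times >= s0 & times < s0 + width),
         numeric(1))
}

#' Average population vectors over consecutive trial pairs
#'
#' Within each trial group, consecutive trials are grouped in pairs and
#' averaged into pseudo-trials to reduce trial-to-trial variability; an
#' odd trailing trial is dropped.
#'
#' @param pvs A `population_vectors` object.
#' @param by Columns of the trial table defining the pairing groups
#'   (default CS type only).
#' @return A `population_vectors` object with `floor(n/2)` pseudo-trials
#'   per group.
#' @export
pair_average <- function(pvs, by = "cs") {
  tr <- pvs$trials
  key <- do.call(paste, tr[, by, drop = FALSE])
  keep_rates <- list(); keep_rows <- list()
  for (g in unique(key)) {
    idx <- which(key == g)
    n_pairs <- length(idx) %/% 2L
    if (n_pairs == 0L) next
    for (k in seq_len(n_pairs)) {
      pair <- idx[c(2L * k - 1L, 2L * k)]
      m <- (pvs$rates[, pair[1], , drop = FALSE] +
              pvs$rates[, pair[2], , drop = FALSE]) / 2
      keep_rates[[length(keep_rates) + 1L]] <- m
      row <- tr[pair[1], , drop = FALSE]
      row$rep <- k
      keep_rows[[length(keep_rows) + 1L]] <- row
    }
  }
  rates <- array(0, c(dim(pvs$rates)[1], length(keep_rates),
                      dim(pvs$rates)[3]))
  for (k in seq_along(keep_rates)) rates[, k, ] <- keep_rates[[k]]
  out <- pvs
  out$rates <- rates
  out$trials <- do.call(rbind, keep_rows)
  rownames(out$trials) <- NULL
  out
}

#' Population deviation from baseline
#'
#' Euclidean distance, per time bin and trial, between the population
#' vector and the baseline vector (each unit's mean rate in the -2 to
#' -1.25 s pre-odor window, averaged across all trials of the raw,
#' un-paired data), summarized as mean and SEM per CS type. Computed on
#' pair-averaged pseudo-trials by default.
#'
#' @param pvs A `population_vectors` object.
#' @param baseline_window Window (s) defining the baseline vector; bins
#'   fully inside it are used.
#' @param pair Average consecutive trial pairs first.
#' @return List with `summary` (data frame `cs`, `time`, `mean`, `sem`),
#'   `per_trial` (trials x bins distance matrix), `trials`, `baseline`.
#' @export
distance_from_baseline <- function(pvs, baseline_window = c(-2, -1.25),
                                   pair = TRUE) {
  bsel <- pvs$bin_starts >= baseline_window[1] - 1e-9 &
    (pvs$bin_starts + pvs$bin_width) <= baseline_window[2] + 1e-9
  if (!any(bsel)) stop("baseline window not covered by the binning")
  B <- apply(pvs$rates[, , bsel, drop = FALSE], 1, mean)
  p <- if (pair) pair_average(pvs) else pvs
  n_tr <- dim(p$rates)[2]; n_bin <- dim(p$rates)[3]
  d <- matrix(0, n_tr, n_bin)
  for (t in seq_len(n_bin)) {
    dev <- p$rates[, , t, drop = FALSE][, , 1, drop = FALSE] - B
    d[, t] <- sqrt(colSums(matrix(dev, nrow = dim(p$rates)[1])^2))
  }
  summ <- do.call(rbind, lapply(unique(p$trials$cs), function(ty) {
    sel <- p$trials$cs == ty
    data.frame(cs = ty, time = p$bin_centers,
               mean = colMeans(d[sel, , drop = FALSE]),
               sem = apply(d[sel, , drop = FALSE], 2, stats::sd) /
                 sqrt(sum(sel)))
  }))
  list(summary = summ, per_trial = d, trials = p$trials, baseline = B)
}

#' Mean cross-type correlation of population vectors
#'
#' For each time bin, every (pair-averaged) population vector of one CS
#' type is correlated (Pearson) with every vector of each other CS type;
#' the mean over all cross-type trial pairs quantifies how much the two
#' stimuli recruit overlapping unit sets at that time.
#'
#' @param pvs A `population_vectors` object (needs >= 2 units).
#' @param pair Average consecutive trial pairs first.
#' @return Data frame `pair` (e.g. `"CS100-CS50"`), `time`, `r` (mean
#'   Pearson correlation; `NA` if every trial pair was degenerate at that
#'   bin). Zero-variance vectors are skipped with a message.
#' @export
cross_type_correlation <- function(pvs, pair = TRUE) {
  stopifnot(dim(pvs$rates)[1] >= 2)
  p <- if (pair) pair_average(pvs) else pvs
  types <- unique(p$trials$cs)
  combs <- utils::combn(types, 2, simplify = FALSE)
  n_bin <- dim(p$rates)[3]
  skipped <- 0L
  out <- list()
  for (cb in combs) {
    ia <- which(p$trials$cs == cb[1]); ib <- which(p$trials$cs == cb[2])
    r_t <- numeric(n_bin)
    for (t in seq_len(n_bin)) {
      A <- matrix(p$rates[, ia, t], nrow = dim(p$rates)[1])
      B <- matrix(p$rates[, ib, t], nrow = dim(p$rates)[1])
      sa <- apply(A, 2, stats::sd); sb <- apply(B, 2, stats::sd)
      ka <- sa > 0; kb <- sb > 0
      skipped <- skipped + sum(!ka) * length(ib) +
        sum(!kb) * sum(ka)
      if (!any(ka) || !any(kb)) { r_t[t] <- NA_real_; next }
      r_mat <- stats::cor(A[, ka, drop = FALSE], B[, kb, drop = FALSE])
      r_t[t] <- mean(r_mat)
    }
    out[[length(out) + 1L]] <- data.frame(
      pair = paste(cb, collapse = "-"), time = p$bin_centers, r = r_t)
  }
  if (skipped > 0)
    message(skipped, " zero-variance trial pair(s) skipped")
  do.call(rbind, out)
}

#' Time-embedded population trajectories
#'
#' Averages the population vectors across trials per CS type, applies
#' delay embedding (`m` delayed coordinates, delay of one bin by default)
#' to the unit x time matrix, and projects the embedded points of all CS
#' types jointly onto their first `k` principal components so that
#' trajectories of different trial types share axes.
#'
#' @param pvs A `population_vectors` object.
#' @param m Number of delayed coordinates.
#' @param delay Delay between coordinates, in bins.
#' @param k Number of principal components retained.
#' @return List with `trajectories` (named list per CS type of
#'   `(T - (m-1)*delay) x k` score matrices), `times` (bin centers of the
#'   embedded points), `pca` (the `prcomp` fit).
#' @export
embed_trajectories <- function(pvs, m = 4, delay = 1, k = 3) {
  n_bin <- dim(pvs$rates)[3]
  span <- (m - 1L) * delay
  if (n_bin <= span) stop("fewer time bins than the embedding span")
  types <- unique(pvs$trials$cs)
  avg <- lapply(types, function(ty) {
    sel <- pvs$trials$cs == ty
    apply(pvs$rates[, sel, , drop = FALSE], c(1, 3), mean)
  })
  names(avg) <- types
  embed1 <- function(M) {
    idx <- (span + 1L):n_bin
    do.call(cbind, lapply(0:(m - 1L), function(j) t(M[, idx - j * delay,
                                                      drop = FALSE])))
  }
  emb <- lapply(avg, embed1)
  X <- do.call(rbind, emb)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pca$x))
  n_pts <- nrow(emb[[1]])
  traj <- lapply(seq_along(types), function(i) {
    pca$x[((i - 1L) * n_pts + 1L):(i * n_pts), seq_len(k), drop = FALSE]
  })
  names(traj) <- types
  list(trajectories = traj,
       times = pvs$bin_centers[(span + 1L):n_bin], pca = pca)
}
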