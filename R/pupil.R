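#' Pupil observation-model forward prediction
#'
#' The average pupil dilation (percent change from baseline) at the three
#' trial timepoints is modeled as a weighted sum of current and past state
#' values and absolute prediction errors:
#' `d(t) = sum_{tau=0..t} a_tau V(s_{t-tau}) + sum_{tau=0..t-1} b_tau
#' |delta(t-tau)|`, evaluated literally at t = 0, 1, 2 with `V(s2) = 0`:
#'
#' * `d0 = a0 V(s0)`
#' * `d1 = a0 V(s1) + a1 V(s0) + b0 |delta1|`
#' * `d2 = a1 V(s1) + a2 V(s0) + b0 |delta2| + b1 |delta1|`
#'
#' @param a Coefficients `a0..a2` on state values.
#' @param b Coefficients `b0..b1` on absolute prediction errors.
#' @param td A `td_trace` (per-trial `v0`, `v_cs`, `delta1`, `delta2`).
#' @return Matrix with one row per trial, columns `d0`, `d1`, `d2`.
#' @export
pupil_forward <- function(a, b, td) {
  stopifnot(length(a) == 3, length(b) == 2,
            all(is.finite(a)), all(is.finite(b)))
  X <- pupil_design(td)
  theta <- c(a, b)
  d <- X %*% theta
  out <- matrix(d, ncol = 3L, byrow = TRUE)
  colnames(out) <- c("d0", "d1", "d2")
  out
}

# Stacked linear design for (d0, d1, d2) per trial; columns a0,a1,a2,b0,b1.
# Three rows per trial, in timepoint order.
pupil_design <- function(td) {
  n <- nrow(td)
  ad1 <- abs(td$delta1); ad2 <- abs(td$delta2)
  X <- matrix(0, nrow = 3L * n, ncol = 5L,
              dimnames = list(NULL, c("a0", "a1", "a2", "b0", "b1")))
  r0 <- seq(1L, 3L * n, by = 3L)
  X[r0, "a0"] <- td$v0
  X[r0 + 1L, "a0"] <- td$v_cs
  X[r0 + 1L, "a1"] <- td$v0
  X[r0 + 1L, "b0"] <- ad1
  X[r0 + 2L, "a1"] <- td$v_cs
  X[r0 + 2L, "a2"] <- td$v0
  X[r0 + 2L, "b0"] <- ad2
  X[r0 + 2L, "b1"] <- ad1
  X
}

#' Simulate a session's pupil trace from the observation model
#'
#' Per trial, target window means `d0, d1, d2` are computed with
#' [pupil_forward()] and perturbed by i.i.d. Gaussian noise; a continuous
#' percent-change trace sampled at `fs` Hz (default 20, the video frame
#' rate) is rendered by holding each window's target over its interval
#' (-2..0, 0..2.7, 2.7..5.4 s relative to odor onset) so that window means
#' recomputed from the trace reproduce the targets exactly. Samples outside
#' trial windows are 0.
#'
#' @param seq Trial sequence.
#' @param td Matching `td_trace`.
#' @param a,b Observation-model coefficients (see [pupil_forward()]).
#' @param noise_sd Gaussian noise SD added independently to each window
#'   mean, in percent-change units.
#' @param fs Sample rate, Hz.
#' @param seed Optional seed.
#' @return List with `trace` (data frame `time_s`, `pct_change`) and
#'   `windows` (n_trials x 3 matrix of noisy window targets).
#' @export
simulate_pupil <- function(seq, td, a, b, noise_sd = 0.5, fs = 20,
                           seed = NULL) {
  stopifnot(nrow(seq) == nrow(td), noise_sd >= 0, fs > 0)
  if (!is.null(seed)) set.seed(seed)
  d <- pupil_forward(a, b, td)
  if (noise_sd > 0)
    d <- d + matrix(stats::rnorm(length(d), 0, noise_sd), nrow = nrow(d))
  t_end <- max(seq$onset) + 8
  time_s <- seq(0, t_end, by = 1 / fs)
  pct <- numeric(length(time_s))
  edges <- c(-2, 0, 2.7, 5.4)
  for (i in seq_len(nrow(seq))) {
    for (w in 1:3) {
      idx <- which(time_s >= seq$onset[i] + edges[w] &
                   time_s < seq$onset[i] + edges[w + 1L])
      pct[idx] <- d[i, w]
    }
  }
  list(trace = data.frame(time_s = time_s, pct_change = pct), windows = d)
}

#' Per-trial pupil window means
#'
#' Averages a percent-change pupil trace over the three model windows of
#' one trial: baseline -2..0 s, odor-to-outcome 0..2.7 s, and post-outcome
#' 2.7..5.4 s relative to odor onset (half-open intervals on the sample
#' grid).
#'
#' @param trace Data frame `time_s`, `pct_change`.
#' @param onset Trial onset in seconds.
#' @return Named vector `d0`, `d1`, `d2`.
#' @export
window_average <- function(trace, onset) {
  edges <- c(-2, 0, 2.7, 5.4)
  out <- numeric(3L)
  for (w in 1:3) {
    sel <- trace$time_s >= onset + edges[w] & trace$time_s < onset + edges[w + 1L]
    if (!any(sel)) stop("trial window not covered by trace at onset ", onset)
    out[w] <- mean(trace$pct_change[sel])
  }
  names(out) <- c("d0", "d1", "d2")
  out
}

#' Preprocess a raw pupil-diameter trace into per-trial percent change
#'
#' Expresses the pupil diameter of each trial as percent change from that
#' trial's pre-odor baseline (mean diameter from -2 to 0 s before odor
#' onset). Trials containing an increase or decrease of more than 5%
#' between two consecutive frames (blinks, detection outliers) are excluded
#' entirely, as are trials whose window extends beyond the trace.
#'
#' @param trace Data frame `time_s`, `diameter` (arbitrary units) at a
#'   fixed sample rate.
#' @param seq Trial sequence.
#' @param window Trial extraction window (s relative to odor onset).
#' @param jump_threshold Frame-to-frame percent-change exclusion threshold.
#' @return List with `trials` (list of data frames `time_rel`,
#'   `pct_change`, one per kept trial, names = trial index) and `excluded`
#'   (data frame `trial`, `reason`).
#' @export
preprocess_pupil <- function(trace, seq, window = c(-2, 5.4),
                             jump_threshold = 5) {
  stopifnot(all(c("time_s", "diameter") %in% names(trace)))
  kept <- list(); excl <- list()
  for (i in seq_len(nrow(seq))) {
    on <- seq$onset[i]
    sel <- trace$time_s >= on + window[1] & trace$time_s < on + window[2]
    if (!any(sel) ||
        min(trace$time_s) > on + window[1] ||
        max(trace$time_s) < on + window[2] - 1e-9) {
      excl[[length(excl) + 1L]] <- data.frame(trial = i,
                                              reason = "window outside trace")
      next
    }
    base_sel <- trace$time_s >= on - 2 & trace$time_s < on
    base <- mean(trace$diameter[base_sel])
    pct <- 100 * (trace$diameter[sel] - base) / base
    if (any(abs(diff(pct)) > jump_threshold)) {
      excl[[length(excl) + 1L]] <- data.frame(trial = i,
                                              reason = "frame jump > threshold")
      next
    }
    kept[[as.character(i)]] <- data.frame(time_rel = trace$time_s[sel] - on,
                                          pct_change = pct)
  }
  excluded <- if (length(excl)) do.call(rbind, excl)
              else data.frame(trial = integer(), reason = character())
  if (nrow(excluded)) message(nrow(excluded), " trial(s) excluded")
  list(trials = kept, excluded = excluded)
}

#' Fit the pupil observation model and estimate the learning rate
#'
#' For each candidate learning rate on a grid, the TD(0) model is run on
#' each session's trial sequence; the observation model is then linear in
#' the coefficients `(a, b)`, so the inner fit is an exact least-squares
#' solve and the loss is the summed squared difference between predicted
#' and observed per-trial window means. The outer 1-D problem in alpha is
#' solved by grid search followed by golden-section refinement. By default
#' alpha is estimated per session and averaged across sessions (`joint =
#' TRUE` instead minimizes the pooled loss over all sessions with one
#' shared alpha and per-session coefficients).
#'
#' Sessions with no pupil-value signal leave the loss flat in alpha; this
#' non-identifiability is flagged in the diagnostics (relative loss range
#' across the grid below `flat_tol`).
#'
#' @param sessions List of sessions, each a list with elements `seq` (trial
#'   sequence) and `d` (n_trials x 3 matrix of observed window means; rows
#'   with any `NA` — excluded trials — are omitted from the loss).
#' @param alpha_grid Candidate learning rates.
#' @param init TD initialization mode passed to [run_td_session()].
#' @param joint Fit one alpha jointly across sessions instead of averaging
#'   per-session estimates.
#' @param flat_tol Relative loss range under which alpha is flagged
#'   non-identifiable.
#' @return List with `alpha` (study-level estimate), `per_session` (data
#'   frame: `session`, `alpha`, `loss`, `identifiable`, `n_trials_used`),
#'   and `coef` (list of per-session `(a, b)` at the selected alpha).
#' @export
fit_pupil_model <- function(sessions, alpha_grid = seq(0.02, 0.98, by = 0.02),
                            init = "zeros", joint = FALSE, flat_tol = 1e-8) {
  stopifnot(length(sessions) >= 1)
  session_loss <- function(sess, alpha) {
    td <- run_td_session(sess$seq, alpha = alpha, init = init)
    X <- pupil_design(td)
    y <- as.vector(t(sess$d))
    ok <- rep(stats::complete.cases(sess$d), each = 3L)
    X <- X[ok, , drop = FALSE]; y <- y[ok]
    fit <- stats::lm.fit(X, y)
    list(loss = sum(fit$residuals^2), coef = fit$coefficients,
         n = sum(ok) / 3)
  }
  refine <- function(lossf, grid) {
    losses <- vapply(grid, lossf, numeric(1))
    i <- which.min(losses)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(lossf, c(lo, hi), tol = 1e-6)
    flat <- (max(losses) - min(losses)) <= flat_tol * max(max(losses), 1e-12)
    list(alpha = opt$minimum, loss = opt$objective, flat = flat)
  }
  if (joint) {
    lossf <- function(al) sum(vapply(sessions,
                                     function(s) session_loss(s, al)$loss,
                                     numeric(1)))
    r <- refine(lossf, alpha_grid)
    per <- data.frame(session = seq_along(sessions), alpha = r$alpha,
                      loss = NA_real_, identifiable = !r$flat,
                      n_trials_used = vapply(sessions, function(s)
                        sum(stats::complete.cases(s$d)), numeric(1)))
    alpha_hat <- r$alpha
  } else {
    rows <- lapply(seq_along(sessions), function(k) {
      lossf <- function(al) session_loss(sessions[[k]], al)$loss
      r <- refine(lossf, alpha_grid)
      data.frame(session = k, alpha = r$alpha, loss = r$loss,
                 identifiable = !r$flat,
                 n_trials_used = sum(stats::complete.cases(sessions[[k]]$d)))
    })
    per <- do.call(rbind, rows)
    use <- per$identifiable
    if (!any(use)) {
      warning("alpha non-identifiable in every session (flat loss)")
      use <- rep(TRUE, nrow(per))
    }
    alpha_hat <- mean(per$alpha[use])
  }
  coefs <- lapply(sessions, function(s) {
    sl <- session_loss(s, alpha_hat)
    list(a = unname(sl$coef[1:3]), b = unname(sl$coef[4:5]))
  })
  list(alpha = alpha_hat, per_session = per, coef = coefs)
}
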