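#' Parameters of the synthetic licking agent
#'
#' Lick rates in the anticipatory window scale with the TD value of the
#' presented cue; on CS50 trials the rate is additionally modulated by the
#' outcome of the previous CS50 trial (cue-specific history) and reduced
#' after any recently rewarded trial (satiety). Rewarded trials append a
#' consumption burst in the reward window.
#'
#' @param base_lick_rate Baseline lick rate, Hz, active throughout.
#' @param anticipatory_gain Hz of anticipatory licking per unit of cue
#'   value.
#' @param consumption_rate Hz of consummatory licking on rewarded trials.
#' @param history_weight Hz added (subtracted) on CS50 trials whose
#'   previous CS50 trial was rewarded (unrewarded).
#' @param satiety_weight Hz subtracted when the immediately preceding trial
#'   (any cue) was rewarded.
#' @param anticipatory_window Interval (s from odor onset) over which the
#'   anticipatory rate applies.
#' @param consumption_window Interval (s from odor onset) of the
#'   consumption burst on rewarded trials.
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(base_lick_rate = 0.2, anticipatory_gain = 10,
                            consumption_rate = 8, history_weight = 1,
                            satiety_weight = 0.5,
                            anticipatory_window = c(1.0, 2.8),
                            consumption_window = c(2.8, 4.1)) {
  stopifnot(base_lick_rate >= 0, anticipatory_gain >= 0,
            consumption_rate >= 0, is.finite(history_weight),
            is.finite(satiety_weight))
  structure(list(base_lick_rate = base_lick_rate,
                 anticipatory_gain = anticipatory_gain,
                 consumption_rate = consumption_rate,
                 history_weight = history_weight,
                 satiety_weight = satiety_weight,
                 anticipatory_window = anticipatory_window,
                 consumption_window = consumption_window),
            class = "behavior_params")
}

#' Simulate licking behavior for one session
#'
#' Draws lick timestamps from an inhomogeneous Poisson process whose rate
#' is piecewise constant within each trial: baseline everywhere, an
#' anticipatory rate `base + gain * V(CS) + history - satiety` in the
#' anticipatory window, and a consumption burst on rewarded trials.
#' Negative instantaneous rates are clamped to zero (with a message).
#'
#' @param seq Trial sequence.
#' @param td Matching `td_trace` supplying per-trial `v_cs`.
#' @param params A [behavior_params()].
#' @param seed Optional seed.
#' @return Data frame with column `time_s` (absolute lick times, sorted).
#' @export
simulate_agent_behavior <- function(seq, td, params = behavior_params(),
                                    seed = NULL) {
  stopifnot(nrow(seq) == nrow(td))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n <- nrow(seq)
  last_cs50_outcome <- NA
  clamped <- FALSE
  licks <- vector("list", n + 1L)
  # Baseline licking across the whole session.
  t_end <- max(seq$onset) + 8
  n_base <- stats::rpois(1L, p$base_lick_rate * t_end)
  licks[[n + 1L]] <- sort(stats::runif(n_base, 0, t_end))
  for (i in seq_len(n)) {
    hist_term <- 0
    if (seq$cs[i] == "CS50" && !is.na(last_cs50_outcome))
      hist_term <- p$history_weight * (if (last_cs50_outcome) 1 else -1)
    sat_term <- if (i > 1L && seq$rewarded[i - 1L]) p$satiety_weight else 0
    rate <- p$base_lick_rate + p$anticipatory_gain * td$v_cs[i] +
      hist_term - sat_term
    # base rate already covered session-wide; add the increment only
    rate <- rate - p$base_lick_rate
    if (rate < 0) { clamped <- TRUE; rate <- 0 }
    w <- p$anticipatory_window
    k <- stats::rpois(1L, rate * diff(w))
    ant <- stats::runif(k, seq$onset[i] + w[1], seq$onset[i] + w[2])
    cons <- numeric(0)
    if (seq$rewarded[i]) {
      cw <- p$consumption_window
      kc <- stats::rpois(1L, p$consumption_rate * diff(cw))
      cons <- stats::runif(kc, seq$onset[i] + cw[1], seq$onset[i] + cw[2])
    }
    licks[[i]] <- c(ant, cons)
    if (seq$cs[i] == "CS50") last_cs50_outcome <- seq$rewarded[i]
  }
  if (clamped) message("negative instantaneous lick rate clamped to 0")
  data.frame(time_s = sort(unlist(licks)))
}

#' Classify one trial as Hit, Miss, False alarm or Correct rejection
#'
#' A go-response is at least `min_licks` licks in the anticipatory window
#' (1.5-2.8 s after odor onset) or at least `min_licks` licks in the reward
#' window (2.8-4.1 s); the two windows are evaluated separately, not
#' pooled. CS100 and CS50 are go cues (go-response = Hit, else Miss); CS0
#' is the no-go cue (go-response = False alarm, else Correct rejection).
#'
#' @param lick_times Lick times in seconds relative to odor onset.
#' @param cs CS label of the trial.
#' @param anticipatory_window,reward_window Scoring windows (s).
#' @param min_licks Lick-count criterion per window.
#' @return One of `"Hit"`, `"Miss"`, `"FalseAlarm"`, `"CorrectRejection"`.
#' @export
classify_trial <- function(lick_times, cs,
                           anticipatory_window = c(1.5, 2.8),
                           reward_window = c(2.8, 4.1), min_licks = 3) {
  n_ant <- sum(lick_times >= anticipatory_window[1] &
               lick_times < anticipatory_window[2])
  n_rew <- sum(lick_times >= reward_window[1] &
               lick_times < reward_window[2])
  go <- (n_ant >= min_licks) || (n_rew >= min_licks)
  if (cs %in% c("CS100", "CS50")) {
    if (go) "Hit" else "Miss"
  } else {
    if (go) "FalseAlarm" else "CorrectRejection"
  }
}

#' Classify all trials of a session
#'
#' @param licks Data frame with absolute lick times (`time_s`).
#' @param seq Trial sequence.
#' @param ... Passed to [classify_trial()].
#' @return Data frame `trial`, `cs`, `rewarded`, `class`,
#'   `anticipatory_count` (licks in the 1.5-2.8 s window).
#' @export
classify_session <- function(licks, seq, ...) {
  classes <- character(nrow(seq))
  counts <- integer(nrow(seq))
  for (i in seq_len(nrow(seq))) {
    rel <- licks$time_s - seq$onset[i]
    rel <- rel[rel >= -2 & rel < 8]
    classes[i] <- classify_trial(rel, seq$cs[i], ...)
    counts[i] <- sum(rel >= 1.5 & rel < 2.8)
  }
  data.frame(trial = seq$trial, cs = seq$cs, rewarded = seq$rewarded,
             class = classes, anticipatory_count = counts)
}

#' Session performance in percent
#'
#' `100 * (Hits + Correct rejections) / total trials`. Sessions above 80%
#' met the study inclusion criterion.
#'
#' @param classes Character vector of trial classes, or the data frame from
#'   [classify_session()].
#' @return Percent correct.
#' @export
session_performance <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  if (length(classes) == 0L) stop("empty session")
  100 * mean(classes %in% c("Hit", "CorrectRejection"))
}

#' Per-trial anticipatory lick rates with history and satiety splits
#'
#' Computes the lick rate (Hz) of every trial in the anticipatory window
#' and, for CS50 trials, group means split by the outcome of the previous
#' CS50 trial (`lastCS50_R` vs `lastCS50_N`) and by the identity of the
#' immediately preceding trial (`prior_CS100` vs `prior_CS0`).
#'
#' @param licks Data frame with absolute lick times (`time_s`).
#' @param seq Trial sequence.
#' @param window Anticipatory window, s relative to odor onset.
#' @return List with `rates` (data frame `trial`, `cs`, `rate_hz`,
#'   `history`, `prior_cs`) and `group_means` (named vector; `NA` for empty
#'   groups).
#' @export
anticipatory_rate <- function(licks, seq, window = c(1.5, 2.8)) {
  n <- nrow(seq)
  rate <- numeric(n)
  for (i in seq_len(n)) {
    rel <- licks$time_s - seq$onset[i]
    rate[i] <- sum(rel >= window[1] & rel < window[2]) / diff(window)
  }
  history <- rep(NA_character_, n)
  i50 <- which(seq$cs == "CS50")
  if (length(i50) >= 2L)
    history[i50[-1L]] <- ifelse(seq$rewarded[i50][-length(i50)], "R", "N")
  prior_cs <- c(NA_character_, seq$cs[-n])
  rates <- data.frame(trial = seq$trial, cs = seq$cs, rate_hz = rate,
                      history = history, prior_cs = prior_cs)
  g <- function(sel) if (any(sel, na.rm = TRUE))
    mean(rate[which(sel)]) else NA_real_
  is50 <- seq$cs == "CS50"
  group_means <- c(
    lastCS50_R = g(is50 & history == "R"),
    lastCS50_N = g(is50 & history == "N"),
    prior_CS100 = g(is50 & prior_cs == "CS100"),
    prior_CS0 = g(is50 & prior_cs == "CS0"))
  list(rates = rates, group_means = group_means)
}

#' Build the n-back outcome-history design for CS50 licking
#'
#' The dependent variable is the anticipatory lick count of each CS50
#' trial; regressors are the outcomes of the previous `n_back` trials of
#' the conditioning set, coded +1 (rewarded) / -1 (unrewarded). In
#' `"cue"` mode the conditioning set is the previous CS50 trials
#' themselves (outcome history); in `"satiety"` mode it is the previous
#' CS100/CS0 trials. CS50 trials without a complete n-back history are
#' dropped.
#'
#' @param counts Integer vector of anticipatory lick counts, one per trial
#'   of the session (all trials, in order).
#' @param seq Trial sequence.
#' @param mode `"cue"` or `"satiety"`.
#' @param n_back History depth (default 6).
#' @return List with `y` (counts for retained CS50 trials) and `X`
#'   (matrix, columns `lag1..lagN` in 1-back..N-back order, entries +/-1).
#' @export
lick_history_design <- function(counts, seq, mode = c("cue", "satiety"),
                                n_back = 6) {
  mode <- match.arg(mode)
  stopifnot(length(counts) == nrow(seq))
  pool <- if (mode == "cue") which(seq$cs == "CS50")
          else which(seq$cs != "CS50")
  targets <- which(seq$cs == "CS50")
  rows <- list(); y <- integer(0)
  for (t in targets) {
    prior <- pool[pool < t]
    if (length(prior) < n_back) next
    back <- rev(utils::tail(prior, n_back))
    rows[[length(rows) + 1L]] <- ifelse(seq$rewarded[back], 1, -1)
    y <- c(y, counts[t])
  }
  if (!length(rows)) stop("no CS50 trial has a complete n-back history")
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("lag", seq_len(n_back))
  list(y = y, X = X)
}

#' Poisson regression of anticipatory licking on outcome history
#'
#' Fits, for one session, a Poisson GLM with log link of the CS50
#' anticipatory lick counts on the +/-1-coded outcomes of the `n_back`
#' previous CS50 trials (`mode = "cue"`) or previous CS100/CS0 trials
#' (`mode = "satiety"`). Each raw coefficient is standardized by the ratio
#' of its regressor's SD to the SD of the observed counts, then transformed
#' to `exp(beta*) - 1` so that positive values indicate more anticipatory
#' licking after rewarded n-back trials. An intercept is included by
#' default since lick counts have a nonzero baseline.
#'
#' @param licks Data frame with absolute lick times (`time_s`), or `NULL`
#'   if `counts` is given.
#' @param seq Trial sequence.
#' @param mode `"cue"` or `"satiety"`.
#' @param n_back History depth.
#' @param counts Optional precomputed per-trial anticipatory lick counts.
#' @param window Anticipatory count window (s from odor onset).
#' @param intercept Include an intercept term.
#' @return Data frame `lag`, `beta` (raw), `beta_star` (standardized and
#'   `exp(.)-1`-transformed), or `NULL` (with a warning) if the counts have
#'   zero variance or the fit does not converge.
#' @export
poisson_history_regression <- function(licks, seq,
                                       mode = c("cue", "satiety"),
                                       n_back = 6, counts = NULL,
                                       window = c(1.5, 2.8),
                                       intercept = TRUE) {
  mode <- match.arg(mode)
  if (is.null(counts)) {
    stopifnot(!is.null(licks))
    counts <- integer(nrow(seq))
    for (i in seq_len(nrow(seq))) {
      rel <- licks$time_s - seq$onset[i]
      counts[i] <- sum(rel >= window[1] & rel < window[2])
    }
  }
  des <- lick_history_design(counts, seq, mode = mode, n_back = n_back)
  sd_y <- stats::sd(des$y)
  if (!is.finite(sd_y) || sd_y == 0) {
    warning("constant lick counts; standardization undefined, session skipped")
    return(NULL)
  }
  if (any(apply(des$X, 2, stats::sd) == 0)) {
    warning("zero-variance history regressor; session skipped")
    return(NULL)
  }
  dat <- data.frame(y = des$y, des$X)
  form <- if (intercept) stats::as.formula(paste("y ~", paste(colnames(des$X),
                                                              collapse = "+")))
          else stats::as.formula(paste("y ~ 0 +",
                                       paste(colnames(des$X), collapse = "+")))
  fit <- suppressWarnings(stats::glm(form, family = stats::poisson(),
                                     data = dat))
  if (!fit$converged) {
    warning("Poisson fit did not converge; session skipped")
    return(NULL)
  }
  beta <- stats::coef(fit)[colnames(des$X)]
  beta_star <- beta * apply(des$X, 2, stats::sd) / sd_y
  data.frame(lag = seq_len(n_back), beta = unname(beta),
             beta_star = unname(exp(beta_star) - 1))
}
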