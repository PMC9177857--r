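#' Task configuration for the three-odor conditioning paradigm
#'
#' Describes one session of the go/no-go odor task: three conditioned
#' stimuli presented in equal proportions, each followed after a fixed delay
#' by a probabilistic water reward. Trial timing is 1 s of odor, a 1.7 s
#' waiting period, and outcome delivery 2.7 s after odor onset; trial onsets
#' are jittered uniformly between 10 and 12 s.
#'
#' @param n_trials Number of trials per session; must be divisible by 3 so
#'   that the three odors can be presented in equal proportion. 150 for
#'   training-style sessions, 120 for scanner-style sessions.
#' @param reward_probs Named vector of reward probabilities per CS type.
#' @param odor_duration Odor presentation time in seconds.
#' @param wait_duration Delay between odor offset and outcome, seconds.
#' @param us_time Outcome (US) time relative to odor onset, seconds. Must
#'   equal `odor_duration + wait_duration`.
#' @param iti_range Length-2 vector, uniform jitter bounds (s) for the
#'   interval between successive trial onsets.
#' @param max_stim_run Maximum allowed run of identical CS types.
#' @param max_reward_run Maximum allowed run of consecutively rewarded
#'   trials.
#' @return A `task_config` list.
#' @export
task_config <- function(n_trials = 150,
                        reward_probs = c(CS100 = 1, CS50 = 0.5, CS0 = 0),
                        odor_duration = 1, wait_duration = 1.7,
                        us_time = odor_duration + wait_duration,
                        iti_range = c(10, 12),
                        max_stim_run = 3, max_reward_run = 3) {
  stopifnot(n_trials >= 3, n_trials %% 3 == 0,
            all(reward_probs >= 0), all(reward_probs <= 1),
            length(reward_probs) == 3, !is.null(names(reward_probs)),
            length(iti_range) == 2, iti_range[1] <= iti_range[2],
            max_stim_run >= 1, max_reward_run >= 1)
  if (abs(us_time - (odor_duration + wait_duration)) > 1e-9)
    stop("us_time must equal odor_duration + wait_duration")
  structure(list(n_trials = n_trials, reward_probs = reward_probs,
                 odor_duration = odor_duration,
                 wait_duration = wait_duration, us_time = us_time,
                 iti_range = iti_range, max_stim_run = max_stim_run,
                 max_reward_run = max_reward_run),
            class = "task_config")
}

#' Generate a pseudo-random trial sequence
#'
#' Draws a balanced CS sequence (equal counts per odor) under the constraint
#' that no stimulus appears more than `max_stim_run` times in a row, then
#' draws rewards per the CS-specific reward probability under the constraint
#' that no more than `max_reward_run` consecutive trials are rewarded.
#'
#' The stimulus sequence is drawn position by position, sampling among the
#' still-available CS types (probability proportional to the remaining count
#' of each type) while excluding any type that would exceed the run limit;
#' dead ends trigger a restart.
#'
#' Two reward schemes are provided. The default, `"balanced"`, keeps the
#' proportion of rewarded trials per cue constant across sessions (as the
#' odor proportions are): each cue's rewards are assigned as an exact
#' quota (`round(p * n_per_type)` trials) in random order, and any run of
#' more than `max_reward_run` consecutive rewarded trials is repaired by
#' moving a rewarded CS50 draw from inside the run to a randomly chosen
#' legal unrewarded position of the same cue, preserving the marginal
#' reward frequency exactly. The `"resample"` scheme instead draws rewards
#' independently per trial and resamples the offending draw whenever a run
#' would exceed the limit; because CS100 is deterministically rewarded,
#' this forces non-reward onto CS50 trials after lucky streaks and biases
#' the realized CS50 reward frequency well below its programmed
#' probability, so it is not the default. Both schemes necessarily leave a
#' local bias (a CS50 trial right after a long rewarded run is less likely
#' rewarded); only the marginal frequency differs.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed for reproducibility.
#' @param reward_scheme `"balanced"` (exact per-cue quota,
#'   marginal-preserving repair) or `"resample"` (independent draws with
#'   per-trial resampling).
#' @return Data frame with columns `trial` (1-based), `cs` (character,
#'   `"CS100"`/`"CS50"`/`"CS0"`), `rewarded` (logical) and `onset` (s from
#'   session start).
#' @export
generate_trial_sequence <- function(config = task_config(), seed = NULL,
                                    reward_scheme = c("balanced",
                                                      "resample")) {
  stopifnot(inherits(config, "task_config"))
  reward_scheme <- match.arg(reward_scheme)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  types <- names(config$reward_probs)
  per_type <- n / 3L

  cs_idx <- draw_balanced_runs(n, n_types = 3L, per_type = per_type,
                               max_run = config$max_stim_run)
  cs <- types[cs_idx]
  probs <- unname(config$reward_probs[cs])

  rewarded <- if (reward_scheme == "resample")
    draw_rewards_with_run_limit(probs, config$max_reward_run)
  else
    draw_rewards_balanced(cs, config$reward_probs, config$max_reward_run)

  onset <- cumsum(stats::runif(n, config$iti_range[1], config$iti_range[2]))
  data.frame(trial = seq_len(n), cs = cs, rewarded = rewarded,
             onset = onset)
}

# Balanced sequence of type indices with bounded runs; restarts on dead ends.
draw_balanced_runs <- function(n, n_types, per_type, max_run,
                               max_restarts = 1000L) {
  for (attempt in seq_len(max_restarts)) {
    remaining <- rep.int(per_type, n_types)
    out <- integer(n)
    run_len <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      w <- as.numeric(remaining)
      if (i > 1L && run_len >= max_run) w[out[i - 1L]] <- 0
      if (all(w <= 0)) { ok <- FALSE; break }
      pick <- sample.int(n_types, 1L, prob = w)
      run_len <- if (i > 1L && pick == out[i - 1L]) run_len + 1L else 1L
      out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
    }
    if (ok) return(out)
  }
  stop("could not draw a balanced sequence with the stimulus-run ",
       "constraint after ", max_restarts, " restarts")
}

# Quota-based reward assignment: exactly round(p * n_type) rewarded trials
# per cue, in random order; forbidden rewarded runs are repaired by moving a
# stochastic-cue reward from inside the run to a random legal position of
# the same cue. Preserves the marginal reward frequency per cue exactly.
draw_rewards_balanced <- function(cs, reward_probs, max_run,
                                  max_iter = 10000L) {
  n <- length(cs)
  rewarded <- logical(n)
  for (ty in names(reward_probs)) {
    idx <- which(cs == ty)
    k <- round(reward_probs[[ty]] * length(idx))
    rewarded[sample(idx, k)] <- TRUE
  }
  movable <- reward_probs > 0 & reward_probs < 1
  # length of rewarded run ending at i if rewarded[i] were TRUE
  run_if_true <- function(i) {
    len <- 1L; j <- i - 1L
    while (j >= 1L && rewarded[j]) { len <- len + 1L; j <- j - 1L }
    j <- i + 1L
    while (j <= n && rewarded[j]) { len <- len + 1L; j <- j + 1L }
    len
  }
  for (iter in seq_len(max_iter)) {
    r <- rle(rewarded)
    bad <- which(r$values & r$lengths > max_run)
    if (!length(bad)) return(rewarded)
    ends <- cumsum(r$lengths)
    b <- bad[1]
    run_idx <- (ends[b] - r$lengths[b] + 1L):ends[b]
    cand_out <- run_idx[movable[cs[run_idx]]]
    if (!length(cand_out))
      stop("reward-run constraint unsatisfiable: run of deterministically ",
           "rewarded trials longer than max_reward_run")
    i_out <- cand_out[sample.int(length(cand_out), 1L)]
    rewarded[i_out] <- FALSE
    cand_in <- which(!rewarded & cs == cs[i_out])
    cand_in <- cand_in[vapply(cand_in, run_if_true, integer(1)) <= max_run]
    if (length(cand_in))
      rewarded[cand_in[sample.int(length(cand_in), 1L)]] <- TRUE
    # else: drop the reward; quota broken by one in a pathological layout
  }
  stop("reward-run repair did not converge")
}

# Bernoulli reward draws with a cap on consecutive rewarded trials.
draw_rewards_with_run_limit <- function(probs, max_run) {
  n <- length(probs)
  rewarded <- stats::runif(n) < probs
  run <- 0L
  for (i in seq_len(n)) {
    if (!rewarded[i]) { run <- 0L; next }
    if (run < max_run) { run <- run + 1L; next }
    # Adding trial i would create a rewarded run > max_run.
    if (probs[i] < 1) {
      rewarded[i] <- FALSE            # resampled draw conditioned on legality
      run <- 0L
    } else {
      # Deterministically rewarded cue: resample the most recent stochastic
      # trial inside the current run instead.
      j <- i - 1L
      while (j >= 1L && rewarded[j] && probs[j] >= 1) j <- j - 1L
      if (j < 1L || !rewarded[j])
        stop("reward-run constraint unsatisfiable: run of deterministically ",
             "rewarded trials longer than max_reward_run")
      rewarded[j] <- FALSE
      # Recompute run length ending at i.
      run <- 0L
      k <- i
      while (k >= 1L && rewarded[k]) { run <- run + 1L; k <- k - 1L }
    }
  }
  rewarded
}

#' Validate a trial sequence against the task invariants
#'
#' Checks strictly increasing onsets with inter-trial intervals inside the
#' configured jitter range, balanced CS counts, and the stimulus- and
#' reward-run limits.
#'
#' @param seq Trial sequence data frame as from [generate_trial_sequence()].
#' @param config The [task_config()] the sequence should satisfy.
#' @return `TRUE` invisibly if valid, otherwise an error.
#' @export
validate_trial_sequence <- function(seq, config = task_config()) {
  stopifnot(is.data.frame(seq),
            all(c("trial", "cs", "rewarded", "onset") %in% names(seq)))
  d <- diff(seq$onset)
  if (any(d <= 0)) stop("onsets not strictly increasing")
  if (any(d < config$iti_range[1] - 1e-9 | d > config$iti_range[2] + 1e-9))
    stop("inter-trial interval outside configured range")
  counts <- table(seq$cs)
  if (length(unique(counts)) != 1L)
    stop("CS counts not balanced across types")
  if (max_run_length(seq$cs) > config$max_stim_run)
    stop("stimulus-run constraint violated")
  if (max_run_length(seq$rewarded)["TRUE"] > config$max_reward_run)
    stop("reward-run constraint violated")
  invisible(TRUE)
}

# Longest run per value; returns named vector for logical input, scalar max
# for others.
max_run_length <- function(x) {
  r <- rle(as.character(x))
  if (is.logical(x)) {
    out <- c("TRUE" = 0L, "FALSE" = 0L)
    for (v in c("TRUE", "FALSE"))
      if (any(r$values == v)) out[v] <- max(r$lengths[r$values == v])
    out
  } else {
    max(r$lengths)
  }
}
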