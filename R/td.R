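#' Initial state values for the trial-based TD(0) model
#'
#' The model tracks five states: a pre-trial baseline state, one state per
#' conditioned stimulus at odor presentation, and an outcome state whose
#' value is fixed at 0 because each trial ends there. Two initializations
#' are supported: all zeros (naive animal, used for learning simulations)
#' and values pre-set to the programmed reward probabilities 0, 0.5 and 1
#' (trained animal, used to build scanner-session regressors).
#'
#' @param mode `"zeros"` or `"fmri"`.
#' @return Named numeric vector with elements `s0`, `CS0`, `CS50`, `CS100`.
#' @export
td_init_values <- function(mode = c("zeros", "fmri")) {
  mode <- match.arg(mode)
  if (mode == "zeros") c(s0 = 0, CS0 = 0, CS50 = 0, CS100 = 0)
  else                 c(s0 = 0, CS0 = 0, CS50 = 0.5, CS100 = 1)
}

#' One TD(0) trial update
#'
#' Within a trial three timepoints are modeled: baseline (t = 0), odor
#' (t = 1) and outcome (t = 2). The prediction error compares successive
#' value predictions, `delta_t = r_t + V(s_t) - V(s_t-1)`, and updates the
#' previous state's value by `alpha * delta_t`. Rewards are 0 at t = 0 and
#' t = 1 and binary at t = 2; the outcome state's value is identically 0.
#' Both prediction errors are computed from the values holding at the start
#' of the trial, then both updates are applied (the two updates touch
#' disjoint states, so the order is immaterial); set
#' `sequential_within_trial = TRUE` to instead apply the t = 1 update before
#' computing `delta2` (numerically identical here, provided for
#' explicitness).
#'
#' @param values Named value vector as from [td_init_values()].
#' @param cs CS label of the trial (`"CS100"`, `"CS50"`, `"CS0"`).
#' @param rewarded Logical outcome of the trial.
#' @param alpha Learning rate in `[0, 1]` (0 freezes all values).
#' @param sequential_within_trial Apply the baseline-state update before
#'   computing the outcome prediction error.
#' @return List with updated `values`, `delta1`, `delta2`, and the pre-update
#'   `v_cs` and `v0` used for the trial.
#' @export
td_step <- function(values, cs, rewarded, alpha,
                    sequential_within_trial = FALSE) {
  if (!cs %in% c("CS100", "CS50", "CS0")) stop("unknown CS label: ", cs)
  stopifnot(alpha >= 0, alpha <= 1, all(is.finite(values)))
  r2 <- as.numeric(rewarded)
  v0 <- values[["s0"]]
  v_cs <- values[[cs]]
  delta1 <- 0 + v_cs - v0             # r1 = 0
  delta2 <- r2 + 0 - v_cs             # V(s2) = 0
  if (sequential_within_trial) {
    values[["s0"]] <- v0 + alpha * delta1
    delta2 <- r2 + 0 - values[[cs]]   # V(s1) unchanged by delta1; identical
    values[[cs]] <- values[[cs]] + alpha * delta2
  } else {
    values[["s0"]] <- v0 + alpha * delta1
    values[[cs]] <- v_cs + alpha * delta2
  }
  list(values = values, delta1 = delta1, delta2 = delta2,
       v_cs = v_cs, v0 = v0)
}

#' Run the TD(0) model over one trial sequence
#'
#' Applies [td_step()] sequentially over the trials of a session and records,
#' per trial, the value of the presented CS at presentation time (before the
#' trial's update), the baseline-state value, and the two prediction errors.
#' The prediction error at outcome is `delta2 = r - V(CS)`.
#'
#' @param seq Trial sequence as from [generate_trial_sequence()].
#' @param alpha Learning rate in (0, 1].
#' @param init `"zeros"`, `"fmri"`, or a named value vector.
#' @return Data frame of class `td_trace` with columns `trial`, `cs`,
#'   `rewarded`, `v0`, `v_cs`, `delta1`, `delta2`, plus attributes `alpha`
#'   and `final_values`.
#' @export
run_td_session <- function(seq, alpha = 0.28, init = "zeros") {
  values <- if (is.character(init)) td_init_values(init) else init
  stopifnot(all(c("s0", "CS0", "CS50", "CS100") %in% names(values)))
  n <- nrow(seq)
  v0 <- v_cs <- d1 <- d2 <- numeric(n)
  for (i in seq_len(n)) {
    st <- td_step(values, seq$cs[i], seq$rewarded[i], alpha)
    values <- st$values
    v0[i] <- st$v0; v_cs[i] <- st$v_cs
    d1[i] <- st$delta1; d2[i] <- st$delta2
  }
  out <- data.frame(trial = seq$trial, cs = seq$cs, rewarded = seq$rewarded,
                    v0 = v0, v_cs = v_cs, delta1 = d1, delta2 = d2)
  attr(out, "alpha") <- alpha
  attr(out, "final_values") <- values
  class(out) <- c("td_trace", "data.frame")
  out
}

#' Simulate TD learning across many sessions
#'
#' Generates `n_sessions` fresh trial sequences, runs the TD(0) model on
#' each from zero initial values, and averages the per-trial CS values and
#' absolute outcome prediction errors across sessions, trial-index-aligned
#' within each CS type.
#'
#' @param n_sessions Number of simulated sessions.
#' @param alpha Learning rate.
#' @param config [task_config()] used to generate each sequence.
#' @param seed Optional seed.
#' @return List with data frames `value` and `abs_delta`, each with columns
#'   `cs`, `presentation` (per-type presentation index), `mean`, `sem`.
#' @export
simulate_td_sessions <- function(n_sessions = 100, alpha = 0.28,
                                 config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per_type <- config$n_trials / 3L
  types <- names(config$reward_probs)
  v <- d <- array(NA_real_, c(n_sessions, 3L, per_type),
                  dimnames = list(NULL, types, NULL))
  for (s in seq_len(n_sessions)) {
    seq_s <- generate_trial_sequence(config)
    td <- run_td_session(seq_s, alpha = alpha, init = "zeros")
    for (ty in types) {
      sel <- td$cs == ty
      v[s, ty, ] <- td$v_cs[sel]
      d[s, ty, ] <- abs(td$delta2[sel])
    }
  }
  summarize <- function(a) {
    do.call(rbind, lapply(types, function(ty) {
      m <- a[, ty, , drop = FALSE]
      data.frame(cs = ty, presentation = seq_len(per_type),
                 mean = apply(m, 3, mean),
                 sem = apply(m, 3, stats::sd) / sqrt(n_sessions))
    }))
  }
  list(value = summarize(v), abs_delta = summarize(d),
       alpha = alpha, n_sessions = n_sessions)
}

#' Split CS50 trials by the outcome of the previous CS50 trial
#'
#' Each CS50 trial except the first is assigned to the `R` group if the
#' immediately preceding CS50 trial (ignoring interleaved CS100/CS0 trials)
#' was rewarded, else to the `N` group.
#'
#' @param td A `td_trace` from [run_td_session()] (any data frame with
#'   `cs`, `rewarded` and `v_cs` columns works).
#' @return List with `groups` (data frame: `trial`, `history` in
#'   `c("R","N")`, `v_cs`) and `mean_v` (named means for R and N). Empty
#'   groups data frame if fewer than two CS50 trials.
#' @export
split_by_history <- function(td) {
  i50 <- which(td$cs == "CS50")
  if (length(i50) < 2L) {
    message("fewer than two CS50 trials; history split is empty")
    return(list(groups = data.frame(trial = integer(), history = character(),
                                    v_cs = numeric()),
                mean_v = c(R = NA_real_, N = NA_real_)))
  }
  prev_outcome <- td$rewarded[i50][-length(i50)]
  cur <- i50[-1L]
  groups <- data.frame(trial = td$trial[cur],
                       history = ifelse(prev_outcome, "R", "N"),
                       v_cs = td$v_cs[cur])
  mean_v <- c(R = mean(groups$v_cs[groups$history == "R"]),
              N = mean(groups$v_cs[groups$history == "N"]))
  list(groups = groups, mean_v = mean_v)
}
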