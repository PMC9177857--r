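# Independent oracle implementations used to cross-check the package's
# vectorized / optimized code paths on small inputs.

# Literal trial-by-trial TD(0) recursion: three timepoints, delta = r +
# V(current) - V(previous), previous state's value incremented by
# alpha * delta.
oracle_td <- function(seq, alpha, init = c(s0 = 0, CS0 = 0, CS50 = 0,
                                           CS100 = 0)) {
  V <- init
  out <- data.frame(v0 = numeric(nrow(seq)), v_cs = NA_real_,
                    delta1 = NA_real_, delta2 = NA_real_)
  for (i in seq_len(nrow(seq))) {
    cs <- seq$cs[i]
    r <- c(0, 0, as.numeric(seq$rewarded[i]))
    v_states <- c(V[["s0"]], V[[cs]], 0)   # V(s2) fixed at 0
    d1 <- r[2] + v_states[2] - v_states[1]
    d2 <- r[3] + v_states[3] - v_states[2]
    out$v0[i] <- v_states[1]; out$v_cs[i] <- v_states[2]
    out$delta1[i] <- d1; out$delta2[i] <- d2
    V[["s0"]] <- V[["s0"]] + alpha * d1
    V[[cs]] <- V[[cs]] + alpha * d2
  }
  out
}

# Brute-force auROC: all pairs, ties counted half.
oracle_auroc <- function(x, y) {
  tot <- 0
  for (xi in x) for (yi in y)
    tot <- tot + (xi > yi) + 0.5 * (xi == yi)
  tot / (length(x) * length(y))
}

# Poisson IRLS with log link (optionally with intercept), from scratch.
oracle_poisson_irls <- function(X, y, intercept = TRUE, tol = 1e-12,
                                max_iter = 200) {
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    beta_new <- solve(t(X) %*% (W * X), t(X) %*% (W * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(beta)
}

# Loop-based population distance from baseline.
oracle_distance <- function(rates, B) {
  n_tr <- dim(rates)[2]; n_bin <- dim(rates)[3]
  d <- matrix(0, n_tr, n_bin)
  for (tr in seq_len(n_tr)) for (b in seq_len(n_bin)) {
    acc <- 0
    for (u in seq_len(dim(rates)[1]))
      acc <- acc + (rates[u, tr, b] - B[u])^2
    d[tr, b] <- sqrt(acc)
  }
  d
}

# Loop-based mean cross-type Pearson correlation at one bin.
oracle_cross_corr <- function(A, B) {
  vals <- c()
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    if (stats::sd(A[, i]) == 0 || stats::sd(B[, j]) == 0) next
    vals <- c(vals, stats::cor(A[, i], B[, j]))
  }
  mean(vals)
}

# OLS by explicit normal equations.
oracle_ols <- function(X, y) as.vector(solve(t(X) %*% X, t(X) %*% y))

# A tiny hand-rollable trial sequence with fixed onsets 10 s apart.
make_seq <- function(cs, rewarded, iti = 10) {
  data.frame(trial = seq_along(cs), cs = cs, rewarded = rewarded,
             onset = seq_along(cs) * iti)
}

# Raster set built from explicit spike times (list per unit of data frames
# trial/time), for deterministic unit-analysis fixtures.
make_raster_set <- function(spike_list, seq, window = c(-3, 6),
                            region = "Tu") {
  units <- lapply(seq_along(spike_list), function(u)
    list(id = sprintf("u%03d", u), archetype = NA_character_,
         tuning = NA_character_, pref_cs = NA_character_,
         baseline = NA_real_, spikes = spike_list[[u]]))
  structure(list(units = units, seq = seq, window = window,
                 region = region),
            class = "unit_raster_set")
}

# Poisson spikes at a constant rate in a window, one data frame row per
# spike.
poisson_trial_spikes <- function(trial, rate, window) {
  n <- stats::rpois(1, rate * diff(window))
  if (n == 0) return(data.frame(trial = integer(0), time = numeric(0)))
  data.frame(trial = trial, time = sort(stats::runif(n, window[1],
                                                     window[2])))
}
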