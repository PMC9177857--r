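#' Hemodynamic response kernel for mouse BOLD
#'
#' Unit-peak gamma-family kernel with a configurable time to peak
#' (default 1.0 s; the rodent response peaks several-fold faster than the
#' canonical human response). The kernel is zero outside `[0, duration]`.
#'
#' @param peak_time Time to peak, s (> 0).
#' @param shape Gamma shape parameter (> 1).
#' @param duration Kernel support, s.
#' @param tr If given, the kernel is also returned sampled at this
#'   repetition time.
#' @return An `hrf` object: list with `fun` (vectorized kernel function of
#'   time in s), `peak_time`, `peak` (always 1), and, when `tr` is given,
#'   `kernel` (samples at `0, tr, 2 tr, ...`).
#' @export
mouse_hrf <- function(peak_time = 1.0, shape = 4, duration = 8, tr = NULL) {
  stopifnot(peak_time > 0, shape > 1)
  scale <- peak_time / (shape - 1)
  dmax <- stats::dgamma(peak_time, shape = shape, scale = scale)
  fun <- function(t) {
    out <- stats::dgamma(t, shape = shape, scale = scale) / dmax
    out[t < 0 | t > duration] <- 0
    out
  }
  obj <- list(fun = fun, peak_time = peak_time, peak = 1,
              duration = duration)
  if (!is.null(tr)) obj$kernel <- fun(seq(0, duration, by = tr))
  structure(obj, class = "hrf")
}

# HRF-convolved regressor(s) sampled at the volume times: events are stick
# functions at arbitrary (acquisition-unaligned) onsets, convolved in
# continuous time and sampled at the volume grid.
convolve_events <- function(vol_times, onsets, amplitudes = NULL,
                            hrf = mouse_hrf(), collapse = TRUE) {
  if (!length(onsets)) {
    if (collapse) return(numeric(length(vol_times)))
    return(matrix(0, length(vol_times), 0))
  }
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  H <- outer(vol_times, onsets, function(t, o) hrf$fun(t - o))
  if (collapse) as.vector(H %*% amplitudes)
  else sweep(H, 2, amplitudes, "*")
}

#' Build an event-related design matrix
#'
#' Implements the study's session-level design variants. CS and US are
#' modeled as zero-duration events convolved with the HRF; parametric
#' modulators are mean-centered over their events and, for the
#' prediction-error variant, deliberately not orthogonalized against each
#' other. All variants append a lick-event regressor, an optional CSF
#' nuisance series and a constant term.
#'
#' * `"glm1"`: one regressor for all CS events plus a `V(CS)` parametric
#'   modulator; four US event types (reward after CS100, reward after
#'   CS50, non-reward after CS50, non-reward after CS0).
#' * `"glm2"`: separate CS100/CS50/CS0 regressors; the CS50 regressor is
#'   parametrically modulated by the previous CS50 outcome; four US types.
#' * `"glm3"`: separate CS regressors; one US regressor with two
#'   non-orthogonalized parametric modulators, `-V(CS)` and binary `r`.
#' * `"betaseries"`: one regressor per event (every CS and every US of
#'   every trial).
#'
#' @param seq Trial sequence.
#' @param n_vols Number of volumes.
#' @param tr Repetition time, s.
#' @param variant One of `"glm1"`, `"glm2"`, `"glm3"`, `"betaseries"`.
#' @param td `td_trace` supplying `V(CS)` (required for glm1/glm3; run
#'   with the trained-animal initialization for scanner sessions).
#' @param licks Optional data frame of lick times (`time_s`).
#' @param csf Optional numeric CSF nuisance series of length `n_vols`.
#' @param hrf An [mouse_hrf()] kernel.
#' @param us_delay US time after odor onset, s.
#' @return A `design_matrix` object: list with `X` (volumes x regressors,
#'   named columns), `vol_times`, `variant`, `events` (per-event metadata
#'   for beta-series designs), `hrf`.
#' @export
build_design <- function(seq, n_vols, tr = 1.3,
                         variant = c("glm1", "glm2", "glm3", "betaseries"),
                         td = NULL, licks = NULL, csf = NULL,
                         hrf = mouse_hrf(), us_delay = 2.7) {
  variant <- match.arg(variant)
  if (variant %in% c("glm1", "glm3") && is.null(td))
    stop("variant ", variant, " requires a TD trace for V(CS)")
  vol_times <- (seq_len(n_vols) - 1L) * tr
  on_cs <- seq$onset
  on_us <- seq$onset + us_delay
  us_type <- paste0("US_", seq$cs, ifelse(seq$rewarded, "R", "N"))
  stopifnot(all(us_type %in% c("US_CS100R", "US_CS50R", "US_CS50N",
                               "US_CS0N")))
  center <- function(x) x - mean(x)
  cols <- list()
  events <- NULL
  if (variant == "glm1") {
    cols[["CS"]] <- convolve_events(vol_times, on_cs, hrf = hrf)
    cols[["CSxV"]] <- convolve_events(vol_times, on_cs,
                                      center(td$v_cs), hrf = hrf)
    for (ty in c("US_CS100R", "US_CS50R", "US_CS50N", "US_CS0N"))
      cols[[ty]] <- convolve_events(vol_times, on_us[us_type == ty],
                                    hrf = hrf)
  } else if (variant == "glm2") {
    for (ty in c("CS100", "CS50", "CS0"))
      cols[[ty]] <- convolve_events(vol_times, on_cs[seq$cs == ty],
                                    hrf = hrf)
    i50 <- which(seq$cs == "CS50")
    hist_mod <- rep(0, length(i50))
    if (length(i50) >= 2L) {
      h <- ifelse(seq$rewarded[i50][-length(i50)], 1, -1)
      hist_mod[-1L] <- h - mean(h)   # first CS50 has no history; weight 0
    }
    cols[["CS50xHist"]] <- convolve_events(vol_times, on_cs[i50],
                                           hist_mod, hrf = hrf)
    for (ty in c("US_CS100R", "US_CS50R", "US_CS50N", "US_CS0N"))
      cols[[ty]] <- convolve_events(vol_times, on_us[us_type == ty],
                                    hrf = hrf)
  } else if (variant == "glm3") {
    for (ty in c("CS100", "CS50", "CS0"))
      cols[[ty]] <- convolve_events(vol_times, on_cs[seq$cs == ty],
                                    hrf = hrf)
    cols[["US"]] <- convolve_events(vol_times, on_us, hrf = hrf)
    cols[["USxNegV"]] <- convolve_events(vol_times, on_us,
                                         center(-td$v_cs), hrf = hrf)
    cols[["USxR"]] <- convolve_events(vol_times, on_us,
                                      center(as.numeric(seq$rewarded)),
                                      hrf = hrf)
  } else { # betaseries
    cs_mat <- convolve_events(vol_times, on_cs, hrf = hrf,
                              collapse = FALSE)
    colnames(cs_mat) <- sprintf("CS_t%03d", seq$trial)
    us_mat <- convolve_events(vol_times, on_us, hrf = hrf,
                              collapse = FALSE)
    colnames(us_mat) <- sprintf("US_t%03d", seq$trial)
    for (j in seq_len(ncol(cs_mat))) cols[[colnames(cs_mat)[j]]] <-
        cs_mat[, j]
    for (j in seq_len(ncol(us_mat))) cols[[colnames(us_mat)[j]]] <-
        us_mat[, j]
    events <- data.frame(column = c(colnames(cs_mat), colnames(us_mat)),
                         trial = rep(seq$trial, 2),
                         cs = rep(seq$cs, 2),
                         rewarded = rep(seq$rewarded, 2),
                         event = rep(c("CS", "US"), each = nrow(seq)))
  }
  if (!is.null(licks) && nrow(licks))
    cols[["licks"]] <- convolve_events(vol_times, licks$time_s, hrf = hrf)
  if (!is.null(csf)) {
    stopifnot(length(csf) == n_vols)
    cols[["csf"]] <- csf
  }
  cols[["constant"]] <- rep(1, n_vols)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(X = X, vol_times = vol_times, variant = variant,
                 events = events, hrf = hrf, tr = tr),
            class = "design_matrix")
}

#' Voxel-wise ordinary least squares fit
#'
#' Fits the design to every voxel's time series by OLS. A rank-deficient
#' design is an error naming the offending columns.
#'
#' @param image 4-D array (x, y, z, t) or `niftiImage`, or a time x voxel
#'   matrix.
#' @param design A `design_matrix`.
#' @param mask Optional logical array over the spatial grid; voxels
#'   outside are skipped (betas `NA`).
#' @return A `beta_map`: list with `beta` (voxel x regressor matrix),
#'   `sigma2` (residual variance per voxel), `df`, `dim` (spatial
#'   dimensions, or `NULL` for matrix input), `labels` (regressor names).
#' @export
fit_glm <- function(image, design, mask = NULL) {
  X <- design$X
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.matrix(image) && length(dim(image)) == 2L) {
    Y <- image
    spatial <- NULL
  } else {
    arr <- as.array(image)
    stopifnot(length(dim(arr)) == 4L)
    spatial <- dim(arr)[1:3]
    Y <- t(matrix(arr, prod(spatial), dim(arr)[4]))
  }
  stopifnot(nrow(Y) == nrow(X))
  keep <- if (is.null(mask)) rep(TRUE, ncol(Y)) else as.vector(mask)
  beta <- matrix(NA_real_, ncol(Y), ncol(X),
                 dimnames = list(NULL, colnames(X)))
  sigma2 <- rep(NA_real_, ncol(Y))
  co <- qr.coef(qr_x, Y[, keep, drop = FALSE])
  res <- Y[, keep, drop = FALSE] - X %*% co
  df <- nrow(X) - ncol(X)
  beta[keep, ] <- t(co)
  sigma2[keep] <- colSums(res^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df, dim = spatial,
                 labels = colnames(X)),
            class = "beta_map")
}

# Extract one contrast value per voxel from a beta map.
contrast_values <- function(bm, contrast) {
  if (is.character(contrast)) {
    stopifnot(contrast %in% bm$labels)
    bm$beta[, contrast]
  } else {
    stopifnot(length(contrast) == length(bm$labels))
    as.vector(bm$beta %*% contrast)
  }
}

#' Group-level one-sample t test with two-sided FDR thresholding
#'
#' Voxel-wise one-sample t across sessions on a contrast of the
#' session-level betas, thresholded per tail with Benjamini-Hochberg at
#' `q` (default 0.025 per tail, i.e. two-sided 0.05).
#'
#' @param beta_maps List of `beta_map`s, one per session, on a common
#'   grid.
#' @param contrast Regressor name, or a numeric contrast vector over the
#'   regressors.
#' @param q FDR level per tail.
#' @return List with `t`, `p` (two-sided), `mask_pos`, `mask_neg`, `mask`
#'   (either tail), `n_sessions`, `dim`.
#' @export
group_stats <- function(beta_maps, contrast, q = 0.025) {
  n <- length(beta_maps)
  if (n < 2) stop("need at least two sessions for group statistics")
  V <- vapply(beta_maps, contrast_values, contrast = contrast,
              numeric(nrow(beta_maps[[1]]$beta)))
  m <- rowMeans(V)
  s <- apply(V, 1, stats::sd)
  tval <- m / (s / sqrt(n))
  tval[s == 0 & m == 0] <- 0
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  ok <- is.finite(p)
  mask_pos <- mask_neg <- rep(FALSE, length(p))
  pos <- ok & tval > 0
  if (any(pos))
    mask_pos[pos] <- stats::p.adjust(p[pos] / 2, method = "BH") < q
  neg <- ok & tval < 0
  if (any(neg))
    mask_neg[neg] <- stats::p.adjust(p[neg] / 2, method = "BH") < q
  list(t = tval, p = p, mask_pos = mask_pos, mask_neg = mask_neg,
       mask = mask_pos | mask_neg, n_sessions = n,
       dim = beta_maps[[1]]$dim)
}

#' Intersect thresholded maps
#'
#' Voxel-wise logical AND of two or more masks on the same grid (e.g. the
#' CS100 > CS50 and CS50 > CS0 contrast masks defining strictly monotonic
#' value coding).
#'
#' @param ... Logical vectors or arrays of identical dimensions.
#' @return Logical mask of the same shape.
#' @export
intersect_maps <- function(...) {
  masks <- list(...)
  stopifnot(length(masks) >= 2)
  d1 <- dim(masks[[1]]); l1 <- length(masks[[1]])
  for (m in masks[-1])
    if (length(m) != l1 || !identical(dim(m), d1))
      stop("masks are not on the same grid")
  Reduce(`&`, masks)
}

#' Percent signal change per region and event type
#'
#' Scales event betas to the region-wise signal intensity: `100 * beta *
#' kernel_peak / mean constant-term beta of the region`, so that regions
#' with low absolute intensity (ventral structures under a surface coil)
#' are not under-represented.
#'
#' @param bm A `beta_map`.
#' @param labels Integer vector/array of region labels per voxel (0 =
#'   background).
#' @param regressors Regressor names to report (default: all event
#'   regressors, i.e. everything except `licks`, `csf`, `constant`).
#' @param kernel_peak Peak of the HRF kernel used in the design.
#' @return Data frame `region`, `regressor`, `psc`; regions whose mean
#'   constant beta is zero are flagged `NA` with a message.
#' @export
percent_signal_change <- function(bm, labels, regressors = NULL,
                                  kernel_peak = 1) {
  labels <- as.vector(labels)
  stopifnot(length(labels) == nrow(bm$beta))
  if (is.null(regressors))
    regressors <- setdiff(bm$labels, c("licks", "csf", "constant"))
  out <- list()
  for (r in sort(unique(labels[labels > 0]))) {
    sel <- labels == r
    const <- mean(bm$beta[sel, "constant"])
    if (!is.finite(const) || const == 0) {
      message("region ", r, ": zero constant beta; PSC undefined")
      psc <- rep(NA_real_, length(regressors))
    } else {
      psc <- vapply(regressors, function(rg)
        100 * mean(bm$beta[sel, rg]) * kernel_peak / const, numeric(1))
    }
    out[[length(out) + 1L]] <- data.frame(region = r,
                                          regressor = regressors,
                                          psc = psc)
  }
  do.call(rbind, out)
}

#' Frame-wise displacement from realignment parameters
#'
#' Sum of the absolute first differences of the six rigid-body
#' realignment parameters (three translations, three rotations) per
#' volume; the first volume has FD 0.
#'
#' @param motion Volumes x 6 matrix of realignment parameters.
#' @return Numeric FD series (same units as the parameters).
#' @export
framewise_displacement <- function(motion) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  c(0, rowSums(abs(diff(motion))))
}

#' Label events as low motion by frame-wise displacement
#'
#' An event is low motion iff the FD of the volume at the event and of
#' the following volume are both at or below the threshold (default
#' 0.05 mm), the frames that carry the peak of the fast mouse
#' hemodynamic response.
#'
#' @param fd FD series from [framewise_displacement()].
#' @param vol_times Volume acquisition times, s.
#' @param onsets Event onsets, s.
#' @param threshold FD threshold.
#' @return Logical vector per event.
#' @export
stratify_events_by_motion <- function(fd, vol_times, onsets,
                                      threshold = 0.05) {
  stopifnot(length(fd) == length(vol_times))
  vapply(onsets, function(on) {
    i <- findInterval(on, vol_times)
    i <- max(i, 1L)
    j <- min(i + 1L, length(fd))
    fd[i] <= threshold && fd[j] <= threshold
  }, logical(1))
}

#' Beta-series functional connectivity with group inference
#'
#' For each session, Pearson correlations between per-trial beta series
#' of region pairs (for one event type) are Fisher z-transformed; group
#' significance is a one-sample t test over sessions per pair, corrected
#' with Bonferroni (ROI mode) or per-tail Benjamini-Hochberg at `q`
#' (voxel mode); group correlations are the hyperbolic tangent of the
#' mean z.
#'
#' @param series_list List of sessions; each a trials x region matrix of
#'   beta estimates for the event type (>= 10 rows recommended).
#' @param correction `"bonferroni"` or `"fdr"`.
#' @param alpha Family-wise level for Bonferroni mode.
#' @param q FDR level per tail for FDR mode.
#' @return List with `group_r`, `t`, `p`, `significant` (region x region
#'   matrices; diagonal r = 1), `n_sessions`. Pairs constant in some
#'   session are skipped (`NA`) with a message.
#' @export
beta_series_connectivity <- function(series_list,
                                     correction = c("bonferroni", "fdr"),
                                     alpha = 0.05, q = 0.025) {
  correction <- match.arg(correction)
  n_reg <- ncol(series_list[[1]])
  n_ses <- length(series_list)
  z <- array(NA_real_, c(n_ses, n_reg, n_reg))
  skipped <- 0L
  for (s in seq_len(n_ses)) {
    M <- series_list[[s]]
    stopifnot(ncol(M) == n_reg)
    sds <- apply(M, 2, stats::sd)
    r <- suppressWarnings(stats::cor(M))
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
    skipped <- skipped + sum(sds == 0)
    r[r > 1 - 1e-12] <- 1 - 1e-12
    r[r < -1 + 1e-12] <- -1 + 1e-12
    z[s, , ] <- atanh(r)
  }
  if (skipped) message(skipped, " constant beta series skipped")
  mz <- apply(z, c(2, 3), mean)
  sz <- apply(z, c(2, 3), stats::sd)
  tval <- mz / (sz / sqrt(n_ses))
  p <- 2 * stats::pt(-abs(tval), df = n_ses - 1)
  diag(p) <- NA
  up <- upper.tri(p)
  sig <- matrix(FALSE, n_reg, n_reg)
  if (correction == "bonferroni") {
    p_adj <- p * sum(up)
    sig[up] <- !is.na(p[up]) & p_adj[up] < alpha
  } else {
    pos <- up & !is.na(tval) & tval > 0
    neg <- up & !is.na(tval) & tval < 0
    if (any(pos)) sig[pos] <- stats::p.adjust(p[pos] / 2, "BH") < q
    if (any(neg)) sig[neg] <- stats::p.adjust(p[neg] / 2, "BH") < q
  }
  sig <- sig | t(sig)
  group_r <- tanh(mz)
  diag(group_r) <- 1
  dn <- colnames(series_list[[1]])
  if (!is.null(dn))
    dimnames(group_r) <- dimnames(p) <- dimnames(sig) <-
      dimnames(tval) <- list(dn, dn)
  list(group_r = group_r, t = tval, p = p, significant = sig,
       n_sessions = n_ses)
}

#' Simulate a 4-D BOLD phantom with labeled regions
#'
#' A small labeled grid (abstract regions, not anatomy) whose voxel time
#' series are region-specific linear combinations of the design's
#' regressors plus AR(1) noise. Optionally a shared per-trial CS
#' amplitude series can drive chosen regions, creating ground-truth
#' beta-series connectivity.
#'
#' @param design A `design_matrix` (any variant).
#' @param region_effects Regions x regressors matrix of amplitudes;
#'   column names must be design columns (missing columns default to 0).
#'   Region means (the constant term) are added automatically if not
#'   given.
#' @param grid_shape 3-D grid dimensions; regions are consecutive slabs
#'   along x.
#' @param noise_sd Innovation SD of the AR(1) noise.
#' @param ar AR(1) coefficient.
#' @param baseline Constant signal level added to every voxel.
#' @param trial_amplitudes Optional regions x trials matrix; region rows
#'   receive additional CS responses with these per-trial amplitudes
#'   (requires `trial_onsets`).
#' @param trial_onsets Event onsets (s) used with `trial_amplitudes`.
#' @param seed Optional seed.
#' @return List with `image` (`niftiImage`, 4-D), `labels` (`niftiImage`,
#'   3-D), `truth` (regions x regressors amplitude matrix including the
#'   constant), `n_regions`.
#' @export
simulate_bold <- function(design, region_effects,
                          grid_shape = c(24, 24, 4), noise_sd = 1,
                          ar = 0.3, baseline = 100,
                          trial_amplitudes = NULL, trial_onsets = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region_effects <- as.matrix(region_effects)
  n_reg <- nrow(region_effects)
  X <- design$X
  n_vols <- nrow(X)
  eff <- matrix(0, n_reg, ncol(X), dimnames = list(NULL, colnames(X)))
  common <- intersect(colnames(region_effects), colnames(X))
  eff[, common] <- region_effects[, common]
  if (!("constant" %in% colnames(region_effects)))
    eff[, "constant"] <- baseline
  labels <- array(0L, grid_shape)
  xs <- split(seq_len(grid_shape[1]),
              cut(seq_len(grid_shape[1]), n_reg, labels = FALSE))
  for (r in seq_len(n_reg)) labels[xs[[r]], , ] <- r
  extra <- matrix(0, n_vols, n_reg)
  if (!is.null(trial_amplitudes)) {
    stopifnot(!is.null(trial_onsets),
              ncol(trial_amplitudes) == length(trial_onsets),
              nrow(trial_amplitudes) == n_reg)
    H <- convolve_events(design$vol_times, trial_onsets,
                         hrf = design$hrf, collapse = FALSE)
    extra <- H %*% t(trial_amplitudes)
  }
  arr <- array(0, c(grid_shape, n_vols))
  flat_labels <- as.vector(labels)
  n_vox <- prod(grid_shape)
  Y <- matrix(0, n_vols, n_vox)
  for (r in seq_len(n_reg)) {
    mu <- X %*% eff[r, ] + extra[, r]
    vox <- which(flat_labels == r)
    for (v in vox) {
      e <- stats::rnorm(n_vols, 0, noise_sd)
      noise <- if (ar != 0)
        as.numeric(stats::filter(e, ar, method = "recursive")) else e
      Y[, v] <- mu + noise
    }
  }
  arr <- array(t(Y), c(grid_shape, n_vols))
  list(image = RNifti::asNifti(arr), labels = RNifti::asNifti(labels),
       truth = eff, n_regions = n_reg)
}
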