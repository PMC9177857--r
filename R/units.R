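#' Per-trial firing rates of every unit in a time window
#'
#' @param rs A `unit_raster_set` from [simulate_population()] (or with the
#'   same structure).
#' @param window Length-2 interval, s relative to odor onset (half-open).
#' @return Units x trials matrix of rates in Hz.
#' @export
raster_rates <- function(rs, window) {
  n_tr <- nrow(rs$seq)
  width <- diff(window)
  out <- matrix(0, length(rs$units), n_tr)
  for (u in seq_along(rs$units)) {
    sp <- rs$units[[u]]$spikes
    sel <- sp$time >= window[1] & sp$time < window[2]
    if (any(sel)) {
      tb <- tabulate(sp$trial[sel], nbins = n_tr)
      out[u, ] <- tb / width
    }
  }
  rownames(out) <- vapply(rs$units, `[[`, character(1), "id")
  out
}

#' Task-window responsiveness of every unit
#'
#' Compares, per unit, trial type and task window, the within-trial paired
#' rates (baseline -1.5..-0.5 s vs window) with a Friedman test over
#' trials, corrects all p-values jointly with Benjamini-Hochberg, and
#' labels significant units excited or inhibited by the sign of the median
#' paired difference. With two paired conditions the Friedman test reduces
#' to a sign-type test; an exact two-sided Wilcoxon signed-rank alternative
#' is available via `method = "signed-rank"`.
#'
#' @param rs A `unit_raster_set`.
#' @param windows Named list of task windows (s).
#' @param baseline_window Baseline window (s).
#' @param p_threshold Significance level after correction.
#' @param method `"friedman"` or `"signed-rank"`.
#' @return Data frame `unit`, `cs`, `window`, `p`, `p_adj`, `label`
#'   (`"excited"`, `"inhibited"` or `"none"`).
#' @export
test_responsiveness <- function(rs,
                                windows = list(CS = c(0, 1),
                                               wait = c(1, 2.5),
                                               US = c(2.7, 3.7)),
                                baseline_window = c(-1.5, -0.5),
                                p_threshold = 0.05,
                                method = c("friedman", "signed-rank")) {
  method <- match.arg(method)
  base <- raster_rates(rs, baseline_window)
  types <- unique(rs$seq$cs)
  rows <- list()
  for (w in names(windows)) {
    rate <- raster_rates(rs, windows[[w]])
    for (ty in types) {
      sel <- rs$seq$cs == ty
      for (u in seq_len(nrow(rate))) {
        x <- base[u, sel]; y <- rate[u, sel]
        d <- y - x
        p <- if (all(d == 0)) 1 else if (method == "friedman") {
          stats::friedman.test(cbind(x, y))$p.value
        } else {
          suppressWarnings(stats::wilcox.test(y, x, paired = TRUE,
                                              exact = FALSE)$p.value)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          unit = rownames(rate)[u], cs = ty, window = w, p = p,
          med_diff = stats::median(d))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p[is.na(out$p)] <- 1
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$label <- ifelse(out$p_adj < p_threshold,
                      ifelse(out$med_diff > 0, "excited", "inhibited"),
                      "none")
  out$label[out$p_adj < p_threshold & out$med_diff == 0] <- "none"
  out$med_diff <- NULL
  out
}

#' Area under the ROC curve between two rate distributions
#'
#' Probability that a draw from `x` exceeds a draw from `y`, with ties
#' counted half (midrank convention). 0.5 means no separation; values
#' above (below) 0.5 mean `x` tends to be larger (smaller).
#'
#' @param x,y Numeric samples.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  r <- rank(c(x, y))
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Sliding-window auROC response profiles
#'
#' For each unit, the across-trial firing-rate distribution in a 500 ms
#' window slid in 125 ms steps is compared against the unit's pooled
#' baseline distribution (rates in -1.8..-1.4 s across all trials) with
#' [auroc()]. Profiles are computed per condition (CS0, unrewarded CS50,
#' rewarded CS50, CS100) and concatenated in that order.
#'
#' @param rs A `unit_raster_set`.
#' @param bin Sliding window width, s.
#' @param step Window step, s.
#' @param range Time range covered by window starts (s from odor onset).
#' @param baseline_window Baseline pooling window (s).
#' @return Matrix units x (4 * n windows) with attributes `times` (window
#'   centers, one block) and `condition` (per-column condition label).
#' @export
auroc_profile <- function(rs, bin = 0.5, step = 0.125,
                          range = c(-1, 4.9), baseline_window = c(-1.8, -1.4)) {
  starts <- seq(range[1], range[2] - bin + 1e-9, by = step)
  centers <- starts + bin / 2
  conds <- list(CS0 = rs$seq$cs == "CS0",
                CS50N = rs$seq$cs == "CS50" & !rs$seq$rewarded,
                CS50R = rs$seq$cs == "CS50" & rs$seq$rewarded,
                CS100 = rs$seq$cs == "CS100")
  base <- raster_rates(rs, baseline_window)
  win_rates <- lapply(starts, function(s0) raster_rates(rs, c(s0, s0 + bin)))
  n_u <- length(rs$units)
  out <- matrix(NA_real_, n_u, 4L * length(starts))
  for (u in seq_len(n_u)) {
    prof <- numeric(0)
    for (cn in names(conds)) {
      sel <- conds[[cn]]
      prof <- c(prof, vapply(win_rates, function(wr)
        auroc(wr[u, sel], base[u, ]), numeric(1)))
    }
    out[u, ] <- prof
  }
  rownames(out) <- vapply(rs$units, `[[`, character(1), "id")
  attr(out, "times") <- centers
  attr(out, "condition") <- rep(names(conds), each = length(starts))
  out
}

#' Hierarchical clustering of auROC profiles into functional groups
#'
#' PCA reduces the concatenated auROC profiles to their first `n_pcs`
#' components; units are then clustered by average-linkage agglomeration
#' on Euclidean distances and the tree is cut at `cutoff` (a fraction of
#' the maximum merge height by default, or an absolute height). Each flat
#' cluster is assigned to a functional group by threshold rules on its
#' mean profile: predominantly below 0.5 in the task window = `inhibited`;
#' rising and elevated late in the wait = `ramping`; elevated at CS with
#' the wait back near baseline = `transient`; otherwise `sustained`.
#'
#' @param profiles Matrix from [auroc_profile()].
#' @param n_pcs Number of principal components used.
#' @param cutoff Tree-cut height.
#' @param cutoff_mode `"normalized"` (fraction of the maximum linkage
#'   height) or `"absolute"`.
#' @param linkage Linkage method for [stats::hclust()].
#' @return List `cluster` (integer per unit), `group` (character per
#'   unit), `cluster_group` (named map cluster -> group), `tree`
#'   (`hclust`), `scores` (PC scores).
#' @export
cluster_units <- function(profiles, n_pcs = 5, cutoff = 0.5,
                          cutoff_mode = c("normalized", "absolute"),
                          linkage = "average") {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(nrow(profiles) >= 2)
  pca <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  avail <- sum(pca$sdev > 1e-12)
  if (avail < n_pcs) {
    message("PCA rank ", avail, " < ", n_pcs, "; using ", avail,
            " components")
    n_pcs <- avail
  }
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  tree <- stats::hclust(stats::dist(scores), method = linkage)
  h <- if (cutoff_mode == "normalized") cutoff * max(tree$height) else cutoff
  cl <- stats::cutree(tree, h = h)
  groups <- vapply(sort(unique(cl)), function(k) {
    classify_cluster_profile(colMeans(profiles[cl == k, , drop = FALSE]),
                             attr(profiles, "times"),
                             attr(profiles, "condition"))
  }, character(1))
  names(groups) <- as.character(sort(unique(cl)))
  list(cluster = cl, group = unname(groups[as.character(cl)]),
       cluster_group = groups, tree = tree, scores = scores)
}

# Threshold rules mapping a mean auROC profile to a functional group.
# Value-driven epochs are judged on the strong-value conditions (CS100 and
# rewarded CS50).
classify_cluster_profile <- function(profile, times, condition,
                                     thr = 0.04) {
  sel_cond <- condition %in% c("CS100", "CS50R")
  tt <- rep(times, length.out = length(profile))
  p <- profile[sel_cond]
  t2 <- tt[sel_cond]
  m <- function(a, b) mean(p[t2 >= a & t2 < b])
  cs_m <- m(0, 1)
  wait_m <- m(1, 2.5)
  wait_early <- m(1, 1.75)
  wait_late <- m(1.75, 2.5)
  task_all <- mean(profile[tt >= 0 & tt < 2.5])
  if (task_all < 0.5 - thr) return("inhibited")
  if (wait_late > 0.5 + thr && wait_late - wait_early > 0.02)
    return("ramping")
  if (cs_m > 0.5 + thr && (wait_m - 0.5) < (cs_m - 0.5) / 2)
    return("transient")
  "sustained"
}

#' Test one unit for monotonic reward-probability coding or CS dominance
#'
#' A unit codes monotonic reward probability if its trial-wise rates
#' satisfy `{R0} < {R50}` and `{R50} < {R100}` by two-tailed Wilcoxon
#' rank-sum tests (both p < `p_threshold`, locations ordered accordingly);
#' inequalities are reversed for units from inhibited clusters. If
#' monotonic coding fails, CS dominance requires the strongest response to
#' differ significantly from the second strongest (lowest vs second lowest
#' for inhibited units).
#'
#' @param r0,r50,r100 Trial-wise rates (Hz) per CS type in the tested
#'   window (CS window for transient, wait window for ramping clusters).
#' @param inhibited Use the inverted inequalities.
#' @param p_threshold Per-test significance level.
#' @param min_trials Minimum trials per CS; below it the unit is `neither`
#'   (flagged).
#' @return List `label` (`"monotonic"`, `"dominant"`, `"neither"`),
#'   `dominant_cs` (or `NA`), `p` (named p-values), `flagged`.
#' @export
test_monotonic_rp <- function(r0, r50, r100, inhibited = FALSE,
                              p_threshold = 0.05, min_trials = 5) {
  if (min(length(r0), length(r50), length(r100)) < min_trials)
    return(list(label = "neither", dominant_cs = NA_character_,
                p = c(low = NA, high = NA), flagged = TRUE))
  w <- function(a, b) suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE)$p.value)
  p_low <- w(r0, r50); p_high <- w(r50, r100)
  means <- c(CS0 = mean(r0), CS50 = mean(r50), CS100 = mean(r100))
  ordered_ok <- if (inhibited)
    means["CS0"] > means["CS50"] && means["CS50"] > means["CS100"]
  else
    means["CS0"] < means["CS50"] && means["CS50"] < means["CS100"]
  if (!is.na(p_low) && !is.na(p_high) &&
      p_low < p_threshold && p_high < p_threshold && ordered_ok)
    return(list(label = "monotonic", dominant_cs = NA_character_,
                p = c(low = p_low, high = p_high), flagged = FALSE))
  # dominance: strongest vs second strongest response
  ord <- order(means, decreasing = !inhibited)
  samples <- list(CS0 = r0, CS50 = r50, CS100 = r100)
  first <- names(means)[ord[1]]; second <- names(means)[ord[2]]
  p_dom <- w(samples[[first]], samples[[second]])
  if (!is.na(p_dom) && p_dom < p_threshold)
    return(list(label = "dominant", dominant_cs = first,
                p = c(low = p_low, high = p_high, dom = p_dom),
                flagged = FALSE))
  list(label = "neither", dominant_cs = NA_character_,
       p = c(low = p_low, high = p_high, dom = p_dom), flagged = FALSE)
}

#' Population-level monotonic coding of the non-monotonic remainder
#'
#' Removes the individually monotonic units from a cluster and asks
#' whether the remaining units still carry a monotonic reward-probability
#' signal as a population: their per-trial summed rate is compared across
#' CS types with a one-way ANOVA and Tukey post-hoc contrasts.
#'
#' @param rate_mat Units x trials rate matrix (one window).
#' @param cs Per-trial CS labels.
#' @param monotonic Logical per unit; `TRUE` units are removed.
#' @return List `ordering` (CS names by increasing population response),
#'   `anova_p`, `tukey` (matrix from [stats::TukeyHSD()]),
#'   `population_monotonic` (both adjacent Tukey contrasts significant and
#'   correctly ordered), `n_units_used`; `NULL` (with a warning) if no
#'   units remain.
#' @export
distributed_coding_test <- function(rate_mat, cs, monotonic) {
  keep <- !monotonic
  if (!any(keep)) {
    warning("no non-monotonic units remain; distributed coding undefined")
    return(NULL)
  }
  y <- colSums(rate_mat[keep, , drop = FALSE])
  dat <- data.frame(y = y, cs = factor(cs, levels = c("CS0", "CS50",
                                                      "CS100")))
  fit <- stats::aov(y ~ cs, data = dat)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$cs
  means <- tapply(y, dat$cs, mean)
  get <- function(a, b) {
    key1 <- paste(a, b, sep = "-"); key2 <- paste(b, a, sep = "-")
    if (key1 %in% rownames(tk)) tk[key1, ] else
      { r <- tk[key2, ]; r["diff"] <- -r["diff"]; r }
  }
  c1 <- get("CS50", "CS0"); c2 <- get("CS100", "CS50")
  pop_mono <- c1["diff"] > 0 && c1["p adj"] < 0.05 &&
    c2["diff"] > 0 && c2["p adj"] < 0.05
  list(ordering = names(sort(means)), anova_p = anova_p, tukey = tk,
       population_monotonic = unname(pop_mono),
       n_units_used = sum(keep))
}

#' Per-trial firing-rate jump at the US
#'
#' Rate difference `d = fr_after - fr_prior` around outcome delivery,
#' where `fr_prior` is the rate in the 500 ms before the US (2.2..2.7 s
#' after odor onset) and `fr_after` the rate in a short-latency
#' (2.7..3.2 s) or long-latency (3.2..4.5 s) response window.
#'
#' @param rs A `unit_raster_set`.
#' @param after `"A"` (2.7..3.2 s) or `"B"` (3.2..4.5 s).
#' @return Units x trials matrix of rate jumps (Hz).
#' @export
us_rate_jump <- function(rs, after = c("A", "B")) {
  after <- match.arg(after)
  win <- if (after == "A") c(2.7, 3.2) else c(3.2, 4.5)
  raster_rates(rs, win) - raster_rates(rs, c(2.2, 2.7))
}

#' Test one unit for reward surprise
#'
#' A unit encodes reward surprise if, in either US window, (a) its mean
#' rate jump on rewarded CS50 trials is positive and (b) the rewarded-CS50
#' jumps exceed the CS100 jumps in a two-tailed Wilcoxon rank-sum test.
#' For inhibited-cluster units both criteria are inverted.
#'
#' @param d50_a,d100_a Trial-wise rate jumps (rewarded CS50, CS100) in the
#'   short-latency window.
#' @param d50_b,d100_b Same for the long-latency window (optional; omit to
#'   test one window only).
#' @param inhibited Invert the criteria.
#' @param p_threshold Significance level.
#' @return List `surprise` (logical), `window` (which window satisfied the
#'   criteria first, or `NA`), `p` (per window).
#' @export
test_reward_surprise <- function(d50_a, d100_a, d50_b = NULL,
                                 d100_b = NULL, inhibited = FALSE,
                                 p_threshold = 0.05) {
  one <- function(d50, d100) {
    if (is.null(d50)) return(list(ok = FALSE, p = NA_real_))
    p <- suppressWarnings(stats::wilcox.test(d50, d100,
                                             exact = FALSE)$p.value)
    ok <- if (inhibited)
      mean(d50) < 0 && !is.na(p) && p < p_threshold &&
        mean(d50) < mean(d100)
    else
      mean(d50) > 0 && !is.na(p) && p < p_threshold &&
        mean(d50) > mean(d100)
    list(ok = ok, p = p)
  }
  ra <- one(d50_a, d100_a); rb <- one(d50_b, d100_b)
  win <- if (ra$ok) "A" else if (rb$ok) "B" else NA_character_
  list(surprise = ra$ok || rb$ok, window = win,
       p = c(A = ra$p, B = rb$p))
}

#' Test one unit for outcome discrimination at the US
#'
#' Flags the unit if its post-US rate (`fr_after`, either latency window)
#' is larger on rewarded than on unrewarded CS50 trials by a two-tailed
#' Wilcoxon rank-sum test (smaller for inhibited-cluster units). The
#' opposite direction is not scored.
#'
#' @param after50r_a,after50n_a Trial-wise `fr_after` in the short-latency
#'   window for rewarded / unrewarded CS50 trials.
#' @param after50r_b,after50n_b Same for the long-latency window
#'   (optional).
#' @param inhibited Invert the direction.
#' @param p_threshold Significance level.
#' @return List `discriminates` (logical), `window`, `p`.
#' @export
test_outcome_discrimination <- function(after50r_a, after50n_a,
                                        after50r_b = NULL,
                                        after50n_b = NULL,
                                        inhibited = FALSE,
                                        p_threshold = 0.05) {
  one <- function(r, n) {
    if (is.null(r)) return(list(ok = FALSE, p = NA_real_))
    p <- suppressWarnings(stats::wilcox.test(r, n, exact = FALSE)$p.value)
    dir_ok <- if (inhibited) mean(r) < mean(n) else mean(r) > mean(n)
    list(ok = !is.na(p) && p < p_threshold && dir_ok, p = p)
  }
  ra <- one(after50r_a, after50n_a); rb <- one(after50r_b, after50n_b)
  win <- if (ra$ok) "A" else if (rb$ok) "B" else NA_character_
  list(discriminates = ra$ok || rb$ok, window = win,
       p = c(A = ra$p, B = rb$p))
}

#' Chance level for strict response orderings across the three cues
#'
#' Discriminative units respond with different intensity to all three CS
#' (all three pairwise two-tailed rank-sum tests significant). Since
#' 3! = 6 strict orderings exist, the count expected by chance for any
#' specific ordering (e.g. CS100 > CS50 > CS0) is the number of
#' discriminative units divided by 6.
#'
#' @param rates_by_unit List, one element per unit: list with trial-rate
#'   vectors `r0`, `r50`, `r100`.
#' @param p_threshold Per-test significance level.
#' @return List `n_discriminative`, `expected_per_ordering`, `observed`
#'   (named counts per ordering among discriminative units).
#' @export
chance_level_monotonic <- function(rates_by_unit, p_threshold = 0.05) {
  orderings <- character(0)
  n_disc <- 0L
  for (u in rates_by_unit) {
    w <- function(a, b) suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE)$p.value)
    ps <- c(w(u$r0, u$r50), w(u$r50, u$r100), w(u$r0, u$r100))
    if (any(is.na(ps)) || any(ps >= p_threshold)) next
    n_disc <- n_disc + 1L
    means <- c(CS0 = mean(u$r0), CS50 = mean(u$r50), CS100 = mean(u$r100))
    orderings <- c(orderings,
                   paste(names(sort(means, decreasing = TRUE)),
                         collapse = ">"))
  }
  observed <- if (length(orderings)) table(orderings) else table(character(0))
  list(n_discriminative = n_disc,
       expected_per_ordering = n_disc / 6,
       observed = observed)
}

#' History and satiety modulation of CS50 responses
#'
#' CS50 trials are annotated by cue-specific outcome history (previous
#' CS50 rewarded or not) and by satiety context (immediately preceding
#' trial CS100 or CS0); each annotated trial contributes its response
#' value to the matching group(s). A one-way ANOVA across the four groups
#' is followed by Tukey contrasts, from which the history pair
#' (`lastCS50_R - lastCS50_N`) and the satiety pair (`prior_CS100 -
#' prior_CS0`) are reported.
#'
#' @param values Per-trial response values for all trials of the session
#'   (e.g., a cluster's mean rate in the CS or wait window).
#' @param seq Trial sequence the values align to.
#' @return List `anova_p`, `history` (diff, p), `satiety` (diff, p),
#'   `group_means`; comparisons with an empty group are `NA` (skipped with
#'   a message).
#' @export
history_satiety_effects <- function(values, seq) {
  stopifnot(length(values) == nrow(seq))
  n <- nrow(seq)
  history <- rep(NA_character_, n)
  i50 <- which(seq$cs == "CS50")
  if (length(i50) >= 2L)
    history[i50[-1L]] <- ifelse(seq$rewarded[i50][-length(i50)], "R", "N")
  prior_cs <- c(NA_character_, seq$cs[-n])
  is50 <- seq$cs == "CS50"
  memb <- list(
    lastCS50_R = which(is50 & !is.na(history) & history == "R"),
    lastCS50_N = which(is50 & !is.na(history) & history == "N"),
    prior_CS100 = which(is50 & !is.na(prior_cs) & prior_cs == "CS100"),
    prior_CS0 = which(is50 & !is.na(prior_cs) & prior_cs == "CS0"))
  sizes <- lengths(memb)
  if (any(sizes == 0)) message("empty CS50 subgroup(s): ",
                               paste(names(memb)[sizes == 0],
                                     collapse = ", "))
  long <- do.call(rbind, lapply(names(memb), function(g) {
    if (!length(memb[[g]])) return(NULL)
    data.frame(value = values[memb[[g]]], group = g)
  }))
  group_means <- tapply(long$value, long$group, mean)
  if (length(unique(long$group)) < 2)
    return(list(anova_p = NA_real_, history = c(diff = NA, p = NA),
                satiety = c(diff = NA, p = NA), group_means = group_means))
  long$group <- factor(long$group)
  fit <- stats::aov(value ~ group, data = long)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pick <- function(a, b) {
    k1 <- paste(a, b, sep = "-"); k2 <- paste(b, a, sep = "-")
    if (k1 %in% rownames(tk))
      c(diff = unname(tk[k1, "diff"]), p = unname(tk[k1, "p adj"]))
    else if (k2 %in% rownames(tk))
      c(diff = -unname(tk[k2, "diff"]), p = unname(tk[k2, "p adj"]))
    else c(diff = NA_real_, p = NA_real_)
  }
  list(anova_p = anova_p,
       history = pick("lastCS50_R", "lastCS50_N"),
       satiety = pick("prior_CS100", "prior_CS0"),
       group_means = group_means)
}
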