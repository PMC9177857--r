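test_that("HRF kernel peaks at one and vanishes outside its support", {
  h <- mouse_hrf(peak_time = 1, tr = 1.3)
  expect_equal(h$fun(1), 1)
  expect_equal(max(h$fun(seq(0, 8, by = 0.001))), 1, tolerance = 1e-6)
  expect_equal(h$fun(c(-0.5, 8.4)), c(0, 0))
  expect_equal(h$kernel, h$fun(seq(0, 8, by = 1.3)))
  # a single stick reproduces the shifted kernel
  tms <- seq(0, 20, by = 0.65)
  y <- olfrl:::convolve_events(tms, onsets = 4.2, hrf = h)
  expect_equal(y, h$fun(tms - 4.2))
})

test_that("design variants have the documented structure", {
  s <- generate_trial_sequence(task_config(120), seed = 471)
  td <- run_td_session(s, 0.28, init = "fmri")
  licks <- data.frame(time_s = s$onset + 3)
  csf <- stats::rnorm(900)
  d1 <- build_design(s, 900, variant = "glm1", td = td, licks = licks,
                     csf = csf)
  expect_equal(colnames(d1$X),
               c("CS", "CSxV", "US_CS100R", "US_CS50R", "US_CS50N",
                 "US_CS0N", "licks", "csf", "constant"))
  d2 <- build_design(s, 900, variant = "glm2", licks = licks, csf = csf)
  # 3 CS + 1 modulator + 4 US + licks + CSF + constant
  expect_equal(ncol(d2$X), 11L)
  d3 <- build_design(s, 900, variant = "glm3", td = td)
  expect_true(all(c("US", "USxNegV", "USxR") %in% colnames(d3$X)))
  db <- build_design(s, 900, variant = "betaseries")
  expect_equal(sum(grepl("^CS_t", colnames(db$X))), 120L)
  expect_equal(sum(grepl("^US_t", colnames(db$X))), 120L)
  expect_error(build_design(s, 900, variant = "glm1"), "requires")
  # modulator columns are mean-centered over their events
  expect_lt(abs(sum(d1$X[, "CSxV"]) /
                  sum(d1$X[, "CS"])), 0.2)
})

test_that("trained-init TD values give first-trial modulator amplitudes", {
  s <- generate_trial_sequence(task_config(120), seed = 481)
  td <- run_td_session(s, 0.28, init = "fmri")
  first <- !duplicated(s$cs)
  v <- td$v_cs[first]
  names(v) <- s$cs[first]
  expect_equal(v[["CS0"]], 0)
  expect_equal(v[["CS50"]], 0.5)
  expect_equal(v[["CS100"]], 1)
})

test_that("noiseless phantoms are recovered exactly and nuisance is inert", {
  s <- generate_trial_sequence(task_config(30), seed = 491)
  td <- run_td_session(s, 0.28, init = "fmri")
  n_vols <- ceiling((max(s$onset) + 10) / 1.3)
  des <- build_design(s, n_vols, variant = "glm1", td = td)
  eff <- matrix(c(1, 2, 0.5, -1, 0, 0), nrow = 3, byrow = TRUE,
                dimnames = list(NULL, c("CS", "CSxV")))
  ph <- simulate_bold(des, eff, grid_shape = c(6, 6, 2), noise_sd = 0,
                      seed = 492)
  bm <- fit_glm(ph$image, des)
  lab <- as.vector(as.array(ph$labels))
  for (r in 1:3) {
    expect_equal(unname(bm$beta[lab == r, "CS"]),
                 rep(unname(eff[r, "CS"]), sum(lab == r)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(bm$beta[lab == r, "CSxV"]),
                 rep(unname(eff[r, "CSxV"]), sum(lab == r)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # a nuisance column orthogonal to the task leaves task betas unchanged
  des2 <- des
  set.seed(493)
  z <- stats::rnorm(n_vols)
  z <- stats::residuals(stats::lm(z ~ des$X + 0))
  des2$X <- cbind(des$X[, 1:6, drop = FALSE], extra = z,
                  constant = des$X[, "constant"])
  bm2 <- fit_glm(ph$image, des2)
  expect_equal(bm2$beta[, "CSxV"], bm$beta[, "CSxV"], tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear column", {
  s <- generate_trial_sequence(task_config(30), seed = 501)
  des <- build_design(s, 260, variant = "glm2")
  des$X <- cbind(des$X, dup = des$X[, "CS100"])
  img <- matrix(stats::rnorm(260 * 4), 260, 4)
  expect_error(fit_glm(img, des), "rank deficient.*dup|dup.*rank")
})

test_that("modulator betas match the normal-equations oracle and are
           invariant to modulator mean", {
  s <- generate_trial_sequence(task_config(30), seed = 511)
  td <- run_td_session(s, 0.28, init = "fmri")
  n_vols <- 260
  des <- build_design(s, n_vols, variant = "glm3", td = td)
  set.seed(512)
  y <- des$X %*% stats::rnorm(ncol(des$X)) + stats::rnorm(n_vols, 0, 0.5)
  bm <- fit_glm(matrix(y, ncol = 1), des)
  expect_equal(unname(bm$beta[1, ]), oracle_ols(des$X, y),
               tolerance = 1e-10)
  # adding a constant to a modulator before centering changes nothing
  td_shift <- td
  td_shift$v_cs <- td$v_cs + 5
  des_shift <- build_design(s, n_vols, variant = "glm3", td = td_shift)
  expect_equal(des_shift$X[, "USxNegV"], des$X[, "USxNegV"],
               tolerance = 1e-12)
})

test_that("group inference recovers planted effects and respects symmetry", {
  set.seed(521)
  n_vox <- 200; n_ses <- 10
  planted <- c(rep(1.5, 20), rep(0, n_vox - 20))
  maps <- lapply(1:n_ses, function(k) {
    b <- matrix(planted + stats::rnorm(n_vox, 0, 0.5), ncol = 1,
                dimnames = list(NULL, "CSxV"))
    structure(list(beta = b, sigma2 = rep(1, n_vox), df = 100,
                   dim = NULL, labels = "CSxV"), class = "beta_map")
  })
  g <- group_stats(maps, "CSxV")
  expect_true(all(g$mask_pos[1:20]))
  expect_lt(mean(g$mask[21:n_vox]), 0.05)
  # all-zero betas -> empty mask
  zero_maps <- lapply(maps, function(m) { m$beta[] <- 0; m })
  gz <- group_stats(zero_maps, "CSxV")
  expect_false(any(gz$mask))
  # sign flip swaps the positive and negative masks
  neg_maps <- lapply(maps, function(m) { m$beta <- -m$beta; m })
  gn <- group_stats(neg_maps, "CSxV")
  expect_equal(gn$mask_neg, g$mask_pos)
  expect_equal(gn$mask_pos, g$mask_neg)
  expect_error(group_stats(maps[1], "CSxV"), "at least two")
})

test_that("FDR control holds on null simulations", {
  set.seed(531)
  fp <- vapply(1:200, function(k) {
    maps <- lapply(1:8, function(j) {
      b <- matrix(stats::rnorm(50), ncol = 1,
                  dimnames = list(NULL, "c"))
      structure(list(beta = b, sigma2 = rep(1, 50), df = 40, dim = NULL,
                     labels = "c"), class = "beta_map")
    })
    any(group_stats(maps, "c")$mask)
  }, logical(1))
  # per-tail BH at 0.025: family-wise null rejections should stay modest
  expect_lt(mean(fp), 0.12)
})

test_that("map intersection is a voxelwise AND on a common grid", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(intersect_maps(a, b), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(intersect_maps(a, a), a)
  expect_false(any(intersect_maps(a, !a)))
  expect_error(intersect_maps(a, c(TRUE, FALSE)), "same grid")
})

test_that("monotonic value regions survive both contrasts intersected", {
  set.seed(541)
  s <- generate_trial_sequence(task_config(30), seed = 542)
  n_vols <- ceiling((max(s$onset) + 10) / 1.3)
  des <- build_design(s, n_vols, variant = "glm2")
  # region 1: amplitudes ordered with value; region 2: flat
  eff <- matrix(0, 2, 3, dimnames = list(NULL, c("CS100", "CS50", "CS0")))
  eff[1, ] <- c(3, 1.5, 0)
  sessions <- lapply(1:8, function(k)
    fit_glm(simulate_bold(des, eff, grid_shape = c(4, 4, 2),
                          noise_sd = 0.4, seed = 542 + k)$image, des))
  g_hi <- group_stats(sessions, c(1, -1, 0, rep(0, ncol(des$X) - 3)))
  g_lo <- group_stats(sessions, c(0, 1, -1, rep(0, ncol(des$X) - 3)))
  inter <- intersect_maps(g_hi$mask_pos, g_lo$mask_pos)
  lab <- as.vector(as.array(simulate_bold(des, eff,
                                          grid_shape = c(4, 4, 2),
                                          noise_sd = 0)$labels))
  expect_true(all(inter[lab == 1]))
  expect_false(any(inter[lab == 2]))
})

test_that("percent signal change scales with the regional constant", {
  s <- generate_trial_sequence(task_config(30), seed = 551)
  n_vols <- ceiling((max(s$onset) + 10) / 1.3)
  des <- build_design(s, n_vols, variant = "glm2")
  eff <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "CS100"))
  ph <- simulate_bold(des, eff, grid_shape = c(4, 4, 1), noise_sd = 0,
                      baseline = 100)
  bm <- fit_glm(ph$image, des)
  psc <- percent_signal_change(bm, as.array(ph$labels))
  p1 <- psc$psc[psc$region == 1 & psc$regressor == "CS100"]
  expect_equal(p1, 1, tolerance = 1e-6)   # 1% planted response
  expect_equal(psc$psc[psc$region == 2 & psc$regressor == "CS100"], 0,
               tolerance = 1e-6)
  # doubling the constant halves the PSC
  ph2 <- simulate_bold(des, eff, grid_shape = c(4, 4, 1), noise_sd = 0,
                       baseline = 200)
  psc2 <- percent_signal_change(fit_glm(ph2$image, des),
                                as.array(ph2$labels))
  expect_equal(psc2$psc[psc2$region == 1 & psc2$regressor == "CS100"],
               p1 / 2, tolerance = 1e-6)
})

test_that("frame-wise displacement and motion stratification behave", {
  m <- matrix(0, 50, 6)
  expect_equal(framewise_displacement(m), rep(0, 50))
  m2 <- m; m2[20:50, 1] <- 0.1    # one 0.1-unit step in a translation
  fd <- framewise_displacement(m2)
  expect_equal(fd[20], 0.1)
  expect_equal(sum(fd), 0.1)
  vt <- (0:49) * 1.3
  expect_true(all(stratify_events_by_motion(rep(0, 50), vt,
                                            c(5, 20, 40))))
  low <- stratify_events_by_motion(fd, vt, c(5, 24.3, 40))
  expect_equal(low, c(TRUE, FALSE, TRUE))
  # threshold sweep is monotone in retained events
  set.seed(561)
  fd_r <- abs(stats::rnorm(50, 0.05, 0.03))
  on <- stats::runif(20, 0, 60)
  kept <- vapply(c(0.01, 0.05, 0.1, 0.2), function(thr)
    sum(stratify_events_by_motion(fd_r, vt, on, thr)), numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("beta-series connectivity finds shared trial-amplitude structure", {
  set.seed(571)
  n_trials <- 40
  make_session <- function(shared_sd, noise_sd) {
    latent <- stats::rnorm(n_trials, 0, shared_sd)
    cbind(r1 = latent + stats::rnorm(n_trials, 0, noise_sd),
          r2 = latent + stats::rnorm(n_trials, 0, noise_sd),
          r3 = stats::rnorm(n_trials, 0, 1))
  }
  sessions <- lapply(1:12, function(k) make_session(1, 0.5))
  out <- beta_series_connectivity(sessions)
  expect_equal(unname(diag(out$group_r)), rep(1, 3))
  expect_gt(out$group_r["r1", "r2"], 0.5)
  expect_true(out$significant["r1", "r2"])
  expect_false(out$significant["r1", "r3"])
  # independent series: nominal-level rejections only
  null_sessions <- lapply(1:12, function(k) make_session(0, 1))
  out0 <- beta_series_connectivity(null_sessions)
  expect_lt(mean(out0$significant[upper.tri(out0$significant)]), 0.34)
  # constant series are skipped
  const_sessions <- lapply(sessions, function(m) { m[, 3] <- 2; m })
  expect_message(beta_series_connectivity(const_sessions), "skipped")
})

test_that("beta-series GLM recovers shared latent connectivity end to end", {
  set.seed(581)
  s <- generate_trial_sequence(task_config(21), seed = 582)
  n_vols <- ceiling((max(s$onset) + 10) / 1.3)
  des <- build_design(s, n_vols, variant = "betaseries")
  latent <- stats::rnorm(nrow(s), 0, 2)
  amp <- rbind(latent + stats::rnorm(nrow(s), 0, 0.3),
               latent + stats::rnorm(nrow(s), 0, 0.3))
  ph <- simulate_bold(des, matrix(0, 2, 1, dimnames = list(NULL, "CS")),
                      grid_shape = c(4, 4, 1), noise_sd = 0.3,
                      trial_amplitudes = amp, trial_onsets = s$onset,
                      seed = 583)
  bm <- fit_glm(ph$image, des)
  lab <- as.vector(as.array(ph$labels))
  cs_cols <- des$events$column[des$events$event == "CS"]
  ser <- vapply(1:2, function(r)
    colMeans(bm$beta[lab == r, cs_cols, drop = FALSE]),
    numeric(length(cs_cols)))
  expect_gt(stats::cor(ser[, 1], ser[, 2]), 0.5)
})
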