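# Window averaging, mixed-model fitting, backward elimination, R-squared,
# contralateral-covariate models, slopes and slope correlations.

test_that("window averages equal direct slices of the condition means", {
  arr <- array(3, c(2, 2, 3, 100))
  ws <- window_average(make_cond(arr), c(10, 60))
  expect_true(all(ws$mean_force_mN == 3))
  expect_equal(nrow(ws), 2 * 2 * 3)
  expect_setequal(unique(ws$hand_code), c(-0.5, 0.5))
  expect_setequal(unique(ws$side_code), c(-1, 0, 1))

  ramp <- array(0, c(1, 2, 3, 100))
  for (j in 1:2) for (k in 1:3) ramp[1, j, k, ] <- seq(0, 9.9, by = 0.1)
  wr <- window_average(make_cond(ramp), c(0, 100))
  expect_equal(unique(round(wr$mean_force_mN, 9)), mean(seq(0, 9.9, .1)))

  set.seed(1)
  arr2 <- array(rnorm(4 * 2 * 3 * 50), c(4, 2, 3, 50))
  w2 <- window_average(make_cond(arr2), c(20, 35))
  oracle <- apply(arr2[, , , 21:35, drop = FALSE], c(1, 2, 3), mean)
  expect_equal(w2$mean_force_mN[w2$participant == 3 & w2$hand == "right" &
                                  w2$side_code == 1],
               oracle[3, 2, 3], tolerance = 1e-12)
  expect_error(window_average(make_cond(arr2), c(60, 70)), "bounds")
})

test_that("noise-free data are reproduced exactly and the OLS limit holds", {
  d0 <- make_window_data(8, b_hand = 0, b_side = 0, icpt_sd = 4,
                         resid_sd = 0, intercept = 2)
  f0 <- fit_lmm(d0)
  co <- f0$coefficients
  expect_lt(abs(co$b[co$term == "hand_code"]), 1e-6)
  expect_lt(abs(co$b[co$term == "side_code"]), 1e-6)

  # zero participant-intercept variance in truth: fixed effects equal the
  # closed-form least-squares solution
  d <- make_window_data(10, b_hand = -4, b_side = 1, b_int = 4,
                        icpt_sd = 0, resid_sd = 2, seed = 5)
  fit <- fit_lmm(d)
  ols <- coef(lm(mean_force_mN ~ hand_code * side_code, data = d))
  expect_equal(fit$coefficients$b, unname(ols), tolerance = 1e-5)
})

test_that("the design coding is sum -0.5/+0.5 by -1/0/+1 with a product interaction", {
  d <- make_window_data(5, seed = 2, resid_sd = 1)
  fit <- fit_lmm(d)
  X <- model.matrix(fit$model)
  expect_setequal(unique(X[, "hand_code"]), c(-0.5, 0.5))
  expect_setequal(unique(X[, "side_code"]), c(-1, 0, 1))
  expect_equal(X[, "hand_code:side_code"], X[, "hand_code"] * X[, "side_code"],
               ignore_attr = TRUE)
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  d <- make_window_data(20, b_hand = 0, b_side = 0, icpt_sd = 3,
                        resid_sd = 1, seed = 7)
  fit <- fit_lmm(d, fixed = ~ 1)
  expect_lt(fit$marginal_R2, 1e-6)  # no fixed effects beyond the intercept
  expect_gt(fit$conditional_R2, 0.5)

  d2 <- make_window_data(15, b_hand = -4, b_side = 1, b_int = 4,
                         icpt_sd = 2, resid_sd = 1.5, seed = 8)
  fit2 <- fit_lmm(d2)
  m <- fit2$model
  vf <- var(as.vector(model.matrix(m) %*% lme4::fixef(m)))
  vr <- as.data.frame(lme4::VarCorr(m))$vcov[1]
  ve <- sigma(m)^2
  r2 <- nakagawa_r2(fit2)
  expect_equal(unname(r2["marginal"]), vf / (vf + vr + ve),
               tolerance = 1e-9)
  expect_equal(unname(r2["conditional"]), (vf + vr) / (vf + vr + ve),
               tolerance = 1e-9)
  expect_lte(r2["marginal"], r2["conditional"])
  expect_lte(r2["conditional"], 1)
})

test_that("backward elimination drops noise terms, keeps signal, respects marginality", {
  # pure noise: everything droppable goes, intercept-only model remains
  d0 <- make_window_data(12, icpt_sd = 1, resid_sd = 3, seed = 11)
  red0 <- drop1_eliminate(fit_lmm(d0))
  expect_equal(length(attr(terms(red0$fit$fixed), "term.labels")), 0L)
  expect_equal(nrow(red0$trail), 3L)
  # every dropped term had LRT p > .1 at its step (re-checkable trail)
  expect_true(all(red0$trail$p > 0.1))

  # strong interaction: retained together with both main effects
  d1 <- make_window_data(15, b_hand = 0, b_side = 0, b_int = 8,
                         icpt_sd = 1, resid_sd = 1, seed = 12)
  red1 <- drop1_eliminate(fit_lmm(d1))
  kept <- attr(terms(red1$fit$fixed), "term.labels")
  expect_true("hand_code:side_code" %in% kept)
  expect_true(all(c("hand_code", "side_code") %in% kept))
  expect_false("hand_code:side_code" %in% red1$trail$term)
})

test_that("the contralateral covariate model identifies the self-regression limit", {
  # opposite-hand force identical to the target: covariate b ~ 1, side ~ 0
  set.seed(3)
  d <- make_window_data(10, icpt_sd = 2, resid_sd = 0, seed = 3)
  shared <- rnorm(nrow(d) / 2, sd = 4)
  # identical per (participant, side) across hands
  d$mean_force_mN <- shared[d$participant +
                              10 * (match(d$side_code, c(-1, 0, 1)) - 1)]
  fit <- contralateral_model(d, "right")
  co <- fit$coefficients
  expect_equal(co$b[co$term == "contra_c"], 1, tolerance = 1e-6)
  expect_lt(abs(co$b[co$term == "side_code"]), 1e-6)
  # missing pairing is a hard error
  expect_error(contralateral_model(d[d$hand == "right", ], "right"),
               "pairing")
})

test_that("contralateral models recover opposite hand signs from generated data", {
  spec <- experiment_spec("stars", n_participants = 14, n_trials = 90)
  eff <- effect_params("stars")  # ipsilateral positive
  nz <- noise_params("stars")
  sim <- simulate_condition_averages(spec, eff, nz, seed = 41)
  ws <- window_average(sim$cond, c(60, 460))
  bl <- contralateral_model(ws, "left")$coefficients
  br <- contralateral_model(ws, "right")$coefficients
  expect_lt(bl$b[bl$term == "side_code"], 0)
  expect_gt(br$b[br$term == "side_code"], 0)

  effw <- effect_params("words", effect_onset_ms = 60,
                        effect_duration_ms = 400, effect_amplitude_mN = 10)
  simw <- simulate_condition_averages(
    experiment_spec("words", n_participants = 14, n_trials = 90),
    effw, noise_params("words"), seed = 42)
  wsw <- window_average(simw$cond, c(60, 460))
  blw <- contralateral_model(wsw, "left")$coefficients
  brw <- contralateral_model(wsw, "right")$coefficients
  expect_gt(blw$b[blw$term == "side_code"], 0)   # contralateral positive
  expect_lt(brw$b[brw$term == "side_code"], 0)
})

test_that("individual slopes shrink to the fixed effect when variance is zero", {
  d <- make_window_data(10, b_side = 2, icpt_sd = 0.5, resid_sd = 0.05,
                        seed = 4)
  st <- participant_slopes(d, "right")
  expect_equal(nrow(st), 10L)
  expect_lt(max(abs(st$slope - 2)), 0.1)
  st2 <- participant_slopes(d, "right")
  expect_identical(st, st2)  # deterministic
})

test_that("injected slope heterogeneity survives extraction within a shrinkage band", {
  spec <- experiment_spec("stars", n_participants = 20, n_trials = 360)
  eff <- effect_params("stars", participant_slope_sd_mN = 3)
  sim <- simulate_condition_averages(spec, eff, noise_params("stars"),
                                     seed = 77)
  ws <- window_average(sim$cond, c(60, 460))
  st <- participant_slopes(ws, "right")
  truthR <- sim$truth$side_slope_mN[sim$truth$hand == "right"]
  expect_gt(cor(st$slope, truthR[st$participant]), 0.6)
  expect_gt(sd(st$slope), 1.2)  # shrinkage-aware band around sd = 3
  expect_lt(sd(st$slope), 4.5)
})

test_that("slope correlations equal the closed-form Pearson computation", {
  t1 <- data.frame(participant = 1:4, experiment_kind = "stars",
                   window = "60-460", hand = "left",
                   slope = c(1, -1, 1, -1))
  t2 <- t1; t2$hand <- "right"; t2$slope <- c(1, 1, -1, -1)
  out <- slope_correlations(list(t1, t2))
  expect_equal(out$r, 0, tolerance = 1e-12)  # orthogonal contrasts
  expect_equal(out$n, 4L)

  set.seed(6)
  t3 <- t1; t3$slope <- rnorm(4); t4 <- t2; t4$slope <- rnorm(4)
  out2 <- slope_correlations(list(t3, t4))
  x <- t3$slope; y <- t4$slope
  r_formula <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out2$r, r_formula, tolerance = 1e-12)
  tt <- r_formula * sqrt(2 / (1 - r_formula^2))
  expect_equal(out2$p, 2 * pt(-abs(tt), df = 2), tolerance = 1e-9)

  # small overlap is skipped with a notice
  t5 <- data.frame(participant = 1:2, experiment_kind = "words",
                   window = "250-300", hand = "left", slope = c(1, 2))
  expect_message(out3 <- slope_correlations(list(t1, t5)), "skipping")
  expect_equal(nrow(out3), 0L)

  # significance stars follow the conventional thresholds
  t6 <- data.frame(participant = 1:30, experiment_kind = "arrows",
                   window = "100-150", hand = "left",
                   slope = seq(-1, 1, length.out = 30))
  t7 <- t6; t7$hand <- "right"
  t7$slope <- t6$slope + rnorm(30, sd = 0.1)
  out4 <- slope_correlations(list(t6, t7))
  expect_equal(out4$stars, "***")
})
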