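# Wiener first-passage machinery and chi-square quantile fitting.

test_that("first-passage density is zero before zero and symmetric for unbiased drift", {
  p <- ddm_params(a = 0.16, v = 0.25, ter = 0.3, s = 0.1)
  expect_equal(wiener_fpt_density(-0.1, "correct", p), 0)
  expect_equal(wiener_fpt_density(0, "correct", p), 0)

  ps <- ddm_params(a = 0.16, v = 0, ter = 0.3, s = 0.1)
  ts <- seq(0.05, 2, by = 0.05)
  expect_equal(wiener_fpt_density(ts, "correct", ps),
               wiener_fpt_density(ts, "error", ps))

  expect_error(ddm_params(a = -1, v = 0.2, ter = 0.3), "a must")
  expect_error(ddm_params(a = 0.1, v = 0.2, ter = 0.3, z = 0.2), "z must")
})

test_that("defective densities integrate to the choice probabilities (mass 1 total)", {
  for (pars in list(ddm_params(a = 0.16, v = 0.25, ter = 0, s = 0.1),
                    ddm_params(a = 0.08, v = 0.25, ter = 0, s = 0.1),
                    ddm_params(a = 0.16, v = 0.25, ter = 0, eta = 0.1, s = 0.1),
                    ddm_params(a = 0.12, v = 0.05, ter = 0, z = 0.04, s = 0.1))) {
    ic <- integrate(function(t) wiener_fpt_density(t, "correct", pars),
                    0, 30, rel.tol = 1e-8)$value
    ie <- integrate(function(t) wiener_fpt_density(t, "error", pars),
                    0, 30, rel.tol = 1e-8)$value
    expect_lt(abs(ic + ie - 1), 1e-4)
    expect_lt(abs(ic - ddm_choice_prob("correct", pars)), 1e-4)
  }
})

test_that("density agrees with the large-time sine series written out independently", {
  # independent oracle: the sine-series expansion evaluated directly, at
  # times where it converges quickly (moderate-to-large normalized time)
  p <- ddm_params(a = 0.16, v = 0.25, ter = 0, s = 0.1)
  vv <- -0.25 / 0.1; av <- 1.6; w <- 0.5  # upper boundary via reflection
  oracle <- function(t) {
    k <- 1:500
    pi * sum(k * exp(-k^2 * pi^2 * (t / av^2) / 2) * sin(k * pi * w)) *
      exp(-vv * av * w - vv^2 * t / 2) / av^2
  }
  for (t in c(0.15, 0.3, 0.6, 1.2)) {
    expect_lt(abs(wiener_fpt_density(t, "correct", p) - oracle(t)), 1e-6)
  }
})

test_that("defective CDF is nondecreasing with closed-form absorption limits", {
  p <- ddm_params(a = 0.16, v = 0.25, ter = 0, s = 0.1)
  ts <- seq(0, 3, by = 0.02)
  Fc <- ddm_defective_cdf(ts, "correct", p)
  Fe <- ddm_defective_cdf(ts, "error", p)
  expect_equal(Fc[1], 0)
  expect_equal(Fe[1], 0)
  expect_true(all(diff(Fc) >= -1e-10))
  expect_true(all(diff(Fe) >= -1e-10))

  # independent closed form for absorption of drifted Brownian motion
  vv <- 0.25 / 0.1; av <- 0.16 / 0.1; zv <- 0.08 / 0.1
  p_up <- (1 - exp(-2 * vv * zv)) / (1 - exp(-2 * vv * av))
  expect_lt(abs(ddm_defective_cdf(60, "correct", p) - p_up), 1e-6)
  expect_lt(abs(ddm_choice_prob("correct", p) - p_up), 1e-10)
  expect_lt(abs(ddm_defective_cdf(60, "correct", p) +
                  ddm_defective_cdf(60, "error", p) - 1), 1e-6)

  ps <- ddm_params(a = 0.16, v = 0, ter = 0, s = 0.1)
  expect_lt(abs(ddm_choice_prob("correct", ps) - 0.5), 1e-10)
})

test_that("density and CDF match an Euler-simulated first-passage sample", {
  p <- ddm_params(a = 0.16, v = 0.25, ter = 0, s = 0.1)
  n <- 2e4
  sim <- simulate_ddm_trials(p, n, deadline = Inf, seed = 31, dt = 5e-5)
  p_mc <- mean(sim$correct)
  p_th <- ddm_choice_prob("correct", p)
  expect_lt(abs(p_mc - p_th), 3.5 * sqrt(p_th * (1 - p_th) / n))
  rt <- sim$rt_ms[sim$correct] / 1000 - p$ter
  ts <- seq(0.05, 2.5, by = 0.01)
  Fc <- ddm_defective_cdf(ts, "correct", p) / p_th
  expect_lt(max(abs(ecdf(rt)(ts) - Fc)), 1.95 / sqrt(length(rt)))
})

test_that("bin probabilities telescope, mirror under symmetry, and sum to one", {
  sp <- ddm_truth()
  # single edge far in the tail: bin masses reduce to the choice probabilities
  wide <- ddm_bin_probabilities(sp, "accuracy",
                                edges_correct = c(1e3), edges_error = c(1e3))
  cp <- ddm_cue_params(sp, "accuracy")
  expect_lt(abs(wide$correct[2]), 1e-8)
  expect_lt(abs(sum(wide$correct) - ddm_choice_prob("correct", cp)), 1e-6)
  expect_lt(abs(sum(unlist(wide)) - 1), 1e-4)

  # v = 0, centered start: mirrored edges give mirrored bin vectors
  sym <- ddm_session_params(a_speed = 0.08, a_accuracy = 0.16,
                            ter_speed = 0.3, ter_accuracy = 0.3, v = 0)
  edges <- c(0.45, 0.55, 0.7)
  bb <- ddm_bin_probabilities(sym, "accuracy", edges, edges)
  expect_equal(bb$correct, bb$error, tolerance = 1e-8)

  # collapsed error class: single bin holding the whole error probability
  coll <- ddm_bin_probabilities(sp, "accuracy", edges_correct = edges,
                                edges_error = NULL)
  expect_length(coll$error, 1L)
  expect_lt(abs(coll$error - ddm_choice_prob("error", cp)), 1e-6)
})

test_that("bin masses match Monte-Carlo proportions in the same bins", {
  sp <- ddm_truth()
  cp <- ddm_cue_params(sp, "accuracy")
  n <- 2e4
  sim <- simulate_ddm_trials(cp, n, deadline = Inf, seed = 17, dt = 5e-5)
  rt <- sim$rt_ms / 1000
  edges_c <- unname(quantile(rt[sim$correct], c(0.1, 0.3, 0.5, 0.7, 0.9)))
  pred <- ddm_bin_probabilities(sp, "accuracy", edges_c, NULL)
  counts <- hist(rt[sim$correct], c(0, edges_c, Inf), plot = FALSE)$counts
  prop <- counts / n
  for (i in seq_along(pred$correct)) {
    se <- sqrt(pred$correct[i] * (1 - pred$correct[i]) / n)
    expect_lt(abs(pred$correct[i] - prop[i]), 4 * se + 0.003)
  }
})

test_that("chi-square matches direct summation, is zero at self-consistency, linear in N", {
  sp <- ddm_truth()
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  # self-consistent summary: observed quantiles = model quantiles
  mk_summary <- function(cue, n) {
    cp <- ddm_cue_params(sp, cue)
    structure(list(
      session = "placebo", cue = cue, n_trials = n,
      n_correct = round(n * ddm_choice_prob("correct", cp)),
      n_error = n - round(n * ddm_choice_prob("correct", cp)),
      p_correct = ddm_choice_prob("correct", cp),
      probs = probs,
      correct_quantiles = ddm_predicted_quantiles(sp, cue, probs, "correct"),
      error_quantiles = ddm_predicted_quantiles(sp, cue, probs, "error"),
      sparse_error = FALSE), class = "quantile_summary")
  }
  summ <- list(speed = mk_summary("speed", 200), accuracy = mk_summary("accuracy", 200))
  expect_lt(as.numeric(ddm_chi_square(summ, sp)), 1e-4)

  # direct-summation oracle on perturbed data
  pert <- summ
  pert$accuracy$p_correct <- pert$accuracy$p_correct - 0.05
  chi <- as.numeric(ddm_chi_square(pert, sp))
  oracle <- 0
  for (cue in c("speed", "accuracy")) {
    sm <- pert[[cue]]
    pr <- ddm_bin_probabilities(sp, cue, sm$correct_quantiles, sm$error_quantiles)
    wts <- diff(c(0, probs, 1))
    p_obs <- c(sm$p_correct * wts, (1 - sm$p_correct) * wts)
    p_exp <- pmax(c(pr$correct, pr$error), 1e-5)
    oracle <- oracle + sm$n_trials * sum((p_obs - p_exp)^2 / p_exp)
  }
  expect_equal(chi, oracle, tolerance = 1e-12)
  expect_gt(chi, 0)

  doubled <- pert
  doubled$speed$n_trials <- 2 * doubled$speed$n_trials
  doubled$accuracy$n_trials <- 2 * doubled$accuracy$n_trials
  expect_equal(as.numeric(ddm_chi_square(doubled, sp)), 2 * chi,
               tolerance = 1e-12)
})

test_that("raising the boundary raises accuracy and mean decision time", {
  grid_a <- c(0.06, 0.10, 0.16, 0.24)
  acc <- mt <- numeric(length(grid_a))
  for (i in seq_along(grid_a)) {
    p <- ddm_params(a = grid_a[i], v = 0.25, ter = 0, s = 0.1)
    acc[i] <- ddm_choice_prob("correct", p)
    mt[i] <- integrate(function(t)
      t * (wiener_fpt_density(t, "correct", p) +
             wiener_fpt_density(t, "error", p)), 0, 60)$value
  }
  expect_true(all(diff(acc) > 0))
  expect_true(all(diff(mt) > 0))
})

test_that("fit_ddm recovers planted parameters and is deterministic", {
  truth <- ddm_truth()
  frag <- rbind(
    simulate_ddm_trials(ddm_cue_params(truth, "speed"), 2000,
                        deadline = Inf, seed = 101, cue = "speed"),
    simulate_ddm_trials(ddm_cue_params(truth, "accuracy"), 2000,
                        deadline = Inf, seed = 102, cue = "accuracy"))
  sm <- summarize_session(preprocess(trial_table(frag)), "placebo")
  cfg <- ddm_fit_config(eta_fixed = TRUE, restarts = 2, maxit = 500,
                        n_coarse = 150, seed = 9)
  fit <- fit_ddm(sm, cfg)
  expect_lt(abs(fit$params$a_speed - truth$a_speed) / truth$a_speed, 0.10)
  expect_lt(abs(fit$params$a_accuracy - truth$a_accuracy) / truth$a_accuracy, 0.10)
  expect_lt(fit$params$a_speed, fit$params$a_accuracy)

  # reported objective is reproducible from the reported parameters
  expect_equal(as.numeric(ddm_chi_square(sm, fit$params)), fit$chi2,
               tolerance = 1e-8)

  fit2 <- fit_ddm(sm, cfg)
  expect_equal(fit2$params, fit$params)
  expect_equal(fit2$chi2, fit$chi2)
})
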