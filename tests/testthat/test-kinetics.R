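test_that("noiseless one-phase decay fits recover tau to 0.1%", {
  for (tau in c(5, 50, 500)) {
    cat_grid <- choose_sampling_category(1 / tau)$times
    tc <- simulate_timecourse(kin_sim_config(tau = tau, plateau = 1,
                                             times = cat_grid, noise_sd = 0,
                                             seed = 1))
    fit <- fit_one_phase_decay(tc)
    expect_lt(abs(fit$tau - tau) / tau, 0.001, label = paste("tau", tau))
    expect_equal(fit$k * fit$tau, 1, tolerance = 1e-12)
    expect_true(fit$converged)
    expect_false(fit$poorly_constrained)
  }
  # partial cleavage: the plateau is fitted, not fixed at 1
  tc <- simulate_timecourse(kin_sim_config(tau = 30, plateau = 0.55,
                                           times = sampling_grid("medium"),
                                           noise_sd = 0, seed = 1))
  fit <- fit_one_phase_decay(tc)
  expect_lt(abs(fit$plateau - 0.55), 0.001)
  expect_lt(abs(fit$tau - 30) / 30, 0.001)
})

test_that("under-sampled time courses are flagged as poorly constrained", {
  # tau = 300 s observed only on the fast grid (3-30 s)
  tc <- simulate_timecourse(kin_sim_config(tau = 300, plateau = 1,
                                           times = sampling_grid("fast"),
                                           noise_sd = 0, seed = 1))
  fit <- fit_one_phase_decay(tc)
  expect_true(fit$poorly_constrained)
  # the same tau on its proper grid is not
  tc2 <- simulate_timecourse(kin_sim_config(tau = 300, plateau = 1,
                                            times = sampling_grid("slow"),
                                            noise_sd = 0, seed = 1))
  expect_false(fit_one_phase_decay(tc2)$poorly_constrained)
})

test_that("all-zero time courses return the no-activity sentinel", {
  tc <- data.frame(time = sampling_grid("slow"), cleaved = 0)
  fit <- fit_one_phase_decay(tc)
  expect_true(fit$no_activity)
  expect_equal(fit$k, 0)
  expect_equal(fit$tau, Inf)
})

test_that("time-course input contracts are enforced", {
  expect_error(fit_one_phase_decay(data.frame(time = c(1, 2, 3),
                                              cleaved = c(0, 0.1, 0.2))),
               "at least 4")
  expect_error(fit_one_phase_decay(data.frame(time = c(1, 2, 3, 4),
                                              cleaved = rep(0.5, 4))),
               "decade")
  expect_error(fit_one_phase_decay(data.frame(time = c(1, 2, 30, 3),
                                              cleaved = rep(0.5, 4))),
               "strictly increasing")
  expect_error(fit_one_phase_decay(data.frame(time = c(1, 3, 10, 30),
                                              cleaved = c(0, 0.5, 0.9, 1.2))),
               "\\[0, 1\\]")
})

test_that("noisy rate recovery has low median relative error", {
  # reduced-size recovery study; the full grid runs in the acceptance suite
  errs <- vapply(1:25, function(s) {
    tc <- simulate_timecourse(kin_sim_config(tau = 50, plateau = 1,
                                             times = sampling_grid("medium"),
                                             noise_sd = 0.02, seed = s))
    fit <- fit_one_phase_decay(tc)
    abs(fit$k - 1 / 50) / (1 / 50)
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("fit SSE never exceeds the SSE of its initialisation", {
  set.seed(6)
  for (i in 1:10) {
    tau <- exp(runif(1, log(5), log(500)))
    grid <- choose_sampling_category(1 / tau)$times
    tc <- simulate_timecourse(kin_sim_config(tau = tau,
                                             plateau = runif(1, 0.4, 1),
                                             times = grid, noise_sd = 0.05,
                                             seed = i))
    fit <- fit_one_phase_decay(tc)
    # initialisation: tau0 from half-plateau time, P0 from last observation
    p0 <- max(tc$cleaved[nrow(tc)], max(tc$cleaved) * 0.5, 0.05)
    half <- which(tc$cleaved >= p0 / 2)
    t_half <- if (length(half)) tc$time[half[1]] else max(tc$time)
    tau0 <- t_half / log(2)
    sse0 <- sum((tc$cleaved - p0 * (1 - exp(-tc$time / tau0)))^2)
    expect_lte(fit$sse, sse0 + 1e-9)
    expect_equal(fit$k * fit$tau, 1, tolerance = 1e-12)
  }
})

test_that("sampling categories map pilot rates to the narrowest grid", {
  expect_equal(choose_sampling_category(1 / 5)$category, "fast")
  expect_equal(choose_sampling_category(1 / 60)$category, "medium")
  expect_equal(choose_sampling_category(1 / 2000)$category, "slow")
  slow <- choose_sampling_category(1 / 2000)
  expect_false(slow$covered)  # 3 * 2000 s exceeds even the slow span
  expect_equal(choose_sampling_category(0)$category, "slow")
  expect_false(choose_sampling_category(0)$covered)
  g <- choose_sampling_category(1 / 5)$times
  expect_equal(range(g), c(3, 30))
  expect_equal(length(g), 8L)
})

test_that("titration fits recover the active fraction", {
  ti <- simulate_titration(kin_sim_config(active_fraction = 1, noise_sd = 0,
                                          seed = 1))
  fit <- estimate_active_fraction(ti)
  expect_lt(abs(fit$active_fraction - 1), 0.001)

  errs <- vapply(1:25, function(s) {
    ti <- simulate_titration(kin_sim_config(active_fraction = 0.4,
                                            noise_sd = 0.02, seed = s))
    abs(estimate_active_fraction(ti)$active_fraction - 0.4)
  }, numeric(1))
  expect_lte(median(errs), 0.04)

  all_one <- data.frame(ratio = c(0.8, 1, 2, 4, 8, 12), intact = 1)
  fit0 <- estimate_active_fraction(all_one)
  expect_true(fit0$no_activity)
  expect_equal(fit0$active_fraction, 0)

  rising <- data.frame(ratio = c(0.8, 1, 2, 4, 8, 12),
                       intact = c(0.2, 0.3, 0.45, 0.6, 0.8, 0.95))
  expect_error(estimate_active_fraction(rising), "increases")
  expect_error(estimate_active_fraction(all_one[1:3, ]), "at least 4")
  expect_error(estimate_active_fraction(
    data.frame(ratio = c(2, 3, 4, 5), intact = c(0.5, 0.4, 0.3, 0.2))),
    "below and above")
})

test_that("titration fits report active concentration against nominal", {
  ti <- simulate_titration(kin_sim_config(active_fraction = 0.6,
                                          noise_sd = 0, seed = 1))
  fit <- estimate_active_fraction(ti, nominal_conc = 31)
  expect_equal(fit$active_conc, fit$active_fraction * 31)
  expect_lte(fit$active_conc, 31)
})

test_that("threefold-excess check applies a 10% tolerance around 3", {
  expect_true(threefold_excess_check(18.6, 6.2)$pass)   # exactly 3.0
  expect_equal(threefold_excess_check(18.6, 6.2)$ratio, 3)
  expect_false(threefold_excess_check(12.4, 6.2)$pass)  # ratio 2.0
  expect_true(threefold_excess_check(3.29, 1)$pass)     # inside tolerance
  expect_false(threefold_excess_check(3.31, 1)$pass)
  expect_true(threefold_excess_check(2.7, 1)$pass)      # boundary inclusive
})
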