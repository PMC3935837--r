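test_that("void schedules cover the duration with the requested structure", {
  s <- generate_void_schedule(120, 4, jitter = 0, nocturnal_gap = FALSE)
  expect_equal(nrow(s), 30)
  expect_equal(unique(diff(s$t_start)), 4)
  expect_equal(s$t_start[1], 0)
  expect_equal(s$t_end[nrow(s)], 120)
  # contiguous and ordered
  expect_equal(s$t_start[-1], s$t_end[-nrow(s)])
  # determinism under a seed
  a <- generate_void_schedule(120, 4, 0.3, TRUE, seed = 11)
  b <- generate_void_schedule(120, 4, 0.3, TRUE, seed = 11)
  expect_identical(a, b)
  # invalid interval
  expect_error(generate_void_schedule(10, 12), "smaller")
})

test_that("jittered intervals keep the requested mean (law of large numbers)", {
  s <- generate_void_schedule(4100, 4, jitter = 0.3, nocturnal_gap = FALSE,
                              seed = 3)
  ints <- s$t_end - s$t_start
  expect_gt(nrow(s), 900)
  expect_lt(abs(mean(ints) - 4) / 4, 0.05)
})

test_that("noiseless synthesis reproduces model increments and calibrated recovery", {
  sched <- generate_void_schedule(120, 4, jitter = 0, nocturnal_gap = FALSE)
  tcs <- synthesize_timecourse(TBL, woollen_oral_scenario, sched,
                               noise_model(cv = 0))
  an <- analytic_bolus_solution(TBL, "oral", woollen_dose_mol, 0.5)
  for (a in c("cisDCCA", "transDCCA", "PBA3")) {
    v <- tcs[[a]]$voids
    # per-void amounts equal closed-form increments of the cumulative curve
    inc <- an$U(v$t_end, a) - an$U(v$t_start, a)
    expect_lt(max(abs(v$amount_mol - inc)) / an$U_inf[[a]], 1e-6)
    expect_false(any(v$incomplete))
    # total synthesized recovery never exceeds the asymptotic yield
    expect_lte(sum(v$amount_mol), an$U_inf[[a]] * (1 + 1e-9))
  }
  # 120-h trans-DCCA recovery approaches the calibrated 18.4% of dose
  trans_pct <- 100 * sum(tcs$transDCCA$voids$amount_mol) / woollen_dose_mol
  expect_equal(trans_pct, 18.4, tolerance = 0.05)
})

test_that("multiplicative noise is mean-one and incomplete voids are flagged", {
  sched <- generate_void_schedule(120, 4, 0.3, TRUE, seed = 20)
  tot <- sapply(1:20, function(sd) {
    tcs <- synthesize_timecourse(TBL, woollen_oral_scenario, sched,
                                 noise_model(cv = 0.2), seed = 700 + sd)
    sum(tcs$transDCCA$voids$amount_mol)
  })
  ref <- sum(synthesize_timecourse(TBL, woollen_oral_scenario, sched,
                                   noise_model(cv = 0))$transDCCA$voids$amount_mol)
  se <- sd(tot / ref) / sqrt(length(tot))
  expect_lt(abs(mean(tot / ref) - 1), 3 * se + 0.01)
  # incomplete-void process
  tcs <- synthesize_timecourse(TBL, woollen_oral_scenario, sched,
                               noise_model(cv = 0, incomplete_prob = 0.5,
                                           incomplete_fraction = 0.4),
                               seed = 99)
  v <- tcs$cisDCCA$voids
  expect_gt(sum(v$incomplete), 0)
  expect_lt(sum(v$incomplete), nrow(v))
})

test_that("bundled design fixtures carry the documented exposures", {
  fo <- design_fixture("woollen_oral")
  e <- fo$scenario$events[[1]]
  expect_equal(e$route, "oral")
  expect_equal(e$amount_mol, 3.3e-3 / 416.3)
  expect_equal(e$cis_fraction, 0.5)
  fd <- design_fixture("woollen_dermal")
  e <- fd$scenario$events[[1]]
  expect_equal(e$route, "dermal")
  expect_equal(e$amount_mol, 31e-3 / 416.3)
  expect_equal(e$cis_fraction, 0.56)
  expect_equal(e$washoff_h, 8)
  ts <- design_fixture("tomalik_scalp")$scenario$events[[1]]
  expect_equal(ts$route, "dermal")
  expect_equal(ts$amount_mol, 215e-3 / 391.3)
  expect_error(design_fixture("nope"), "woollen_oral")
})
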