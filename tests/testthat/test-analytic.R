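test_that("closed-form solutions start at zero and reach the branching-fraction asymptote", {
  an <- analytic_bolus_solution(TBL, "oral", 1, 0.5)
  for (a in c("cisDCCA", "transDCCA", "PBA3")) {
    expect_equal(an$U(0, a), 0)
    expect_equal(an$QU(0, a), 0)
  }
  # asymptotic yield identity: U_inf / isomer dose = f_abs * omega /
  # (k_metabolism * k_elim)
  p <- TBL$trans
  expect_equal(an$U_inf[["transDCCA"]],
               0.5 * p$f_abs_oral * p$omega / (p$k_metabolism * p$k_elim),
               tolerance = 1e-12)
  # ... which equals the calibrated 18.4% of the total 50:50 dose
  expect_equal(100 * an$U_inf[["transDCCA"]], 18.4, tolerance = 1e-9)
  # evaluators converge to the asymptote
  expect_equal(unname(an$U(3000, "transDCCA")), an$U_inf[["transDCCA"]],
               tolerance = 1e-8)
})

test_that("analytic and numerical solutions agree on the calibrated preset", {
  tt <- c(0.5, 2, 8, 24, 72, 200)
  scen <- exposure_scenario(exposure_event("oral", 0, amount_mol = 1), 200)
  sim <- simulate_scenario(TBL, scen)
  an <- analytic_bolus_solution(TBL, "oral", 1, 0.5)
  for (a in c("cisDCCA", "transDCCA", "PBA3")) {
    num <- approx(sim$time, switch(a, cisDCCA = sim$states[, "U_cis"],
                                   transDCCA = sim$states[, "U_trans"],
                                   PBA3 = sim$states[, "U_3PBA"]), tt)$y
    expect_lt(max(abs(num - an$U(tt, a)) / an$U_inf[[a]]), 1e-6)
  }
})

test_that("coincident rate constants switch to the confluent limit form", {
  skip_if_not_installed("Matrix")
  # k_elim_trans set exactly equal to k_abs_oral_trans: a double pole
  ps <- modify_parameter_set(TBL, k_elim_trans = TBL$trans$k_abs_oral,
                             omega_trans = 1.0)
  an <- analytic_bolus_solution(ps, "oral", 1, 0.5)
  tt <- c(0.5, 2, 10, 50, 150)
  ref <- oracle_bolus(ps, "oral", 1, 0.5, tt)
  expect_lt(max(abs(an$U(tt, "transDCCA") - ref$U_transDCCA)) /
              max(ref$U_transDCCA), 1e-9)
  # near-coincident (within the switch tolerance) is also stable
  ps2 <- modify_parameter_set(TBL, k_elim_trans = TBL$trans$k_abs_oral *
                                (1 + 1e-9), omega_trans = 1.0)
  an2 <- analytic_bolus_solution(ps2, "oral", 1, 0.5)
  expect_lt(max(abs(an2$U(tt, "transDCCA") - ref$U_transDCCA)) /
              max(ref$U_transDCCA), 1e-6)
})

test_that("exponential divided differences match their defining recursion", {
  t <- 3.7
  lam <- c(0.1, 0.5, 1.2)
  f <- exp(-lam * t)
  dd2 <- (f[2] - f[1]) / (lam[2] - lam[1])
  dd2b <- (f[3] - f[2]) / (lam[3] - lam[2])
  dd3 <- (dd2b - dd2) / (lam[3] - lam[1])
  expect_equal(exp_divided_diff(lam[1:2], t), dd2, tolerance = 1e-12)
  expect_equal(exp_divided_diff(lam, t), dd3, tolerance = 1e-12)
  # confluent limit equals the derivative form: f[a, a] = -t e^(-a t)
  expect_equal(exp_divided_diff(c(0.3, 0.3), t), -t * exp(-0.3 * t),
               tolerance = 1e-12)
})

test_that("dermal wash-off superposition matches the simulated depot removal", {
  scen <- exposure_scenario(
    exposure_event("dermal", 0, amount_mol = 1, cis_fraction = 0.56,
                   washoff_h = 8), 400)
  sim <- simulate_scenario(TBL, scen)
  an <- analytic_bolus_solution(TBL, "dermal", 1, 0.56, washoff_h = 8)
  tt <- c(2, 7.9, 8.1, 24, 120, 350)
  for (a in c("cisDCCA", "transDCCA", "PBA3")) {
    num <- approx(sim$time, switch(a, cisDCCA = sim$states[, "U_cis"],
                                   transDCCA = sim$states[, "U_trans"],
                                   PBA3 = sim$states[, "U_3PBA"]), tt)$y
    expect_lt(max(abs(num - an$U(tt, a)) / an$U_inf[[a]]), 1e-6)
  }
})

test_that("urinary outputs are invariant to the (k_MU, k_MF) split", {
  # omega and k_elim pinned; any fecal split must leave QU and U unchanged
  base <- analytic_bolus_solution(TBL, "oral", 1, 0.5)
  tt <- c(1, 6, 24, 96)
  # fecal fractions capped by k_BM + k_BM_3PBA <= k_metabolism (k_BM grows
  # as 1/(1 - frac) with omega pinned)
  for (frac in c(0.1, 0.2, 0.3)) {
    ps <- modify_parameter_set(TBL, k_MF_fraction = frac)
    an <- analytic_bolus_solution(ps, "oral", 1, 0.5)
    for (a in c("cisDCCA", "transDCCA", "PBA3")) {
      expect_lt(max(abs(an$U(tt, a) - base$U(tt, a))) / base$U_inf[[a]], 1e-10)
      expect_lt(max(abs(an$QU(tt, a) - base$QU(tt, a))) /
                  max(base$QU(tt, a)), 1e-10)
    }
  }
  # and the same through the numerical solver
  psf <- modify_parameter_set(TBL, k_MF_fraction = 0.35)
  scen <- exposure_scenario(exposure_event("oral", 0, amount_mol = 1), 120)
  s0 <- simulate_scenario(TBL, scen)
  s1 <- simulate_scenario(psf, scen)
  expect_lt(max(abs(s1$states[, "U_trans"] - s0$states[, "U_trans"])) /
              max(s0$states[, "U_trans"]), 1e-8)
  # feces now accumulate mass but the balance still closes
  expect_gt(max(s1$states[, "F_trans"]), 0)
  expect_lt(mass_balance_residual(s1), 1e-6)
})
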