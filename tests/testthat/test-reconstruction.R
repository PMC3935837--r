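test_that("steady-state reconstruction inverts the calibrated yields", {
  # 0.184 umol/day of trans-DCCA under the 50:50 oral yield of 18.4%
  # corresponds to 1 umol/day of total parent compound
  rec <- steady_state_reconstruct(c(transDCCA = 0.184e-6), TBL, "oral", 0.5)
  expect_equal(rec$dose_mol, 1e-6, tolerance = 1e-9)
  # zero excretion reconstructs a zero dose
  expect_equal(steady_state_reconstruct(c(PBA3 = 0), TBL, "oral")$dose_mol, 0)
  # multi-analyte input averages the per-analyte estimates
  y <- urinary_yield(TBL, "oral", 0.5)
  rec3 <- steady_state_reconstruct(
    c(cisDCCA = 2 * y[["cisDCCA"]], transDCCA = 2 * y[["transDCCA"]],
      PBA3 = 2 * y[["PBA3"]]), TBL, "oral", 0.5)
  expect_equal(rec3$dose_mol, 2, tolerance = 1e-9)
  expect_equal(unname(rec3$per_analyte), rep(2, 3), tolerance = 1e-9)
  # oral and dermal agree on absorbed-dose scale (route invariance)
  psd <- pk_preset(f_abs_dermal = 0.01)
  d_oral <- steady_state_reconstruct(c(transDCCA = 1e-6), psd, "oral")
  d_derm <- steady_state_reconstruct(c(transDCCA = 1e-6), psd, "dermal")
  expect_equal(d_oral$dose_mol * 0.8, d_derm$dose_mol * 0.01,
               tolerance = 1e-9)
})

test_that("time-course reconstruction is exact without noise and linear in dose", {
  sched <- generate_void_schedule(120, 4, jitter = 0, nocturnal_gap = FALSE)
  tcs <- synthesize_timecourse(TBL, woollen_oral_scenario, sched,
                               noise_model(cv = 0))
  rec <- timecourse_reconstruct(tcs, TBL, woollen_oral_scenario)
  expect_equal(rec$dose_mol, woollen_dose_mol, tolerance = 1e-6)
  expect_lt(rec$residual, (1e-6 * woollen_dose_mol)^2)
  # doubling every observed amount doubles the reconstructed dose exactly
  tcs2 <- tcs
  for (a in names(tcs2)) tcs2[[a]]$voids$amount_mol <-
      2 * tcs2[[a]]$voids$amount_mol
  rec2 <- timecourse_reconstruct(tcs2, TBL, woollen_oral_scenario)
  expect_equal(rec2$dose_mol, 2 * rec$dose_mol, tolerance = 1e-9)
  # the template's own dose magnitude is irrelevant
  half_template <- exposure_scenario(
    exposure_event("oral", 0, amount_mol = woollen_dose_mol / 2), 120)
  rec_h <- timecourse_reconstruct(tcs, TBL, half_template)
  expect_equal(rec_h$dose_mol, rec$dose_mol, tolerance = 1e-6)
})

test_that("assuming the wrong route leaves a much larger residual", {
  sched <- generate_void_schedule(120, 4, jitter = 0, nocturnal_gap = FALSE)
  dermal_fx <- design_fixture("woollen_dermal")$scenario
  tcs <- synthesize_timecourse(TBL, dermal_fx, sched, noise_model(cv = 0))
  right <- timecourse_reconstruct(tcs, TBL, dermal_fx)
  wrong <- timecourse_reconstruct(tcs, TBL, woollen_oral_scenario)
  expect_gt(wrong$residual, 100 * max(right$residual, 1e-30))
})

test_that("incomplete voids are excluded from the reconstruction", {
  sched <- generate_void_schedule(120, 4, jitter = 0, nocturnal_gap = FALSE)
  tcs <- synthesize_timecourse(TBL, woollen_oral_scenario, sched,
                               noise_model(cv = 0))
  # corrupt two voids but flag them incomplete: the estimate is unaffected
  for (a in names(tcs)) {
    tcs[[a]]$voids$amount_mol[3:4] <- tcs[[a]]$voids$amount_mol[3:4] * 0.2
    tcs[[a]]$voids$incomplete[3:4] <- TRUE
  }
  rec <- timecourse_reconstruct(tcs, TBL, woollen_oral_scenario)
  expect_equal(rec$dose_mol, woollen_dose_mol, tolerance = 1e-6)
})
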