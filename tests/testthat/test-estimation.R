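make_exp_tc <- function(k, window = c(0, 120), n = 30) {
  # voids whose midpoint rates lie exactly on r(t) = exp(-k t)
  b <- seq(window[1], window[2], length.out = n + 1)
  mid <- (b[-1] + b[-(n + 1)]) / 2
  amt <- exp(-k * mid) * diff(b)
  observed_timecourse("x", "transDCCA",
                      data.frame(t_start = b[-(n + 1)], t_end = b[-1],
                                 amount_mol = amt),
                      route = "oral", dose_mol = 1, cis_fraction = 0.5)
}

test_that("log-linear regression recovers an exact exponential rate", {
  tc <- make_exp_tc(0.157)
  expect_equal(loglinear_rate_estimate(tc, c(0, 120)), 0.157,
               tolerance = 1e-10)
  expect_equal(loglinear_rate_estimate(tc, c(66, 114)), 0.157,
               tolerance = 1e-10)
  # terminal slope of the synthetic trans profile approaches the slowest
  # eigenvalue (k_SB scaled by the blood-storage coupling), not k_SB itself
  ksb_hat <- loglinear_rate_estimate(noiseless_woollen_tcs$transDCCA,
                                     c(66, 114))
  lam2 <- min(Re(polyroot(c(0.072 * 20.8, -(10.4 + 20.8 + 0.072), 1))))
  expect_equal(ksb_hat, lam2, tolerance = 0.05)
})

test_that("log-linear regression demands enough usable voids and positive slopes", {
  tc <- make_exp_tc(0.2, n = 30)
  expect_error(loglinear_rate_estimate(tc, c(0, 8)), "insufficient")
  rising <- make_exp_tc(-0.05, window = c(0, 40))
  expect_warning(k <- loglinear_rate_estimate(rising, c(0, 40)),
                 "non-positive")
  expect_equal(k, 0.05, tolerance = 1e-8)
})

test_that("sensitivity windows bracket the conventional fitting windows", {
  scen <- exposure_scenario(exposure_event("oral", 0, amount_mol = 1), 120)
  sw <- sensitivity_windows(TBL, scen)
  g <- function(p, col) sw[[col]][sw$parameter == p]
  # k_elim influences the rate profile over a window overlapping 6-30 h
  expect_true(g("k_elim", "t_min") <= 30 && g("k_elim", "t_max") >= 6)
  expect_equal(g("k_elim", "profile"), "rate")
  # k_SB influence reaches deep into the terminal phase (42-114 h)
  expect_true(g("k_SB", "t_max") >= 114)
  # k_BS acts on the cumulative profile around 12-48 h
  expect_true(g("k_BS", "t_min") <= 48 && g("k_BS", "t_max") >= 12)
  expect_equal(g("k_BS", "profile"), "cumulative")
  # globally acting constants carry no window
  expect_true(all(sw$global[sw$parameter %in%
                              c("k_abs_oral", "k_metabolism")]))
  # zero perturbation finds nothing
  sw0 <- suppressWarnings(sensitivity_windows(TBL, scen,
                                              rel_perturbation = 0))
  expect_true(all(is.na(sw0$t_min[!sw0$global])))
})

test_that("windowed SSE is zero at the data and n*c^2 under a constant offset", {
  tc <- noiseless_woollen_tcs$transDCCA
  v <- tc$voids
  cum <- cumsum(v$amount_mol)
  U_exact <- approxfun(c(0, v$t_end), c(0, cum))
  expect_equal(windowed_sse(U_exact, tc, NULL, "cumulative"), 0)
  cshift <- 1e-9
  U_off <- function(t) U_exact(t) + cshift
  expect_equal(windowed_sse(U_off, tc, NULL, "cumulative"),
               nrow(v) * cshift^2, tolerance = 1e-8)
  # empty window intersection is an error naming the window
  expect_error(windowed_sse(U_exact, tc, c(500, 600), "rate"), "500")
})

test_that("coordinate descent recovers the generating isomer kinetics", {
  tc <- noiseless_woollen_tcs$transDCCA
  fit <- coordinate_descent_fit(tc, 0.457, 20.8, 0.8)
  expect_true(fit$converged)
  expect_equal(fit$k_BS, 10.4, tolerance = 0.01)
  expect_equal(fit$k_SB, 0.072, tolerance = 0.01)
  expect_equal(fit$k_elim, 0.157, tolerance = 0.01)
  expect_equal(fit$omega, TBL$trans$omega, tolerance = 0.01)
  # the composite objective never increases across sweeps
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
  # rate-only and cumulative-only fits agree on noiseless data
  fr <- coordinate_descent_fit(tc, 0.457, 20.8, 0.8, profile = "rate")
  fc <- coordinate_descent_fit(tc, 0.457, 20.8, 0.8, profile = "cumulative")
  expect_equal(fr$k_elim, fc$k_elim, tolerance = 0.02)
  expect_equal(fr$omega, fc$omega, tolerance = 0.02)
})

test_that("a bound excluding the true storage rate pins the estimate and flags it", {
  tc <- noiseless_woollen_tcs$transDCCA
  b <- default_parameter_bounds()
  b$k_BS <- c(0.5, 5)   # true k_BS = 10.4 lies above
  fit <- coordinate_descent_fit(tc, 0.457, 20.8, 0.8, bounds = b)
  expect_equal(fit$k_BS, 5, tolerance = 1e-2)
  expect_true(fit$at_bound[["k_BS"]])
})

test_that("noisy synthetic data are recovered within the expected precision", {
  # 5% multiplicative noise, 10 seeds: median error in k_elim and omega
  # stays below 10%
  errs <- sapply(1:10, function(sd) {
    sch <- generate_void_schedule(120, 4, 0.3, TRUE, seed = 500 + sd)
    tc <- synthesize_timecourse(TBL, woollen_oral_scenario, sch,
                                noise_model(cv = 0.05), seed = 600 + sd)
    f <- coordinate_descent_fit(tc$transDCCA, 0.457, 20.8, 0.8,
                                weighting = "relative")
    c(abs(f$omega / TBL$trans$omega - 1), abs(f$k_elim / 0.157 - 1))
  })
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("a 1x1 grid at the truth yields a single near-perfect candidate", {
  grids <- list(cis = list(k_abs_oral = 0.317, k_metabolism = 13.9),
                trans = list(k_abs_oral = 0.457, k_metabolism = 20.8))
  fm <- grid_search_oral(noiseless_woollen_tcs, grids)
  expect_equal(nrow(fm$table), 1)
  scale <- sum(noiseless_woollen_tcs$transDCCA$voids$amount_mol)^2
  expect_lt(fm$table$sse_cum_transDCCA / scale, 1e-8)
  best <- rank_select(fm)
  expect_s3_class(best, "pk_parameter_set")
  expect_equal(best$trans$omega, TBL$trans$omega, tolerance = 0.01)
  expect_equal(best$shared$k_elim_3PBA, 0.095, tolerance = 0.02)
})

test_that("infeasible constraint grids fail loudly", {
  grids <- list(cis = list(k_abs_oral = 0.9, k_metabolism = 30),
                trans = list(k_abs_oral = 0.457, k_metabolism = 20.8))
  expect_error(grid_search_oral(noiseless_woollen_tcs, grids),
               "constraint-infeasible")
})

test_that("rank-sum selection picks dominance and beats total SSE on ties", {
  cols <- c("sse_rate_cisDCCA", "sse_cum_cisDCCA", "sse_rate_transDCCA",
            "sse_cum_transDCCA", "sse_rate_PBA3", "sse_cum_PBA3")
  mk_fm <- function(m) {
    tab <- as.data.frame(m)
    names(tab) <- cols
    structure(list(table = tab,
                   params = lapply(seq_len(nrow(m)), function(i)
                     structure(list(id = i), class = "pk_parameter_set"))),
              class = "pk_fit_matrix")
  }
  # single row and dominance
  expect_equal(rank_select(mk_fm(matrix(1, 1, 6)))$id, 1)
  dom <- rbind(c(2, 2, 2, 2, 2, 2), c(1, 1, 1, 1, 1, 1), c(3, 3, 3, 3, 3, 3))
  expect_equal(rank_select(mk_fm(dom))$id, 2)
  # rank-sum winner differs from the total-SSE winner: row 1 wins 4 of 6
  # columns narrowly, row 2 wins 2 columns by a landslide
  m <- rbind(c(1, 1, 1, 1, 9, 9),
             c(2, 2, 2, 2, 0.1, 0.1),
             c(3, 3, 3, 3, 10, 10))
  # brute-force expected ranking
  rk <- rowSums(apply(m, 2, rank))
  expect_equal(which.min(rk), 1)           # rank-sum winner
  expect_equal(which.min(rowSums(m)), 2)   # total-SSE winner differs
  expect_equal(rank_select(mk_fm(m))$id, 1)
})

test_that("dermal absorption fraction and rate are recovered from synthetic data", {
  ps <- TBL
  sched <- generate_void_schedule(120, 4, jitter = 0, nocturnal_gap = FALSE)
  tcs <- synthesize_timecourse(ps, design_fixture("woollen_dermal")$scenario,
                               sched, noise_model(cv = 0))
  fit <- fit_dermal(tcs, ps)
  expect_equal(fit$cis$f_abs_dermal, 0.0125, tolerance = 0.02)
  expect_equal(fit$cis$k_abs_dermal, 0.033, tolerance = 0.02)
  expect_equal(fit$trans$f_abs_dermal, 0.0082, tolerance = 0.02)
  expect_equal(fit$trans$k_abs_dermal, 0.047, tolerance = 0.02)
  # scale invariance: doubling dose and amounts gives identical estimates
  tcs2 <- tcs
  for (a in names(tcs2)) {
    tcs2[[a]]$voids$amount_mol <- 2 * tcs2[[a]]$voids$amount_mol
    tcs2[[a]]$dose_mol <- 2 * tcs2[[a]]$dose_mol
  }
  fit2 <- fit_dermal(tcs2, ps)
  expect_equal(fit2$cis$f_abs_dermal, fit$cis$f_abs_dermal, tolerance = 1e-6)
  expect_equal(fit2$cis$k_abs_dermal, fit$cis$k_abs_dermal, tolerance = 1e-6)
  # all-zero data are unidentifiable
  tcs0 <- tcs
  tcs0$cisDCCA$voids$amount_mol <- 0
  expect_error(fit_dermal(tcs0, ps), "unidentifiable")
})
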