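# Shared fixtures and the independent matrix-exponential oracle.

TBL <- pk_preset()  # calibrated mean preset, slash-convention dermal rates

woollen_oral_scenario <- design_fixture("woollen_oral")$scenario
woollen_dose_mol <- 3.3e-3 / molar_mass("cypermethrin")

# Independent reference solution of the linear system: assembles the ODE
# matrix directly from the raw parameter values (own split arithmetic, own
# state layout) and propagates a single bolus with Matrix::expm. This never
# touches the package's solver or system matrix.
oracle_bolus <- function(params, route, dose_mol, cis_fraction, t_grid) {
  raw <- params$raw
  kel3 <- raw$k_elim_3PBA
  idx <- list(cis = 1:7, trans = 8:14)  # GI/D, B, S, M, U, NO per isomer
  # layout per isomer: 1 input, 2 B, 3 S, 4 M, 5 U, 6 NO, 7 M3-feed handled
  n <- 17
  A <- matrix(0, n, n)
  x0 <- numeric(n)
  off <- c(cis = 0, trans = 7)
  for (s in c("cis", "trans")) {
    g <- function(stem) raw[[paste0(stem, "_", s)]]
    o <- off[[s]]
    ka <- if (route == "oral") g("k_abs_oral") else g("k_abs_dermal")
    fa <- if (route == "oral") g("f_abs_oral") else g("f_abs_dermal")
    kMU <- g("k_elim")                 # k_MF = 0 split, done independently
    kBM <- g("omega") / kMU
    kBM3 <- g("omega_3PBA") / kel3
    kNO <- g("k_metabolism") - kBM - kBM3
    A[o + 1, o + 1] <- -ka
    A[o + 2, o + 1] <- ka
    A[o + 2, o + 2] <- -(g("k_BS") + g("k_metabolism"))
    A[o + 2, o + 3] <- g("k_SB")
    A[o + 3, o + 2] <- g("k_BS")
    A[o + 3, o + 3] <- -g("k_SB")
    A[o + 4, o + 2] <- kBM
    A[o + 4, o + 4] <- -g("k_elim")
    A[o + 5, o + 4] <- kMU
    A[o + 6, o + 2] <- kNO
    A[15, o + 2] <- kBM3
    frac <- if (s == "cis") cis_fraction else 1 - cis_fraction
    x0[o + 1] <- fa * frac * dose_mol
  }
  A[15, 15] <- -kel3
  A[16, 15] <- kel3   # U_3PBA
  out <- matrix(0, length(t_grid), n)
  for (i in seq_along(t_grid)) {
    out[i, ] <- as.numeric(Matrix::expm(A * t_grid[i]) %*% x0)
  }
  list(t = t_grid,
       B_cis = out[, 2], B_trans = out[, 9],
       S_cis = out[, 3], S_trans = out[, 10],
       U_cisDCCA = out[, 5], U_transDCCA = out[, 12],
       U_PBA3 = out[, 16])
}

# random positive parameter sets with valid yield structure (ordering
# constraints deliberately not imposed)
random_params <- function(seed) {
  set.seed(seed)
  ln <- function(m, s) stats::rlnorm(1, log(m), s)
  raw <- list(k_elim_3PBA = ln(0.1, 0.4))
  for (s in c("cis", "trans")) {
    kmet <- ln(15, 0.5)
    kel <- ln(0.17, 0.4)
    y <- stats::runif(2)
    y <- 0.85 * y / max(sum(y), 1)   # k_BM + k_BM_3PBA <= 0.85 k_met
    raw[[paste0("k_abs_oral_", s)]] <- ln(0.4, 0.4)
    raw[[paste0("k_abs_dermal_", s)]] <- ln(0.04, 0.4)
    raw[[paste0("f_abs_oral_", s)]] <- stats::runif(1, 0.3, 0.95)
    raw[[paste0("f_abs_dermal_", s)]] <- stats::runif(1, 0.005, 0.05)
    raw[[paste0("k_BS_", s)]] <- ln(5, 0.6)
    raw[[paste0("k_SB_", s)]] <- ln(0.06, 0.4)
    raw[[paste0("k_metabolism_", s)]] <- kmet
    raw[[paste0("k_elim_", s)]] <- kel
    raw[[paste0("omega_", s)]] <- y[1] * kmet * kel
    raw[[paste0("omega_3PBA_", s)]] <- y[2] * kmet * raw$k_elim_3PBA
  }
  assemble_parameter_set(raw, check_constraints = FALSE,
                         provenance = paste0("random", seed))
}

# noiseless Woollen-design synthetic time courses (shared by estimation
# tests; regular 4-h voids keep them deterministic)
noiseless_woollen_tcs <- local({
  sched <- generate_void_schedule(120, 4, jitter = 0, nocturnal_gap = FALSE)
  synthesize_timecourse(TBL, woollen_oral_scenario, sched, noise_model(cv = 0))
})
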