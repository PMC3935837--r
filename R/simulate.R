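# Numerical simulation of the compartmental system.
#
# Between dose events the model is a constant-coefficient linear ODE
# dx/dt = A x; dose events and dermal wash-off are discrete state updates.
# The system is integrated with an adaptive Dormand-Prince 5(4) pair
# (explicit Runge-Kutta with embedded error estimate). Rates span roughly
# 0.04-31 1/h, which is stiff-ish but comfortably tractable explicitly at
# the tolerances used.

.STATE_NAMES <- c(
  paste0(rep(c("GI", "D", "R", "B", "S", "M", "U", "F", "NO", "W"), 2),
         rep(c("_cis", "_trans"), each = 10)),
  "M_3PBA", "U_3PBA", "F_3PBA"
)

.sidx <- function(name) match(name, .STATE_NAMES)

# Constant system matrix of the linear model (23 x 23).
.system_matrix <- function(params) {
  n <- length(.STATE_NAMES)
  A <- matrix(0, n, n, dimnames = list(.STATE_NAMES, .STATE_NAMES))
  for (s in .ISOMERS) {
    p <- params[[s]]
    i <- function(comp) .sidx(paste0(comp, "_", s))
    ka_o <- p$k_abs_oral
    ka_d <- if (is.na(p$k_abs_dermal)) 0 else p$k_abs_dermal
    ka_r <- if (is.na(p$k_abs_inh)) 0 else p$k_abs_inh
    A[i("GI"), i("GI")] <- -ka_o
    A[i("D"), i("D")] <- -ka_d
    A[i("R"), i("R")] <- -ka_r
    A[i("B"), i("GI")] <- ka_o
    A[i("B"), i("D")] <- ka_d
    A[i("B"), i("R")] <- ka_r
    A[i("B"), i("B")] <- -(p$k_BS + p$k_metabolism)
    A[i("B"), i("S")] <- p$k_SB
    A[i("S"), i("B")] <- p$k_BS
    A[i("S"), i("S")] <- -p$k_SB
    A[i("M"), i("B")] <- p$k_BM
    A[i("M"), i("M")] <- -p$k_elim
    A[i("U"), i("M")] <- p$k_MU
    A[i("F"), i("M")] <- p$k_MF
    A[i("NO"), i("B")] <- p$k_BM_NO
    A[.sidx("M_3PBA"), i("B")] <- p$k_BM_3PBA
  }
  A[.sidx("M_3PBA"), .sidx("M_3PBA")] <- -params$shared$k_elim_3PBA
  A[.sidx("U_3PBA"), .sidx("M_3PBA")] <- params$shared$k_MU_3PBA
  A[.sidx("F_3PBA"), .sidx("M_3PBA")] <- params$shared$k_MF_3PBA
  A
}

#' State-derivative field of the model
#'
#' Returns the function `f(t, state)` giving the time derivative of the full
#' state vector. Between dose events the model is linear, so `f` is simply
#' the system matrix applied to the state; dose events and wash-off are
#' discrete state updates handled by [simulate_scenario()], not impulses
#' inside the derivative.
#'
#' @param params a `pk_parameter_set`.
#' @param scenario a `pk_exposure_scenario`; only used for validation (an
#'   inhalation event requires `k_abs_inh` to be set).
#' @return function of `(t, state)` returning the named derivative vector.
#' @export
derivative_field <- function(params, scenario = NULL) {
  if (!is.null(scenario)) .validate_routes(params, scenario)
  A <- .system_matrix(params)
  function(t, state) {
    d <- as.vector(A %*% state)
    names(d) <- .STATE_NAMES
    d
  }
}

.validate_routes <- function(params, scenario) {
  for (e in scenario$events) {
    for (s in .ISOMERS) {
      p <- params[[s]]
      if (e$route == "inhalation" && is.na(p$k_abs_inh))
        stop("unsupported route: scenario has an inhalation event but ",
             "k_abs_inh_", s, " is not set", call. = FALSE)
      if (e$route == "dermal" &&
          (is.na(p$k_abs_dermal) || is.na(p$f_abs_dermal)))
        stop("unsupported route: scenario has a dermal event but dermal ",
             "absorption parameters for isomer '", s, "' are not set",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

# state jump applied at a dose event (absorption-fraction loss taken here:
# input compartments hold bioavailable amounts)
.apply_event <- function(state, e, params) {
  frac <- c(cis = e$cis_fraction, trans = 1 - e$cis_fraction)
  for (s in .ISOMERS) {
    p <- params[[s]]
    amt <- frac[[s]] * e$amount_mol
    if (amt == 0) next
    tgt <- switch(e$route,
                  oral = list(comp = "GI", f = p$f_abs_oral),
                  dermal = list(comp = "D", f = p$f_abs_dermal),
                  inhalation = list(comp = "R", f = 1))
    j <- .sidx(paste0(tgt$comp, "_", s))
    state[j] <- state[j] + tgt$f * amt
  }
  state
}

.apply_washoff <- function(state, s) {
  jd <- .sidx(paste0("D_", s))
  jw <- .sidx(paste0("W_", s))
  state[jw] <- state[jw] + state[jd]
  state[jd] <- 0
  state
}

# Dormand-Prince 5(4) coefficients
.DP <- local({
  a <- matrix(0, 7, 7)
  a[2, 1] <- 1 / 5
  a[3, 1:2] <- c(3 / 40, 9 / 40)
  a[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
  a[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
  a[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656)
  a[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  list(a = a,
       c = c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1),
       b5 = a[7, ],
       b4 = c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
              187 / 2100, 1 / 40))
})

# integrate dx = A x from t0 to t1 (adaptive DP54); returns state at t1
.rk_span <- function(A, x, t0, t1, rtol, atol, max_steps) {
  if (t1 <= t0) return(x)
  a <- .DP$a; b5 <- .DP$b5; b4 <- .DP$b4
  maxrate <- max(abs(diag(A)), 1e-8)
  h <- min(t1 - t0, 0.1 / maxrate)
  t <- t0
  k <- vector("list", 7)
  nstep <- 0L
  while (t < t1) {
    nstep <- nstep + 1L
    if (nstep > max_steps)
      stop("integration error: step limit (", max_steps,
           ") exceeded at t = ", format(t), " h", call. = FALSE)
    h <- min(h, t1 - t)
    k[[1]] <- A %*% x
    for (j in 2:7) {
      xs <- x
      for (l in seq_len(j - 1)) if (a[j, l] != 0) xs <- xs + h * a[j, l] * k[[l]]
      k[[j]] <- A %*% xs
    }
    x5 <- x
    for (j in 1:7) if (b5[j] != 0) x5 <- x5 + h * b5[j] * k[[j]]
    err <- numeric(length(x))
    for (j in 1:7) {
      db <- b5[j] - b4[j]
      if (db != 0) err <- err + h * db * k[[j]]
    }
    sc <- atol + rtol * pmax(abs(x), abs(x5))
    en <- sqrt(mean((err / sc)^2))
    if (en <= 1) {
      t <- t + h
      x <- x5
    }
    fac <- if (en > 0) 0.9 * en^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
  }
  x
}

# default output grid: event times plus refinement after each event
.default_grid <- function(scenario) {
  dur <- scenario$duration_h
  ev_t <- vapply(scenario$events, `[[`, numeric(1), "time_h")
  wash <- unlist(lapply(scenario$events, function(e) e$washoff_h))
  base <- seq(0, dur, length.out = 601)
  fine <- if (length(ev_t) <= 5) {
    c(seq(0.004, 0.4, by = 0.004), seq(0.42, 2, by = 0.02),
      seq(2.1, 12, by = 0.1))
  } else {
    c(seq(0.01, 0.5, by = 0.01), seq(0.6, 3, by = 0.1))
  }
  g <- sort(unique(c(base, ev_t, wash,
                     as.vector(outer(fine, c(ev_t, wash), `+`)))))
  g[g <= dur & g >= 0]
}

#' Simulate an exposure scenario
#'
#' Integrates the full compartmental system over a time grid, applying dose
#' events and dermal wash-off as discrete state updates. Event times are
#' always included as grid points; the default grid is refined after each
#' event so that early blood-compartment peaks (minutes post-dose) are
#' resolved.
#'
#' @param params a `pk_parameter_set`.
#' @param scenario a `pk_exposure_scenario`.
#' @param t_grid optional output time grid (h); the scenario's event times
#'   are added automatically.
#' @param rtol,atol solver tolerances. `atol` is interpreted per mol of
#'   bioavailable dose (scaled internally); for a zero-dose scenario it is
#'   used as an absolute floor.
#' @param max_steps safety cap on solver steps per output interval span.
#' @return object of class `pk_sim`: list with `time` (h), `states`
#'   (matrix, one named column per compartment), `params`, `scenario`,
#'   `dose_to_date` (bioavailable dose delivered up to each time) and
#'   `dose` totals.
#' @export
simulate_scenario <- function(params, scenario, t_grid = NULL,
                              rtol = 1e-9, atol = 1e-12,
                              max_steps = 2e5) {
  stopifnot(inherits(params, "pk_parameter_set"),
            inherits(scenario, "pk_exposure_scenario"))
  .validate_routes(params, scenario)
  A <- .system_matrix(params)
  if (is.null(t_grid)) t_grid <- .default_grid(scenario)
  ev_t <- vapply(scenario$events, `[[`, numeric(1), "time_h")
  wash <- unlist(lapply(scenario$events, function(e) e$washoff_h))
  t_grid <- sort(unique(c(0, t_grid, ev_t, wash)))
  if (max(t_grid) > scenario$duration_h + 1e-9)
    stop("t_grid extends beyond the scenario duration")

  dose <- scenario_dose(scenario, params)
  # atol is per mol of bioavailable dose; absolute floor for zero-dose runs
  atol_abs <- if (dose$bioavailable_mol > 0)
    atol * dose$bioavailable_mol else atol

  n <- length(.STATE_NAMES)
  out <- matrix(0, length(t_grid), n,
                dimnames = list(NULL, .STATE_NAMES))
  x <- numeric(n)
  d2d <- numeric(length(t_grid))

  # discrete actions keyed by time
  acts <- list()
  addact <- function(tt, what) {
    key <- sprintf("%.12g", tt)
    acts[[key]] <<- c(acts[[key]], list(what))
  }
  for (e in scenario$events) {
    addact(e$time_h, list(type = "dose", event = e))
    if (!is.null(e$washoff_h)) {
      cf <- e$cis_fraction
      if (cf > 0) addact(e$washoff_h, list(type = "washoff", iso = "cis"))
      if (cf < 1) addact(e$washoff_h, list(type = "washoff", iso = "trans"))
    }
  }

  bio_now <- 0
  do_actions <- function(tt) {
    key <- sprintf("%.12g", tt)
    for (act in acts[[key]]) {
      if (act$type == "dose") {
        before <- sum(x)
        x <<- .apply_event(x, act$event, params)
        bio_now <<- bio_now + (sum(x) - before)
      } else {
        x <<- .apply_washoff(x, act$iso)
      }
    }
  }

  do_actions(t_grid[1])
  out[1, ] <- x
  d2d[1] <- bio_now
  for (i in seq_along(t_grid)[-1]) {
    x <- as.vector(.rk_span(A, x, t_grid[i - 1], t_grid[i],
                            rtol, atol_abs, max_steps))
    do_actions(t_grid[i])
    neg <- x < 0
    if (any(neg)) {
      if (min(x) < -max(1e-7 * dose$bioavailable_mol, 100 * atol_abs))
        stop("stability error: negative state beyond tolerance at t = ",
             format(t_grid[i]), " h (min = ", format(min(x)), ")",
             call. = FALSE)
      x[neg] <- 0
    }
    out[i, ] <- x
    d2d[i] <- bio_now
  }

  structure(list(time = t_grid, states = out, params = params,
                 scenario = scenario, dose_to_date = d2d,
                 dose_mol = dose$dose_mol,
                 bioavailable_mol = dose$bioavailable_mol),
            class = "pk_sim")
}

#' Instantaneous urinary excretion rates
#'
#' `QU_a(t) = M_a(t) * k_MU_a` for each analyte, evaluated on the
#' simulation's time grid.
#'
#' @param result a `pk_sim`.
#' @return matrix with columns `cisDCCA`, `transDCCA`, `PBA3` (mol/h).
#' @export
excretion_rates <- function(result) {
  stopifnot(inherits(result, "pk_sim"))
  p <- result$params
  cbind(
    cisDCCA = result$states[, "M_cis"] * p$cis$k_MU,
    transDCCA = result$states[, "M_trans"] * p$trans$k_MU,
    PBA3 = result$states[, "M_3PBA"] * p$shared$k_MU_3PBA
  )
}

# cumulative urinary series per analyte
.cum_urine <- function(result) {
  cbind(cisDCCA = result$states[, "U_cis"],
        transDCCA = result$states[, "U_trans"],
        PBA3 = result$states[, "U_3PBA"])
}

#' Tidy data frame of a simulation
#'
#' @param x a `pk_sim`.
#' @param row.names,optional,... ignored (S3 conformance).
#' @return long data frame with columns `time_h`, `compartment`, `analyte`,
#'   `amount_mol`, `pct_of_dose`.
#' @export
as.data.frame.pk_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  an_map <- c(U_cis = "cisDCCA", U_trans = "transDCCA", U_3PBA = "PBA3",
              M_cis = "cisDCCA", M_trans = "transDCCA", M_3PBA = "PBA3",
              F_cis = "cisDCCA", F_trans = "transDCCA", F_3PBA = "PBA3")
  nm <- colnames(x$states)
  df <- data.frame(
    time_h = rep(x$time, times = length(nm)),
    compartment = rep(nm, each = length(x$time)),
    analyte = rep(unname(an_map[nm]), each = length(x$time)),
    amount_mol = as.vector(x$states),
    stringsAsFactors = FALSE
  )
  df$pct_of_dose <- if (x$dose_mol > 0) 100 * df$amount_mol / x$dose_mol else 0
  df
}
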