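# Synthetic urine-void time courses with the statistical structure the
# fitting assumes: jittered void schedules (optional nocturnal gap),
# multiplicative lognormal measurement noise, and occasional incomplete
# voids. Fixtures emulate the published volunteer study designs so the
# estimation pipeline can be exercised without any external data.

#' Generate a urine-void collection schedule
#'
#' Contiguous void intervals covering `[0, duration_h]`: inter-void
#' intervals are `mean_interval_h * (1 + jitter * U(-1, 1))`, optionally
#' replaced by a single 8-h interval overnight (one long nocturnal void).
#'
#' @param duration_h total collection period (h).
#' @param mean_interval_h mean inter-void interval (h); must be shorter
#'   than the duration.
#' @param jitter relative uniform jitter of the intervals in `[0, 1)`.
#' @param nocturnal_gap if `TRUE` (default) an interval starting within the
#'   23:00-24:00 clock hour spans 8 h.
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `pk_void_schedule`: data frame with `t_start`,
#'   `t_end` (h).
#' @export
generate_void_schedule <- function(duration_h = 120, mean_interval_h = 4,
                                   jitter = 0.3, nocturnal_gap = TRUE,
                                   seed = NULL) {
  stopifnot(duration_h > 0, jitter >= 0, jitter < 1)
  if (mean_interval_h >= duration_h)
    stop("mean_interval_h must be smaller than duration_h")
  if (!is.null(seed)) set.seed(seed)
  t <- 0
  starts <- numeric(0)
  ends <- numeric(0)
  while (t < duration_h - 1e-9) {
    dt <- if (nocturnal_gap && (t %% 24) >= 23) 8 else
      mean_interval_h * (1 + jitter * stats::runif(1, -1, 1))
    nxt <- min(t + dt, duration_h)
    starts <- c(starts, t)
    ends <- c(ends, nxt)
    t <- nxt
  }
  structure(data.frame(t_start = starts, t_end = ends),
            class = c("pk_void_schedule", "data.frame"),
            mean_interval_h = mean_interval_h, jitter = jitter,
            nocturnal_gap = nocturnal_gap)
}

#' Measurement noise model for synthetic voids
#'
#' Multiplicative lognormal noise (mean-one, coefficient of variation `cv`)
#' per void, plus an incomplete-void process: with probability
#' `incomplete_prob` a void retains only `incomplete_fraction` of its true
#' amount and is flagged.
#'
#' @param cv lognormal coefficient of variation (default 0.15).
#' @param incomplete_prob probability a void is incomplete.
#' @param incomplete_fraction fraction of the amount retained by an
#'   incomplete void.
#' @return list of class `pk_noise_model`.
#' @export
noise_model <- function(cv = 0.15, incomplete_prob = 0,
                        incomplete_fraction = 0.5) {
  stopifnot(cv >= 0, incomplete_prob >= 0, incomplete_prob <= 1,
            incomplete_fraction >= 0, incomplete_fraction <= 1)
  structure(list(cv = cv, incomplete_prob = incomplete_prob,
                 incomplete_fraction = incomplete_fraction),
            class = "pk_noise_model")
}

#' Synthesize observed urinary time courses
#'
#' Simulates the kinetic model for a scenario, bins the cumulative urinary
#' excretion of each analyte into the voids of a schedule, and applies the
#' noise model. With `cv = 0` and no incompleteness the amounts equal the
#' model increments exactly. Under dermal exposure the 3-PBA amounts are
#' multiplied by the parameter set's `dermal_3PBA_factor` (observation
#' layer; default 1).
#'
#' @param params a `pk_parameter_set`.
#' @param scenario a `pk_exposure_scenario` (single-event scenarios carry
#'   their route/dose metadata into the time courses).
#' @param schedule a `pk_void_schedule`.
#' @param noise a `pk_noise_model`.
#' @param subject subject label.
#' @param seed optional RNG seed.
#' @return named list of three `pk_timecourse` objects (`cisDCCA`,
#'   `transDCCA`, `PBA3`).
#' @export
synthesize_timecourse <- function(params, scenario, schedule,
                                  noise = noise_model(), subject = "synth1",
                                  seed = NULL) {
  stopifnot(inherits(params, "pk_parameter_set"),
            inherits(scenario, "pk_exposure_scenario"),
            inherits(schedule, "pk_void_schedule"))
  if (!is.null(seed)) set.seed(seed)
  bounds <- sort(unique(c(schedule$t_start, schedule$t_end)))
  grid <- sort(unique(c(.default_grid(scenario), bounds)))
  grid <- grid[grid <= scenario$duration_h]
  sim <- simulate_scenario(params, scenario, t_grid = grid)
  U <- .cum_urine(sim)
  dermal <- any(vapply(scenario$events, function(e) e$route == "dermal",
                       logical(1)))
  ev <- scenario$events[[1]]
  n <- nrow(schedule)
  sdlog <- sqrt(log(1 + noise$cv^2))
  out <- list()
  for (a in .ANALYTES) {
    ua <- stats::approx(sim$time, U[, a], bounds)$y
    inc <- diff(ua)[match(schedule$t_start, bounds[-length(bounds)])]
    if (a == "PBA3" && dermal)
      inc <- inc * params$shared$dermal_3PBA_factor
    if (noise$cv > 0)
      inc <- inc * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    incomplete <- stats::runif(n) < noise$incomplete_prob
    inc[incomplete] <- inc[incomplete] * noise$incomplete_fraction
    out[[a]] <- observed_timecourse(
      subject = subject, analyte = a,
      voids = data.frame(t_start = schedule$t_start,
                         t_end = schedule$t_end,
                         amount_mol = inc, incomplete = incomplete),
      route = ev$route, dose_mol = sum(vapply(scenario$events, `[[`,
                                              numeric(1), "amount_mol")),
      cis_fraction = ev$cis_fraction, washoff_h = ev$washoff_h)
  }
  out
}

#' Bundled exposure-design fixtures
#'
#' Named exposure scenarios emulating the volunteer study designs used for
#' model calibration and evaluation:
#' \describe{
#'   \item{woollen_oral}{single oral bolus of 3.3 mg cypermethrin
#'     (cis:trans 50:50), 120-h urine collection.}
#'   \item{woollen_dermal}{dermal application of 31 mg cypermethrin
#'     (cis:trans 56:44), skin cleaned 8 h post-application, 120-h
#'     collection.}
#'   \item{tomalik_wholebody}{whole-body dermal application of 3 g
#'     permethrin (cream).}
#'   \item{tomalik_scalp}{scalp application of 215 mg permethrin
#'     (solution).}
#' }
#' The permethrin fixtures use a 25:75 cis:trans composition (typical
#' technical permethrin; not stated in the source designs).
#'
#' @param kind fixture name.
#' @return list with the `scenario` and default `schedule` arguments
#'   (duration, mean interval, jitter, nocturnal gap).
#' @export
design_fixture <- function(kind = c("woollen_oral", "woollen_dermal",
                                    "tomalik_wholebody", "tomalik_scalp")) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    stop("unknown fixture '", kind[1], "'; valid kinds: woollen_oral, ",
         "woollen_dermal, tomalik_wholebody, tomalik_scalp", call. = FALSE))
  sched <- list(duration_h = 120, mean_interval_h = 4, jitter = 0.3,
                nocturnal_gap = TRUE)
  scenario <- switch(kind,
    woollen_oral = exposure_scenario(
      exposure_event("oral", 0, amount_mg = 3.3, compound = "cypermethrin",
                     cis_fraction = 0.5), duration_h = 120),
    woollen_dermal = exposure_scenario(
      exposure_event("dermal", 0, amount_mg = 31, compound = "cypermethrin",
                     cis_fraction = 0.56, washoff_h = 8), duration_h = 120),
    tomalik_wholebody = exposure_scenario(
      exposure_event("dermal", 0, amount_mg = 3000, compound = "permethrin",
                     cis_fraction = 0.25), duration_h = 120),
    tomalik_scalp = exposure_scenario(
      exposure_event("dermal", 0, amount_mg = 215, compound = "permethrin",
                     cis_fraction = 0.25), duration_h = 120)
  )
  list(kind = kind, scenario = scenario, schedule = sched)
}
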