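# Exposure scenarios: timed dose events with route, cis:trans split and
# optional dermal wash-off.

#' Create a single exposure event
#'
#' A dose event delivers `amount_mol` of total parent compound (both isomers)
#' at `time_h` by the given route. Doses may instead be given in mg together
#' with the compound name for molar conversion. For dermal events an optional
#' `washoff_h` removes whatever remains of the skin depot at that time.
#'
#' @param route `"oral"`, `"dermal"` or `"inhalation"`.
#' @param time_h event time in hours (>= 0).
#' @param amount_mol total parent-compound dose in mol.
#' @param amount_mg alternative dose in mg; requires `compound`.
#' @param compound `"cypermethrin"` or `"permethrin"` (used for mg
#'   conversion only).
#' @param cis_fraction molar fraction of the cis isomer in `[0, 1]`.
#' @param washoff_h dermal only: time (h, absolute) at which the remaining
#'   surface depot is removed; must exceed `time_h`.
#' @return a list of class `pk_exposure_event`.
#' @export
exposure_event <- function(route = c("oral", "dermal", "inhalation"),
                           time_h = 0, amount_mol = NULL, amount_mg = NULL,
                           compound = c("cypermethrin", "permethrin"),
                           cis_fraction = 0.5, washoff_h = NULL) {
  route <- match.arg(route)
  if (is.null(amount_mol)) {
    if (is.null(amount_mg)) stop("supply amount_mol or amount_mg")
    compound <- match.arg(compound)
    amount_mol <- amount_mg / 1000 / molar_mass(compound)
  }
  stopifnot(is.numeric(amount_mol), amount_mol >= 0,
            is.numeric(time_h), time_h >= 0,
            cis_fraction >= 0, cis_fraction <= 1)
  if (!is.null(washoff_h)) {
    if (route != "dermal") stop("washoff_h applies to dermal events only")
    if (washoff_h <= time_h) stop("washoff_h must be later than the event time")
  }
  structure(list(route = route, time_h = time_h, amount_mol = amount_mol,
                 cis_fraction = cis_fraction, washoff_h = washoff_h),
            class = "pk_exposure_event")
}

#' Create an exposure scenario
#'
#' An ordered collection of exposure events plus the total simulated
#' duration.
#'
#' @param events a `pk_exposure_event` or list of them.
#' @param duration_h total duration in hours; must cover the last event (and
#'   any wash-off time).
#' @return a list of class `pk_exposure_scenario`.
#' @export
exposure_scenario <- function(events, duration_h) {
  if (inherits(events, "pk_exposure_event")) events <- list(events)
  stopifnot(length(events) >= 1,
            all(vapply(events, inherits, logical(1), "pk_exposure_event")))
  events <- events[order(vapply(events, `[[`, numeric(1), "time_h"))]
  tmax <- max(vapply(events, function(e)
    max(e$time_h, e$washoff_h %||% e$time_h), numeric(1)))
  if (duration_h < tmax) stop("duration_h must cover all events and wash-off times")
  structure(list(events = events, duration_h = duration_h),
            class = "pk_exposure_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total and bioavailable dose of a scenario
#'
#' @param scenario a `pk_exposure_scenario`.
#' @param params a `pk_parameter_set` (needed for absorption fractions).
#' @return list with `dose_mol` (administered) and `bioavailable_mol`
#'   (dose entering the input compartments, i.e. after the absorption
#'   fraction is applied; for inhalation the full amount).
#' @export
scenario_dose <- function(scenario, params) {
  dose <- sum(vapply(scenario$events, `[[`, numeric(1), "amount_mol"))
  bio <- sum(vapply(scenario$events, function(e) {
    frac <- c(cis = e$cis_fraction, trans = 1 - e$cis_fraction)
    sum(vapply(.ISOMERS, function(s) {
      fa <- switch(e$route,
                   oral = params[[s]]$f_abs_oral,
                   dermal = params[[s]]$f_abs_dermal,
                   inhalation = 1)
      if (is.na(fa)) stop("f_abs_", e$route, "_", s,
                          " is not set but the scenario has a ", e$route,
                          " event", call. = FALSE)
      fa * frac[[s]] * e$amount_mol
    }, numeric(1)))
  }, numeric(1)))
  list(dose_mol = dose, bioavailable_mol = bio)
}

#' Repeated-dosing scenario builder
#'
#' Convenience constructor for a repeated oral exposure at fixed clock times
#' each day (default 7:30, 12:30 and 18:30) over several days.
#'
#' @param daily_mg total daily dose in mg of `compound`.
#' @param n_days number of dosing days.
#' @param times_h dose clock times within a day (hours).
#' @param compound,cis_fraction passed to [exposure_event()].
#' @param extra_h additional simulated time after the last dosing day.
#' @return a `pk_exposure_scenario`.
#' @export
repeated_oral_scenario <- function(daily_mg = 0.33, n_days = 10,
                                   times_h = c(7.5, 12.5, 18.5),
                                   compound = "cypermethrin",
                                   cis_fraction = 0.5, extra_h = 6) {
  per_dose <- daily_mg / length(times_h)
  events <- list()
  for (d in seq_len(n_days) - 1) {
    for (tt in times_h) {
      events[[length(events) + 1]] <- exposure_event(
        "oral", time_h = 24 * d + tt, amount_mg = per_dose,
        compound = compound, cis_fraction = cis_fraction)
    }
  }
  exposure_scenario(events, duration_h = 24 * n_days + extra_h)
}
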