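# File formats: observed time-course CSV, parameter and scenario files
# (JSON/YAML), tidy simulation output.
#
# Time-course CSV dialect: comma-separated, UTF-8, header required, columns
# subject, analyte, t_start_h, t_end_h, amount_nmol, incomplete_flag.
# Amounts are stored in nmol; molar masses are bundled for ug <-> nmol
# conversion of the analytes.

#' Write observed time courses to CSV
#'
#' @param tcs a `pk_timecourse` or (named) list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tcs, path) {
  if (inherits(tcs, "pk_timecourse")) tcs <- list(tcs)
  rows <- do.call(rbind, lapply(tcs, function(tc) {
    data.frame(subject = tc$subject, analyte = tc$analyte,
               t_start_h = tc$voids$t_start, t_end_h = tc$voids$t_end,
               amount_nmol = tc$voids$amount_mol * 1e9,
               incomplete_flag = as.integer(tc$voids$incomplete),
               route = tc$route, dose_mol = tc$dose_mol,
               cis_fraction = tc$cis_fraction,
               washoff_h = tc$washoff_h %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read observed time courses from CSV
#'
#' Validates intervals, analytes and amounts; parse errors name the
#' offending rows (1-based, excluding the header).
#'
#' @param path CSV file in the documented dialect.
#' @return named list of `pk_timecourse` objects, one per
#'   (subject, analyte).
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "analyte", "t_start_h", "t_end_h", "amount_nmol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  bad <- which(!df$analyte %in% .ANALYTES)
  if (length(bad))
    stop("unknown analyte in rows ", paste(bad, collapse = ", "),
         " (valid: ", paste(.ANALYTES, collapse = ", "), ")", call. = FALSE)
  bad <- which(df$amount_nmol < 0)
  if (length(bad))
    stop("negative amount in rows ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(df$t_end_h <= df$t_start_h)
  if (length(bad))
    stop("non-positive interval in rows ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(df$incomplete_flag)) df$incomplete_flag <- 0L
  df$row <- seq_len(nrow(df))
  out <- list()
  for (key in unique(paste(df$subject, df$analyte, sep = "\r"))) {
    sub <- df[paste(df$subject, df$analyte, sep = "\r") == key, , drop = FALSE]
    sub <- sub[order(sub$t_start_h), , drop = FALSE]
    if (nrow(sub) > 1) {
      ov <- which(sub$t_start_h[-1] < sub$t_end_h[-nrow(sub)] - 1e-9)
      if (length(ov))
        stop("overlapping voids in rows ",
             paste(sub$row[ov], sub$row[ov + 1], sep = "/", collapse = ", "),
             call. = FALSE)
    }
    tc <- observed_timecourse(
      subject = sub$subject[1], analyte = sub$analyte[1],
      voids = data.frame(t_start = sub$t_start_h, t_end = sub$t_end_h,
                         amount_mol = sub$amount_nmol / 1e9,
                         incomplete = as.logical(sub$incomplete_flag)),
      route = if (!is.null(sub$route)) sub$route[1] else "oral",
      dose_mol = if (!is.null(sub$dose_mol)) sub$dose_mol[1] else NA_real_,
      cis_fraction = if (!is.null(sub$cis_fraction)) sub$cis_fraction[1] else 0.5,
      washoff_h = if (!is.null(sub$washoff_h) && !is.na(sub$washoff_h[1]))
        sub$washoff_h[1] else NULL)
    out[[tc$analyte]] <- tc
  }
  out
}

.read_by_ext <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

.write_by_ext <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Write a parameter set to a JSON or YAML file
#'
#' Keys are the ASCII symbol names (`k_abs_oral_cis`, `omega_trans`, ...);
#' rates are in 1/h.
#'
#' @param params a `pk_parameter_set`.
#' @param path output file (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(params, path) {
  stopifnot(inherits(params, "pk_parameter_set"))
  x <- params$raw
  x$units <- "h^-1 (rates); fractions dimensionless; omega in h^-2"
  x$provenance <- params$provenance
  .write_by_ext(x, path)
}

#' Read a parameter set from a JSON or YAML file
#'
#' @param path file written by [write_parameter_file()] or hand-authored
#'   with the same keys; a `preset` key may name a bundled preset to use as
#'   the base, with remaining keys as overrides.
#' @param ... passed to [assemble_parameter_set()].
#' @return a `pk_parameter_set`.
#' @export
read_parameter_file <- function(path, ...) {
  x <- .read_by_ext(path)
  x$units <- NULL
  prov <- x$provenance %||% path
  x$provenance <- NULL
  if (!is.null(x$preset)) {
    preset <- x$preset
    x$preset <- NULL
    return(do.call(pk_preset, c(list(name = preset), x)))
  }
  assemble_parameter_set(x, provenance = prov, ...)
}

#' Read an exposure scenario from a JSON or YAML file
#'
#' The file holds `duration_h` and an `events` list; each event has
#' `route`, `time_h`, and either `amount_mol` or `amount_mg` (+
#' `compound`), plus optional `cis_fraction` and `washoff_h`.
#'
#' @param path scenario file.
#' @return a `pk_exposure_scenario`.
#' @export
read_scenario_file <- function(path) {
  x <- .read_by_ext(path)
  evs <- x$events
  if (is.data.frame(evs)) evs <- split(evs, seq_len(nrow(evs)))
  events <- lapply(evs, function(e) {
    exposure_event(route = e$route, time_h = e$time_h %||% 0,
                   amount_mol = if (is.null(e$amount_mol) ||
                                    is.na(e$amount_mol)) NULL else e$amount_mol,
                   amount_mg = if (is.null(e$amount_mg) ||
                                   is.na(e$amount_mg)) NULL else e$amount_mg,
                   compound = e$compound %||% "cypermethrin",
                   cis_fraction = e$cis_fraction %||% 0.5,
                   washoff_h = if (is.null(e$washoff_h) ||
                                   is.na(e$washoff_h)) NULL else e$washoff_h)
  })
  exposure_scenario(events, duration_h = x$duration_h)
}

#' Write an exposure scenario to a JSON or YAML file
#'
#' @param scenario a `pk_exposure_scenario`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_file <- function(scenario, path) {
  stopifnot(inherits(scenario, "pk_exposure_scenario"))
  .write_by_ext(list(
    duration_h = scenario$duration_h,
    events = lapply(scenario$events, function(e)
      list(route = e$route, time_h = e$time_h, amount_mol = e$amount_mol,
           cis_fraction = e$cis_fraction,
           washoff_h = e$washoff_h %||% NA))
  ), path)
}

#' Write a simulation as tidy CSV
#'
#' Long format: `time_h`, `compartment`, `analyte`, `amount_mol`,
#' `pct_of_dose`.
#'
#' @param result a `pk_sim`.
#' @param path output file.
#' @param thin write every `thin`-th grid point (default 1 = all).
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(result, path, thin = 1) {
  df <- as.data.frame(result)
  if (thin > 1) {
    keep <- result$time %in% result$time[seq(1, length(result$time), by = thin)]
    df <- df[rep(keep, times = ncol(result$states)), , drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
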