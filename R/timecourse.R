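# Observed urinary time courses: per-void collections for one subject,
# analyte and exposure.

#' Create an observed urinary time course
#'
#' One subject's per-void urine collections of a single analyte after a
#' known exposure. Voids are contiguous or gapped intervals; amounts are the
#' total moles of the analyte collected in each interval. Voids flagged as
#' incomplete are kept but excluded from fitting objectives.
#'
#' @param subject subject identifier.
#' @param analyte one of `"cisDCCA"`, `"transDCCA"`, `"PBA3"`.
#' @param voids data frame with columns `t_start`, `t_end` (h) and
#'   `amount_mol`; optional logical column `incomplete`.
#' @param route exposure route (`"oral"` or `"dermal"`).
#' @param dose_mol administered parent-compound dose (mol).
#' @param cis_fraction molar cis fraction of the dose.
#' @param washoff_h optional dermal wash-off time (h).
#' @return object of class `pk_timecourse`.
#' @export
observed_timecourse <- function(subject, analyte, voids,
                                route = c("oral", "dermal"),
                                dose_mol, cis_fraction = 0.5,
                                washoff_h = NULL) {
  route <- match.arg(route)
  analyte <- match.arg(analyte, .ANALYTES)
  stopifnot(is.data.frame(voids),
            all(c("t_start", "t_end", "amount_mol") %in% names(voids)))
  if (is.null(voids$incomplete)) voids$incomplete <- FALSE
  voids <- voids[order(voids$t_start), , drop = FALSE]
  if (any(voids$t_end <= voids$t_start))
    stop("void intervals must have t_end > t_start")
  if (nrow(voids) > 1 &&
      any(voids$t_start[-1] < voids$t_end[-nrow(voids)] - 1e-9))
    stop("void intervals must not overlap")
  if (any(voids$amount_mol < 0)) stop("void amounts must be >= 0")
  structure(list(subject = subject, analyte = analyte,
                 voids = voids, route = route, dose_mol = dose_mol,
                 cis_fraction = cis_fraction, washoff_h = washoff_h),
            class = "pk_timecourse")
}

# observed interval excretion rates at void midpoints (complete voids only
# unless include_incomplete)
.void_rates <- function(tc, include_incomplete = FALSE) {
  v <- tc$voids
  if (!include_incomplete) v <- v[!v$incomplete, , drop = FALSE]
  data.frame(mid = (v$t_start + v$t_end) / 2,
             t_start = v$t_start, t_end = v$t_end,
             rate = v$amount_mol / (v$t_end - v$t_start),
             amount = v$amount_mol)
}

#' @export
print.pk_timecourse <- function(x, ...) {
  cat("<pk_timecourse> subject:", x$subject, " analyte:", x$analyte,
      " route:", x$route, "\n  ", nrow(x$voids), "voids over [",
      min(x$voids$t_start), ",", max(x$voids$t_end), "] h;",
      sum(x$voids$incomplete), "incomplete\n")
  invisible(x)
}
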