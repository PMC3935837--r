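# Closed-form urinary excretion for a single bolus.
#
# For one isomer the Laplace transform of the urinary excretion rate is
#   QU(s) = K (s + k_SB) / [(s + k_abs)(s + l1)(s + l2)(s + k_elim)],
# with K = D0 * k_abs * k_BM * k_MU, where l1, l2 are the eigenvalues of the
# blood-storage subsystem (roots of l^2 - (k_BS + k_metabolism + k_SB) l +
# k_SB * k_metabolism, both positive). With distinct poles QU(t) and U(t)
# are four-exponential partial-fraction sums; when poles (nearly) coincide
# the evaluation switches automatically to divided differences of the
# exponential (Opitz formula), which is exact in the confluent limit.

# exp of a small matrix by scaling-and-squaring + Taylor (self-contained;
# only used for <= 6 x 6 bidiagonal matrices)
.expm_small <- function(M) {
  nrm <- max(colSums(abs(M)), 0)
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.xmin)) + 1))
  if (!is.finite(s)) s <- 0L
  Ms <- M / 2^s
  E <- diag(nrow(M))
  term <- E
  for (k in 1:18) {
    term <- term %*% Ms / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Divided differences of the decaying exponential
#'
#' Computes the divided difference of `f(l) = exp(-l * t)` over the points
#' `lambda`, stably for coincident or nearly coincident points via the Opitz
#' (bidiagonal matrix exponential) representation. This is the numerical
#' primitive behind the closed-form bolus solutions: the impulse response of
#' a cascade of first-order transfers with rates `lambda` is, up to sign and
#' a product of rates, exactly such a divided difference.
#'
#' @param lambda numeric vector of rate points (1/h), any multiplicity.
#' @param t numeric vector of times (h).
#' @return numeric vector, one divided difference per element of `t`.
#' @export
exp_divided_diff <- function(lambda, t) {
  n <- length(lambda)
  if (n == 1) return(exp(-lambda * t))
  vapply(t, function(tt) {
    Z <- diag(-tt * lambda, n)
    Z[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
    (-tt)^(n - 1) * .expm_small(Z)[1, n]
  }, numeric(1))
}

# Eigenvalues of the blood-storage block, stable quadratic formula.
.bs_eigen <- function(k_BS, k_SB, k_metabolism) {
  p <- k_BS + k_metabolism + k_SB
  q <- k_SB * k_metabolism
  disc <- p^2 - 4 * q
  disc <- max(disc, 0)
  l1 <- (p + sqrt(disc)) / 2
  l2 <- q / l1
  c(l1, l2)
}

# Single-metabolite bolus evaluator. D0 enters the input compartment (i.e.
# bioavailable amount); poles = (k_abs, l1, l2, k_elim_met). Returns list of
# vectorized functions QU(t), U(t) and the asymptote U_inf.
.bolus_kernel <- function(D0, k_abs, k_BS, k_SB, k_metabolism,
                          k_form, k_MU, k_elim_met) {
  lam <- c(k_abs, .bs_eigen(k_BS, k_SB, k_metabolism), k_elim_met)
  K <- D0 * k_abs * k_form * k_MU
  U_inf <- K * k_SB / prod(lam)
  gaps <- abs(outer(lam, lam, `-`))
  diag(gaps) <- Inf
  degenerate <- min(gaps) < 1e-6 * max(lam)
  if (!degenerate) {
    w <- vapply(seq_along(lam), function(i) {
      K * (k_SB - lam[i]) / prod(lam[-i] - lam[i])
    }, numeric(1))
    QU <- function(t) {
      E <- exp(-outer(t, lam))
      pmax(as.vector(E %*% w), 0) * (t >= 0)
    }
    U <- function(t) {
      E <- exp(-outer(t, lam))
      pmax(U_inf - as.vector(E %*% (w / lam)), 0) * (t >= 0)
    }
  } else {
    # confluent limit: divided-difference forms (drop the first pole from
    # the short set; the representation is pole-order independent)
    QU <- function(t) {
      v <- K * (exp_divided_diff(lam[-1], t) -
                  (k_SB - lam[1]) * exp_divided_diff(lam, t))
      pmax(v, 0) * (t >= 0)
    }
    U <- function(t) {
      v <- K * (-exp_divided_diff(c(0, lam[-1]), t) +
                  (k_SB - lam[1]) * exp_divided_diff(c(0, lam), t))
      pmax(v, 0) * (t >= 0)
    }
  }
  list(QU = QU, U = U, U_inf = U_inf, poles = lam)
}

# wrap a kernel with dermal wash-off superposition: removing the remaining
# depot at t_w is, by linearity, equivalent to subtracting the response of a
# fresh bolus of size D(t_w) started at t_w
.washoff_kernel <- function(make_kernel, D0, k_abs, washoff_h) {
  full <- make_kernel(D0)
  Dw <- D0 * exp(-k_abs * washoff_h)
  resid <- make_kernel(Dw)
  list(
    QU = function(t) {
      v <- full$QU(t)
      late <- t > washoff_h
      v[late] <- v[late] - resid$QU(t[late] - washoff_h)
      pmax(v, 0)
    },
    U = function(t) {
      v <- full$U(t)
      late <- t > washoff_h
      v[late] <- v[late] - resid$U(t[late] - washoff_h)
      pmax(v, 0)
    },
    U_inf = full$U_inf - resid$U_inf,
    poles = full$poles
  )
}

#' Closed-form urinary excretion after a single bolus
#'
#' Returns closed-form evaluators of the urinary excretion rate `QU(t)` and
#' cumulative urinary excretion `U(t)` of each analyte after a single oral or
#' dermal bolus at `t = 0`, by eigen-decomposition of the blood-storage
#' subsystem cascaded through first-order absorption and metabolite
#' elimination. Near-degenerate rate constants are handled by an automatic
#' switch to confluent (divided-difference) limit forms.
#'
#' An optional dermal wash-off (removal of the remaining skin depot at
#' `washoff_h`) is handled exactly by linear superposition.
#'
#' @param params a `pk_parameter_set`.
#' @param route `"oral"` or `"dermal"`.
#' @param dose_mol total administered parent compound (mol).
#' @param cis_fraction molar cis fraction of the dose.
#' @param washoff_h optional wash-off time (dermal only).
#' @return object of class `pk_analytic` with elements `U(t, analyte)` and
#'   `QU(t, analyte)` (vectorized in `t`), `U_inf` (named asymptotes, mol),
#'   and the route/dose metadata.
#' @export
analytic_bolus_solution <- function(params, route = c("oral", "dermal"),
                                    dose_mol = 1, cis_fraction = 0.5,
                                    washoff_h = NULL) {
  route <- match.arg(route)
  stopifnot(inherits(params, "pk_parameter_set"), dose_mol >= 0)
  if (!is.null(washoff_h) && route != "dermal")
    stop("washoff_h applies to dermal exposure only")
  frac <- c(cis = cis_fraction, trans = 1 - cis_fraction)
  sh <- params$shared

  kernels <- list()
  for (s in .ISOMERS) {
    p <- params[[s]]
    ka <- switch(route, oral = p$k_abs_oral, dermal = p$k_abs_dermal)
    fa <- switch(route, oral = p$f_abs_oral, dermal = p$f_abs_dermal)
    if (is.na(ka) || is.na(fa))
      stop("absorption parameters for route '", route, "', isomer '", s,
           "' are not set", call. = FALSE)
    D0 <- fa * frac[[s]] * dose_mol
    mk_dcca <- function(d0) .bolus_kernel(d0, ka, p$k_BS, p$k_SB,
                                          p$k_metabolism, p$k_BM, p$k_MU,
                                          p$k_elim)
    mk_pba <- function(d0) .bolus_kernel(d0, ka, p$k_BS, p$k_SB,
                                         p$k_metabolism, p$k_BM_3PBA,
                                         sh$k_MU_3PBA, sh$k_elim_3PBA)
    if (is.null(washoff_h)) {
      kernels[[paste0("dcca_", s)]] <- mk_dcca(D0)
      kernels[[paste0("pba_", s)]] <- mk_pba(D0)
    } else {
      kernels[[paste0("dcca_", s)]] <- .washoff_kernel(mk_dcca, D0, ka, washoff_h)
      kernels[[paste0("pba_", s)]] <- .washoff_kernel(mk_pba, D0, ka, washoff_h)
    }
  }

  pick <- function(analyte) {
    analyte <- match.arg(analyte, .ANALYTES)
    switch(analyte,
           cisDCCA = list(kernels$dcca_cis),
           transDCCA = list(kernels$dcca_trans),
           PBA3 = list(kernels$pba_cis, kernels$pba_trans))
  }
  U_inf <- c(
    cisDCCA = kernels$dcca_cis$U_inf,
    transDCCA = kernels$dcca_trans$U_inf,
    PBA3 = kernels$pba_cis$U_inf + kernels$pba_trans$U_inf
  )
  structure(list(
    U = function(t, analyte) Reduce(`+`, lapply(pick(analyte), function(k) k$U(t))),
    QU = function(t, analyte) Reduce(`+`, lapply(pick(analyte), function(k) k$QU(t))),
    U_inf = U_inf,
    route = route, dose_mol = dose_mol, cis_fraction = cis_fraction,
    washoff_h = washoff_h
  ), class = "pk_analytic")
}
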