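#' Kinetic parameters of a one-compartment biomarker model
#'
#' Bundles the first-order absorption rate constant `ka` (brain to blood,
#' per hour), the elimination rate constant `ke` (blood to renal clearance,
#' per hour) and the bioavailability `F` (unitless fraction of released
#' biomarker that ever reaches the blood).
#'
#' @param ka Absorption rate constant, hr^-1. Must be > 0.
#' @param ke Elimination rate constant, hr^-1. Must be > 0.
#' @param F Bioavailability fraction in (0, 1]. Default 0.8, the value used
#'   for every published biomarker parameterization.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(ka = 0.08, ke = 0.0193)
#' @export
kinetic_params <- function(ka, ke, F = 0.8) {
  stopifnot(is.numeric(ka), is.numeric(ke), is.numeric(F),
            length(ka) == 1L, length(ke) == 1L, length(F) == 1L)
  if (!is.finite(ka) || ka <= 0) stop("`ka` must be a positive finite number (hr^-1)")
  if (!is.finite(ke) || ke <= 0) stop("`ke` must be a positive finite number (hr^-1)")
  if (!is.finite(F) || F <= 0 || F > 1) stop("`F` must lie in (0, 1]")
  structure(list(ka = ka, ke = ke, F = F), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters: ka = %g hr^-1, ke = %g hr^-1, F = %g\n",
              x$ka, x$ke, x$F))
  cat(sprintf("  (t1/2 = %.4g h, Tmax = %.4g h)\n",
              half_life_from_ke(x$ke), time_of_peak(x)$Tmax))
  invisible(x)
}

#' Subject-level injury scenario
#'
#' The concussion-dependent model inputs: the amount of biomarker released
#' into the brain at impact (`D0`, pg) and the volume of distribution
#' (`Vd`, ml), approximated by total blood volume. Release is assumed
#' complete and simultaneous at the time origin `t0`.
#'
#' @param D0 Biomarker released at impact, pg. Must be >= 0.
#' @param Vd Volume of distribution, ml. Must be > 0. Default 5000 ml, the
#'   nominal total blood volume used throughout the published models.
#' @param t0 Injury time origin, hours. Default 0.
#'
#' @return An object of class `injury_scenario`.
#' @examples
#' injury_scenario(D0 = 4e5)
#' @export
injury_scenario <- function(D0 = 400000, Vd = 5000, t0 = 0) {
  stopifnot(is.numeric(D0), is.numeric(Vd), is.numeric(t0),
            length(D0) == 1L, length(Vd) == 1L, length(t0) == 1L)
  if (!is.finite(D0) || D0 < 0) stop("`D0` must be a nonnegative finite amount (pg)")
  if (!is.finite(Vd) || Vd <= 0) stop("`Vd` must be a positive finite volume (ml)")
  structure(list(D0 = D0, Vd = Vd, t0 = t0), class = "injury_scenario")
}

#' @export
print.injury_scenario <- function(x, ...) {
  cat(sprintf("Injury scenario: D0 = %g pg released at t0 = %g h, Vd = %g ml\n",
              x$D0, x$t0, x$Vd))
  invisible(x)
}

# Relative ka/ke difference below which the removable singularity of the
# bi-exponential is replaced by its analytic limit F*D0*ka*t*exp(-ka*t)/Vd.
.KA_KE_TOL <- 1e-8

#' Plasma concentration of a biomarker at time t
#'
#' Evaluates the bi-exponential solution of the one-compartment model,
#' \deqn{C_p(t) = \frac{F D_0 k_a}{V_d (k_a - k_e)}
#'       \left(e^{-k_e t} - e^{-k_a t}\right),}
#' the plasma concentration (pg/ml) at `t` hours after injury. When
#' `|ka - ke|/ke < 1e-8` the removable singularity is replaced by its
#' analytic limit \eqn{F D_0 k_a t e^{-k_a t} / V_d}, so the function is
#' numerically continuous across `ka = ke`.
#'
#' @param params A [kinetic_params()] object.
#' @param scenario An [injury_scenario()] object.
#' @param t Hours since injury; vectorized; all values must be >= 0.
#'
#' @return Numeric vector of plasma concentrations, pg/ml (always >= 0).
#' @examples
#' gfap <- kinetic_params(ka = 0.08, ke = 0.0193)
#' plasma_concentration(gfap, injury_scenario(), t = 5)  # ~20.05 pg/ml
#' @export
plasma_concentration <- function(params, scenario, t) {
  check_params(params); check_scenario(scenario)
  if (!is.numeric(t)) stop("`t` must be numeric (hours)")
  if (any(t < 0)) stop("`t` must be >= 0: time is measured from injury")
  with_t <- t - scenario$t0
  with_t[with_t < 0] <- 0   # before release nothing is in the blood
  ka <- params$ka; ke <- params$ke
  if (abs(ka - ke) / ke < .KA_KE_TOL) {
    cp <- params$F * scenario$D0 * ka * with_t * exp(-ka * with_t) / scenario$Vd
  } else {
    cp <- params$F * scenario$D0 * ka / (scenario$Vd * (ka - ke)) *
      (exp(-ke * with_t) - exp(-ka * with_t))
  }
  pmax(cp, 0)
}

#' Compartment amounts and concentration at time t
#'
#' Mass-balance state of the model: the amount still in the brain
#' compartment decays as \eqn{D_{br}(t) = D_0 e^{-k_a t}}; the amount in
#' blood is \eqn{D_{bl}(t) = V_d C_p(t)}; the net rate of change of
#' `D_bl` equals inflow minus outflow, \eqn{F k_a D_{br} - k_e D_{bl}}.
#'
#' @inheritParams plasma_concentration
#' @return A data.frame of class `model_state` with columns `t`, `D_br`
#'   (pg), `D_bl` (pg) and `Cp` (pg/ml).
#' @examples
#' gfap <- kinetic_params(ka = 0.08, ke = 0.0193)
#' amounts_at(gfap, injury_scenario(), t = c(0, 5, 50))
#' @export
amounts_at <- function(params, scenario, t) {
  cp <- plasma_concentration(params, scenario, t)
  structure(
    data.frame(t = t,
               D_br = scenario$D0 * exp(-params$ka * pmax(t - scenario$t0, 0)),
               D_bl = scenario$Vd * cp,
               Cp = cp),
    class = c("model_state", "data.frame"))
}

#' Elimination rate constant from half-life (and back)
#'
#' First-order elimination gives `ke = 0.693 / t_half`. The printed
#' constant 0.693 is the default so that derived rate constants reproduce
#' the published tables digit-for-digit; pass `const = log(2)` for the
#' exact relation.
#'
#' @param t_half Elimination half-life, hours (> 0).
#' @param ke Elimination rate constant, hr^-1 (> 0).
#' @param const Numerator constant; 0.693 (printed) by default, `log(2)`
#'   for full precision.
#' @return `ke_from_half_life()`: ke in hr^-1. `half_life_from_ke()`:
#'   half-life in hours. The two are exact inverses for a common `const`.
#' @examples
#' ke_from_half_life(36)     # GFAP: 0.01925
#' half_life_from_ke(0.462)  # S100B: 1.5
#' @export
ke_from_half_life <- function(t_half, const = 0.693) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0))
    stop("`t_half` must be positive and finite (hours)")
  const / t_half
}

#' @rdname ke_from_half_life
#' @export
half_life_from_ke <- function(ke, const = 0.693) {
  if (!is.numeric(ke) || any(!is.finite(ke)) || any(ke <= 0))
    stop("`ke` must be positive and finite (hr^-1)")
  const / ke
}

#' Time and height of the concentration peak
#'
#' The concentration curve peaks at
#' \eqn{T_{max} = \ln(k_a/k_e) / (k_a - k_e)}, the boundary between the
#' absorption phase (levels rising) and the elimination phase (levels
#' falling). At `ka = ke` the expression has the removable limit
#' `1 / ka`. `Cmax` is filled in by evaluating the curve at `Tmax` when a
#' scenario is supplied.
#'
#' @param params A [kinetic_params()] object.
#' @param scenario Optional [injury_scenario()]; when given, `Cmax` is the
#'   concentration at `Tmax` for that subject, otherwise `NA`.
#' @return An object of class `peak_summary`: list with `Tmax` (h),
#'   `Cmax` (pg/ml or NA) and `t_half` (h, = 0.693/ke).
#' @examples
#' time_of_peak(kinetic_params(ka = 0.08, ke = 0.0193))  # Tmax ~ 23.4 h
#' @export
time_of_peak <- function(params, scenario = NULL) {
  check_params(params)
  ka <- params$ka; ke <- params$ke
  tmax <- if (abs(ka - ke) / ke < .KA_KE_TOL) 1 / ka else log(ka / ke) / (ka - ke)
  cmax <- if (is.null(scenario)) NA_real_ else
    plasma_concentration(params, scenario, tmax)
  structure(list(Tmax = tmax, Cmax = cmax, t_half = half_life_from_ke(ke)),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("Peak: Tmax = %.4g h, Cmax = %s, t1/2 = %.4g h\n", x$Tmax,
              if (is.na(x$Cmax)) "NA (no scenario)" else sprintf("%.4g pg/ml", x$Cmax),
              x$t_half))
  invisible(x)
}

#' Absorption rate constant consistent with an observed time of peak
#'
#' Inverts \eqn{T_{max} = \ln(k_a/k_e)/(k_a - k_e)} for `ka` given `ke`.
#' The relation is symmetric under exchange of the two rate constants
#' ("flip-flop" kinetics), so two roots exist: one with `ka > ke`
#' (absorption faster than elimination, the regime of every published
#' biomarker preset) and one with `ka < ke`. The root on the requested
#' branch is found by Brent's method on a bracketing interval and is
#' accurate to a relative tolerance of 1e-12.
#'
#' At `Tmax * ke = 1` the two branches meet and the unique solution is
#' `ka = ke`; this is returned with attribute `degenerate = TRUE`.
#'
#' @param Tmax Observed time of peak concentration, hours (> 0).
#' @param ke Elimination rate constant, hr^-1 (> 0).
#' @param branch `"absorption-faster"` (default, ka > ke) or
#'   `"absorption-slower"` (ka < ke).
#' @return `ka` in hr^-1, satisfying `time_of_peak()` to ~1e-12 relative.
#' @examples
#' ka_from_tmax(240, 0.0014)  # NF-L: ~0.00928, prints as 0.009
#' ka_from_tmax(24, 0.0193)   # GFAP: ~0.0769, prints as 0.08
#' @export
ka_from_tmax <- function(Tmax, ke,
                         branch = c("absorption-faster", "absorption-slower")) {
  branch <- match.arg(branch)
  if (!is.numeric(Tmax) || length(Tmax) != 1L || !is.finite(Tmax) || Tmax <= 0)
    stop("`Tmax` must be a single positive number (hours)")
  if (!is.numeric(ke) || length(ke) != 1L || !is.finite(ke) || ke <= 0)
    stop("`ke` must be a single positive number (hr^-1)")

  # Tmax(ka) -> 1/ke * ... ; at ka == ke, Tmax = 1/ka, so Tmax*ke == 1 is the
  # degenerate meeting point of the two branches.
  if (abs(Tmax * ke - 1) < 1e-12)
    return(structure(ke, degenerate = TRUE))

  fobj <- function(ka) log(ka / ke) / (ka - ke) - Tmax
  if (branch == "absorption-faster") {
    lo <- ke * (1 + 1e-9)
    hi <- max(10, 100 * ke)
    # Tmax(ka) decreases in ka on this branch: need Tmax(lo) > Tmax > Tmax(hi)
    if (fobj(lo) < 0)
      stop("no `ka > ke` solves this Tmax: Tmax*ke > 1 places the peak on the ",
           "absorption-slower branch")
    while (fobj(hi) > 0 && hi < 1e8) hi <- hi * 10
    if (fobj(hi) > 0) stop("failed to bracket a root for `ka` above `ke`")
  } else {
    lo <- ke * 1e-12
    hi <- ke * (1 - 1e-9)
    if (fobj(hi) > 0)
      stop("no `ka < ke` solves this Tmax: Tmax*ke < 1 places the peak on the ",
           "absorption-faster branch")
    while (fobj(lo) < 0 && lo > ke * 1e-30) lo <- lo / 10
    if (fobj(lo) < 0) stop("failed to bracket a root for `ka` below `ke`")
  }
  uniroot(fobj, lower = lo, upper = hi, tol = ke * 1e-13)$root
}

#' Concentration curve over a time grid
#'
#' @param params A [kinetic_params()] object.
#' @param scenario An [injury_scenario()] object.
#' @param times Strictly increasing, nonnegative time grid, hours. An empty
#'   grid yields an empty curve.
#' @return A data.frame of class `concentration_curve` with columns
#'   `time_hr` and `level_pg_ml`.
#' @examples
#' gfap <- kinetic_params(ka = 0.08, ke = 0.0193)
#' head(curve_over_grid(gfap, injury_scenario(), seq(0, 120, by = 0.5)))
#' @export
curve_over_grid <- function(params, scenario, times) {
  if (!is.numeric(times)) stop("`times` must be numeric (hours)")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (length(times) && any(times < 0)) stop("`times` must be nonnegative")
  levels <- if (length(times)) plasma_concentration(params, scenario, times)
            else numeric(0)
  structure(data.frame(time_hr = as.numeric(times), level_pg_ml = levels),
            class = c("concentration_curve", "data.frame"))
}

#' @export
plot.concentration_curve <- function(x, ..., xlab = "Time after injury (h)",
                                     ylab = "Plasma level (pg/ml)", type = "l") {
  graphics::plot(x$time_hr, x$level_pg_ml, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# internal validators shared across modules
check_params <- function(params) {
  if (!inherits(params, "kinetic_params"))
    stop("`params` must be a `kinetic_params` object (see kinetic_params())")
  invisible(params)
}
check_scenario <- function(scenario) {
  if (!inherits(scenario, "injury_scenario"))
    stop("`scenario` must be an `injury_scenario` object (see injury_scenario())")
  invisible(scenario)
}
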