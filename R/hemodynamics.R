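# Physical constants and boundary-condition models for the reduced-order
# coronary network: blood properties, allometric inflow from myocardial
# volume, Murray's-law flow distribution, and three-element Windkessel
# outlets. Units are CGS internally (dyn/cm^2, mL/s, cm); interfaces use
# mmHg and mm. 1 mmHg = 1333.22 dyn/cm^2.

#' Blood properties
#'
#' Constant density and dynamic viscosity of blood, treated as a laminar
#' incompressible Newtonian fluid. Defaults: rho = 1.050 g/cm^3,
#' mu = 0.035 poise (g/(cm.s)).
#'
#' @param density g/cm^3
#' @param viscosity dynamic viscosity, poise
#' @return object of class `blood_properties`
#' @export
blood_properties <- function(density = 1.050, viscosity = 0.035) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "blood_properties")
}

#' Total coronary flow from myocardial volume (allometric scaling)
#'
#' Cycle-mean total coronary flow `Qbar = c * Vm^gamma` (mL/s). The default
#' coefficient is calibrated so that a 120 mL myocardium yields 2.0 mL/s of
#' resting total coronary flow with the conventional 3/4 allometric
#' exponent.
#'
#' @param vm_ml myocardial volume (mL), > 0
#' @param coefficient allometric coefficient c; default `2 / 120^0.75`
#' @param exponent allometric exponent gamma, default 0.75
#' @return flow, mL/s
#' @export
total_coronary_flow <- function(vm_ml, coefficient = 2 / 120^0.75,
                                exponent = 0.75) {
  if (!is.finite(vm_ml) || vm_ml <= 0)
    stop_ffrct("myocardial volume must be positive (got %s)", format(vm_ml),
               class = "ffrct_model_error")
  coefficient * vm_ml^exponent
}

#' Aortic-like inflow waveform
#'
#' A two-phase piecewise-cosine pulse: a systolic ejection hump over the
#' first `systole_frac` of the cycle on top of a low diastolic level,
#' normalized to cycle mean 1. Returns a vectorized periodic function of
#' time (s). With `constant = TRUE` the waveform is identically 1, the
#' steady-analysis mode.
#'
#' @param period cardiac period T (s), default 0.8
#' @param systole_frac fraction of the cycle occupied by systole
#' @param diastolic_level waveform value during diastole (before
#'   normalization the hump is scaled so the cycle mean is exactly 1)
#' @param constant if TRUE return the constant waveform w(t) = 1
#' @return function of time t (s), periodic with period `period`
#' @export
aortic_waveform <- function(period = 0.8, systole_frac = 0.33,
                            diastolic_level = 0.4, constant = FALSE) {
  if (constant) {
    f <- function(t) rep(1, length(t))
    attr(f, "period") <- period
    return(f)
  }
  stopifnot(period > 0, systole_frac > 0, systole_frac < 1,
            diastolic_level >= 0, diastolic_level < 1)
  ts <- systole_frac * period
  # hump integral: A/2 * ts  =>  mean = delta + A*ts/(2T) = 1
  amp <- (1 - diastolic_level) * 2 * period / ts
  f <- function(t) {
    tt <- t %% period
    w <- rep(diastolic_level, length(tt))
    sys <- tt < ts
    w[sys] <- diastolic_level + amp * (1 - cos(2 * pi * tt[sys] / ts)) / 2
    w
  }
  attr(f, "period") <- period
  f
}

#' Inflow model
#'
#' Bundles the allometric cycle-mean flow, the periodic waveform and the
#' target mean aortic pressure used to calibrate total resistance at rest.
#'
#' @param vm_ml myocardial volume (mL)
#' @param mean_aortic_pressure target resting mean aortic pressure (mmHg)
#' @param coefficient,exponent passed to [total_coronary_flow()]
#' @param waveform a function as returned by [aortic_waveform()]; default
#'   the pulsatile aortic-like waveform with period 0.8 s
#' @param period cardiac period (s), used when `waveform` is NULL
#' @return object of class `inflow_model` with fields `qbar_ml_s`,
#'   `waveform`, `period`, `mean_aortic_pressure`
#' @export
inflow_model <- function(vm_ml, mean_aortic_pressure = 93,
                         coefficient = 2 / 120^0.75, exponent = 0.75,
                         waveform = NULL, period = 0.8) {
  qbar <- total_coronary_flow(vm_ml, coefficient, exponent)
  if (is.null(waveform)) waveform <- aortic_waveform(period = period)
  period <- attr(waveform, "period") %||% period
  # cycle-mean must be 1 (checked numerically)
  tt <- seq(0, period, length.out = 4001)
  m <- mean((waveform(tt)[-1] + waveform(tt)[-4001]) / 2)
  if (abs(m - 1) > 1e-4)
    stop_ffrct("waveform cycle mean is %.6f, must be 1", m, class = "ffrct_model_error")
  if (any(waveform(tt) < 0))
    stop_ffrct("waveform must be non-negative", class = "ffrct_model_error")
  structure(list(vm_ml = vm_ml, qbar_ml_s = qbar, waveform = waveform,
                 period = period, mean_aortic_pressure = mean_aortic_pressure),
            class = "inflow_model")
}

#' Murray's-law flow fractions
#'
#' Fraction of parental flow taken by each daughter branch, proportional to
#' diameter to the power `exponent` (classically 3).
#'
#' @param child_diameters_mm daughter diameters (mm), all > 0
#' @param exponent Murray exponent m, default 3
#' @return numeric vector of fractions summing to 1
#' @export
murray_fractions <- function(child_diameters_mm, exponent = 3) {
  if (length(child_diameters_mm) == 0L)
    stop_ffrct("murray_fractions needs at least one diameter",
               class = "ffrct_model_error")
  if (any(child_diameters_mm <= 0))
    stop_ffrct("all diameters must be positive", class = "ffrct_model_error")
  w <- child_diameters_mm^exponent
  w / sum(w)
}

#' Viscous (Poiseuille) resistance of a segment
#'
#' `R = integral of 128 mu / (pi d(s)^4) ds` over the profile, by the
#' trapezoid rule with s and d converted to cm. This is the generalized
#' Poiseuille resistance of the axisymmetric lumen.
#'
#' @param profile a [centerline_profile()]
#' @param viscosity dynamic viscosity (poise)
#' @return resistance, dyn.s/cm^5
#' @export
segment_viscous_resistance <- function(profile, viscosity = 0.035) {
  s_cm <- profile$s_mm / 10
  d_cm <- 2 * profile$r_mm / 10
  integrand <- 128 * viscosity / (pi * d_cm^4)
  sum(diff(s_cm) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2)
}

#' Stenosis pressure loss (Young-Tsai form)
#'
#' `dP = R_visc * Q + Kt * (rho/2) * (1/A_s - 1/A_0)^2 * Q * |Q|` with
#' `A_s` the minimal lumen area and `A_0` the reference area (cm^2 from mm
#' diameters). The sign of the loss follows the sign of the flow. The
#' empirical turbulence coefficient defaults to `Kt = 1.52`.
#'
#' @param q_ml_s flow through the lesion (mL/s), may be negative
#' @param d_min_mm minimal lumen diameter (mm)
#' @param d_ref_mm reference diameter at the lesion (mm)
#' @param props [blood_properties()]
#' @param kt empirical loss coefficient, default 1.52
#' @param r_visc viscous resistance of the lesion segment (dyn.s/cm^5),
#'   e.g. from [segment_viscous_resistance()] over the lesion extent
#' @return pressure loss, dyn/cm^2
#' @export
stenosis_pressure_loss <- function(q_ml_s, d_min_mm, d_ref_mm,
                                   props = blood_properties(), kt = 1.52,
                                   r_visc = 0) {
  if (d_min_mm <= 0)
    stop_ffrct("minimal lumen area must be positive", class = "ffrct_model_error")
  a_s <- pi * (d_min_mm / 10)^2 / 4
  a_0 <- pi * (d_ref_mm / 10)^2 / 4
  k2 <- kt * (props$density / 2) * (1 / a_s - 1 / a_0)^2
  r_visc * q_ml_s + k2 * q_ml_s * abs(q_ml_s)
}

#' Three-element Windkessel outlet
#'
#' Proximal resistance, compliance and distal resistance representing the
#' downstream vascular bed; `p_v` is the venous reference pressure. At
#' steady state with constant flow Q the outlet pressure is
#' `P = p_v + Q * (rp + rd)`.
#'
#' @param rp proximal resistance (dyn.s/cm^5), > 0
#' @param c compliance (cm^5/dyn), >= 0
#' @param rd distal resistance (dyn.s/cm^5), > 0
#' @param p_v venous/reference pressure (dyn/cm^2), default 0
#' @return object of class `windkessel_outlet`
#' @export
windkessel_outlet <- function(rp, c, rd, p_v = 0) {
  stopifnot(rp > 0, rd > 0, c >= 0)
  structure(list(rp = rp, c = c, rd = rd, p_v = p_v),
            class = "windkessel_outlet")
}

#' Distribute Windkessel outlets over a tree by Murray's law
#'
#' Total resting effective resistance is `R_tot = (Pa - Pv) / Qbar`. Each
#' terminal outlet receives the share of `R_tot` left after subtracting the
#' flow-weighted viscous drop along its epicardial path, divided by its
#' Murray flow fraction, so that the healthy rest-state network reproduces
#' the target mean aortic pressure exactly. The outlet resistance splits
#' into `Rp = kappa * R`, `Rd = (1-kappa) * R` with compliance
#' `C = tau / Rd`; both resistances are then multiplied by
#' `hyperemia_factor`, the conventional adenosine response of the coronary
#' microcirculation.
#'
#' @param tree a [coronary_tree()]
#' @param inflow an [inflow_model()]
#' @param props [blood_properties()]
#' @param hyperemia_factor multiplier on outlet resistances, (0, 1];
#'   default 0.24
#' @param kappa proximal share of outlet resistance, default 0.09
#' @param tau Windkessel time constant Rd*C (s), default 0.5
#' @param p_v_mmhg venous pressure (mmHg), default 0
#' @param murray_exponent Murray exponent, default 3
#' @return named list of [windkessel_outlet()]s, one per terminal node,
#'   with the network attached as attribute `network`
#' @export
assign_outlets <- function(tree, inflow, props = blood_properties(),
                           hyperemia_factor = 0.24, kappa = 0.09, tau = 0.5,
                           p_v_mmhg = 0, murray_exponent = 3) {
  stopifnot(hyperemia_factor > 0, hyperemia_factor <= 1, kappa > 0, kappa < 1)
  net <- build_network(tree, viscosity = props$viscosity,
                       density = props$density)
  fr <- terminal_fractions(net, murray_exponent)
  pa <- inflow$mean_aortic_pressure * MMHG
  pv <- p_v_mmhg * MMHG
  qbar <- inflow$qbar_ml_s
  r_tot <- (pa - pv) / qbar
  outlets <- list()
  for (term in names(fr$fraction)) {
    path <- fr$path[[term]]
    path_drop <- sum(net$edges_df$r_lin[path] * fr$edge_fraction[path])
    r_i <- (r_tot - path_drop) / fr$fraction[[term]]
    if (r_i <= 0)
      stop_ffrct(paste0("epicardial resistance exceeds the target pressure ",
                        "gradient at outlet '%s'; calibration impossible"), term,
                 class = "ffrct_calibration_error")
    rp <- kappa * r_i
    rd <- (1 - kappa) * r_i
    outlets[[term]] <- windkessel_outlet(rp = rp * hyperemia_factor,
                                         c = tau / rd,
                                         rd = rd * hyperemia_factor,
                                         p_v = pv)
  }
  attr(outlets, "network") <- net
  attr(outlets, "hyperemia_factor") <- hyperemia_factor
  outlets
}
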