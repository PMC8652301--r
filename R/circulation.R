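#' Parameters of the five-compartment systemic circulation
#'
#' Constructs and validates the parameter set of the closed-loop
#' lumped-parameter circulation: left atrium (LA), left ventricle (LV),
#' proximal and distal peripheral arteries, and peripheral veins, connected
#' by linear resistances with diode (unidirectional) mitral and aortic
#' valves.  The LA is a time-varying-elastance chamber.
#'
#' @param R_ao,R_ap,R_ad,R_ven,R_mv Flow resistances of the aortic valve,
#'   proximal arteries, distal arteries, veins and mitral valve
#'   [mmHg.ms/ml].
#' @param C_ap,C_ad,C_ven Compliances of the proximal arterial, distal
#'   arterial and venous storage compartments [ml/mmHg].
#' @param V_ap0,V_ad0,V_ven0 Resting (zero-pressure) volumes of the storage
#'   compartments [ml].
#' @param E_es_LA Maximal LA chamber elastance [mmHg/ml].
#' @param V_LA0 LA volume at zero end-systolic pressure [ml].
#' @param A_LA,B_LA LA end-diastolic pressure-volume parameters
#'   [mmHg and 1/ml].
#' @param T_max_LA Time to LA end systole [ms].
#' @param tau_LA LA relaxation time constant [ms].
#' @param cycle_length Cardiac cycle length [ms].
#' @return An object of class `circulation_params` (a named list).
#' @export
circulation_params <- function(R_ao = 10, R_ap = 480.744, R_ad = 571.206,
                               R_ven = 60, R_mv = 10,
                               C_ap = 0.863917, C_ad = 0.14, C_ven = 50,
                               V_ap0 = 540, V_ad0 = 100, V_ven0 = 3231.99,
                               E_es_LA = 0.35, V_LA0 = 10,
                               A_LA = 0.35, B_LA = 0.035,
                               T_max_LA = 150, tau_LA = 25,
                               cycle_length = 800) {
  p <- list(R_ao = R_ao, R_ap = R_ap, R_ad = R_ad, R_ven = R_ven,
            R_mv = R_mv, C_ap = C_ap, C_ad = C_ad, C_ven = C_ven,
            V_ap0 = V_ap0, V_ad0 = V_ad0, V_ven0 = V_ven0,
            E_es_LA = E_es_LA, V_LA0 = V_LA0, A_LA = A_LA, B_LA = B_LA,
            T_max_LA = T_max_LA, tau_LA = tau_LA,
            cycle_length = cycle_length)
  validate_circulation_params(p)
  structure(p, class = "circulation_params")
}

validate_circulation_params <- function(p) {
  pos <- c("R_ao", "R_ap", "R_ad", "R_ven", "R_mv",
           "C_ap", "C_ad", "C_ven", "T_max_LA", "tau_LA", "cycle_length")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("circulation parameter '", nm, "' must be a strictly positive number",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' State of the systemic circulation
#'
#' Compartment volumes plus the time within the cardiac cycle.
#'
#' @param V_LA,V_LV,V_ap,V_ad,V_ven Compartment volumes [ml].
#' @param t Time within the cycle [ms].
#' @return An object of class `circulation_state`.
#' @export
circulation_state <- function(V_LA, V_LV, V_ap, V_ad, V_ven, t = 0) {
  v <- c(V_LA = V_LA, V_LV = V_LV, V_ap = V_ap, V_ad = V_ad, V_ven = V_ven)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all compartment volumes must be positive and finite", call. = FALSE)
  }
  structure(list(V_LA = V_LA, V_LV = V_LV, V_ap = V_ap, V_ad = V_ad,
                 V_ven = V_ven, t = t),
            class = "circulation_state")
}

#' Normalized left-atrial elastance waveform
#'
#' Piecewise activation function of the LA time-varying elastance model: a
#' sinusoidal rise/fall for `t <= 1.5 * T_max_LA` followed by exponential
#' relaxation.  The printed form of this function in the source model is
#' typographically garbled; the implementation below is the reconstruction
#' implied by its stated properties (value 1 at the time of end systole,
#' relaxation constant `tau_LA`, continuity at the branch point).
#'
#' @param t Time within the cycle [ms]; vectorized.
#' @param params A [circulation_params()] object.
#' @return Dimensionless elastance fraction in \[0, 1\].
#' @export
la_elastance <- function(t, params) {
  Tm <- params$T_max_LA
  tb <- 1.5 * Tm
  ifelse(t <= tb,
         0.5 * (sin(pi * t / Tm - pi / 2) + 1),
         0.5 * exp(-(t - tb) / params$tau_LA))
}

#' Left-atrial pressure from the time-varying elastance model
#'
#' Interpolates between the end-systolic line
#' `E_es_LA * (V_LA - V_LA0)` and the end-diastolic exponential
#' `A_LA * (exp(B_LA * (V_LA - V_LA0)) - 1)` with weight [la_elastance()].
#'
#' @param V_LA LA volume [ml].
#' @param t Time within the cycle [ms].
#' @param params A [circulation_params()] object.
#' @return LA pressure [mmHg].
#' @export
la_pressure <- function(V_LA, t, params) {
  if (any(V_LA <= 0)) stop("V_LA must be positive", call. = FALSE)
  e <- la_elastance(t, params)
  dV <- V_LA - params$V_LA0
  ped <- params$A_LA * (exp(params$B_LA * dV) - 1)
  if (any(!is.finite(ped))) {
    stop("diverged state: LA end-diastolic pressure overflowed", call. = FALSE)
  }
  e * params$E_es_LA * dV + (1 - e) * ped
}

#' Compartment pressures of the systemic circulation
#'
#' Linear pressure-volume laws for the three storage compartments, the LA
#' elastance model for `P_LA`, and pass-through of the externally supplied
#' LV pressure (the LV backend owns `P_LV`; it is never computed here).
#'
#' @param state A [circulation_state()] object.
#' @param params A [circulation_params()] object.
#' @param P_LV LV cavity pressure [mmHg] from the LV backend.
#' @return A named list of class `pressure_set` with elements
#'   `P_LA`, `P_LV`, `P_ap`, `P_ad`, `P_ven` [mmHg].
#' @export
compartment_pressures <- function(state, params, P_LV) {
  structure(list(
    P_LA  = la_pressure(state$V_LA, state$t, params),
    P_LV  = P_LV,
    P_ap  = (state$V_ap  - params$V_ap0)  / params$C_ap,
    P_ad  = (state$V_ad  - params$V_ad0)  / params$C_ad,
    P_ven = (state$V_ven - params$V_ven0) / params$C_ven
  ), class = "pressure_set")
}

#' Branch flows of the systemic circulation
#'
#' Resistive flows between compartments.  The aortic and mitral valves are
#' ideal diodes: flow is the positive part of the pressure drop divided by
#' the valve resistance.  Coronary totals belong to the coupling layer and
#' are zero here.
#'
#' @param pressures A `pressure_set` from [compartment_pressures()].
#' @param params A [circulation_params()] object.
#' @return A named list of class `flow_set` with elements `q_mv`, `q_ao`,
#'   `q_ap`, `q_ad`, `q_ven`, `q_cor_in_total`, `q_cor_out_total` [ml/ms].
#' @export
branch_flows <- function(pressures, params) {
  with(pressures, structure(list(
    q_ao  = max(P_LV - P_ap, 0) / params$R_ao,
    q_mv  = max(P_LA - P_LV, 0) / params$R_mv,
    q_ap  = (P_ap - P_ad)  / params$R_ap,
    q_ad  = (P_ad - P_ven) / params$R_ad,
    q_ven = (P_ven - P_LA) / params$R_ven,
    q_cor_in_total = 0,
    q_cor_out_total = 0
  ), class = "flow_set"))
}

#' Advance compartment volumes by one explicit Euler step
#'
#' Forward-Euler update of the five compartment volumes.  The coronary
#' networks withdraw `q_cor_in_total` from the proximal arterial compartment
#' and return `q_cor_out_total` to the veins, so with zero coronary exchange
#' the sum of the five volumes is conserved exactly (telescoping flows).
#'
#' @param state A [circulation_state()] object.
#' @param flows A `flow_set` from [branch_flows()] (with coronary totals
#'   filled in by the coupling layer when networks are attached).
#' @param params A [circulation_params()] object.
#' @param dt Time step [ms].
#' @return The advanced `circulation_state` with `t` wrapped into the cycle.
#' @export
advance_volumes <- function(state, flows, params, dt = 1) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  V <- with(flows, c(
    V_LA  = state$V_LA  + dt * (q_ven - q_mv),
    V_LV  = state$V_LV  + dt * (q_mv - q_ao),
    V_ap  = state$V_ap  + dt * (q_ao - q_ap - q_cor_in_total),
    V_ad  = state$V_ad  + dt * (q_ap - q_ad),
    V_ven = state$V_ven + dt * (q_ad - q_ven + q_cor_out_total)
  ))
  if (any(V <= 0)) {
    bad <- names(V)[which(V <= 0)[1L]]
    stop("diverged simulation: compartment volume ", bad,
         " became non-positive", call. = FALSE)
  }
  circulation_state(V[["V_LA"]], V[["V_LV"]], V[["V_ap"]], V[["V_ad"]],
                    V[["V_ven"]],
                    t = (state$t + dt) %% params$cycle_length)
}

#' @export
print.circulation_params <- function(x, ...) {
  cat("<circulation_params>\n")
  cat(sprintf("  resistances [mmHg.ms/ml]: R_ao=%g R_ap=%g R_ad=%g R_ven=%g R_mv=%g\n",
              x$R_ao, x$R_ap, x$R_ad, x$R_ven, x$R_mv))
  cat(sprintf("  compliances [ml/mmHg]:    C_ap=%g C_ad=%g C_ven=%g\n",
              x$C_ap, x$C_ad, x$C_ven))
  cat(sprintf("  resting volumes [ml]:     V_ap0=%g V_ad0=%g V_ven0=%g\n",
              x$V_ap0, x$V_ad0, x$V_ven0))
  cat(sprintf("  LA elastance: E_es=%g V_LA0=%g A=%g B=%g T_max=%g tau=%g\n",
              x$E_es_LA, x$V_LA0, x$A_LA, x$B_LA, x$T_max_LA, x$tau_LA))
  cat(sprintf("  cycle length: %g ms\n", x$cycle_length))
  invisible(x)
}
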