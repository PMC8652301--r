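#' Left-ventricular constitutive and geometric parameters
#'
#' Parameters of the reduced transmural LV backend: an incompressible
#' thick-walled spherical shell with tangentially oriented fibers, a
#' one-dimensional Fung-type passive fiber law, and a Guccione-type active
#' stress law with length-dependent calcium sensitivity.
#'
#' @param V_cav0 Unloaded cavity volume [ml].
#' @param V_wall Wall volume [ml] (conserved exactly by incompressibility).
#' @param n_shells Number of transmural shells (>= 8).
#' @param C_f Passive fiber stiffness scale [kPa].
#' @param b_f Passive fiber exponent [-].
#' @param T_max Isometric tension at the longest sarcomere length
#'   ("contractility") [kPa].
#' @param Ca0 Peak intracellular calcium [uM].
#' @param Ca0_max Maximum peak intracellular calcium [uM].
#' @param B Length-sensitivity constant [1/um].
#' @param l0 Sarcomere length below which no active tension develops [um].
#' @param l_ref Sarcomere length at unit fiber stretch [um].
#' @param t0 Time to peak tension [ms].
#' @param tau Relaxation time constant of the active waveform [ms].
#' @param T_trans Transition time of the active waveform [ms]
#'   (defaults to `t0`).
#' @return An object of class `lv_params`.
#' @export
lv_params <- function(V_cav0 = 72.2189, V_wall = 68.3051, n_shells = 24,
                      C_f = 1.83548, b_f = 9.5,
                      T_max = 130, Ca0 = 4.35, Ca0_max = 4.35,
                      B = 4.75, l0 = 1.58, l_ref = 1.85,
                      t0 = 275, tau = 25, T_trans = t0) {
  stopifnot(V_cav0 > 0, V_wall > 0, n_shells >= 8,
            C_f >= 0, b_f > 0, T_max >= 0, l0 < l_ref,
            t0 > 0, tau > 0, T_trans > 0)
  structure(list(V_cav0 = V_cav0, V_wall = V_wall, n_shells = n_shells,
                 C_f = C_f, b_f = b_f,
                 T_max = T_max, Ca0 = Ca0, Ca0_max = Ca0_max, B = B,
                 l0 = l0, l_ref = l_ref, t0 = t0, tau = tau,
                 T_trans = T_trans),
            class = "lv_params")
}

#' Build the reference shell discretization of the LV wall
#'
#' The unloaded wall, a spherical annulus between radii
#' `R_i = (3 V_cav0 / 4 pi)^(1/3)` and `R_o = (3 (V_cav0 + V_wall)/4 pi)^(1/3)`
#' [cm], is partitioned into `n_shells` shells of equal reference wall
#' volume.  `Rhat` is the normalized transmural depth, 0 at the endocardium
#' and 1 at the epicardium, linear in the reference radius.
#'
#' @param V_cav0 Unloaded cavity volume [ml].
#' @param V_wall Wall volume [ml].
#' @param n_shells Number of shells.
#' @return An object of class `lv_geometry` with the shell boundary and
#'   midpoint radii (`Rb`, `Rm`), their cubes, normalized depths (`Rhat_b`,
#'   `Rhat_m`), per-shell reference volumes and the wall thickness `h`.
#' @export
make_geometry <- function(V_cav0, V_wall, n_shells = 24) {
  stopifnot(V_cav0 > 0, V_wall > 0, n_shells >= 8)
  R_i <- (3 * V_cav0 / (4 * pi))^(1 / 3)
  R_o <- (3 * (V_cav0 + V_wall) / (4 * pi))^(1 / 3)
  ## equal-volume partition: cubes of boundary radii equally spaced
  Rb3 <- seq(R_i^3, R_o^3, length.out = n_shells + 1)
  Rm3 <- (Rb3[-1] + Rb3[-(n_shells + 1)]) / 2
  Rb <- Rb3^(1 / 3)
  Rm <- Rm3^(1 / 3)
  structure(list(
    V_cav0 = V_cav0, V_wall = V_wall, n_shells = n_shells,
    R_i = R_i, R_o = R_o, h = R_o - R_i,
    Rb = Rb, Rb3 = Rb3, Rm = Rm, Rm3 = Rm3,
    Rhat_b = (Rb - R_i) / (R_o - R_i),
    Rhat_m = (Rm - R_i) / (R_o - R_i),
    shell_Vref = diff(Rb3) * 4 * pi / 3
  ), class = "lv_geometry")
}

#' Incompressible spherical deformation of the wall
#'
#' Given the current cavity volume, every material sphere of reference
#' radius `R` moves to `r = (R^3 - R_i^3 + r_i^3)^(1/3)`, which preserves
#' the volume of every sub-shell exactly.  Tangential (fiber) stretch is
#' `lambda = r/R`, radial stretch `lambda_r = (R/r)^2`, and the
#' Green-Lagrange fiber strain is `E_ff = (lambda^2 - 1)/2`.
#'
#' @param geometry An [make_geometry()] object.
#' @param V_LV Current cavity volume [ml], > 0.
#' @return An object of class `shell_kinematics` with per-shell midpoint
#'   values `r`, `lambda`, `lambda_r`, `E_ff`, boundary radii `rb`, and the
#'   normalized depths copied from the geometry.
#' @export
deform <- function(geometry, V_LV) {
  if (V_LV <= 0) stop("diverged state: LV cavity volume collapsed", call. = FALSE)
  ri3 <- 3 * V_LV / (4 * pi)
  shift <- ri3 - geometry$R_i^3
  rb <- (geometry$Rb3 + shift)^(1 / 3)
  rm <- (geometry$Rm3 + shift)^(1 / 3)
  lambda <- rm / geometry$Rm
  structure(list(
    V_LV = V_LV, rb = rb, r = rm,
    lambda = lambda, lambda_r = (geometry$Rm / rm)^2,
    E_ff = (lambda^2 - 1) / 2,
    Rhat_m = geometry$Rhat_m, Rhat_b = geometry$Rhat_b
  ), class = "shell_kinematics")
}

#' Passive fiber stress (Fung-type, tension-only, fiber direction)
#'
#' `S_pas = C_f * b_f * E_ff * exp(b_f * E_ff^2)` [kPa] for positive fiber
#' strain and zero otherwise: muscle fibers bear no compressive load (they
#' buckle), the standard convention of fiber-reinforced myocardial
#' constitutive models.  Zero at zero strain, small-strain tensile modulus
#' `C_f * b_f`.  Keeping the tangential extra stress non-negative also
#' guarantees a transmurally monotone intramyocardial pressure profile.
#'
#' @param E_ff Green-Lagrange fiber strain; vectorized.
#' @param params An [lv_params()] object (fields `C_f`, `b_f`).
#' @return Second Piola-Kirchhoff passive fiber stress [kPa].
#' @export
passive_fiber_stress <- function(E_ff, params) {
  S <- ifelse(E_ff > 0,
              params$C_f * params$b_f * E_ff * exp(params$b_f * E_ff^2), 0)
  if (any(!is.finite(S))) {
    stop("diverged state: passive fiber stress overflowed", call. = FALSE)
  }
  S
}

#' Time course of active tension
#'
#' Sinusoidal rise to peak at `t0` (when `T_trans = t0`), then exponential
#' relaxation with constant `tau`; continuous at `t = T_trans`.
#'
#' @param t Time within the cycle [ms]; vectorized.
#' @param params An [lv_params()] object.
#' @return Dimensionless activation in \[0, 1\].
#' @export
activation_waveform <- function(t, params) {
  ct <- 0.5 * (1 - cos(pi * t / params$t0))
  cT <- 0.5 * (1 - cos(pi * params$T_trans / params$t0))
  ifelse(t <= params$T_trans, ct,
         cT * exp(-(t - params$T_trans) / params$tau))
}

#' Active fiber stress with length-dependent calcium sensitivity
#'
#' Guccione-type active stress
#' `S_act = T_max * Ca0^2 / (Ca0^2 + ECa50^2) * C(t)` with
#' `ECa50 = Ca0_max / sqrt(exp(B (l - l0)) - 1)` for sarcomere lengths above
#' the zero-tension length `l0`, and zero tension at or below it
#' (the `ECa50 -> Inf` limit).
#'
#' @param t Time within the cycle [ms].
#' @param l Sarcomere length [um] (`l = l_ref * lambda`); vectorized.
#' @param params An [lv_params()] object.
#' @return Active second Piola-Kirchhoff fiber stress [kPa].
#' @export
active_fiber_stress <- function(t, l, params) {
  Ct <- activation_waveform(t, params)
  scale <- numeric(length(l))
  above <- l > params$l0
  if (any(above)) {
    eca50sq <- params$Ca0_max^2 / (exp(params$B * (l[above] - params$l0)) - 1)
    scale[above] <- params$Ca0^2 / (params$Ca0^2 + eca50sq)
  }
  params$T_max * scale * Ct
}

#' LV cavity pressure and transmural intramyocardial pressure profile
#'
#' Radial equilibrium of the thick-walled shell: with tangential Cauchy
#' extra stress `T_t = lambda^2 * S_ff` [kPa], the cavity pressure is
#' `P_LV = int_{r_i}^{r_o} 2 T_t(r)/r dr` and the intramyocardial pressure
#' (IMP) at radius `r` is `p(r) = int_r^{r_o} 2 T_t(s)/s ds`, the radial
#' compressive stress standing in for the incompressibility Lagrange
#' multiplier.  By construction `p(endo) = P_LV` and `p(epi) = 0` exactly.
#' Quadrature is per shell with the midpoint tangential stress:
#' `2 T_t,k ln(r_b[k+1]/r_b[k])`.
#'
#' @param geometry An [make_geometry()] object.
#' @param kinematics A [deform()] object at the same cavity volume.
#' @param S_ff Per-shell total fiber PK2 stress [kPa]
#'   (passive + active at shell midpoints).
#' @return A list of class `lv_pressure_state`: `P_LV` [mmHg], `p_b` IMP at
#'   the shell boundaries [mmHg] (length `n_shells + 1`, endo first),
#'   `Rhat_b` the matching depths, and `T_t` [kPa].
#' @export
lv_pressure <- function(geometry, kinematics, S_ff) {
  T_t <- kinematics$lambda^2 * S_ff
  dcontrib <- 2 * T_t * log(kinematics$rb[-1] / kinematics$rb[-length(kinematics$rb)])
  ## p at boundaries: integral from r to r_o, cumulated from the epicardium
  p_b_kpa <- rev(cumsum(rev(c(dcontrib))))
  p_b_kpa <- c(p_b_kpa, 0)
  structure(list(
    P_LV = p_b_kpa[1] * .MMHG_PER_KPA,
    p_b = p_b_kpa * .MMHG_PER_KPA,
    Rhat_b = kinematics$Rhat_b,
    T_t = T_t
  ), class = "lv_pressure_state")
}

#' Evaluate the full LV backend at one instant
#'
#' Convenience wrapper implementing the backend contract
#' `(V_LV, t) -> (P_LV, IMP at depths, per-shell S_ff / E_ff)`.
#'
#' @param geometry An [make_geometry()] object.
#' @param params An [lv_params()] object.
#' @param V_LV Cavity volume [ml].
#' @param t Time within the cycle [ms].
#' @param depths Normalized depths at which to sample the IMP.
#' @return A list with `P_LV` [mmHg], `p_depths` [mmHg], `kinematics`,
#'   `S_pas`, `S_act`, `S_ff` [kPa] and the `lv_pressure_state`.
#' @export
lv_state <- function(geometry, params, V_LV, t,
                     depths = c(0, 1 / 3, 2 / 3, 1)) {
  kin <- deform(geometry, V_LV)
  S_pas <- passive_fiber_stress(kin$E_ff, params)
  S_act <- active_fiber_stress(t, params$l_ref * kin$lambda, params)
  S_ff <- S_pas + S_act
  ps <- lv_pressure(geometry, kin, S_ff)
  list(P_LV = ps$P_LV,
       p_depths = imp_at_depths(ps, depths),
       kinematics = kin, S_pas = S_pas, S_act = S_act, S_ff = S_ff,
       pressure_state = ps)
}

#' Sample the IMP profile at prescribed transmural depths
#'
#' Linear interpolation of the boundary IMP profile at normalized depths;
#' depth 0 returns `P_LV` and depth 1 returns 0 exactly (the boundary
#' identities of the radial-equilibrium construction).
#'
#' @param pressure_state An `lv_pressure_state` from [lv_pressure()].
#' @param depths Normalized depths in \[0, 1\].
#' @return IMP at the requested depths [mmHg].
#' @export
imp_at_depths <- function(pressure_state, depths = c(0, 1 / 3, 2 / 3, 1)) {
  stopifnot(all(depths >= 0 & depths <= 1))
  approx(pressure_state$Rhat_b, pressure_state$p_b, xout = depths,
         rule = 2)$y
}

#' Euler-Almansi tangential strains relative to end-diastole
#'
#' With end-diastole as the reference configuration and relative stretch
#' `lambda_rel = lambda(t)/lambda(ED)`, the Euler-Almansi strain is
#' `e = (1 - 1/lambda_rel^2)/2`.  In the spherical reduction the
#' circumferential and longitudinal directions are indistinguishable, so
#' `e_cc = e_ll` (a stated limitation of the reduced backend).
#'
#' @param kinematics A [deform()] object at time `t`.
#' @param kinematics_ed The [deform()] object at end-diastole.
#' @return A list with per-shell `e_cc` and `e_ll` (equal by construction).
#' @export
almansi_strains <- function(kinematics, kinematics_ed) {
  lam_rel <- kinematics$lambda / kinematics_ed$lambda
  e <- 0.5 * (1 - 1 / lam_rel^2)
  list(e_cc = e, e_ll = e)
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat("<lv_geometry>\n")
  cat(sprintf("  V_cav0=%g ml, V_wall=%g ml, n_shells=%d\n",
              x$V_cav0, x$V_wall, x$n_shells))
  cat(sprintf("  R_i=%.3f cm, R_o=%.3f cm, h=%.3f cm\n", x$R_i, x$R_o, x$h))
  invisible(x)
}
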