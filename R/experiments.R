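#' Define a parameter sweep
#'
#' The five study factors, each applied to the calibrated baseline with the
#' coronary network held fixed: contractility (`T_max` [kPa]), afterload
#' (distal arterial resistance `R_ad` [kPa.ms/ml], with preload held),
#' preload (venous resting volume `V_ven0` [ml]), wall thickness (`h` [cm]
#' at fixed unloaded cavity volume, preload and afterload held) and
#' unloaded cavity volume (`V_cav0` [ml] at fixed wall volume, preload and
#' afterload held).  A `tau` factor (active relaxation constant [ms]) is
#' available for sensitivity runs.
#'
#' @param factor One of `"contractility"`, `"afterload"`, `"preload"`,
#'   `"thickness"`, `"cavity_volume"`, `"tau"`.
#' @param levels Numeric vector (>= 2 values) in the factor's units.
#' @param constraints Named list of quantities to hold and their targets,
#'   e.g. `list(EDP = 8)` or `list(EDP = 8, peakP = 141)`.
#' @param labels Optional per-level labels.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(factor = c("contractility", "afterload", "preload",
                                  "thickness", "cavity_volume", "tau"),
                       levels, constraints = list(), labels = NULL) {
  factor <- match.arg(factor)
  if (length(levels) < 2) stop("a sweep needs at least 2 levels", call. = FALSE)
  if (is.null(labels)) labels <- paste0(factor, "=", signif(levels, 4))
  structure(list(factor = factor, levels = levels,
                 constraints = constraints, labels = labels),
            class = "sweep_spec")
}

## apply one sweep level to a parameter bundle
.apply_level <- function(params, factor, value) {
  switch(factor,
    contractility = { params$lv$T_max <- value; params },
    afterload = {
      params$circulation$R_ad <- value * .MMHG_PER_KPA   # kPa.ms/ml -> mmHg.ms/ml
      params
    },
    preload = { params$circulation$V_ven0 <- value; params },
    thickness = {
      R_i <- (3 * params$lv$V_cav0 / (4 * pi))^(1 / 3)
      params$lv$V_wall <- 4 * pi / 3 * ((R_i + value)^3 - R_i^3)
      params
    },
    cavity_volume = { params$lv$V_cav0 <- value; params },
    tau = { params$lv$tau <- value; params }
  )
}

.summary_row <- function(summ, extra = list()) {
  depth_names <- c("endo", "mid_endo", "mid_epi", "epi")
  row <- list(EF = summ$EF, EDV = summ$EDV, ESV = summ$ESV,
              peak_P_LV = summ$peak_P_LV, LVEDP = summ$LVEDP,
              SBP = summ$SBP, DBP = summ$DBP, peak_e_cc = summ$peak_e_cc)
  if (!is.null(summ$Q)) {
    n <- length(summ$Q)
    nm <- if (n == 4) depth_names else paste0("d", seq_len(n))
    row <- c(row,
             setNames(as.list(summ$peak_IMP), paste0("peak_IMP_", nm)),
             setNames(as.list(summ$Q), paste0("Q_", nm)),
             setNames(as.list(summ$W_f), paste0("Wf_", nm)),
             setNames(as.list(summ$mismatch), paste0("WfQ_", nm)),
             list(Q_endo_epi = summ$Q_endo_epi,
                  Wf_endo_epi = summ$Wf_endo_epi,
                  WfQ_endo_epi = summ$mismatch_endo_epi))
  }
  as.data.frame(c(row, extra))
}

#' Run a parameter sweep with load-holding constraints
#'
#' For every level the factor is applied to the base parameters, the
#' holding constraints (if any) are enforced by [hold_preload()] /
#' [hold_loads()], the closed loop is run to its periodic state, and the
#' [cycle_summary()] is recorded together with the constraint residuals.
#' Infeasible levels are flagged and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param params Base [model_params()] (normally the calibrated baseline).
#' @param config A [simulation_config()].
#' @param network Optional fixed [build_tree()] topology, shared across all
#'   levels (built once from the baseline otherwise).
#' @return A data.frame of class `summary_table`, one row per level, with
#'   the summary scalars, constraint residuals and a `feasible` flag.
#' @export
run_sweep <- function(spec, params, config = simulation_config(),
                      network = NULL) {
  if (is.null(network) && config$n_networks > 0) {
    network <- build_tree(config$n_bif, config$n_trif, config$network_seed,
                          params$network)
  }
  rows <- vector("list", length(spec$levels))
  for (i in seq_along(spec$levels)) {
    p <- .apply_level(params, spec$factor, spec$levels[i])
    feasible <- TRUE
    resid_edp <- resid_peak <- NA_real_
    if (length(spec$constraints)) {
      cn <- names(spec$constraints)
      if (setequal(cn, "EDP")) {
        h <- hold_preload(spec$constraints$EDP, p, config, network)
        p <- h$params; feasible <- h$feasible
        resid_edp <- h$EDP - spec$constraints$EDP
      } else if (setequal(cn, c("EDP", "peakP"))) {
        h <- hold_loads(c(EDP = spec$constraints$EDP,
                          peakP = spec$constraints$peakP), p, config,
                        network)
        p <- h$params; feasible <- h$feasible
        resid_edp <- h$achieved[["EDP"]] - spec$constraints$EDP
        resid_peak <- h$achieved[["peakP"]] - spec$constraints$peakP
      } else {
        stop("unsupported constraint set: ", paste(cn, collapse = ", "),
             call. = FALSE)
      }
    }
    res <- run_closed_loop(p, config, network = network)
    rows[[i]] <- .summary_row(cycle_summary(res),
                              list(level = spec$levels[i],
                                   label = spec$labels[i],
                                   resid_EDP = resid_edp,
                                   resid_peakP = resid_peak,
                                   feasible = feasible,
                                   converged = res$converged))
  }
  structure(do.call(rbind, rows), class = c("summary_table", "data.frame"))
}

## EDP of a converged run; NULL if the run diverges
.run_edp <- function(params, config, network) {
  res <- tryCatch(
    suppressWarnings(run_closed_loop(params, config, network = network)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  s <- res$series
  c(EDP = s$P_LV[which.max(s$V_LV)], peakP = max(s$P_LV))
}

#' Hold preload by adjusting the venous resting volume
#'
#' Secant iteration on `V_ven0` (each iterate a full converged closed-loop
#' run) until the end-diastolic LV pressure matches the target within
#' `tol`.  EDP decreases monotonically in `V_ven0` near the baseline (a
#' larger venous resting volume lowers venous pressure and filling).
#'
#' @param target Target end-diastolic pressure [mmHg].
#' @param params Base [model_params()].
#' @param config A [simulation_config()].
#' @param network Fixed network topology (rebuilt from the bundle if NULL).
#' @param tol Tolerance on `|EDP - target|` [mmHg].
#' @param max_iter Maximum secant iterations.
#' @return A list: adjusted `params`, achieved `EDP`, `iterations`,
#'   `feasible`.
#' @export
hold_preload <- function(target, params, config = simulation_config(),
                         network = NULL, tol = 0.2, max_iter = 12) {
  if (is.null(network) && config$n_networks > 0) {
    network <- build_tree(config$n_bif, config$n_trif, config$network_seed,
                          params$network)
  }
  v0 <- params$circulation$V_ven0
  m <- .run_edp(params, config, network)
  if (is.null(m)) {
    return(list(params = params, EDP = NA_real_, iterations = 0L,
                feasible = FALSE))
  }
  e0 <- m[["EDP"]] - target
  if (abs(e0) <= tol) {
    return(list(params = params, EDP = e0 + target, iterations = 0L,
                feasible = TRUE))
  }
  ## first secant point from the venous-compliance slope dEDP/dV_ven0 ~ -1/C_ven
  v1 <- v0 + e0 * params$circulation$C_ven
  it <- 0L
  e1 <- e0
  repeat {
    it <- it + 1L
    params$circulation$V_ven0 <- v1
    m <- .run_edp(params, config, network)
    if (is.null(m)) {            # diverged iterate: back off halfway
      v1 <- (v0 + v1) / 2
      if (it >= max_iter) break
      next
    }
    e1 <- m[["EDP"]] - target
    if (abs(e1) <= tol) {
      return(list(params = params, EDP = e1 + target, iterations = it,
                  feasible = TRUE))
    }
    if (it >= max_iter || e1 == e0) break
    v2 <- v1 - e1 * (v1 - v0) / (e1 - e0)
    v0 <- v1; e0 <- e1; v1 <- v2
  }
  list(params = params, EDP = e1 + target, iterations = it, feasible = FALSE)
}

#' Hold preload and afterload by adjusting the arterial resistances
#'
#' Enforces the load-holding constraints of the geometry sweeps: the peak
#' LV pressure (afterload index) is matched by a bounded secant iteration
#' on the distal arterial resistance `R_ad`, and the end-diastolic pressure
#' (preload index) by a secant on the proximal arterial resistance `R_ap`,
#' alternating until both tolerances are met (each iterate a full converged
#' closed-loop run).  The best point seen is kept, so an infeasible target
#' combination returns the closest achievable operating point, flagged.
#'
#' @param targets Named vector `c(EDP = ..., peakP = ...)` [mmHg].
#' @param params,config,network As in [hold_preload()].
#' @param tol Named tolerances, default `c(EDP = 0.2, peakP = 2)` [mmHg].
#' @param max_iter Maximum total closed-loop evaluations.
#' @return A list: adjusted `params`, `achieved` values, `iterations`,
#'   `feasible`, final `residuals`.
#' @export
hold_loads <- function(targets, params, config = simulation_config(),
                       network = NULL, tol = c(EDP = 0.2, peakP = 2),
                       max_iter = 30) {
  if (is.null(network) && config$n_networks > 0) {
    network <- build_tree(config$n_bif, config$n_trif, config$network_seed,
                          params$network)
  }
  lo <- c(R_ad = 40, R_ap = 15)       # resistance floors [mmHg.ms/ml]
  it <- 0L
  best <- NULL
  score <- function(r) abs(r[1]) / tol[["EDP"]] + abs(r[2]) / tol[["peakP"]]
  evalx <- function(R_ad, R_ap) {
    p <- params
    p$circulation$R_ad <- R_ad; p$circulation$R_ap <- R_ap
    m <- .run_edp(p, config, network)
    it <<- it + 1L
    if (is.null(m)) return(NULL)
    r <- m - targets[c("EDP", "peakP")]
    if (is.null(best) || score(r) < score(best$r)) {
      best <<- list(p = p, r = r)
    }
    r
  }
  ok <- function(r) !is.null(r) && abs(r[1]) <= tol[["EDP"]] &&
    abs(r[2]) <= tol[["peakP"]]

  x <- pmax(c(params$circulation$R_ad, params$circulation$R_ap), lo)
  r <- evalx(x[1], x[2])
  it <- 0L                              # the probe run is not an iteration
  ## secant in log-resistance for one scalar residual, bounded below
  secant1 <- function(idx, ridx, x, r, rel0 = 1.15, iters = 6) {
    v0 <- log(x[idx]); e0 <- r[ridx]
    v1 <- log(max(x[idx] * if (e0 > 0) 1 / rel0 else rel0, lo[idx]))
    for (k in seq_len(iters)) {
      if (it >= max_iter) break
      xk <- x; xk[idx] <- exp(v1)
      rk <- evalx(xk[1], xk[2])
      if (is.null(rk)) { v1 <- (v0 + v1) / 2; next }
      e1 <- rk[ridx]
      x <- xk; r <- rk
      if (abs(e1) <= tol[[ridx]] || e1 == e0) break
      v2 <- v1 - e1 * (v1 - v0) / (e1 - e0)
      v2 <- min(max(v2, v1 - 0.7), v1 + 0.7)      # damped log step
      v0 <- v1; e0 <- e1
      v1 <- max(v2, log(lo[idx]))
    }
    list(x = x, r = r)
  }
  for (round in 1:4) {
    if (is.null(r)) break
    if (ok(r)) break
    if (abs(r[2]) > tol[["peakP"]]) {
      st <- secant1(1, 2, x, r); x <- st$x; r <- st$r
    }
    if (it >= max_iter || is.null(r)) break
    if (ok(r)) break
    if (abs(r[1]) > tol[["EDP"]]) {
      st <- secant1(2, 1, x, r); x <- st$x; r <- st$r
    }
    if (it >= max_iter) break
  }
  if (is.null(best)) {
    return(list(params = params, achieved = c(EDP = NA, peakP = NA),
                iterations = it, feasible = FALSE, residuals = c(NA, NA)))
  }
  list(params = best$p,
       achieved = best$r + targets[c("EDP", "peakP")],
       iterations = it, feasible = ok(best$r), residuals = best$r)
}

#' Analytic boundary-waveform fixtures for standalone network runs
#'
#' Generates smooth periodic perfusion-pressure, venous-pressure and IMP
#' waveforms on the global time grid, so the coronary module can be
#' exercised without the LV solve: a two-phase arterial-like inlet (flat
#' diastolic level plus a systolic half-sine), a constant low outlet, and a
#' half-sine systolic IMP pulse scaled by a transmural depth factor.
#'
#' @param cycle_length Cycle length [ms].
#' @param dt Grid spacing [ms].
#' @param P_dia Diastolic inlet level [mmHg].
#' @param pulse Systolic inlet pulse amplitude [mmHg].
#' @param t_sys,T_ej Ejection onset and duration of the inlet bump [ms].
#' @param P_out Outlet (venous) pressure [mmHg].
#' @param imp_peak Peak IMP of the pulse at depth factor 1 [mmHg].
#' @param T_imp Duration of the IMP half-sine [ms].
#' @param depth_factor Transmural scaling of the IMP pulse in \[0, 1\]
#'   (0 = epicardial, 1 = endocardial).
#' @param path Optional CSV output path
#'   (columns `t_ms`, `P_in_mmHg`, `P_out_mmHg`, `IMP_mmHg`).
#' @return A data.frame with columns `t`, `P_in`, `P_out`, `IMP`.
#' @export
make_waveform_fixture <- function(cycle_length = 800, dt = 1, P_dia = 75,
                                  pulse = 55, t_sys = 50, T_ej = 350,
                                  P_out = 5, imp_peak = 120, T_imp = 300,
                                  depth_factor = 1, path = NULL) {
  t <- seq(0, cycle_length - dt, by = dt)
  bump <- sin(pi * (t - t_sys) / T_ej)
  bump[t < t_sys | t > t_sys + T_ej] <- 0
  P_in <- P_dia + pulse * bump
  imp <- depth_factor * imp_peak * pmax(sin(pi * t / T_imp), 0)
  imp[t >= T_imp] <- 0
  df <- data.frame(t = t, P_in = P_in, P_out = P_out, IMP = imp)
  if (!is.null(path)) {
    out <- df
    names(out) <- c("t_ms", "P_in_mmHg", "P_out_mmHg", "IMP_mmHg")
    write.csv(out, path, row.names = FALSE)
  }
  df
}

#' Run a single coronary network against prescribed boundary waveforms
#'
#' Steps one network over repeated cycles of a boundary waveform table
#' (operator splitting: boundaries frozen over each grid step) until the
#' cycle-integrated inlet flow is periodic.
#'
#' @param network A [build_tree()] topology.
#' @param waveform A data.frame from [make_waveform_fixture()] (or read
#'   from CSV with the same columns).
#' @param n_cycles Maximum waveform repetitions.
#' @param tol Relative cycle-to-cycle change of cycle flow for periodicity.
#' @param n_sub Sub-steps per grid step.
#' @return A list: final-cycle `q_in` and `q_out` series [ml/ms],
#'   cycle-integrated flow `Q` [ml], final `state`, `n_cycles` used.
#' @export
run_network_standalone <- function(network, waveform, n_cycles = 20,
                                   tol = 1e-4, n_sub = 5) {
  st <- network_state(network)
  dt <- diff(waveform$t[1:2])
  n <- nrow(waveform)
  Q_prev <- NA_real_
  used <- 0L
  for (cyc in seq_len(n_cycles)) {
    q_in <- q_out <- numeric(n)
    for (k in seq_len(n)) {
      st <- advance_network(network, st,
                            list(P_in = waveform$P_in[k],
                                 P_out = waveform$P_out[k],
                                 P_T = waveform$IMP[k]),
                            dt = dt, method = "semi_implicit", n_sub = n_sub)
      q_in[k] <- attr(st, "q_in_avg")
      q_out[k] <- attr(st, "q_out_avg")
    }
    Q <- total_network_flow(q_in, dt)
    used <- cyc
    if (is.finite(Q_prev) && abs(Q - Q_prev) <= tol * max(abs(Q_prev), 1e-12))
      break
    Q_prev <- Q
  }
  list(q_in = q_in, q_out = q_out, Q = Q, state = st, n_cycles = used)
}

#' Calibrate the baseline operating point
#'
#' Greedy coordinate search over the calibration knobs
#' (`C_ap`, `R_ap`, `R_ad`, `V_ven0`, initial `V_LV`, `C_f`, `T_max`),
#' minimizing the maximum relative error over the hemodynamic targets
#' (each evaluation a full converged run).  Stops when the worst error
#' drops below `tol` or the evaluation budget is exhausted.
#'
#' @param targets Named list: `EDV`, `EDP` , `EF`, `peakP`, `SBP`, `DBP`
#'   (ml, mmHg, %, mmHg, mmHg, mmHg).
#' @param params Starting [model_params()].
#' @param config A [simulation_config()].
#' @param network Fixed topology (built from the bundle if NULL).
#' @param tol Acceptable worst relative error.
#' @param budget Maximum number of closed-loop evaluations.
#' @return A list: calibrated `params`, `report` (data.frame of targets,
#'   achieved values and relative errors), `worst_error`, `evaluations`,
#'   `converged`.
#' @export
calibrate_baseline <- function(targets = list(EDV = 110, EDP = 8, EF = 61,
                                              peakP = 131, SBP = 130,
                                              DBP = 73),
                               params = default_params(),
                               config = simulation_config(),
                               network = NULL, tol = 0.05, budget = 60) {
  if (is.null(network) && config$n_networks > 0) {
    network <- build_tree(config$n_bif, config$n_trif, config$network_seed,
                          params$network)
  }
  evals <- 0L
  measure <- function(p) {
    evals <<- evals + 1L
    s <- cycle_summary(run_closed_loop(p, config, network = network))
    c(EDV = s$EDV, EDP = s$LVEDP, EF = s$EF, peakP = s$peak_P_LV,
      SBP = s$SBP, DBP = s$DBP)
  }
  tgt <- unlist(targets)
  err <- function(m) max(abs(m[names(tgt)] - tgt) / abs(tgt))

  knobs <- list(
    C_ap   = list(get = function(p) p$circulation$C_ap,
                  set = function(p, v) { p$circulation$C_ap <- v; p }),
    R_ap   = list(get = function(p) p$circulation$R_ap,
                  set = function(p, v) { p$circulation$R_ap <- v; p }),
    R_ad   = list(get = function(p) p$circulation$R_ad,
                  set = function(p, v) { p$circulation$R_ad <- v; p }),
    V_ven0 = list(get = function(p) p$circulation$V_ven0,
                  set = function(p, v) { p$circulation$V_ven0 <- v; p }),
    V_LV0  = list(get = function(p) p$initial$V_LV,
                  set = function(p, v) { p$initial$V_LV <- v; p }),
    C_f    = list(get = function(p) p$lv$C_f,
                  set = function(p, v) { p$lv$C_f <- v; p }),
    T_max  = list(get = function(p) p$lv$T_max,
                  set = function(p, v) { p$lv$T_max <- v; p })
  )

  best_m <- measure(params)
  best_e <- err(best_m)
  step <- 0.06
  while (best_e > tol && evals < budget && step > 0.005) {
    improved <- FALSE
    for (nm in names(knobs)) {
      if (evals >= budget || best_e <= tol) break
      k <- knobs[[nm]]
      v <- k$get(params)
      for (f in c(1 + step, 1 - step)) {
        if (evals >= budget) break
        cand <- k$set(params, v * f)
        m <- tryCatch(measure(cand), error = function(e) NULL)
        if (is.null(m)) next
        e <- err(m)
        if (e < best_e) {
          params <- cand; best_e <- e; best_m <- m; improved <- TRUE
          break
        }
      }
    }
    if (!improved) step <- step / 2
  }
  report <- data.frame(target = names(tgt), goal = as.numeric(tgt),
                       achieved = as.numeric(best_m[names(tgt)]),
                       rel_error = as.numeric(abs(best_m[names(tgt)] - tgt)
                                              / abs(tgt)))
  list(params = params, report = report, worst_error = best_e,
       evaluations = evals, converged = best_e <= tol)
}

#' Run the full study battery: baseline plus the five sweeps
#'
#' Reproduces the complete simulation protocol around the calibrated
#' baseline: the converged baseline run, the contractility sweep
#' (T_max 65/130/205 kPa, no constraints), the afterload sweep
#' (R_ad 33 and 318 kPa.ms/ml with preload held at EDP 8 mmHg via the
#' venous resting volume), the preload sweep (V_ven0 3707 and 2696 ml),
#' and the wall-thickness (0.53 and 1.73 cm) and unloaded-cavity-volume
#' (65 and 205 ml) sweeps with preload and afterload held by the arterial
#' resistances (peak LV pressure targets 141 and 138 mmHg respectively).
#' The same canonical coronary tree is used throughout.
#'
#' @param params Calibrated [model_params()].
#' @param config A [simulation_config()].
#' @param network Optional pre-built tree; generated from the config
#'   otherwise.
#' @param quiet Suppress per-stage progress messages.
#' @return A list with the baseline `result` and `summary`, the five
#'   `summary_table`s (`contractility`, `afterload`, `preload`,
#'   `thickness`, `cavity`), and the `network` used.
#' @export
run_study <- function(params = default_params(),
                      config = simulation_config(max_cycles = 14),
                      network = NULL, quiet = FALSE) {
  if (is.null(network) && config$n_networks > 0) {
    network <- build_tree(config$n_bif, config$n_trif, config$network_seed,
                          params$network)
  }
  say <- function(...) if (!quiet) message(...)
  say("baseline run")
  base <- suppressWarnings(run_closed_loop(params, config, network = network))
  say("contractility sweep")
  sw_c <- suppressWarnings(run_sweep(
    sweep_spec("contractility", c(65, 130, 205)), params, config, network))
  say("afterload sweep (preload held)")
  sw_a <- suppressWarnings(run_sweep(
    sweep_spec("afterload", c(33, 318), constraints = list(EDP = 8)),
    params, config, network))
  say("preload sweep")
  sw_p <- suppressWarnings(run_sweep(
    sweep_spec("preload", c(3707, 2696)), params, config, network))
  say("thickness sweep (loads held)")
  sw_t <- suppressWarnings(run_sweep(
    sweep_spec("thickness", c(0.53, 1.73),
               constraints = list(EDP = 8, peakP = 141)),
    params, config, network))
  say("cavity-volume sweep (loads held)")
  sw_v <- suppressWarnings(run_sweep(
    sweep_spec("cavity_volume", c(65, 205),
               constraints = list(EDP = 8, peakP = 138)),
    params, config, network))
  list(result = base, summary = cycle_summary(base),
       contractility = sw_c, afterload = sw_a, preload = sw_p,
       thickness = sw_t, cavity = sw_v, network = network)
}

#' Headline quantities of a completed study battery
#'
#' Extracts the scalar outcomes reported by the study: baseline global
#' hemodynamics and transmural ratios, sweep-endpoint mismatch ratios,
#' flow fold-changes and pressures.
#'
#' @param study A [run_study()] result.
#' @return A named list of scalars.
#' @export
study_headlines <- function(study) {
  s <- study$summary
  at <- function(tab, lvl) tab[tab$level == lvl, , drop = FALSE]
  list(
    baseline_EF = s$EF,
    baseline_peak_P_LV = s$peak_P_LV,
    baseline_peak_IMP_endo = unname(s$peak_IMP[1]),
    baseline_Q_endo_epi = s$Q_endo_epi,
    baseline_Wf_endo_epi = s$Wf_endo_epi,
    mismatch_ratio_high_Tmax = at(study$contractility, 205)$WfQ_endo_epi,
    EF_high_Tmax = at(study$contractility, 205)$EF,
    Q_endo_fold_afterload = at(study$afterload, 318)$Q_endo /
      at(study$afterload, 33)$Q_endo,
    Q_endo_fold_preload = at(study$preload, 2696)$Q_endo /
      at(study$preload, 3707)$Q_endo,
    mismatch_ratio_thick_wall = at(study$thickness, 1.73)$WfQ_endo_epi,
    mismatch_ratio_large_cavity = at(study$cavity, 205)$WfQ_endo_epi,
    peak_P_LV_high_afterload = at(study$afterload, 318)$peak_P_LV
  )
}
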