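#' Full model parameter bundle
#'
#' Collects the circulation, LV, coronary-morphometry parameters and the
#' initial compartment volumes into one bundle.  The defaults are the
#' calibrated baseline operating point of the model (end-diastolic volume
#' 110 ml at 8 mmHg, ejection fraction ~61%, arterial pressure ~130/73
#' mmHg, peak LV pressure ~131 mmHg at contractility `T_max` = 130 kPa).
#'
#' @param circulation A [circulation_params()] object.
#' @param lv An [lv_params()] object.
#' @param network A [network_params()] object.
#' @param initial Named list of initial compartment volumes
#'   `V_LA`, `V_LV`, `V_ap`, `V_ad`, `V_ven` [ml].
#' @return An object of class `model_params`.
#' @export
model_params <- function(circulation = circulation_params(),
                         lv = lv_params(),
                         network = network_params(),
                         initial = list(V_LA = 60, V_LV = 229.161,
                                        V_ap = 660, V_ad = 113,
                                        V_ven = 3800)) {
  structure(list(circulation = circulation, lv = lv, network = network,
                 initial = initial),
            class = "model_params")
}

#' @rdname model_params
#' @export
default_params <- function() model_params()

#' Simulation controls
#'
#' @param dt Global coupling time step [ms].
#' @param max_cycles Maximum number of cardiac cycles.
#' @param convergence_tol Relative cycle-to-cycle change (composite over
#'   EDV, ESV, peak LV pressure, per-network flow) below which the run is
#'   declared periodic.
#' @param n_sub Sub-steps of the network stepper per global step.
#' @param depths Normalized transmural depths of the coronary networks.
#' @param n_networks Number of coronary networks (0 disables the coronary
#'   branch entirely).
#' @param n_bif,n_trif Branching counts of the generated tree.
#' @param network_seed Seed of the synthetic tree generator.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1, max_cycles = 10,
                              convergence_tol = 1e-3, n_sub = 5,
                              depths = c(0, 1 / 3, 2 / 3, 1),
                              n_networks = 4, n_bif = 195, n_trif = 3,
                              network_seed = 1) {
  stopifnot(dt > 0, max_cycles >= 1, all(depths >= 0 & depths <= 1))
  structure(list(dt = dt, max_cycles = max_cycles,
                 convergence_tol = convergence_tol, n_sub = n_sub,
                 depths = depths, n_networks = n_networks,
                 n_bif = n_bif, n_trif = n_trif,
                 network_seed = network_seed),
            class = "simulation_config")
}

.series_names <- function(n_net) {
  c("t", "P_LA", "P_LV", "P_ap", "P_ad", "P_ven",
    "V_LA", "V_LV", "V_ap", "V_ad", "V_ven",
    "q_mv", "q_ao", "q_ap", "q_ad", "q_ven",
    if (n_net > 0) c(paste0("q_cor_in_", seq_len(n_net)),
                     paste0("q_cor_out_", seq_len(n_net)),
                     paste0("imp_", seq_len(n_net)),
                     paste0("V_net_", seq_len(n_net))))
}

.dummy_topology <- function() {
  stats <- network_params()
  net <- build_tree(0, 0, seed = 1, stats = stats)
  net
}

.run_one_cycle <- function(params, config, geometry, network, circ_state,
                           net_vol) {
  p <- params$circulation
  circ_vec <- c(p$R_ao, p$R_ap, p$R_ad, p$R_ven, p$R_mv, p$C_ap, p$C_ad,
                p$C_ven, p$V_ap0, p$V_ad0, p$V_ven0, p$E_es_LA, p$V_LA0,
                p$A_LA, p$B_LA, p$T_max_LA, p$tau_LA, p$cycle_length)
  l <- params$lv
  lv_vec <- c(l$C_f, l$b_f, l$T_max, l$Ca0, l$Ca0_max, l$B, l$l0, l$l_ref,
              l$t0, l$tau, l$T_trans)
  n_steps <- as.integer(round(p$cycle_length / config$dt))
  cpp_run_cycle(circ_vec, lv_vec,
                geometry$Rb3, geometry$Rm3, geometry$Rm, geometry$Rhat_b,
                geometry$R_i^3,
                network$cpp$parent, network$cpp$elim_order,
                network$cpp$child_start, network$cpp$child_idx,
                network$cpp$is_terminal,
                network$vessels$L, network$vessels$Ap, network$vessels$Bp,
                network$vessels$phi_p, network$vessels$Cp, network$mu,
                circ_state, net_vol, config$depths, config$dt, n_steps,
                as.integer(config$n_sub))
}

#' Run the closed-loop cardiac-coronary simulation to a periodic state
#'
#' Iterates cardiac cycles of the three-way coupling (LV backend ->
#' circulation -> coronary networks, exchanged once per global step) until
#' the composite cycle-to-cycle residual falls below the configured
#' tolerance or `max_cycles` is reached.  The first cycle is transient and
#' excluded from all reported statistics; all returned series are the final
#' cycle.
#'
#' @param params A [model_params()] bundle.
#' @param config A [simulation_config()].
#' @param network Optionally a pre-built [build_tree()] network, reused as
#'   is (geometry sweeps hold the network fixed); by default one is
#'   generated from `params$network` and the config seed/counts.
#' @return An object of class `simulation_result`: the final-cycle time
#'   series (`series`, a data.frame on the global grid), per-shell
#'   kinematics/stress matrices (`shells`), the convergence table
#'   (`cycles`), event markers, and the inputs.
#' @export
run_closed_loop <- function(params, config = simulation_config(),
                            network = NULL) {
  geometry <- make_geometry(params$lv$V_cav0, params$lv$V_wall,
                            params$lv$n_shells)
  n_net <- config$n_networks
  if (is.null(network)) {
    network <- if (n_net > 0)
      build_tree(config$n_bif, config$n_trif, config$network_seed,
                 params$network)
    else .dummy_topology()
  }
  if (n_net > 0 && length(config$depths) != n_net) {
    stop("length(depths) must equal n_networks", call. = FALSE)
  }
  circ_state <- with(params$initial, c(V_LA, V_LV, V_ap, V_ad, V_ven))
  st0 <- network_state(network)
  net_vol <- matrix(rep(st0$Vol, n_net), nrow = length(st0$Vol),
                    ncol = n_net)

  cyc <- list()
  prev <- NULL
  converged <- FALSE
  n_run <- 0
  diag_rows <- list()
  for (ic in seq_len(config$max_cycles)) {
    out <- .run_one_cycle(params, config, geometry, network, circ_state,
                          net_vol)
    circ_state <- out$state
    net_vol <- out$Vol
    n_run <- ic
    V_LV <- out$series[, 8]
    metr <- c(EDV = max(V_LV), ESV = min(V_LV),
              peakP = max(out$series[, 3]))
    if (n_net > 0) {
      Q <- colSums(out$series[, 16 + seq_len(n_net), drop = FALSE]) *
        config$dt
      metr <- c(metr, setNames(Q, paste0("Q_", seq_len(n_net))))
    }
    resid <- if (is.null(prev)) NA_real_ else
      max(abs(metr - prev) / pmax(abs(prev), 1e-12))
    diag_rows[[ic]] <- c(cycle = ic, metr, residual = resid)
    if (!is.null(prev) && ic >= 2 && is.finite(resid) &&
        resid < config$convergence_tol) {
      converged <- TRUE
      cyc <- out
      break
    }
    prev <- metr
    cyc <- out
  }
  if (!converged) {
    warning("closed-loop run did not reach the periodicity tolerance in ",
            config$max_cycles, " cycles (last residual ",
            signif(diag_rows[[n_run]][["residual"]], 3), ")", call. = FALSE)
  }

  series <- as.data.frame(cyc$series)
  names(series) <- .series_names(n_net)
  ed <- which.max(series$V_LV)
  es <- which.min(series$V_LV)
  structure(list(
    series = series,
    shells = list(lambda = t(cyc$lambda), E_ff = t(cyc$E_ff),
                  S_ff = t(cyc$S_ff), Rhat = geometry$Rhat_m),
    cycles = as.data.frame(do.call(rbind, diag_rows)),
    converged = converged, n_cycles = n_run,
    markers = c(ED = ed, ES = es),
    depths = if (n_net > 0) config$depths else numeric(0),
    params = params, config = config,
    geometry = geometry,
    network = network,
    final_state = list(circulation = cyc$state, network_vol = cyc$Vol)
  ), class = "simulation_result")
}

#' One explicit coupling step (reference implementation)
#'
#' Executes the three exchanges of a single global step in R, using the
#' module functions directly: (1) the LV backend maps `V_LV` to `P_LV` and
#' the transmural IMP; (2) compartment pressures and branch flows are
#' evaluated and the proximal arterial / venous pressures are handed to the
#' networks as boundary conditions; (3) the networks advance over `dt` with
#' frozen boundaries and their interval-averaged inlet/outlet flows enter
#' the volume update with negative sign in the proximal arterial and
#' positive sign in the venous compartment.  Used for step-level
#' verification; [run_closed_loop()] runs the same scheme compiled.
#'
#' @param bundle A list with `circ` (a [circulation_state()]), `networks`
#'   (list of [network_state()]), `geometry`, `network` (topology) and
#'   `params` (a [model_params()]).
#' @param config A [simulation_config()].
#' @return The advanced bundle, with a `record` element holding the
#'   pressures, flows, IMP samples and the LV shell state at the step start.
#' @export
step_coupled <- function(bundle, config = simulation_config()) {
  params <- bundle$params
  st <- bundle$circ
  lvs <- lv_state(bundle$geometry, params$lv, st$V_LV, st$t,
                  depths = config$depths)
  pres <- compartment_pressures(st, params$circulation, lvs$P_LV)
  fl <- branch_flows(pres, params$circulation)
  nets <- bundle$networks
  q_in <- q_out <- numeric(length(nets))
  for (j in seq_along(nets)) {
    bnd <- list(P_in = pres$P_ap, P_out = pres$P_ven,
                P_T = lvs$p_depths[j])
    nets[[j]] <- advance_network(bundle$network, nets[[j]], bnd,
                                 dt = config$dt, method = "semi_implicit",
                                 n_sub = config$n_sub)
    q_in[j] <- attr(nets[[j]], "q_in_avg")
    q_out[j] <- attr(nets[[j]], "q_out_avg")
  }
  fl$q_cor_in_total <- sum(q_in)
  fl$q_cor_out_total <- sum(q_out)
  bundle$circ <- advance_volumes(st, fl, params$circulation, config$dt)
  bundle$networks <- nets
  bundle$record <- list(pressures = pres, flows = fl, lv = lvs,
                        q_cor_in = q_in, q_cor_out = q_out)
  bundle
}

#' Cycle-to-cycle convergence diagnostics
#'
#' The residual of a cycle is the maximum relative change over end-diastolic
#' volume, end-systolic volume, peak LV pressure and the per-network
#' cycle-integrated flows, against the preceding cycle.
#'
#' @param result A [run_closed_loop()] result (or its `cycles` table).
#' @return A list with `converged`, `n_cycles` and the per-cycle `residuals`.
#' @export
cycle_convergence <- function(result) {
  tab <- if (inherits(result, "simulation_result")) result$cycles else result
  if (nrow(tab) < 2) stop("need at least 2 completed cycles", call. = FALSE)
  list(converged = isTRUE(result$converged),
       n_cycles = nrow(tab),
       residuals = tab$residual)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n")
  cat(sprintf("  %d cycles (%s), %d-ms grid, %d steps/cycle\n",
              x$n_cycles, if (x$converged) "converged" else "NOT converged",
              x$config$dt, nrow(x$series)))
  cat(sprintf("  EDV %.1f ml, ESV %.1f ml, peak P_LV %.1f mmHg\n",
              max(x$series$V_LV), min(x$series$V_LV), max(x$series$P_LV)))
  if (length(x$depths)) {
    cat(sprintf("  %d coronary networks at depths %s\n",
                length(x$depths),
                paste(signif(x$depths, 3), collapse = ", ")))
  }
  invisible(x)
}
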