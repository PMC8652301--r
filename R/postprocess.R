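#' Myofiber work density from the stress-strain loop
#'
#' The work density over one cardiac cycle is the area of the fiber
#' stress-strain loop, `W_f = contour integral of S_ff dE_ff`, evaluated by
#' trapezoidal integration around the closed loop (the series covers exactly
#' one period on the time grid; closure wraps the last sample to the
#' first).  The sign convention is the net work done by the fiber, so
#' `W_f` is positive for the physiological loop orientation (tension high
#' while the fiber shortens, low while it lengthens) and zero for any
#' closed cycle of a purely elastic response.
#'
#' @param S_ff Matrix of fiber PK2 stress [kPa], time steps in rows, shells
#'   in columns (a vector is treated as one shell).
#' @param E_ff Matching matrix of Green-Lagrange fiber strain.
#' @return Per-shell work density [kPa per cycle] (equivalently kJ/m^3).
#' @export
work_density <- function(S_ff, E_ff) {
  S <- as.matrix(S_ff); E <- as.matrix(E_ff)
  if (!identical(dim(S), dim(E))) {
    stop("S_ff and E_ff must have identical dimensions", call. = FALSE)
  }
  if (nrow(S) < 3) stop("not a closed cycle: need at least 3 samples",
                        call. = FALSE)
  nxt <- c(seq_len(nrow(S))[-1], 1L)
  -colSums(0.5 * (S + S[nxt, , drop = FALSE]) *
             (E[nxt, , drop = FALSE] - E))
}

#' Cycle-integrated network flow
#'
#' Integrates a network inlet flow-rate waveform over the (periodic) cycle;
#' retrograde intervals contribute negatively.
#'
#' @param q Flow-rate samples over one cycle [ml/ms].
#' @param dt Sample spacing [ms].
#' @return Total flow per cycle [ml].
#' @export
total_network_flow <- function(q, dt = 1) sum(q) * dt

#' Work density-perfusion mismatch profile
#'
#' Elementwise ratio `W_f / Q` at matched transmural depths, plus the
#' endocardial-to-epicardial ratio.  Depths with non-positive flow are
#' flagged (`NA` with a `flagged` attribute), never a silent infinity.
#'
#' @param W_f Work densities at the sampled depths [kPa/cycle].
#' @param Q Cycle flows at the same depths [ml/cycle].
#' @return Numeric vector `W_f/Q` [kPa.cycle/ml] with attributes
#'   `endo_epi_ratio` (first vs last depth) and `flagged`.
#' @export
mismatch_profile <- function(W_f, Q) {
  stopifnot(length(W_f) == length(Q))
  bad <- !(Q > 0)
  r <- ifelse(bad, NA_real_, W_f / Q)
  ratio <- if (!bad[1] && !bad[length(bad)]) r[1] / r[length(r)] else NA_real_
  structure(r, endo_epi_ratio = ratio, flagged = which(bad))
}

## W_f interpolated from the shell profile to the network depths
.wf_at_depths <- function(result, depths = result$depths) {
  Wf <- work_density(result$shells$S_ff, result$shells$E_ff)
  approx(result$shells$Rhat, Wf, xout = depths, rule = 2)$y
}

#' Transmural profile of a derived quantity
#'
#' @param result A [run_closed_loop()] result.
#' @param quantity One of `"W_f"` (work density on the shell grid),
#'   `"IMP_peak"` (cycle-peak IMP on the shell-boundary grid) or `"Q"`
#'   (cycle flow at the network depths).
#' @return A data.frame of class `transmural_profile` with columns
#'   `quantity`, `Rhat`, `value`, `units`.
#' @export
transmural_profile <- function(result,
                               quantity = c("W_f", "IMP_peak", "Q")) {
  quantity <- match.arg(quantity)
  if (quantity == "W_f") {
    val <- work_density(result$shells$S_ff, result$shells$E_ff)
    grid <- result$shells$Rhat
    units <- "kPa/cycle"
  } else if (quantity == "IMP_peak") {
    n_net <- length(result$depths)
    if (n_net == 0) stop("run has no coronary networks", call. = FALSE)
    imp <- as.matrix(result$series[paste0("imp_", seq_len(n_net))])
    val <- apply(imp, 2, max)
    grid <- result$depths
    units <- "mmHg"
  } else {
    n_net <- length(result$depths)
    if (n_net == 0) stop("run has no coronary networks", call. = FALSE)
    qin <- as.matrix(result$series[paste0("q_cor_in_", seq_len(n_net))])
    val <- apply(qin, 2, total_network_flow, dt = result$config$dt)
    grid <- result$depths
    units <- "ml/cycle"
  }
  structure(data.frame(quantity = quantity, Rhat = grid, value = val,
                       units = units, row.names = NULL),
            class = c("transmural_profile", "data.frame"))
}

#' Scalar summary of a converged cycle
#'
#' Global hemodynamics (EF, EDV, ESV, peak LV pressure, LV end-diastolic
#' pressure, systolic/diastolic arterial pressure), peak IMP per network
#' depth, cycle-integrated network flows, work density and the
#' work density-perfusion mismatch at the network depths with their
#' endocardial/epicardial ratios, and peak Euler-Almansi strains relative
#' to end-diastole.
#'
#' @param result A [run_closed_loop()] result.
#' @return An object of class `cycle_summary` (a named list).
#' @export
cycle_summary <- function(result) {
  s <- result$series
  dt <- result$config$dt
  EDV <- max(s$V_LV); ESV <- min(s$V_LV)
  ed <- which.max(s$V_LV); es <- which.min(s$V_LV)
  EDP <- s$P_LV[ed]
  n_net <- length(result$depths)

  ## Euler-Almansi tangential strain w.r.t. end-diastole, per shell
  lam <- result$shells$lambda
  lam_rel <- sweep(lam, 2, lam[ed, ], "/")
  e_cc <- 0.5 * (1 - 1 / lam_rel^2)
  peak_ecc <- max(abs(e_cc))

  out <- list(
    EF = 100 * (EDV - ESV) / EDV,
    EDV = EDV, ESV = ESV,
    peak_P_LV = max(s$P_LV), LVEDP = EDP,
    SBP = max(s$P_ap), DBP = min(s$P_ap),
    peak_e_cc = 100 * peak_ecc, peak_e_ll = 100 * peak_ecc,
    ED_index = ed, ES_index = es
  )
  if (n_net > 0) {
    imp <- as.matrix(s[paste0("imp_", seq_len(n_net))])
    qin <- as.matrix(s[paste0("q_cor_in_", seq_len(n_net))])
    Q <- unname(apply(qin, 2, total_network_flow, dt = dt))
    Wf <- .wf_at_depths(result)
    mis <- mismatch_profile(Wf, Q)
    out$peak_IMP <- setNames(apply(imp, 2, max),
                             paste0("d", signif(result$depths, 3)))
    out$Q <- Q
    out$W_f <- Wf
    out$mismatch <- as.numeric(mis)
    out$Q_endo_epi <- Q[1] / Q[n_net]
    out$Wf_endo_epi <- Wf[1] / Wf[n_net]
    out$mismatch_endo_epi <- attr(mis, "endo_epi_ratio")
  }
  structure(out, class = "cycle_summary")
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat("<cycle_summary>\n")
  cat(sprintf("  EF %.1f%%  EDV %.1f ml  ESV %.1f ml\n", x$EF, x$EDV, x$ESV))
  cat(sprintf("  peak P_LV %.1f  LVEDP %.1f  SBP %.1f  DBP %.1f [mmHg]\n",
              x$peak_P_LV, x$LVEDP, x$SBP, x$DBP))
  cat(sprintf("  peak |e_cc| %.1f%%\n", x$peak_e_cc))
  if (!is.null(x$Q)) {
    cat(sprintf("  Q endo/epi %.3f   W_f endo/epi %.3f   (W_f/Q) endo/epi %.3f\n",
                x$Q_endo_epi, x$Wf_endo_epi, x$mismatch_endo_epi))
  }
  invisible(x)
}

#' Write the final-cycle time series / summary to disk
#'
#' @param result A [run_closed_loop()] result.
#' @param path Output file path (CSV for the series, JSON for the summary).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  write.csv(result$series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param summary A [cycle_summary()] object.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Dump the per-shell kinematics/stress series as long-format CSV
#'
#' One row per time step and shell: `t`, `Rhat`, `lambda`, `E_ff`, `S_ff`
#' and the IMP `p` interpolated at the shell midpoints [mmHg].
#'
#' @param result A [run_closed_loop()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shell_series <- function(result, path) {
  sh <- result$shells
  n_t <- nrow(sh$lambda)
  n_s <- length(sh$Rhat)
  n_net <- length(result$depths)
  ## IMP at shell midpoints from the recorded depth samples (exact at the
  ## boundaries, linear between the sampled depths)
  p_mid <- if (n_net >= 2) {
    t(apply(as.matrix(result$series[paste0("imp_", seq_len(n_net))]), 1,
            function(row) approx(result$depths, row, xout = sh$Rhat,
                                 rule = 2)$y))
  } else matrix(NA_real_, n_t, n_s)
  df <- data.frame(
    t = rep(result$series$t, times = n_s),
    Rhat = rep(sh$Rhat, each = n_t),
    lambda = as.vector(sh$lambda),
    E_ff = as.vector(sh$E_ff),
    S_ff = as.vector(sh$S_ff),
    p = as.vector(p_mid)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
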