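#' Morphometry configuration for the synthetic coronary tree generator
#'
#' The measured 400-vessel network behind the model is not published, so the
#' package generates a statistically similar surrogate tree: diameters taper
#' from the root to the terminals by a per-generation ratio consistent with
#' a configurable area-expansion factor, with seeded lognormal jitter, and
#' vessel length proportional to diameter.  Passive pressure-diameter
#' parameters are scaled from each vessel's reference diameter and then
#' rescaled uniformly so that the diameter at a transvascular pressure of
#' `P_ref_cal` equals the reference diameter exactly.
#'
#' @param root_D Root vessel reference diameter [um].
#' @param terminal_D Target geometric-mean terminal diameter [um]; after
#'   growth the taper is exponent-corrected (root fixed) so the terminals
#'   land on this morphometric anchor.  `NULL` disables the correction.
#' @param area_ratio Total child-to-parent cross-sectional area ratio at a
#'   branching [-].
#' @param k_LD Length-to-diameter ratio, `L = k_LD * D` [-].
#' @param jitter_sd Standard deviation of the lognormal diameter jitter [-].
#' @param D_min Floor on sampled reference diameters [um].
#' @param Ap_scale,Bp_scale Asymptotic maximal/minimal radii as fractions of
#'   the reference diameter (before the operating-point rescale) [-].
#' @param phi_p Transvascular pressure at the mean radius [mmHg].
#' @param Cp Passive response bandwidth [mmHg].
#' @param P_ref_cal Transvascular pressure pinned to the reference diameter
#'   [mmHg].
#' @param mu Blood viscosity [MPa.s]; constant, no diameter dependence.
#' @return An object of class `network_params`.
#' @export
network_params <- function(root_D = 160, terminal_D = 12, area_ratio = 1.2,
                           k_LD = 20, jitter_sd = 0.12, D_min = 6,
                           Ap_scale = 0.60, Bp_scale = 0.35,
                           phi_p = 70, Cp = 30, P_ref_cal = 100,
                           mu = 2.7e-9) {
  stopifnot(root_D > 0, area_ratio > 0, k_LD > 0, jitter_sd >= 0,
            Ap_scale > Bp_scale, Bp_scale > 0, Cp > 0, mu > 0,
            is.null(terminal_D) || (terminal_D > 0 && terminal_D < root_D))
  structure(list(root_D = root_D, terminal_D = terminal_D,
                 area_ratio = area_ratio, k_LD = k_LD,
                 jitter_sd = jitter_sd, D_min = D_min,
                 Ap_scale = Ap_scale, Bp_scale = Bp_scale,
                 phi_p = phi_p, Cp = Cp, P_ref_cal = P_ref_cal, mu = mu),
            class = "network_params")
}

## viscosity in internal units [mmHg.ms] from MPa.s
.mu_internal <- function(mu_MPa_s) mu_MPa_s * 1e6 / 133.322 * 1e3

#' Build a seeded synthetic coronary microvascular tree
#'
#' Grows a rooted tree by `n_bif + n_trif` branching events, each splitting
#' a uniformly chosen current terminal vessel into 2 (bifurcation) or 3
#' (trifurcation) children; trifurcation events are placed at seeded random
#' positions in the event sequence.  The resulting vessel count is exactly
#' `1 + 2 n_bif + 3 n_trif` (400 with the default 195 bifurcations and 3
#' trifurcations); the terminal count is a derived quantity.  Identical
#' seeds reproduce the topology and diameters bit-for-bit.
#'
#' @param n_bif Number of bifurcations.
#' @param n_trif Number of trifurcations.
#' @param seed Integer RNG seed.
#' @param stats A [network_params()] morphometry configuration.
#' @return An object of class `coro_network`: a vessel table
#'   (`id`, `parent`, `gen`, `L` [cm], `D_ref` [um], `Ap`, `Bp` [um],
#'   `phi_p`, `Cp` [mmHg]), derived counts, and the topology arrays used by
#'   the solvers (children lists, node kinds, elimination order).
#' @export
build_tree <- function(n_bif = 195, n_trif = 3, seed = 1,
                       stats = network_params()) {
  if (n_bif < 0 || n_trif < 0 || (n_bif + n_trif) < 0) {
    stop("impossible topology counts", call. = FALSE)
  }
  n_vessels <- 1L + 2L * n_bif + 3L * n_trif
  n_events <- n_bif + n_trif

  ## seeded, side-effect-free RNG use
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  parent <- integer(n_vessels); parent[1] <- 0L
  gen <- integer(n_vessels); gen[1] <- 0L
  D <- numeric(n_vessels); D[1] <- stats$root_D
  n_now <- 1L
  terminals <- 1L
  trif_events <- if (n_events > 0 && n_trif > 0)
    sort(sample.int(n_events, n_trif)) else integer(0)

  for (ev in seq_len(n_events)) {
    k <- length(trif_events) && ev %in% trif_events
    n_child <- if (k) 3L else 2L
    tgt <- terminals[sample.int(length(terminals), 1L)]
    ratio <- sqrt(stats$area_ratio / n_child)
    ids <- n_now + seq_len(n_child)
    parent[ids] <- tgt
    gen[ids] <- gen[tgt] + 1L
    jit <- exp(stats$jitter_sd * rnorm(n_child))
    D[ids] <- pmax(D[tgt] * ratio * jit, stats$D_min)
    terminals <- c(setdiff(terminals, tgt), ids)
    n_now <- n_now + n_child
  }

  ## exponent correction of the taper so the geometric-mean terminal
  ## diameter lands on the morphometric anchor (root unchanged)
  if (!is.null(stats$terminal_D) && n_events > 0) {
    gm <- exp(mean(log(D[terminals])))
    if (gm < stats$root_D) {
      gamma <- log(stats$terminal_D / stats$root_D) /
        log(gm / stats$root_D)
      D <- stats$root_D * (D / stats$root_D)^gamma
      D <- pmax(D, stats$D_min / 2)
    }
  }
  L <- stats$k_LD * D * 1e-4                # um -> cm
  ## passive law parameters scaled from D_ref, then pinned so that
  ## D(P_trans = P_ref_cal) = D_ref exactly
  Ap <- stats$Ap_scale * D
  Bp <- stats$Bp_scale * D
  D_at_ref <- 2 * Bp + (2 * (Ap - Bp) / pi) *
    (pi / 2 + atan((stats$P_ref_cal - stats$phi_p) / stats$Cp))
  s <- D / D_at_ref
  Ap <- Ap * s
  Bp <- Bp * s

  vessels <- data.frame(
    id = seq_len(n_vessels), parent = parent, gen = gen,
    L = L, D_ref = D, Ap = Ap, Bp = Bp,
    phi_p = stats$phi_p, Cp = stats$Cp
  )
  net <- structure(list(
    vessels = vessels,
    n_vessels = n_vessels, n_bif = n_bif, n_trif = n_trif,
    n_terminal = length(terminals),
    seed = seed, stats = stats,
    mu = .mu_internal(stats$mu)
  ), class = "coro_network")
  .index_topology(net)
}

## derived topology arrays shared by the R and C++ solvers; node j is the
## downstream end of vessel j, node 0 is the network inlet
.index_topology <- function(net) {
  v <- net$vessels
  n <- net$n_vessels
  children <- split(v$id, factor(v$parent, levels = 0:n))
  n_children <- lengths(children)[-1]           # per node 1..n
  is_internal <- n_children > 0
  net$children <- children[-1]
  net$is_terminal_vessel <- !is_internal
  node_depth <- v$gen + 1L
  internal <- which(is_internal)
  net$elim_order <- internal[order(node_depth[internal], decreasing = TRUE)]
  ## flat arrays for the compiled stepper, child slices aligned with the
  ## deepest-first elimination order
  flat_children <- unlist(net$children[as.character(net$elim_order)],
                          use.names = FALSE)
  net$cpp <- list(
    parent = as.integer(v$parent),              # 0 = inlet
    internal = as.integer(internal),
    elim_order = as.integer(net$elim_order),
    child_start = as.integer(c(0L, cumsum(n_children[net$elim_order]))),
    child_idx = as.integer(flat_children),
    is_terminal = net$is_terminal_vessel
  )
  net
}

#' Passive pressure-diameter law of a vessel
#'
#' Arctangent law
#' `D = 2 Bp + (2 (Ap - Bp)/pi) * (pi/2 + arctan((P_trans - phi_p)/Cp))`,
#' saturating at diameter `2 Bp` for strongly negative and `2 Ap` for
#' strongly positive transvascular pressure, with `D = Ap + Bp` at
#' `P_trans = phi_p`.
#'
#' @param P_trans Transvascular pressure (mid-node minus IMP) [mmHg].
#' @param vessel A row (or vectorized columns) of the vessel table with
#'   `Ap`, `Bp` [um] and `phi_p`, `Cp` [mmHg].
#' @return Diameter [um].
#' @export
pressure_to_diameter <- function(P_trans, vessel) {
  2 * vessel$Bp + (2 * (vessel$Ap - vessel$Bp) / pi) *
    (pi / 2 + atan((P_trans - vessel$phi_p) / vessel$Cp))
}

#' @rdname pressure_to_diameter
#' @param D Diameter [um], strictly inside `(2 Bp, 2 Ap)`.
#' @export
diameter_to_pressure <- function(D, vessel) {
  if (any(D <= 2 * vessel$Bp) || any(D >= 2 * vessel$Ap)) {
    stop("diameter outside the open interval (2 Bp, 2 Ap)", call. = FALSE)
  }
  x <- (D - 2 * vessel$Bp) * pi / (2 * (vessel$Ap - vessel$Bp)) - pi / 2
  vessel$phi_p + vessel$Cp * tan(x)
}

#' Poiseuille half-segment resistance
#'
#' Each Windkessel half carries `R1 = R2 = 64 mu L / (pi D^4)`; the series
#' total `128 mu L / (pi D^4)` is the Poiseuille resistance of the whole
#' segment.
#'
#' @param D Diameter [um].
#' @param L Length [cm].
#' @param mu Viscosity [MPa.s].
#' @return Half-segment resistance [mmHg.ms/ml].
#' @export
segment_resistance <- function(D, L, mu = 2.7e-9) {
  64 * .mu_internal(mu) * L / (pi * (D * 1e-4)^4)
}

#' Pressure-dependent vessel capacitance
#'
#' `C = dVol/dP_trans = (pi L D / 2) dD/dP_trans` with the Lorentzian
#' sensitivity `dD/dP = (2 (Ap - Bp)/pi) Cp / ((P - phi_p)^2 + Cp^2)`;
#' strictly positive and maximal at `P_trans = phi_p`.
#'
#' @param P_trans Transvascular pressure [mmHg].
#' @param vessel Vessel parameters as in [pressure_to_diameter()], plus `L`.
#' @return Capacitance [ml/mmHg].
#' @export
vessel_capacitance <- function(P_trans, vessel) {
  D <- pressure_to_diameter(P_trans, vessel)
  dDdP <- (2 * (vessel$Ap - vessel$Bp) / pi) * vessel$Cp /
    ((P_trans - vessel$phi_p)^2 + vessel$Cp^2)
  (pi * vessel$L * (D * 1e-4) / 2) * (dDdP * 1e-4)
}

## diameter [um] implied by a vessel volume [ml]
.volume_to_diameter <- function(Vol, L) sqrt(4 * Vol / (pi * L)) * 1e4
.diameter_to_volume <- function(D, L) pi * (D * 1e-4)^2 * L / 4

#' Initialize a network state
#'
#' Vessels start at the diameter implied by a uniform transvascular
#' pressure (default `phi_p`, i.e. `D = Ap + Bp`).
#'
#' @param network A [build_tree()] object.
#' @param P_trans Initial uniform transvascular pressure [mmHg].
#' @return An object of class `network_state` holding per-vessel volumes
#'   `Vol` [ml] and diameters `D` [um].
#' @export
network_state <- function(network, P_trans = NULL) {
  v <- network$vessels
  if (is.null(P_trans)) P_trans <- v$phi_p
  D <- pressure_to_diameter(P_trans, v)
  structure(list(Vol = .diameter_to_volume(D, v$L), D = D),
            class = "network_state")
}

#' Junction pressures from mid-node pressures
#'
#' With the capacitor attached at each vessel's mid node, the internal
#' junction pressures follow from Kirchhoff mass conservation through the
#' adjacent half-resistances only: each junction pressure is the
#' conductance-weighted mean of the neighbouring mid-node pressures (and
#' boundary pressures at the inlet and terminals).  Flows computed from the
#' resulting half-segment drops satisfy `sum(Q) = 0` at every junction.
#'
#' @param network A [build_tree()] object.
#' @param state A [network_state()] object.
#' @param boundary A list with `P_in`, `P_out`, `P_T` [mmHg].
#' @return Numeric vector of node pressures indexed by vessel (node `j` is
#'   the downstream end of vessel `j`); terminal entries hold `P_out`.
#' @export
junction_pressures <- function(network, state, boundary) {
  v <- network$vessels
  D <- .volume_to_diameter(state$Vol, v$L)
  R1 <- 64 * network$mu * v$L / (pi * (D * 1e-4)^4)   # = R2
  P_mid <- diameter_to_pressure(D, v) + boundary$P_T
  g <- 1 / R1
  P_node <- rep(boundary$P_out, network$n_vessels)
  for (j in network$cpp$internal) {
    kids <- network$children[[as.character(j)]]
    num <- P_mid[j] * g[j] + sum(P_mid[kids] * g[kids])
    den <- g[j] + sum(g[kids])
    P_node[j] <- num / den
  }
  P_node
}

#' Per-vessel and total network flows
#'
#' Half-segment flows from the current pressure drops: `Q_in` across the
#' upstream half and `Q_out` across the downstream half of each vessel.
#' The network inlet flow is `Q_in` of the root vessel; the outlet total is
#' the sum of terminal `Q_out`.
#'
#' @inheritParams junction_pressures
#' @return A list with vectors `Q_in`, `Q_out` [ml/ms], scalars
#'   `q_inlet`, `q_outlet_total`, and the node pressures used.
#' @export
vessel_flows <- function(network, state, boundary) {
  v <- network$vessels
  D <- .volume_to_diameter(state$Vol, v$L)
  R1 <- 64 * network$mu * v$L / (pi * (D * 1e-4)^4)
  P_mid <- diameter_to_pressure(D, v) + boundary$P_T
  P_node <- junction_pressures(network, state, boundary)
  P_up <- ifelse(v$parent == 0L, boundary$P_in, P_node[pmax(v$parent, 1L)])
  Q_in <- (P_up - P_mid) / R1
  Q_out <- (P_mid - P_node) / R1
  list(Q_in = Q_in, Q_out = Q_out,
       q_inlet = Q_in[1],
       q_outlet_total = sum(Q_out[network$is_terminal_vessel]),
       P_node = P_node, P_mid = P_mid)
}

#' Advance the network state over a boundary-frozen interval
#'
#' Integrates the stiff per-vessel Windkessel system over `dt` with the
#' boundary pressures and the IMP held constant (the operator splitting of
#' the explicit coupling scheme).  The state variable is the vessel blood
#' volume, which makes the update exactly mass-conserving; the mid-node
#' pressure follows algebraically from the pressure-diameter law plus the
#' IMP, and junction pressures from Kirchhoff conservation.
#'
#' Two integrators are provided: `"bdf"` uses a backward-differentiation
#' stiff solver (via deSolve) on volumes scaled by each vessel's reference
#' volume, with relative/absolute tolerances `rtol`/`atol`; this is the
#' reference route.  `"semi_implicit"` is the fast compiled
#' linearized-implicit stepper used inside the closed-loop simulation
#' (`n_sub` sub-steps per call), unconditionally stable and equivalent to
#' the BDF route to well under a percent at the default sub-stepping.
#'
#' @inheritParams junction_pressures
#' @param dt Interval length [ms].
#' @param method `"bdf"` or `"semi_implicit"`.
#' @param n_sub Sub-steps for the semi-implicit stepper.
#' @param rtol,atol Tolerances for the BDF route (on scaled volumes).
#' @return The advanced `network_state`, with attributes `q_in_avg` and
#'   `q_out_avg`, the interval-averaged inlet/outlet flows [ml/ms] whose
#'   integrals exactly match the change in total network volume.
#' @export
advance_network <- function(network, state, boundary, dt = 1,
                            method = c("semi_implicit", "bdf"),
                            n_sub = 5, rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  v <- network$vessels
  if (method == "bdf") {
    Vref <- .diameter_to_volume(v$D_ref, v$L)
    rhs <- function(t, u, p) {
      st <- list(Vol = u * Vref)
      fl <- vessel_flows(network, st, boundary)
      list((fl$Q_in - fl$Q_out) / Vref)
    }
    sol <- deSolve::ode(y = state$Vol / Vref, times = c(0, dt), func = rhs,
                        parms = NULL, method = "bdf",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("diverged state: network BDF integration failed", call. = FALSE)
    }
    Vol_new <- as.numeric(sol[2, -1]) * Vref
    st <- list(Vol = Vol_new)
    ## interval-average boundary fluxes from the volume bookkeeping and the
    ## endpoint flow split (trapezoid over the endpoints)
    fl0 <- vessel_flows(network, state, boundary)
    fl1 <- vessel_flows(network, st, boundary)
    q_in_avg <- (fl0$q_inlet + fl1$q_inlet) / 2
    q_out_avg <- q_in_avg - (sum(Vol_new) - sum(state$Vol)) / dt
  } else {
    out <- cpp_advance_network(
      network$cpp$parent, network$cpp$elim_order, network$cpp$child_start,
      network$cpp$child_idx, network$cpp$is_terminal,
      v$L, v$Ap, v$Bp, v$phi_p, v$Cp, network$mu,
      state$Vol, boundary$P_in, boundary$P_out, boundary$P_T,
      dt, as.integer(n_sub))
    Vol_new <- out$Vol
    q_in_avg <- out$q_in_avg
    q_out_avg <- out$q_out_avg
  }
  structure(list(Vol = Vol_new, D = .volume_to_diameter(Vol_new, v$L)),
            class = "network_state",
            q_in_avg = q_in_avg, q_out_avg = q_out_avg)
}

#' Write / read a network topology as an edge list
#'
#' Plain-text round trip: a CSV edge list
#' (`vessel_id`, `parent_id`, `L_cm`, `Dref_um`, `order`, `Ap_um`, `Bp_um`,
#' `phip_mmHg`, `Cp_mmHg`) plus a JSON metadata block (counts, seed,
#' generator parameters).
#'
#' @param network A [build_tree()] object.
#' @param path Path of the CSV file; metadata goes to `<path>.json`.
#' @return `write_network` returns `path` invisibly; `read_network` the
#'   reconstructed `coro_network`.
#' @export
write_network <- function(network, path) {
  v <- network$vessels
  df <- data.frame(vessel_id = v$id, parent_id = v$parent, L_cm = v$L,
                   Dref_um = v$D_ref, order = v$gen, Ap_um = v$Ap,
                   Bp_um = v$Bp, phip_mmHg = v$phi_p, Cp_mmHg = v$Cp)
  write.csv(df, path, row.names = FALSE)
  meta <- list(n_vessels = network$n_vessels, n_bif = network$n_bif,
               n_trif = network$n_trif, n_terminal = network$n_terminal,
               seed = network$seed, stats = unclass(network$stats))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stats <- do.call(network_params, meta$stats)
  vessels <- data.frame(id = df$vessel_id, parent = as.integer(df$parent_id),
                        gen = as.integer(df$order), L = df$L_cm,
                        D_ref = df$Dref_um, Ap = df$Ap_um, Bp = df$Bp_um,
                        phi_p = df$phip_mmHg, Cp = df$Cp_mmHg)
  net <- structure(list(
    vessels = vessels, n_vessels = nrow(vessels),
    n_bif = meta$n_bif, n_trif = meta$n_trif,
    n_terminal = meta$n_terminal, seed = meta$seed, stats = stats,
    mu = .mu_internal(stats$mu)
  ), class = "coro_network")
  .index_topology(net)
}

#' @export
print.coro_network <- function(x, ...) {
  cat("<coro_network>\n")
  cat(sprintf("  %d vessels (%d bif, %d trif, %d terminals), seed %s\n",
              x$n_vessels, x$n_bif, x$n_trif, x$n_terminal,
              format(x$seed)))
  cat(sprintf("  D_ref: root %.1f um, terminal median %.1f um\n",
              x$vessels$D_ref[1],
              stats::median(x$vessels$D_ref[x$is_terminal_vessel])))
  invisible(x)
}
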