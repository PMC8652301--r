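test_that("tree generator: counts, determinism, degenerate cases", {
  net <- fig2b_network()
  expect_equal(net$n_vessels, 3L)          # single bifurcation
  expect_equal(net$n_terminal, 2L)
  big <- build_tree(195, 3, seed = 5)
  expect_equal(big$n_vessels, 400L)        # 1 + 2*195 + 3*3
  expect_equal(big$n_vessels, 1L + 2L * big$n_bif + 3L * big$n_trif)
  # bit-exact determinism for a fixed seed
  again <- build_tree(195, 3, seed = 5)
  expect_identical(big$vessels, again$vessels)
  other <- build_tree(195, 3, seed = 6)
  expect_false(identical(big$vessels$D_ref, other$vessels$D_ref))
  # generator does not disturb the session RNG stream
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(build_tree(5, 0, seed = 1)); x2 <- rnorm(1)
  expect_identical(x1, x2)
  expect_error(build_tree(-1, 0), "topology")
  # diameters taper from root to terminals
  expect_gt(big$vessels$D_ref[1],
            max(big$vessels$D_ref[big$is_terminal_vessel]))
})

test_that("arctangent pressure-diameter law and its inverse", {
  v <- small_network()$vessels[3, ]
  expect_equal(pressure_to_diameter(v$phi_p, v), v$Ap + v$Bp)
  expect_equal(pressure_to_diameter(1e9, v), 2 * v$Ap, tolerance = 1e-6)
  expect_equal(pressure_to_diameter(-1e9, v), 2 * v$Bp, tolerance = 1e-6)
  # round trip to 1e-10
  P <- seq(-150, 250, by = 10)
  D <- pressure_to_diameter(P, v)
  expect_true(all(D > 2 * v$Bp & D < 2 * v$Ap))
  expect_equal(diameter_to_pressure(D, v), P, tolerance = 1e-10)
  expect_error(diameter_to_pressure(2 * v$Ap, v), "interval")
  # build-time operating point: D(100 mmHg) = D_ref
  net <- small_network()
  expect_equal(pressure_to_diameter(100, net$vessels), net$vessels$D_ref,
               tolerance = 1e-10)
})

test_that("Poiseuille half-segment resistance with independent unit oracle", {
  # hand unit-analysis oracle, computed in SI then converted:
  # mu = 2.7e-3 Pa.s, L = 5e-4 m, D = 50e-6 m
  # R_half = 64 mu L / (pi D^4) = 4.40032e12 Pa.s/m^3 = 3.30064e7 mmHg.ms/ml
  oracle <- 64 * 2.7e-3 * 5e-4 / (pi * (50e-6)^4) / 133.322 / 1000
  expect_equal(segment_resistance(50, 0.05, mu = 2.7e-9), oracle,
               tolerance = 1e-10)
  expect_equal(oracle, 3.30052e7, tolerance = 1e-5)
  # fourth-power law: doubling D divides R by 16
  expect_equal(segment_resistance(100, 0.05) * 16,
               segment_resistance(50, 0.05))
  # series total equals the Poiseuille coefficient of the whole segment
  R1 <- segment_resistance(50, 0.05)
  mu_int <- 2.7e-9 * 1e6 / 133.322 * 1e3
  expect_equal(2 * R1, 128 * mu_int * 0.05 / (pi * (50e-4)^4))
})

test_that("pressure-dependent capacitance: positivity, maximum, finite
           differences", {
  v <- small_network()$vessels[5, ]
  P <- seq(-100, 250, by = 5)
  C <- vessel_capacitance(P, v)
  expect_true(all(C > 0))
  expect_equal(P[which.max(C)], v$phi_p)   # Lorentzian peak
  # finite-difference oracle on the vessel volume
  vol <- function(p) pi * (pressure_to_diameter(p, v) * 1e-4)^2 * v$L / 4
  dP <- 1e-4
  for (p0 in c(-40, 0, 70, 180)) {
    expect_equal(vessel_capacitance(p0, v),
                 (vol(p0 + dP) - vol(p0 - dP)) / (2 * dP),
                 tolerance = 1e-6)
  }
})

test_that("junction pressures satisfy Kirchhoff conservation and match a
           dense linear-solve oracle", {
  net <- small_network()
  st <- network_state(net, P_trans = 90 + 10 * sin(seq_len(net$n_vessels)))
  bnd <- list(P_in = 95, P_out = 6, P_T = 12)
  Pn <- junction_pressures(net, st, bnd)
  fl <- vessel_flows(net, st, bnd)
  # sum of flows at every internal node is zero
  for (j in net$cpp$internal) {
    kids <- net$children[[as.character(j)]]
    expect_equal(fl$Q_out[j], sum(fl$Q_in[kids]), tolerance = 1e-10)
  }
  # dense oracle: assemble the full conductance system over internal nodes
  v <- net$vessels
  D <- st$D
  R1 <- segment_resistance(D, v$L, net$stats$mu)
  P_mid <- diameter_to_pressure(D, v) + bnd$P_T
  internal <- net$cpp$internal
  A <- matrix(0, length(internal), length(internal))
  b <- numeric(length(internal))
  for (i in seq_along(internal)) {
    j <- internal[i]
    kids <- net$children[[as.character(j)]]
    A[i, i] <- 1 / R1[j] + sum(1 / R1[kids])
    b[i] <- P_mid[j] / R1[j] + sum(P_mid[kids] / R1[kids])
  }
  expect_equal(unname(Pn[internal]), unname(solve(A, b)), tolerance = 1e-10)
  # symmetric single bifurcation: equal children get equal flows
  net3 <- build_tree(1, 0, seed = 2)
  net3$vessels$D_ref[2:3] <- 60; net3$vessels$L[2:3] <- 0.12
  net3$vessels$Ap[2:3] <- 36; net3$vessels$Bp[2:3] <- 21
  st3 <- network_state(net3, 100)
  fl3 <- vessel_flows(net3, st3, list(P_in = 95, P_out = 5, P_T = 0))
  expect_equal(fl3$Q_in[2], fl3$Q_in[3], tolerance = 1e-12)
})

test_that("equilibrium: equal boundary and transvascular pressures give zero
           flow and the mean diameter", {
  net <- fig2b_network()
  P_T <- 20
  bnd <- list(P_in = P_T + net$vessels$phi_p[1],
              P_out = P_T + net$vessels$phi_p[1], P_T = P_T)
  st <- network_state(net, net$vessels$phi_p)
  st2 <- advance_network(net, st, bnd, dt = 50, method = "semi_implicit",
                         n_sub = 50)
  expect_equal(st2$D, net$vessels$Ap + net$vessels$Bp, tolerance = 1e-9)
  expect_equal(attr(st2, "q_in_avg"), 0, tolerance = 1e-12)
  fl <- vessel_flows(net, st2, bnd)
  expect_equal(max(abs(c(fl$Q_in, fl$Q_out))), 0, tolerance = 1e-12)
})

test_that("single-vessel linearized step response matches the RC closed form", {
  net <- single_vessel_network()
  v <- net$vessels
  P0 <- 90
  st <- network_state(net, P0)
  # small IMP step: P_mid jumps with P_T (volume is continuous), then
  # relaxes back with tau = C * R1 * R2 / (R1 + R2)
  dPT <- 0.01
  R1 <- segment_resistance(st$D, v$L, net$stats$mu)
  C <- vessel_capacitance(P0, v)
  tau <- C * R1 / 2
  bnd <- list(P_in = P0, P_out = P0, P_T = dPT)
  times <- c(50, 150, 400)
  for (m in c("bdf", "semi_implicit")) {
    sti <- st; tprev <- 0
    for (tk in times) {
      sti <- advance_network(net, sti, bnd, dt = tk - tprev, method = m,
                             n_sub = 200)
      tprev <- tk
      x <- diameter_to_pressure(sti$D, v) + dPT - P0  # P_mid - equilibrium
      expect_equal(x, dPT * exp(-tk / tau), tolerance = 1e-3,
                   label = paste("method", m, "t", tk))
    }
  }
})

test_that("volume-state stepper agrees with the BDF reference on a
           physiological interval", {
  net <- small_network()
  st <- network_state(net, 95)
  bnd <- list(P_in = 98, P_out = 6, P_T = 55)
  st_bdf <- st; st_semi <- st
  for (k in 1:20) {
    st_bdf <- advance_network(net, st_bdf, bnd, dt = 1, method = "bdf")
    st_semi <- advance_network(net, st_semi, bnd, dt = 1,
                               method = "semi_implicit", n_sub = 10)
  }
  expect_equal(st_semi$Vol, st_bdf$Vol, tolerance = 5e-3)
  expect_equal(attr(st_semi, "q_in_avg"), attr(st_bdf, "q_in_avg"),
               tolerance = 5e-3)
})

test_that("exact volume bookkeeping and diameter bounds under strong
           transients", {
  net <- small_network()
  st <- network_state(net, 95)
  total0 <- sum(st$Vol)
  flux <- 0
  # square IMP pulse far above perfusion pressure
  for (k in 1:120) {
    imp <- if (k <= 60) 180 else 0
    st <- advance_network(net, st, list(P_in = 90, P_out = 5, P_T = imp),
                          dt = 1, method = "semi_implicit", n_sub = 5)
    flux <- flux + attr(st, "q_in_avg") - attr(st, "q_out_avg")
    if (k == 5) q_sys <- attr(st, "q_in_avg")
  }
  expect_equal(sum(st$Vol) - total0, flux, tolerance = 1e-12)
  # retrograde systolic inflow while the pulse squeezes the network
  expect_lt(q_sys, 0)
  expect_true(all(st$D > 2 * net$vessels$Bp & st$D < 2 * net$vessels$Ap))
})

test_that("cycle-integrated flow never increases with uniform IMP", {
  net <- small_network()
  Q <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
    wf <- make_waveform_fixture(depth_factor = d)
    run_network_standalone(net, wf, n_cycles = 6, n_sub = 5)$Q
  }, numeric(1))
  expect_true(all(diff(Q) < 0))
})

test_that("steady single-vessel flow is the self-consistent Poiseuille fixed
           point", {
  net <- single_vessel_network()
  v <- net$vessels
  bnd <- list(P_in = 100, P_out = 20, P_T = 0)
  st <- network_state(net, 60)
  for (k in 1:40) st <- advance_network(net, st, bnd, dt = 50,
                                        method = "bdf")
  q <- attr(st, "q_in_avg")
  R1 <- segment_resistance(st$D, v$L, net$stats$mu)
  expect_equal(q, (bnd$P_in - bnd$P_out) / (2 * R1), tolerance = 1e-6)
  mu_int <- 2.7e-9 * 1e6 / 133.322 * 1e3
  expect_equal(q, pi * (st$D * 1e-4)^4 * (bnd$P_in - bnd$P_out) /
                 (128 * mu_int * v$L), tolerance = 1e-6)
  # the converged mid-diameter sits at the mid-node pressure minus IMP
  P_mid <- (bnd$P_in + bnd$P_out) / 2
  expect_equal(diameter_to_pressure(st$D, v), P_mid, tolerance = 1e-6)
})

test_that("network edge-list round trip preserves the topology", {
  net <- small_network()
  path <- tempfile(fileext = ".csv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$vessels, net$vessels, tolerance = 1e-12)
  expect_identical(back$cpp$elim_order, net$cpp$elim_order)
  expect_identical(back$n_terminal, net$n_terminal)
  unlink(c(path, paste0(path, ".json")))
})
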