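make_bundle <- function(params, config, network, circ, ptrans = NULL) {
  geometry <- make_geometry(params$lv$V_cav0, params$lv$V_wall,
                            params$lv$n_shells)
  nets <- replicate(length(config$depths),
                    network_state(network, ptrans), simplify = FALSE)
  list(circ = circ, networks = nets, geometry = geometry,
       network = network, params = params)
}

test_that("an equalized, passive, unloaded bundle is a fixed point of the
           coupling step", {
  params <- default_params()
  params$lv$T_max <- 0
  p <- params$circulation
  config <- fast_config()
  net <- small_network()
  # all compartment pressures zero at every phase, LV at its unloaded volume,
  # vessels at zero transvascular pressure with zero boundary pressures
  circ <- circulation_state(p$V_LA0, params$lv$V_cav0, p$V_ap0, p$V_ad0,
                            p$V_ven0, t = 0)
  b <- make_bundle(params, config, net, circ, ptrans = 0)
  b2 <- step_coupled(b, config)
  expect_equal(unlist(b2$circ[1:5]), unlist(b$circ[1:5]), tolerance = 1e-14)
  expect_equal(b2$networks[[1]]$Vol, b$networks[[1]]$Vol, tolerance = 1e-14)
  expect_equal(b2$record$flows$q_ao, 0)
  expect_equal(b2$record$lv$P_LV, 0)
})

test_that("each coupling step conserves total blood volume to machine
           precision", {
  params <- default_params()
  config <- fast_config()
  net <- build_tree(config$n_bif, config$n_trif, config$network_seed,
                    params$network)
  circ <- with(params$initial,
               circulation_state(V_LA, V_LV, V_ap, V_ad, V_ven, t = 0))
  b <- make_bundle(params, config, net, circ)
  total <- function(b) sum(unlist(b$circ[1:5])) +
    sum(vapply(b$networks, function(n) sum(n$Vol), numeric(1)))
  t0 <- total(b)
  for (k in 1:30) {
    b <- step_coupled(b, config)
    expect_equal(total(b), t0, tolerance = 1e-12)
  }
  # the networks actually exchanged volume during those steps
  expect_gt(max(abs(b$record$q_cor_in)), 0)
})

test_that("the compiled cycle loop reproduces the R reference step for step", {
  params <- default_params()
  config <- fast_config()
  net <- build_tree(config$n_bif, config$n_trif, config$network_seed,
                    params$network)
  n_steps <- 50
  # compiled path
  res <- coroperf:::.run_one_cycle(
    params, config,
    make_geometry(params$lv$V_cav0, params$lv$V_wall, params$lv$n_shells),
    net, with(params$initial, c(V_LA, V_LV, V_ap, V_ad, V_ven)),
    matrix(rep(network_state(net)$Vol, 4), ncol = 4))
  # R reference path
  circ <- with(params$initial,
               circulation_state(V_LA, V_LV, V_ap, V_ad, V_ven, t = 0))
  b <- make_bundle(params, config, net, circ)
  PLV <- VLV <- qin1 <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    VLV[k] <- b$circ$V_LV
    b <- step_coupled(b, config)
    PLV[k] <- b$record$pressures$P_LV
    qin1[k] <- b$record$q_cor_in[1]
  }
  expect_equal(res$series[seq_len(n_steps), 3], PLV, tolerance = 1e-9)
  expect_equal(res$series[seq_len(n_steps), 8], VLV, tolerance = 1e-9)
  expect_equal(res$series[seq_len(n_steps), 17], qin1, tolerance = 1e-9)
})

test_that("closed-loop run reaches a periodic state and is idempotent at
           convergence", {
  res <- cached_baseline_run()
  expect_true(res$converged)
  expect_lte(res$n_cycles, 12)
  cc <- cycle_convergence(res)
  expect_equal(cc$n_cycles, res$n_cycles)
  # residuals of the last three cycles do not grow
  r <- cc$residuals[is.finite(cc$residuals)]
  expect_lt(r[length(r)], r[1])
  # continuing from the converged state changes nothing beyond tolerance
  p2 <- res$params
  p2$initial <- as.list(setNames(res$final_state$circulation,
                                 c("V_LA", "V_LV", "V_ap", "V_ad", "V_ven")))
  res2 <- suppressWarnings(run_closed_loop(p2, res$config,
                                           network = res$network))
  expect_equal(max(res2$series$V_LV), max(res$series$V_LV), tolerance = 5e-3)
  expect_equal(max(res2$series$P_LV), max(res$series$P_LV), tolerance = 5e-3)
})

test_that("removing the coronary branch reproduces the pure circulation
           loop (ablation oracle)", {
  res4 <- cached_baseline_run()
  cfg0 <- fast_config(n_networks = 0)
  res0 <- suppressWarnings(run_closed_loop(default_params(), cfg0))
  # coronary volumes are ~1e-3 ml against a 60 ml stroke volume, so global
  # hemodynamics must agree closely
  expect_equal(max(res0$series$V_LV), max(res4$series$V_LV),
               tolerance = 2e-3)
  expect_equal(max(res0$series$P_LV), max(res4$series$P_LV),
               tolerance = 2e-3)
  expect_false(any(grepl("q_cor", names(res0$series))))
})

test_that("degenerate convergence tolerance declares periodicity after two
           cycles", {
  cfg <- fast_config(convergence_tol = Inf, max_cycles = 6)
  res <- run_closed_loop(default_params(), cfg)
  expect_true(res$converged)
  expect_equal(res$n_cycles, 2L)
})

test_that("runs are bit-reproducible for identical seeds and configs", {
  cfg <- fast_config(max_cycles = 3, convergence_tol = 0)
  r1 <- suppressWarnings(run_closed_loop(default_params(), cfg))
  r2 <- suppressWarnings(run_closed_loop(default_params(), cfg))
  expect_identical(r1$series, r2$series)
  expect_identical(r1$shells$S_ff, r2$shells$S_ff)
})

test_that("time series are aligned on one grid with sensible markers", {
  res <- cached_baseline_run()
  s <- res$series
  expect_equal(s$t, seq(0, res$params$circulation$cycle_length - 1, by = 1))
  expect_true(all(s$q_ao >= 0) && all(s$q_mv >= 0))
  expect_equal(unname(res$markers["ED"]), which.max(s$V_LV))
  expect_equal(unname(res$markers["ES"]), which.min(s$V_LV))
  # IMP boundary identities on every recorded step
  expect_equal(s$imp_1, s$P_LV, tolerance = 1e-12)
  expect_equal(s$imp_4, rep(0, nrow(s)))
})
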