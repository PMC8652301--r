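# sweep and load-holding tests run on the reduced tree of fast_config()
# to keep single runs around a second

test_that("an identity sweep level reproduces the baseline summary", {
  cfg <- fast_config()
  net <- build_tree(cfg$n_bif, cfg$n_trif, cfg$network_seed,
                    default_params()$network)
  base <- cycle_summary(cached_baseline_run())
  sw <- suppressWarnings(run_sweep(
    sweep_spec("contractility", c(130, 150)), default_params(), cfg, net))
  expect_equal(sw$EF[1], base$EF, tolerance = 2e-3)
  expect_equal(sw$peak_P_LV[1], base$peak_P_LV, tolerance = 2e-3)
  expect_equal(sw$Q_endo[1], base$Q[1], tolerance = 5e-3)
  expect_true(all(sw$feasible))
  # contractility raises EF and peak pressure
  expect_gt(sw$EF[2], sw$EF[1])
  expect_gt(sw$peak_P_LV[2], sw$peak_P_LV[1])
})

test_that("hold_preload is a no-op at the target and EDP falls with the
           venous resting volume", {
  cfg <- fast_config()
  p <- default_params()
  net <- build_tree(cfg$n_bif, cfg$n_trif, cfg$network_seed, p$network)
  edp0 <- coroperf:::.run_edp(p, cfg, net)[["EDP"]]
  h <- hold_preload(edp0, p, cfg, net)
  expect_true(h$feasible)
  expect_equal(h$iterations, 0L)
  expect_equal(h$params$circulation$V_ven0, p$circulation$V_ven0)
  # monotonicity probe: larger resting volume lowers filling pressure
  p2 <- p; p2$circulation$V_ven0 <- p$circulation$V_ven0 + 150
  edp2 <- coroperf:::.run_edp(p2, cfg, net)[["EDP"]]
  expect_lt(edp2, edp0)
  # and the secant drives EDP to a shifted target within tolerance
  h2 <- hold_preload(edp0 - 1.5, p, cfg, net)
  expect_true(h2$feasible)
  expect_lte(abs(h2$EDP - (edp0 - 1.5)), 0.2)
})

test_that("hold_loads is an identity at current values and meets reachable
           targets", {
  cfg <- fast_config()
  p <- default_params()
  net <- build_tree(cfg$n_bif, cfg$n_trif, cfg$network_seed, p$network)
  m <- coroperf:::.run_edp(p, cfg, net)
  h <- hold_loads(c(EDP = m[["EDP"]], peakP = m[["peakP"]]), p, cfg, net)
  expect_true(h$feasible)
  expect_equal(h$iterations, 0L)
  # a modest afterload shift is reachable by the resistance secants
  h2 <- hold_loads(c(EDP = m[["EDP"]], peakP = m[["peakP"]] + 8),
                   p, cfg, net)
  expect_true(h2$feasible)
  expect_lte(abs(h2$achieved[["peakP"]] - (m[["peakP"]] + 8)), 2)
  expect_lte(abs(h2$achieved[["EDP"]] - m[["EDP"]]), 0.2)
})

test_that("waveform fixtures: depth scaling and periodic smoothness", {
  wf0 <- make_waveform_fixture(depth_factor = 0)
  expect_true(all(wf0$IMP == 0))
  wf1 <- make_waveform_fixture(depth_factor = 1, imp_peak = 150)
  expect_equal(max(wf1$IMP), 150, tolerance = 1e-4)
  expect_equal(wf1$P_in[1], wf1$P_in[nrow(wf1)], tolerance = 1e-6)
  path <- tempfile(fileext = ".csv")
  make_waveform_fixture(depth_factor = 0.5, path = path)
  on_disk <- read.csv(path)
  expect_named(on_disk, c("t_ms", "P_in_mmHg", "P_out_mmHg", "IMP_mmHg"))
  unlink(path)
  # an IMP pulse above perfusion pressure produces retrograde systolic
  # inflow on the fixture network
  net <- small_network()
  wf_hi <- make_waveform_fixture(depth_factor = 1, imp_peak = 200)
  out <- run_network_standalone(net, wf_hi, n_cycles = 4)
  sys_idx <- which(wf_hi$IMP > 20)
  expect_lt(min(out$q_in[sys_idx]), 0)
})

test_that("calibration accepts an already-calibrated baseline immediately
           and reports residuals under ten percent", {
  cfg <- fast_config(n_networks = 0)
  cal <- calibrate_baseline(params = default_params(), config = cfg,
                            tol = 0.05, budget = 5)
  expect_true(cal$converged)
  expect_equal(cal$evaluations, 1L)
  expect_true(all(cal$report$rel_error <= 0.10))
  expect_equal(cal$params$circulation$R_ad,
               default_params()$circulation$R_ad)
})

test_that("calibration improves a detuned starting point", {
  cfg <- fast_config(n_networks = 0, max_cycles = 10)
  p <- default_params()
  p$circulation$R_ad <- p$circulation$R_ad * 1.35
  p$circulation$V_ven0 <- p$circulation$V_ven0 + 120
  base_err <- suppressWarnings(
    calibrate_baseline(params = p, config = cfg, tol = 1e-9,
                       budget = 1))$worst_error
  cal <- suppressWarnings(
    calibrate_baseline(params = p, config = cfg, tol = 0.02, budget = 40))
  expect_lt(cal$worst_error, base_err)
})

test_that("configuration files round-trip the full parameter bundle", {
  p <- default_params()
  p$lv$T_max <- 117
  p$circulation$R_ad <- 700
  cfg <- simulation_config(max_cycles = 4, n_bif = 12, n_trif = 0)
  path <- tempfile(fileext = ".yaml")
  write_config(p, cfg, path)
  back <- read_config(path)
  expect_equal(back$params$lv$T_max, 117)
  expect_equal(back$params$circulation$R_ad, 700)
  expect_equal(back$config$n_bif, 12)
  expect_equal(back$params$initial$V_LV, p$initial$V_LV)
  unlink(path)
})

test_that("the command-line front end writes waveform and topology fixtures", {
  cli <- system.file("cli", "coroperf.R", package = "coroperf")
  expect_true(nzchar(cli))
  out <- file.path(tempdir(), "cli-fixtures")
  log <- suppressWarnings(
    system2("Rscript", c(cli, "make-fixtures", "--out", out, "--seed", "3"),
            stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(file.path(out, "waveform_d1.00.csv")))
  expect_true(file.exists(file.path(out, "fig_network_3vessel.csv")))
  net <- read_network(file.path(out, "fig_network_3vessel.csv"))
  expect_equal(net$n_vessels, 3L)
  unlink(out, recursive = TRUE)
})
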