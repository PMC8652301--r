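# Shared fixtures: all built in code, sized so that single tests stay fast.

# the three-vessel single-bifurcation network (one junction, two terminals)
fig2b_network <- function(seed = 7) build_tree(1, 0, seed = seed)

# a single straight vessel (no junctions)
single_vessel_network <- function(seed = 3) build_tree(0, 0, seed = seed)

# a small but non-trivial tree for solver tests
small_network <- function(seed = 11) build_tree(15, 1, seed = seed)

# closed-loop configuration with a reduced coronary tree, for tests that
# need full runs but not the full 400-vessel morphometry
fast_config <- function(...) {
  args <- modifyList(list(n_bif = 30, n_trif = 1, max_cycles = 12),
                     list(...))
  do.call(simulation_config, args)
}

# one cached baseline run (reduced tree) shared by postprocess/summary tests
baseline_run_cache <- new.env(parent = emptyenv())
cached_baseline_run <- function() {
  if (is.null(baseline_run_cache$res)) {
    baseline_run_cache$res <- suppressWarnings(
      run_closed_loop(default_params(), fast_config()))
  }
  baseline_run_cache$res
}

# uniform-pressure network state helper
state_at_ptrans <- function(net, P_trans) network_state(net, P_trans)
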