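#' Read / write a structured model configuration
#'
#' The configuration is a YAML file with sections `circulation`, `lv`,
#' `network`, `initial` and `simulation`, each holding the corresponding
#' constructor arguments ([circulation_params()], [lv_params()],
#' [network_params()], the initial volumes, [simulation_config()]).
#' Omitted fields fall back to the calibrated baseline defaults.
#'
#' @param path Path to the YAML file.
#' @return For `read_config`, a list with elements `params`
#'   (a [model_params()]) and `config` (a [simulation_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  take <- function(section, ctor) {
    args <- cfg[[section]]
    if (is.null(args)) ctor() else do.call(ctor, args)
  }
  circulation <- take("circulation", circulation_params)
  lv <- take("lv", lv_params)
  network <- take("network", network_params)
  initial <- default_params()$initial
  if (!is.null(cfg$initial)) initial <- modifyList(initial, cfg$initial)
  config <- take("simulation", simulation_config)
  list(params = model_params(circulation, lv, network, initial),
       config = config)
}

#' @rdname read_config
#' @param params A [model_params()] bundle.
#' @param config A [simulation_config()].
#' @export
write_config <- function(params, config, path) {
  yaml::write_yaml(list(
    circulation = unclass(params$circulation),
    lv = unclass(params$lv),
    network = unclass(params$network),
    initial = params$initial,
    simulation = unclass(config)
  ), path)
  invisible(path)
}
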