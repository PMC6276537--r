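# YAML configuration I/O. The shipped canonical file
# inst/extdata/default_config.yaml pins the calibrated defaults; changing it
# is a breaking change.

#' Path to the shipped canonical parameter file
#'
#' @return Path to `default_config.yaml` inside the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "spineLTP",
              mustWork = TRUE)
}

#' Read a model configuration from YAML
#'
#' The file may contain any subset of the sections `membrane`, `ampar`,
#' `nmdar`, `vgcc`, `calcium`, `cascade`, `opioid`, `stimulus`,
#' `simulation`; omitted fields fall back to the package defaults.
#'
#' @param path Path to a YAML file; defaults to the shipped canonical file.
#' @return List with components `params` ([spine_params()]), `condition`
#'   ([opioid_condition()]), `protocol` ([stimulus_protocol()]) and `config`
#'   ([sim_config()]).
#' @export
read_spine_config <- function(path = default_config_path()) {
  raw <- yaml::read_yaml(path)
  build <- function(ctor, section) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop(sprintf("unknown field(s) in section '%s': %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    do.call(ctor, args)
  }
  params <- spine_params(
    membrane = build(membrane_params, "membrane"),
    ampar = build(ampar_params, "ampar"),
    nmdar = build(nmdar_params, "nmdar"),
    vgcc = build(vgcc_params, "vgcc"),
    calcium = build(calcium_params, "calcium"),
    cascade = build(cascade_params, "cascade"))
  list(params = params,
       condition = build(opioid_condition, "opioid"),
       protocol = build(stimulus_protocol, "stimulus"),
       config = build(sim_config, "simulation"))
}

#' Write a model configuration to YAML
#'
#' @param path Output path.
#' @param params,condition,protocol,config Model inputs to serialize.
#' @return `path`, invisibly.
#' @export
write_spine_config <- function(path, params = spine_params(),
                               condition = opioid_condition(),
                               protocol = stimulus_protocol(),
                               config = sim_config()) {
  strip <- function(x) lapply(unclass(x), function(v)
    if (is.null(v)) NULL else unclass(v))
  out <- c(lapply(unclass(params), strip),
           list(opioid = strip(condition),
                stimulus = strip(protocol),
                simulation = strip(config)))
  yaml::write_yaml(out, path)
  invisible(path)
}
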