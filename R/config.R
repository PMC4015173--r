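#' Run configuration
#'
#' Bundles the switches that change identifier or analysis behaviour.  The
#' defaults reproduce the 0.02 behaviour: byte-wise group sorting,
#' duplicate detection on the full identifier string, and stereocentre
#' counting over both tetrahedral (`/t`) and double-bond (`/b`) layers.
#'
#' @param agent_field_patterns Regular expressions (case-insensitive)
#'   matched against RDfile data-field names; a field whose name matches
#'   carries an agent structure.  Vendor files disagree on the vocabulary,
#'   hence a configurable list.
#' @param sort_mode `"bytewise"` or `"major_then_minor"`; see
#'   [sort_group()].
#' @param stereo_mode `"t_and_b"` (default) counts tetrahedral and
#'   double-bond designations as stereocentres; `"t_only"` restricts to
#'   tetrahedral centres.
#' @param dedup_mode `"full"` compares complete identifier strings;
#'   `"core"` ignores the agent group and the direction layer.
#' @param log_level One of `"quiet"`, `"info"`, `"debug"`.
#' @return A list of class `rinchi_config`.
#' @export
rinchi_config <- function(agent_field_patterns = c("catalyst", "solvent",
                                                   "reagent", "agent"),
                          sort_mode = c("bytewise", "major_then_minor"),
                          stereo_mode = c("t_and_b", "t_only"),
                          dedup_mode = c("full", "core"),
                          log_level = c("info", "quiet", "debug")) {
  structure(
    list(agent_field_patterns = agent_field_patterns,
         sort_mode = match.arg(sort_mode),
         stereo_mode = match.arg(stereo_mode),
         dedup_mode = match.arg(dedup_mode),
         log_level = match.arg(log_level)),
    class = "rinchi_config"
  )
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `rinchi_config`.
#' @export
read_rinchi_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(rinchi_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop_validation(sprintf("unknown config key(s): %s",
                            paste(bad, collapse = ", ")),
                    rule = "config")
  do.call(rinchi_config, vals)
}
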