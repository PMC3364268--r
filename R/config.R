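#' Read a pipeline run configuration
#'
#' Loads a YAML run configuration and materializes it into the objects the
#' pipeline consumes. Recognized top-level sections (all optional; omitted
#' values fall back to package defaults): `hydro` (fields of [hydro_config()],
#' with `pulse_windows` as a list of `{pulse_id, start, end}`), `community`
#' (scalar fields of [community_config()]), `alpha`, `error_rule`,
#' `included_species`, `seed`, `out_dir`, and `files` (paths to
#' `water_levels`, `samples`, `catch`, `wetdry`, `pellets` CSVs for runs on
#' existing data instead of simulation).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `hydro`, `community`, `alpha`, `error_rule`,
#'   `included_species`, `seed`, `out_dir`, `files`.
#' @export
read_run_config <- function(path) {
  np_assert(file.exists(path), "config file not found: ", path)
  raw <- yaml::read_yaml(path)
  hy <- raw$hydro %||% list()
  if (!is.null(hy$pulse_windows)) {
    pw <- purrr::map_dfr(hy$pulse_windows, as_tibble)
    hy$pulse_windows <- pulse_windows(pw$pulse_id, pw$start, pw$end)
  }
  hydro <- do.call(hydro_config, hy)
  co <- raw$community %||% list()
  community <- do.call(community_config, co)
  list(hydro = hydro, community = community,
       alpha = raw$alpha %||% 0.05,
       error_rule = raw$error_rule %||% "quadrature",
       included_species = raw$included_species %||% dominant_species(),
       seed = raw$seed,
       out_dir = raw$out_dir %||% "nektonpulse-run",
       files = raw$files)
}
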