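#' Summarize environmental conditions per pulse
#'
#' Mean, standard error, minimum and maximum of salinity, dissolved oxygen,
#' water temperature and turbidity over each pulse's samples.
#'
#' @param samples Sample table with `pulse_id` and the four environmental
#'   columns (`salinity_psu`, `do_ppm`, `temp_c`, `turbidity_ntu`).
#' @return A tibble with `pulse_id`, `variable`, `mean`, `se`, `min`, `max`, `n`.
#' @export
summarize_environment <- function(samples) {
  vars <- c("salinity_psu", "do_ppm", "temp_c", "turbidity_ntu")
  require_columns(samples, c("pulse_id", vars), "samples")
  samples |>
    tidyr::pivot_longer(all_of(vars), names_to = "variable", values_to = "value") |>
    group_by(pulse_id, variable) |>
    summarise(mean = mean(value), se = se_mean(value),
              min = min(value), max = max(value), n = n(), .groups = "drop") |>
    mutate(variable = factor(variable, levels = vars)) |>
    arrange(pulse_id, variable) |>
    mutate(variable = as.character(variable))
}

fmt_env <- function(mean, se, min, max) {
  sprintf("%.1f±%.2f (%.1f−%.1f)", mean, se, min, max)
}

md_table <- function(df) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) format(x, trim = TRUE) else x)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  if (nrow(df) == 0) return(c(header, rule))
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, rows)
}

#' Render a run report
#'
#' Writes a markdown report of one analyzed study: run configuration echo
#' (seed, config hash, error rule), per-stage record counts, environmental
#' summary, allometric fits and energy densities, per-species standing stock
#' per pulse, subsidized-sample shares, and the subsidy summary table, all
#' rounded to reporting precision (values 1 dp, environmental SEs 2 dp).
#' Output is deterministic given the study object.
#'
#' @param study A `pulse_study` from [analyze_pulse_study()] or
#'   [run_pulse_study()].
#' @param path Output file path (default `report.md` in the working directory).
#' @return `path`, invisibly.
#' @export
render_report <- function(study, path = "report.md") {
  np_assert(inherits(study, "pulse_study"), "study must be a pulse_study object")
  s <- study
  L <- c(
    "# Flood-pulse nekton subsidy report", "",
    paste0("- tool: nektonpulse ", as.character(packageVersion("nektonpulse"))),
    paste0("- seed: ", s$seed %||% "none"),
    paste0("- config hash: ", s$config_hash),
    paste0("- error rule: ", attr(s$subsidy, "error_rule")),
    paste0("- alpha (intercept gate): ", s$settings$alpha), "",
    "## Record counts", "",
    paste0("- samples: ", nrow(s$inputs$samples)),
    paste0("- catch rows: ", nrow(s$inputs$catch)),
    paste0("- wet/dry individuals: ", nrow(s$inputs$wetdry)),
    paste0("- pellets: ", nrow(s$inputs$pellets)),
    paste0("- classified samples: ", nrow(s$classification)),
    paste0("- dry-weight predictions floored at 0: ", s$n_floored), "")

  if (nrow(s$inputs$samples) > 0) {
    env <- s$env_summary |>
      mutate(value = fmt_env(mean, se, min, max)) |>
      select("pulse_id", "variable", "value", "n") |>
      tidyr::pivot_wider(names_from = "pulse_id", values_from = c("value", "n"))
    L <- c(L, "## Environmental conditions", "", md_table(env), "")
  } else {
    L <- c(L, "## Environmental conditions", "", "No samples collected.", "")
  }

  allo <- s$models |>
    mutate(across(c(slope, intercept), ~ round(.x, 6)),
           r_squared = round(.data$r_squared, 2),
           water_content = sprintf("%.2f (%.3f)", .data$water_content_mean,
                                   .data$water_content_se)) |>
    select("species", "n", "slope", "intercept", "intercept_dropped",
           "r_squared", "water_content")
  energ <- s$energies |>
    mutate(energy = sprintf("%.2f (%.2f)", mean_energy, se)) |>
    select("species", "n_pellets", "energy")
  L <- c(L, "## Wet:dry allometry", "", md_table(allo), "",
         "## Energy density (cal per g DW)", "", md_table(energ), "")

  if (nrow(s$species_stock) > 0) {
    st <- s$species_stock |>
      mutate(density = sprintf("%.1f±%.1f", .data$density_mean, .data$density_se),
             energy = sprintf("%.1f±%.1f", .data$energy_mean, .data$energy_se)) |>
      select("pulse_id", "species", "density", "energy")
    L <- c(L, "## Standing stock by species and pulse", "", md_table(st), "")
  }

  sh <- s$subsidized_share |>
    mutate(share_pct = sprintf("%.0f%% (n = %d of %d)",
                               100 * proportion, n_subsidized, n_total)) |>
    select("pulse_id", "share_pct")
  L <- c(L, "## Subsidized-sample share", "", md_table(sh), "")

  sub <- s$subsidy |>
    mutate(inflow = sprintf("%.1f (%.1f)", inflow_mean, inflow_se),
           pct = sprintf("%.1f (%.1f)", proportion_pct, proportion_se_pct),
           subsidy_fmt = sprintf("%.1f (%.1f)", subsidy, subsidy_se)) |>
    select(metric, inflow, pct, subsidy = "subsidy_fmt")
  L <- c(L, "## Subsidy summary", "", md_table(sub), "")

  writeLines(L, path)
  invisible(path)
}

output_header <- function(study) {
  paste0("# nektonpulse ", as.character(packageVersion("nektonpulse")),
         "; seed: ", study$seed %||% "none",
         "; config_hash: ", study$config_hash)
}

write_csv_with_header <- function(df, path, header) {
  writeLines(header, path)
  # timestamps as ISO-8601 UTC for portability
  df[] <- lapply(df, function(x)
    if (inherits(x, "POSIXct")) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC") else x)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  path
}

#' Write all pipeline outputs to a directory
#'
#' Writes the input tables, classification, per-sample metrics, allometry,
#' energy densities and the subsidy table as CSV (each with a header comment
#' carrying tool version, seed and config hash), the markdown report, and a
#' `run.log` with per-stage record counts.
#'
#' @param study A `pulse_study` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_pipeline_outputs <- function(study, dir) {
  np_assert(inherits(study, "pulse_study"), "study must be a pulse_study object")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hd <- output_header(study)
  files <- c(
    write_csv_with_header(study$inputs$water_levels, file.path(dir, "water_levels.csv"), hd),
    write_csv_with_header(study$inputs$samples, file.path(dir, "samples.csv"), hd),
    write_csv_with_header(study$inputs$catch, file.path(dir, "catch.csv"), hd),
    write_csv_with_header(study$inputs$wetdry, file.path(dir, "wetdry.csv"), hd),
    write_csv_with_header(study$inputs$pellets, file.path(dir, "pellets.csv"), hd),
    write_csv_with_header(as_tibble(study$models), file.path(dir, "allometry.csv"), hd),
    write_csv_with_header(study$energies, file.path(dir, "energetics.csv"), hd),
    write_csv_with_header(study$metrics, file.path(dir, "sample_metrics.csv"), hd),
    write_csv_with_header(study$classification, file.path(dir, "classification.csv"), hd),
    write_csv_with_header(as_tibble(study$subsidy), file.path(dir, "subsidy.csv"), hd))
  if (!is.null(study$inputs$truth) && nrow(study$inputs$truth) > 0) {
    files <- c(files, write_csv_with_header(study$inputs$truth,
                                            file.path(dir, "truth.csv"), hd))
  }
  files <- c(files, render_report(study, file.path(dir, "report.md")))
  log <- c(hd,
           paste0("samples read/classified: ", nrow(study$inputs$samples),
                  "/", nrow(study$classification)),
           paste0("catch rows: ", nrow(study$inputs$catch)),
           paste0("wetdry individuals: ", nrow(study$inputs$wetdry)),
           paste0("pellets: ", nrow(study$inputs$pellets)),
           paste0("dry-weight predictions floored: ", study$n_floored),
           paste0("files written: ", length(files) + 1))
  writeLines(log, file.path(dir, "run.log"))
  invisible(c(files, file.path(dir, "run.log")))
}

read_np_csv <- function(path, col_types) {
  readr::read_csv(path, comment = "#", col_types = col_types, progress = FALSE)
}

#' Read pipeline CSV files
#'
#' Readers for the pipeline's on-disk schemas (comment headers starting with
#' `#` are skipped; timestamps are parsed as UTC).
#'
#' @param path CSV file path.
#' @return A tibble in the corresponding schema.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_water_levels <- function(path) {
  read_np_csv(path, readr::cols(area = "c", timestamp = readr::col_datetime(),
                                stage_mm = "d", marsh_elev_mm = "d"))
}

#' @rdname read_tables
#' @export
read_samples <- function(path) {
  read_np_csv(path, readr::cols(sample_id = "c", area = "c",
                                timestamp = readr::col_datetime(),
                                pulse_id = "c", .default = "d"))
}

#' @rdname read_tables
#' @export
read_catch <- function(path) {
  read_np_csv(path, readr::cols(sample_id = "c", species = "c", count = "i",
                                wet_weight_g = "d"))
}

#' @rdname read_tables
#' @export
read_wetdry <- function(path) {
  read_np_csv(path, readr::cols(species = "c", individual_id = "c",
                                wet_g = "d", dry_g = "d"))
}

#' @rdname read_tables
#' @export
read_pellets <- function(path) {
  read_np_csv(path, readr::cols(species = "c", replicate = "i", cal_per_g_dw = "d"))
}
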