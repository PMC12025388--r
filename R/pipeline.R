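#' Build a pipeline run configuration
#'
#' @param datasets list of dataset entries; each is a list with paths
#'   `ensemble` (multi-frame XYZ), `fragments` (fragment-spec YAML),
#'   `template` (template YAML with ligand id, substrate kind,
#'   coordination mode, 0-based `chiral_reference` and `anchor_indices`,
#'   `expected_sign`), and optionally `properties` (per-conformer table)
#'   and `baseline` (single XYZ with energy). A directory written by
#'   [write_synthetic_dataset()] is one such entry.
#' @param rmsd_tol,energy_tol deduplication tolerances (angstrom,
#'   kJ/mol).
#' @param window,window_unit energy-window filter (default 6 kcal/mol).
#' @param temperature Boltzmann temperature, kelvin.
#' @param sphere_radius,radii_scale,grid_spacing buried-volume
#'   parameters.
#' @param output_dir run directory for all outputs.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(datasets, rmsd_tol = 0.25, energy_tol = 1.0,
                       window = 6, window_unit = "kcal/mol",
                       temperature = 289, sphere_radius = 3.5,
                       radii_scale = 1.17, grid_spacing = 0.05,
                       output_dir = "rhconf-run", seed = 1L) {
  stopifnot(rmsd_tol > 0, energy_tol > 0, window > 0, temperature > 0,
            sphere_radius > 0, grid_spacing > 0)
  cfg <- list(datasets = datasets, rmsd_tol = rmsd_tol,
              energy_tol = energy_tol, window = window,
              window_unit = window_unit, temperature = temperature,
              sphere_radius = sphere_radius, radii_scale = radii_scale,
              grid_spacing = grid_spacing, output_dir = output_dir,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read/write a run configuration as YAML
#' @param path YAML file path.
#' @param config a `run_config`.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Point a dataset entry at a directory of standard file names
#' @param dir directory containing `ensemble.xyz`, `fragments.yml`,
#'   `template.yml` and optionally `properties.tsv`, `baseline.xyz`.
#' @return a dataset entry list for [run_config()].
#' @export
dataset_entry <- function(dir) {
  entry <- list(ensemble = file.path(dir, "ensemble.xyz"),
                fragments = file.path(dir, "fragments.yml"),
                template = file.path(dir, "template.yml"))
  p <- file.path(dir, "properties.tsv")
  if (file.exists(p)) entry$properties <- p
  b <- file.path(dir, "baseline.xyz")
  if (file.exists(b)) entry$baseline <- b
  entry
}

load_dataset <- function(entry) {
  spec <- read_fragment_spec(entry$fragments)
  tpl <- yaml::read_yaml(entry$template)
  baseline <- if (!is.null(entry$baseline)) {
    read_xyz(entry$baseline, dialect = "crest")
  } else NULL
  ens <- read_ensemble_xyz(entry$ensemble, dialect = "crest",
                           ligand_id = tpl$ligand_id,
                           substrate_kind = tpl$substrate_kind,
                           coordination_mode = tpl$coordination_mode,
                           baseline = baseline, stage = "dft")
  template <- complex_template(tpl$ligand_id, tpl$substrate_kind,
                               tpl$coordination_mode,
                               chiral_reference = tpl$chiral_reference + 1L)
  list(ensemble = ens, spec = spec, template = template,
       anchor_indices = if (!is.null(tpl$anchor_indices))
         tpl$anchor_indices + 1L else NULL,
       expected_sign = if (!is.null(tpl$expected_sign))
         tpl$expected_sign else 1,
       properties = entry$properties)
}

#' Run the full conformer-analysis pipeline
#'
#' For every configured dataset: retention filters (chirality,
#' coordination mode), energy-window selection, deduplication,
#' fragment-resolved RMSD profile, descriptor table (steric plus, when a
#' property table is present, electronic), then one pooled Boltzmann
#' group summary across all datasets (major modes pooled, minor modes
#' pooled, precatalyst ensembles their own group). All outputs are
#' delimited text under `config$output_dir`, plus a JSON run manifest
#' recording the configuration, seed and package version.
#'
#' @param config a `run_config`.
#' @return list with `summaries` (per-dataset one-row summaries,
#'   rbind-ed), `profiles`, `descriptors`, `boltzmann` (pooled group
#'   summary) and `manifest_path`; all tables also on disk.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list(); profiles <- list(); desc_all <- list()
  desc_groups <- character(0); desc_energies <- numeric(0)
  for (di in seq_along(config$datasets)) {
    entry <- config$datasets[[di]]
    ds <- tryCatch(load_dataset(entry), error = function(e) {
      stop(sprintf("stage load (dataset %d, %s): %s", di,
                   entry$ensemble, conditionMessage(e)), call. = FALSE)
    })
    ens <- ds$ensemble
    tag <- paste(ens$ligand_id, ens$substrate_kind, ens$coordination_mode,
                 sep = "-")
    n_raw <- length(ens)

    ret <- tryCatch(
      apply_retention_filters(ens, ds$template, ds$spec,
                              anchor_indices = ds$anchor_indices,
                              expected_sign = ds$expected_sign),
      error = function(e) stop(sprintf("stage filter (%s): %s", tag,
                                       conditionMessage(e)), call. = FALSE))
    ens2 <- energy_window_filter(ret$ensemble, config$window,
                                 config$window_unit)
    dd <- tryCatch(
      deduplicate(ens2, config$rmsd_tol, config$energy_tol),
      error = function(e) stop(sprintf("stage dedup (%s): %s", tag,
                                       conditionMessage(e)), call. = FALSE))
    prof <- rmsd_profile(dd, ds$spec)
    if (is.null(ds$properties)) {
      stop(sprintf(
        "stage descriptors (%s): property table required but not configured",
        tag), call. = FALSE)
    }
    ptab <- ingest_property_table(ds$properties, ens)
    keep <- attr(dd, "representatives")
    # representatives index the post-window ensemble; map back to raw members
    raw_after_ret <- which(seq_len(n_raw) %in%
                             setdiff(seq_len(n_raw), ret$log$member))
    e_kj_ret <- ensemble_energies(ret$ensemble, "kJ/mol")
    win_keep <- which((e_kj_ret - min(e_kj_ret)) <=
                        convert_energy(config$window, config$window_unit,
                                       "kJ/mol") + 1e-12)
    raw_idx <- raw_after_ret[win_keep][keep]
    ptab_dd <- ptab[raw_idx, , drop = FALSE]
    ptab_dd$member <- seq_len(nrow(ptab_dd))
    dtab <- descriptor_table(dd, ds$spec, ptab_dd,
                             sphere_radius = config$sphere_radius,
                             radii_scale = config$radii_scale,
                             grid_spacing = config$grid_spacing)
    summ <- ensemble_summary(ens, dd, spec = ds$spec,
                             n_removed_chirality =
                               sum(ret$log$reason == "chirality"),
                             n_removed_coordination =
                               sum(ret$log$reason == "coordination"))
    summaries[[di]] <- summ
    prof$dataset <- tag
    profiles[[di]] <- prof
    dtab$dataset <- tag
    desc_all[[di]] <- dtab
    desc_groups <- c(desc_groups,
                     rep(pool_modes(ens$coordination_mode), nrow(dtab)))
    desc_energies <- c(desc_energies, ensemble_energies(dd, "hartree"))

    utils::write.table(prof, file.path(config$output_dir,
                                       paste0(tag, "_rmsd_profile.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dtab, file.path(config$output_dir,
                                       paste0(tag, "_descriptors.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summaries <- do.call(rbind, summaries)
  descriptors <- do.call(rbind, desc_all)
  bsum <- group_summary(descriptors[setdiff(names(descriptors), "dataset")],
                        desc_energies, desc_groups,
                        unit = "hartree", temperature = config$temperature)
  utils::write.table(summaries, file.path(config$output_dir,
                                          "ensemble_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bsum, file.path(config$output_dir,
                                     "boltzmann_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  cfg_plain <- unclass(config)
  jsonlite::write_json(list(
    package = "rhconf",
    version = as.character(utils::packageVersion("rhconf")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = digest_config(cfg_plain)
  ), manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(summaries = summaries, profiles = do.call(rbind, profiles),
       descriptors = descriptors, boltzmann = bsum,
       manifest_path = manifest_path)
}

digest_config <- function(cfg) {
  # stable content hash without extra dependencies
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}
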