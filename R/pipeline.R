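# Configuration and the staged pipeline: build -> [external MD] -> score ->
# compare, plus the fully synthetic end-to-end mode. Every run writes a
# manifest naming inputs, the config (and its hash), seeds and outputs, and
# logs every threshold actually applied so reports are self-describing.

#' Pipeline configuration with documented defaults
#'
#' Collects every stage's tunable parameters in one nested list. Unknown
#' keys are rejected. Values not supplied keep the protocol defaults:
#' shell thickness 0.415 nm, contact cutoff 0.315 nm, neighborhood cutoff
#' 0.3 nm, significance threshold ±0.2 PARCH units, 300-800 K ramp at
#' 1 K/10 ps, 5%/5% scoring windows, 5 replicates, seed 1.
#'
#' @param config Optional named list (e.g. parsed from YAML via
#'   [read_config()]) overriding defaults.
#' @return A validated `parch_config` nested list.
#' @export
parch_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    shell = list(d_shell = 0.415, restraint_k = 1e4, d_ion = 3, d_b = 3,
                 min_tol = 1e3),
    schedule = list(t_start = 300, t_end = 800, rate = 0.1,
                    frame_interval = 10),
    contacts = list(d_water = 0.315, probe_element = "O"),
    scoring = list(w_init = 0.05, w_final = 0.05, time_offset = 0),
    compare = list(neighbor_cutoff = 0.3, delta_threshold = 0.2,
                   cumulative_mode = "filtered", alpha = 0.05),
    synthetic = list(n_residues = 6,
                     hydropathy = c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2),
                     waters_per_residue = 50, displacement_radius = 1.5,
                     n_frames = 101, n_replicates = 5,
                     perturb_index = 3, delta_h = 0.4,
                     escape_model = "persistent",
                     persistence_sampling = "stratified")
  )
  merged <- merge_config(defaults, config, path = "")
  class(merged) <- "parch_config"
  merged
}

merge_config <- function(defaults, override, path) {
  if (length(override) == 0) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ",
                 paste(paste0(path, unknown), collapse = ", ")))
  }
  for (k in names(override)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(override[[k]])) {
      merge_config(defaults[[k]], override[[k]], paste0(path, k, "."))
    } else {
      override[[k]]
    }
  }
  defaults
}

#' @rdname parch_config
#' @param path YAML config file.
#' @export
read_config <- function(path) {
  parch_config(yaml::read_yaml(path))
}

config_objects <- function(config) {
  list(
    shell = do.call(shell_params, config$shell),
    schedule = do.call(annealing_schedule, config$schedule),
    contacts = do.call(contact_params, config$contacts),
    compare = do.call(compare_params, config$compare)
  )
}

log_info <- function(...) inform(paste0("[parchr] ", sprintf(...)))

log_thresholds <- function(config) {
  log_info("thresholds: d_shell = %g nm, d_water = %g nm, neighbor_cutoff = %g nm, delta_threshold = +/-%g PV",
           config$shell$d_shell, config$contacts$d_water,
           config$compare$neighbor_cutoff, config$compare$delta_threshold)
}

write_manifest <- function(outdir, mode, config, inputs, outputs) {
  manifest <- list(
    tool = "parchr",
    mode = mode,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    config_hash = hash(unclass(config)),
    thresholds = list(
      d_shell_nm = config$shell$d_shell,
      d_water_nm = config$contacts$d_water,
      neighbor_cutoff_nm = config$compare$neighbor_cutoff,
      delta_threshold_pv = config$compare$delta_threshold
    ),
    inputs = inputs,
    outputs = outputs
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

delta_report_list <- function(delta, site_label) {
  list(
    site = c(as.list(delta$site), label = site_label),
    site_delta = delta$site_delta,
    site_class = delta$site_class,
    cumulative_delta = delta$cumulative_delta,
    cumulative_mode = delta$params$cumulative_mode,
    neighbors = delta$neighbors,
    wilcoxon = unclass(delta$wilcoxon)
  )
}

#' Run a pipeline stage
#'
#' Modes: `"build"` carves the water shell from a pre-solvated snapshot,
#' places counter-ions and emits annealing inputs; `"simulate"` writes a
#' synthetic reference system, replicate trajectories and ground truth;
#' `"score"` converts replicate trajectories to a PARCH profile TSV;
#' `"compare"` produces per-site delta reports (JSON + bar-chart TSV);
#' `"all-synthetic"` chains simulate -> score -> compare fully in-memory on
#' the synthetic generator and writes the combined report.
#'
#' @param config A [parch_config()] (or list coercible to one).
#' @param mode One of `"build"`, `"simulate"`, `"score"`, `"compare"`,
#'   `"all-synthetic"`.
#' @param outdir Output directory.
#' @param structure_file,solvated_file,traj_files Stage inputs (file
#'   paths) as required per mode.
#' @param unmod_profile_file,mod_profile_file,mod_structure_file Compare
#'   stage inputs.
#' @param sites_file YAML list of `{chain, resno}` entries (modified-file
#'   numbering), defaulting to all recognized PTM sites of the modified
#'   structure.
#' @param quiet Suppress INFO logging.
#' @return A list of stage results (invisibly), with `manifest` naming all
#'   written files.
#' @export
run_pipeline <- function(config = parch_config(),
                         mode = c("all-synthetic", "build", "simulate",
                                  "score", "compare"),
                         outdir = ".",
                         structure_file = NULL, solvated_file = NULL,
                         traj_files = NULL, unmod_profile_file = NULL,
                         mod_profile_file = NULL, mod_structure_file = NULL,
                         sites_file = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(config, "parch_config")) config <- parch_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  obj <- config_objects(config)
  if (!quiet) {
    log_info("mode = %s, seed = %d, config hash = %s", mode, config$seed,
             hash(unclass(config)))
    log_thresholds(config)
  }
  res <- switch(mode,
    "build" = pipeline_build(config, obj, outdir, solvated_file),
    "simulate" = pipeline_simulate(config, obj, outdir),
    "score" = pipeline_score(config, obj, outdir, structure_file,
                             traj_files),
    "compare" = pipeline_compare(config, obj, outdir, structure_file,
                                 mod_structure_file, unmod_profile_file,
                                 mod_profile_file, sites_file),
    "all-synthetic" = pipeline_all_synthetic(config, obj, outdir)
  )
  res$manifest <- write_manifest(outdir, mode, config,
                                 inputs = res$inputs %||% list(),
                                 outputs = res$outputs %||% list())
  invisible(res)
}

pipeline_build <- function(config, obj, outdir, solvated_file) {
  if (is.null(solvated_file)) {
    abort("`build` mode requires `solvated_file`")
  }
  solvated <- read_structure(solvated_file)
  shell <- carve_water_shell(solvated, obj$shell) |>
    place_counterions(params = obj$shell, seed = config$seed)
  manifest <- emit_annealing_inputs(shell, obj$schedule, outdir,
                                    replicates = config$synthetic$n_replicates,
                                    base_seed = config$seed)
  list(shell = shell, files = manifest,
       inputs = list(solvated = solvated_file),
       outputs = as.list(setNames(manifest$file, manifest$kind)))
}

synthetic_spec_from_config <- function(config, perturbed = FALSE) {
  syn <- config$synthetic
  spec <- synthetic_spec(
    hydropathy = syn$hydropathy, waters_per_residue = syn$waters_per_residue,
    displacement_radius = syn$displacement_radius, seed = config$seed,
    schedule = do.call(annealing_schedule, config$schedule),
    escape_model = syn$escape_model,
    persistence_sampling = syn$persistence_sampling
  )
  if (perturbed) spec <- perturb_site(spec, syn$perturb_index, syn$delta_h)
  spec
}

pipeline_simulate <- function(config, obj, outdir) {
  spec <- synthetic_spec_from_config(config)
  sys <- generate_reference_system(spec)
  struct_file <- file.path(outdir, "synthetic_system.pdb")
  write_structure(sys$structure, struct_file)
  traj_files <- character(config$synthetic$n_replicates)
  for (k in seq_len(config$synthetic$n_replicates)) {
    sysk <- generate_reference_system(spec, replicate = k)
    traj <- generate_annealing_trajectory(sysk, spec$schedule,
                                          config$synthetic$n_frames)
    traj_files[k] <- file.path(outdir, sprintf("synthetic_rep%d.pdb", k))
    write_trajectory(traj, sysk$structure, traj_files[k])
  }
  truth_file <- file.path(outdir, "ground_truth.tsv")
  readr::write_tsv(sys$truth$residues, truth_file)
  list(spec = spec, structure = sys$structure,
       inputs = list(),
       outputs = list(structure = struct_file, trajectories = traj_files,
                      ground_truth = truth_file))
}

pipeline_score <- function(config, obj, outdir, structure_file, traj_files) {
  if (is.null(structure_file) || is.null(traj_files)) {
    abort("`score` mode requires `structure_file` and `traj_files`")
  }
  st <- read_structure(structure_file)
  trajs <- lapply(traj_files, read_trajectory, structure = st,
                  frame_interval = config$schedule$frame_interval)
  profile <- score_trajectories(
    st, trajs, obj$schedule, obj$contacts,
    retention_ratio_scorer(config$scoring$w_init, config$scoring$w_final),
    time_offset = config$scoring$time_offset
  )
  out <- file.path(outdir, "parch_profile.tsv")
  write_parch_profile(profile, out)
  list(profile = profile,
       inputs = list(structure = structure_file, trajectories = traj_files),
       outputs = list(profile = out))
}

read_sites <- function(sites_file, mod_structure) {
  if (!is.null(sites_file)) {
    raw <- yaml::read_yaml(sites_file)
    if (!is.null(raw$sites)) raw <- raw$sites
    bind_rows(lapply(raw, function(s) {
      tibble(chain = as.character(s$chain %||% "A"),
             resno = as.integer(s$resno))
    }))
  } else {
    identify_ptm_sites(mod_structure)[, c("chain", "resno")]
  }
}

pipeline_compare <- function(config, obj, outdir, structure_file,
                             mod_structure_file, unmod_profile_file,
                             mod_profile_file, sites_file) {
  if (is.null(structure_file) || is.null(mod_structure_file) ||
      is.null(unmod_profile_file) || is.null(mod_profile_file)) {
    abort(paste0("`compare` mode requires `structure_file`, ",
                 "`mod_structure_file`, `unmod_profile_file` and ",
                 "`mod_profile_file`"))
  }
  unmod <- read_structure(structure_file)
  mod <- read_structure(mod_structure_file)
  pu <- read_parch_profile(unmod_profile_file)
  pm <- read_parch_profile(mod_profile_file)
  mapping <- map_residues(unmod, mod)
  sites <- read_sites(sites_file, mod)
  # sites are keyed in modified-structure numbering; map back to unmodified
  sites_u <- mapping |>
    inner_join(sites, by = c(chain_mod = "chain", resno_mod = "resno")) |>
    select(chain = "chain_unmod", resno = "resno_unmod")
  if (nrow(sites_u) == 0) abort("no comparable PTM sites found")
  deltas <- lapply(seq_len(nrow(sites_u)), function(i) {
    compute_delta(pu, pm, mapping,
                  site = sites_u[i, ], structure = unmod,
                  params = obj$compare)
  })
  names(deltas) <- res_key(sites_u$chain, sites_u$resno)
  report_file <- file.path(outdir, "delta_report.json")
  jsonlite::write_json(
    imap(deltas, function(d, nm) delta_report_list(d, nm)),
    report_file, auto_unbox = TRUE, pretty = TRUE, digits = NA,
    dataframe = "rows"
  )
  bars <- bind_rows(imap(deltas, function(d, nm) {
    tibble(site = nm, resname_unmod = d$site$resname_unmod,
           resname_mod = d$site$resname_mod,
           site_delta = d$site_delta, site_class = d$site_class,
           cumulative_delta = d$cumulative_delta,
           n_neighbors = nrow(d$neighbors),
           wilcoxon_p = d$wilcoxon$p_value,
           verdict = d$wilcoxon$verdict)
  }))
  bars_file <- file.path(outdir, "delta_bars.tsv")
  readr::write_tsv(bars, bars_file)
  list(deltas = deltas, bars = bars,
       inputs = list(structure = structure_file,
                     mod_structure = mod_structure_file,
                     unmod_profile = unmod_profile_file,
                     mod_profile = mod_profile_file,
                     sites = sites_file),
       outputs = list(report = report_file, bars = bars_file))
}

pipeline_all_synthetic <- function(config, obj, outdir) {
  syn <- config$synthetic
  spec_u <- synthetic_spec_from_config(config)
  spec_m <- synthetic_spec_from_config(config, perturbed = TRUE)
  scorer <- retention_ratio_scorer(config$scoring$w_init,
                                   config$scoring$w_final)
  run_u <- simulate_parch_experiment(spec_u, syn$n_replicates, syn$n_frames,
                                     obj$contacts, scorer)
  run_m <- simulate_parch_experiment(spec_m, syn$n_replicates, syn$n_frames,
                                     obj$contacts, scorer)
  mapping <- map_residues(run_u$structure, run_m$structure)
  site <- list(chain = "A", resno = syn$perturb_index)
  delta <- compute_delta(run_u$profile, run_m$profile, mapping, site,
                         structure = run_u$structure, params = obj$compare)
  prof_u_file <- file.path(outdir, "parch_unmod.tsv")
  prof_m_file <- file.path(outdir, "parch_mod.tsv")
  write_parch_profile(run_u$profile, prof_u_file)
  write_parch_profile(run_m$profile, prof_m_file)
  report_file <- file.path(outdir, "synthetic_report.json")
  jsonlite::write_json(
    list(
      ground_truth = run_u$truth$residues,
      perturbation = list(residue_index = syn$perturb_index,
                          delta_h = syn$delta_h,
                          expected_site_delta = 10 * syn$delta_h),
      parch_unmod = as_tibble(run_u$profile),
      parch_mod = as_tibble(run_m$profile),
      delta_report = delta_report_list(
        delta, res_key(site$chain, site$resno))
    ),
    report_file, auto_unbox = TRUE, pretty = TRUE, digits = NA,
    dataframe = "rows"
  )
  list(profile_unmod = run_u$profile, profile_mod = run_m$profile,
       delta = delta, truth = run_u$truth,
       inputs = list(),
       outputs = list(parch_unmod = prof_u_file, parch_mod = prof_m_file,
                      report = report_file))
}
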