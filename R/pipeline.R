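## Config-driven pipelines chaining the stages into the three analyses:
## transfer-entropy hotspot mapping with co-localization statistics,
## ANM-LD transition simulation, and (time-delayed) cross-correlation /
## directionality analysis. Configs are plain lists, or JSON/YAML files
## mirroring the argument names.

#' Read a pipeline configuration file
#'
#' @param path JSON or YAML file (by extension).
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

load_structure_input <- function(structure, chains = NULL) {
  if (inherits(structure, "structure_model")) return(structure)
  if (inherits(structure, "synthetic_system")) return(as_structure_model(structure))
  read_structure(structure, chains = chains)
}

write_manifest <- function(outdir, config, seed) {
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE, null = "null", digits = NA)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("allosTE")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the transfer-entropy analysis pipeline
#'
#' Reads one structure, builds the GNM, selects the time delay, computes
#' transfer entropy / TECol per slow-mode subset, detects allosteric
#' peaks, and runs co-localization randomization statistics for each
#' configured reference set at each cutoff. Writes per-subset CSV tables,
#' a JSON report and TECol-painted PDBs to `outdir`.
#'
#' @param config Named list (or path readable by [read_run_config()])
#'   with fields: `structure` (path, `structure_model` or
#'   `synthetic_system`), optional `chains`, `exclude`, `gnm_cutoff`
#'   (default 10), `subsets` (list of `c(slowest, drop)`; default
#'   `list(c(10,0), c(10,1), c(10,2))`), `tau` (optional fixed delay),
#'   `reference_sets` (named list of residue-set specs), `coloc_cutoffs`
#'   (default `c(0, 4, 7)`), `n_iter` (default 100000), `seed`,
#'   `outdir`.
#' @return Invisible list with the fits, peaks and statistics (also
#'   written to disk when `outdir` is set).
#' @export
run_te_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  seed <- config$seed %||% 1L
  model <- load_structure_input(config$structure, config$chains)
  ca <- extract_ca(model, config$exclude)
  residues <- model$residues[ca$index, , drop = FALSE]
  subsets <- config$subsets %||% list(c(10, 0), c(10, 1), c(10, 2))
  cutoffs <- config$coloc_cutoffs %||% c(0, 4, 7)
  n_iter <- config$n_iter %||% 100000L
  g <- gnm(ca$xyz, config$gnm_cutoff %||% 10)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fits <- list(); peaks <- list(); stats_out <- list()
  for (s in subsets) {
    name <- sprintf("modes_%d-%d", s[2] + 1, s[1])
    message("TE subset ", name)
    fit <- gnm_te(g, slowest = s[1], drop = s[2], tau = config$tau)
    fit$residues <- residues
    pk <- detect_peaks(fit$tecol, chains = residues$chain, residues = residues)
    fits[[name]] <- fit
    peaks[[name]] <- pk
    for (rn in names(config$reference_sets)) {
      ref_idx <- resolve_residues(list(residues = residues),
                                  parse_residue_set(config$reference_sets[[rn]]))
      for (cut in cutoffs) {
        ct <- randomization_test(pk, ref_idx, ca$xyz, cutoff = cut,
                                 n_iter = n_iter,
                                 seed = seed + 7L * cut)
        stats_out[[name]][[rn]][[paste0("cutoff_", cut)]] <-
          ct[c("X", "mu", "sigma", "Z", "p", "p_empirical", "cutoff",
               "n_iter", "n_peaks")]
      }
    }
    if (!is.null(outdir)) {
      tab <- coef(fit)
      tab$peak <- tab$residue %in% pk$index
      utils::write.csv(tab, file.path(outdir, paste0("te_", name, ".csv")),
                       row.names = FALSE)
      painted <- structure_model(ca$xyz, chain = residues$chain,
                                 resno = residues$resno,
                                 insert = residues$insert,
                                 resid = residues$resid)
      sc <- fit$tecol / max(fit$tecol) * 99
      write_painted_structure(painted, sc,
                              file.path(outdir, paste0("tecol_", name, ".pdb")))
    }
  }
  report <- list(parameters = list(gnm_cutoff = config$gnm_cutoff %||% 10,
                                   subsets = subsets,
                                   tau = lapply(fits, `[[`, "tau"),
                                   tau_opt = lapply(fits, `[[`, "tau_opt"),
                                   n_modeled = nrow(ca$xyz),
                                   seed = seed),
                 n_peaks = lapply(peaks, nrow),
                 colocalization = stats_out)
  if (!is.null(outdir)) {
    jsonlite::write_json(report, file.path(outdir, "te_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    write_manifest(outdir, config[setdiff(names(config), "structure")], seed)
  }
  invisible(list(fits = fits, peaks = peaks, stats = stats_out,
                 report = report, coords = ca$xyz, residues = residues))
}

#' Run the ANM-LD transition pipeline
#'
#' Runs the configured number of transition replicas (differing only in
#' the relaxation noise stream), writes per-cycle CSVs, multi-model PDB
#' trajectories and a convergence summary.
#'
#' @param config Named list or config file: `start`, `target` (paths or
#'   models), optional `exclude`, `anmld` (arguments for
#'   [anmld_config()]), `replicas` (default 6), `seed`, `outdir`.
#' @return Invisible list of `anmld_trajectory` objects plus the summary.
#' @export
run_anmld_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  seed <- config$seed %||% 1L
  replicas <- config$replicas %||% 6L
  start <- load_structure_input(config$start)
  target <- load_structure_input(config$target)
  base_cfg <- do.call(anmld_config, config$anmld %||% list())
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  trajs <- vector("list", replicas)
  for (r in seq_len(replicas)) {
    cfg <- base_cfg
    cfg$seed <- seed + r - 1L
    message("ANM-LD replica ", r)
    trajs[[r]] <- run_transition(start, target, cfg, exclude = config$exclude)
    if (!is.null(outdir)) {
      tr <- trajs[[r]]
      utils::write.csv(
        data.frame(cycle = seq_along(tr$selected_mode),
                   selected_mode = tr$selected_mode,
                   overlap = tr$overlap,
                   rmsd_to_target = tr$rmsd_to_target[-1]),
        file.path(outdir, sprintf("anmld_replica%d.csv", r)),
        row.names = FALSE)
      write_trajectory_pdb(tr, file.path(outdir,
                                         sprintf("anmld_replica%d.pdb", r)))
    }
  }
  summary_df <- data.frame(
    replica = seq_len(replicas),
    cycles = vapply(trajs, function(t) length(t$selected_mode), integer(1)),
    rmsd_initial = vapply(trajs, function(t) t$rmsd_to_target[1], numeric(1)),
    rmsd_final = vapply(trajs, function(t)
      t$rmsd_to_target[length(t$rmsd_to_target)], numeric(1)),
    converged = vapply(trajs, `[[`, logical(1), "converged"))
  if (!is.null(outdir)) {
    utils::write.csv(summary_df, file.path(outdir, "anmld_summary.csv"),
                     row.names = FALSE)
    write_manifest(outdir, config[setdiff(names(config),
                                          c("start", "target"))], seed)
  }
  invisible(list(trajectories = trajs, summary = summary_df))
}

#' Run the cross-correlation / directionality pipeline
#'
#' Computes the equal-time DCCM, the delayed map at the configured (or
#' auto-chosen) delay, directionality calls and set-correlation profiles
#' for configured anchor residues over a trajectory window.
#'
#' @param config Named list or config file: `window` (`c(start, length)`,
#'   default the 48-cycle window from frame 1), `tau` (frames; NULL for
#'   [choose_time_delay()]), `min_corr` (default 0.4), `anchors` (named
#'   list of residue index vectors), `outdir`.
#' @param trajectory An `anmld_trajectory` or list of frames.
#' @return Invisible list: `dccm0`, `dccm_tau`, `tau`, `directionality`,
#'   `profiles`.
#' @export
run_correlation_pipeline <- function(config, trajectory) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  frames <- if (inherits(trajectory, "anmld_trajectory"))
    trajectory$conformers else trajectory
  nf <- length(frames)
  window <- config$window %||% c(1L, min(48L, nf))
  fl <- window_fluctuations(frames, window)
  tau <- config$tau %||% choose_time_delay(fl)
  dccm0 <- cross_correlation_map(fl, 0)
  dccm_tau <- cross_correlation_map(fl, tau)
  dmap <- directionality_map(dccm_tau, tau, config$min_corr %||% 0.4)
  profiles <- lapply(config$anchors %||% list(), function(a)
    set_correlation_profile(dccm_tau, a))
  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_csv(unclass(dccm0), file.path(outdir, "dccm_tau0.csv"))
    write_matrix_csv(unclass(dccm_tau),
                     file.path(outdir, sprintf("dccm_tau%d.csv", tau)))
    utils::write.csv(directionality_edges(dmap),
                     file.path(outdir, "directionality_edges.csv"),
                     row.names = FALSE)
    if (length(profiles)) {
      pr <- as.data.frame(profiles)
      utils::write.csv(pr, file.path(outdir, "anchor_profiles.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(list(tau = tau, window = window,
                              min_corr = config$min_corr %||% 0.4),
                         file.path(outdir, "correlation_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(dccm0 = dccm0, dccm_tau = dccm_tau, tau = tau,
                 directionality = dmap, profiles = profiles))
}
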