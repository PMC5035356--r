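#' Compute an ensemble B-factor profile from trajectories
#'
#' For each trajectory the two-step average-conformation superposition is
#' applied on the selected atoms and fluctuations are converted to
#' B-factors; per-simulation profiles are then averaged with a standard
#' error.  A pooled mode (all frames of all trajectories superposed as one
#' set before a single fluctuation pass) is available for comparison; it
#' yields no ensemble SE and is not the default.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param selection selection label, [atom_selection()] or name vector
#'   (default `"CA"`).
#' @param window_ps optional sampling window in nominal clock ps (frames
#'   beyond it are dropped; see [truncate_window()]).
#' @param mode `"per_simulation"` (default) or `"pooled"`.
#' @return A `bfactor_profile` (for `"pooled"`, a plain numeric vector of
#'   per-atom B).
#' @export
ensemble_bfactors <- function(ensemble, selection = "CA", window_ps = NULL,
                              mode = c("per_simulation", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (!is.null(window_ps)) ensemble <- truncate_window(ensemble, window_ps)
  sel <- select_atoms(ensemble$atom_table, selection, min_atoms = 3L)
  if (mode == "pooled") {
    pooled <- do.call(function(...) abind_frames(list(...)),
                      ensemble$trajectories)
    fit <- two_step_average_fit(pooled, sel)
    return(bfactors_from_fit(fit))
  }
  per_sim <- lapply(ensemble$trajectories, function(tr) {
    bfactors_from_fit(two_step_average_fit(tr, sel))
  })
  frame_dt <- ensemble$nominal_timestep * ensemble$save_interval_steps
  nf <- dim(ensemble$trajectories[[1L]])[1L]
  aggregate_ensemble(
    per_sim,
    atoms = ensemble$atom_table$atoms[sel, , drop = FALSE],
    window = list(nominal_fs = nf * frame_dt,
                  save_interval_steps = ensemble$save_interval_steps,
                  timestep_fs = ensemble$nominal_timestep))
}

abind_frames <- function(traj_list) {
  nf <- vapply(traj_list, function(t) dim(t)[1L], integer(1L))
  n <- dim(traj_list[[1L]])[2L]
  out <- array(NA_real_, c(sum(nf), n, 3L))
  at <- 0L
  for (t in traj_list) {
    out[at + seq_len(dim(t)[1L]), , ] <- t
    at <- at + dim(t)[1L]
  }
  out
}

#' Configure the end-to-end prediction pipeline
#'
#' Defaults mirror the replicate-simulation protocol the package emulates:
#' 20 independent simulations, a 1.00 fs nominal timestep, frames saved
#' every 1000 steps, and a 50 ps nominal sampling window.
#'
#' @param system a `toy_system` supplying the ensemble (or `NULL` when
#'   `trajectory_files` is given).
#' @param sim a [sim_config()] shared by all replicates.
#' @param seeds integer seeds, one per replicate (N >= 2 so the ensemble SE
#'   is defined).
#' @param selection selection label or [atom_selection()].
#' @param window_ps sampling window, nominal clock ps (`NULL` = all frames).
#' @param reference_pdb optional path to a PDB carrying experimental
#'   B-factors to compare against.
#' @param trajectory_files optional character vector of multi-model PDB
#'   trajectory paths, used instead of simulating.
#' @param mass_factor uniform mass factor of the simulations, recorded in
#'   provenance and used to echo the standard-mass-equivalent window.
#' @param out_dir optional output directory for the profile TSV, report
#'   JSON and provenance block.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(system = NULL, sim = NULL, seeds = 1:20,
                            selection = "CA", window_ps = NULL,
                            reference_pdb = NULL, trajectory_files = NULL,
                            mass_factor = 1, out_dir = NULL) {
  if (length(seeds) < 2L && is.null(trajectory_files)) {
    stop("pipeline needs at least 2 replicates: the ensemble SE is ",
         "undefined for N = 1")
  }
  if (is.null(trajectory_files) &&
      (is.null(system) || is.null(sim))) {
    stop("either a toy system + sim config or trajectory files are required")
  }
  structure(list(system = system, sim = sim, seeds = as.integer(seeds),
                 selection = selection, window_ps = window_ps,
                 reference_pdb = reference_pdb,
                 trajectory_files = trajectory_files,
                 mass_factor = mass_factor, out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_provenance <- function(config, ensemble) {
  win_nominal_ps <- if (is.null(config$window_ps)) {
    dim(ensemble$trajectories[[1L]])[1L] * ensemble$nominal_timestep *
      ensemble$save_interval_steps / 1000
  } else {
    config$window_ps
  }
  list(
    n_sims = length(ensemble$trajectories),
    seeds = ensemble$seeds,
    selection = if (is.character(config$selection)) config$selection
                else config$selection$label,
    save_interval_steps = ensemble$save_interval_steps,
    timestep_fs_nominal = ensemble$nominal_timestep,
    mass_factor = config$mass_factor,
    window_ps_nominal = win_nominal_ps,
    window_ps_standard_mass_equivalent =
      suppressWarnings(convert_time(win_nominal_ps, config$mass_factor,
                                    "nominal_to_standard")$value))
}

#' Run the full B-factor prediction pipeline
#'
#' Ensemble generation (toy simulation or trajectory files) -> window
#' truncation -> two-step superposition per simulation -> per-atom B-factors
#' -> ensemble mean and SE -> optional comparison against experimental
#' B-factors.  Deterministic given the seeds.  When `out_dir` is set, the
#' profile TSV, a provenance JSON block and (with a reference) the
#' comparison JSON are written; on error any partial outputs are removed.
#'
#' @param config a [pipeline_config()].
#' @param initial_conformations optional list of per-replicate starting
#'   coordinate matrices (multi-start mode, one per seed).
#' @return List with `profile` (a `bfactor_profile`), `report` (a
#'   `bfactor_comparison` or `NULL`) and `provenance`.
#' @export
run_pipeline <- function(config, initial_conformations = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  written <- character(0)
  on_fail <- function(stage) {
    function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    }
  }

  ensemble <- tryCatch({
    if (!is.null(config$trajectory_files)) {
      reads <- lapply(config$trajectory_files, read_multimodel_pdb)
      trajectory_ensemble(lapply(reads, `[[`, "coords"),
                          reads[[1L]]$structure,
                          seeds = seq_along(reads),
                          save_interval_steps = 1L,
                          nominal_timestep = 1)
    } else {
      run_ensemble(config$system, config$sim, config$seeds,
                   initial_coords = initial_conformations)
    }
  }, error = on_fail("ensemble"))

  profile <- tryCatch(
    ensemble_bfactors(ensemble, config$selection, config$window_ps),
    error = on_fail("bfactor"))

  report <- NULL
  if (!is.null(config$reference_pdb)) {
    report <- tryCatch({
      ref <- read_pdb(config$reference_pdb)
      compare_bfactors(profile, ref, selection = config$selection,
                       label = basename(config$reference_pdb))
    }, error = on_fail("compare"))
  }

  prov <- pipeline_provenance(config, ensemble)
  if (!is.null(config$out_dir)) {
    tryCatch({
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      p1 <- file.path(config$out_dir, "bfactor_profile.tsv")
      write_bfactor_tsv(profile, p1); written <- c(written, p1)
      p2 <- file.path(config$out_dir, "provenance.json")
      jsonlite::write_json(prov, p2, auto_unbox = TRUE, digits = NA)
      written <- c(written, p2)
      if (!is.null(report)) {
        p3 <- file.path(config$out_dir, "comparison.json")
        write_comparison_json(report, p3,
                              scatter_path = file.path(config$out_dir,
                                                       "scatter.tsv"))
        written <- c(written, p3)
      }
    }, error = on_fail("output"))
  }
  list(profile = profile, report = report, provenance = prov)
}

#' Multi-start pipeline mode
#'
#' One simulation per supplied initial conformation (replicates differ in
#' both seed and starting structure), with aggregation unchanged.  Emulates
#' predicting B-factors from distinct instantaneous starting conformations
#' rather than a single crystal conformation.
#'
#' @param config a [pipeline_config()] with as many seeds as conformations.
#' @param initial_conformations list of n_atoms x 3 matrices, one per seed.
#' @return As [run_pipeline()].
#' @export
multi_start_mode <- function(config, initial_conformations) {
  if (length(initial_conformations) != length(config$seeds)) {
    stop("need exactly one initial conformation per seed")
  }
  run_pipeline(config, initial_conformations = initial_conformations)
}
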