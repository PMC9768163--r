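# Config-driven experiments: replicated runs, parameter sweeps, and named
# presets for the reference experiment grid (n = 100, k = 5, t = 400).

#' Define an experiment
#'
#' @param model A [soam_params()] object.
#' @param interventions Optional [intervention_config()].
#' @param replicates Number of replicate runs; replicate `r` uses seed
#'   `base_seed + r - 1`.
#' @param base_seed Seed of the first replicate.
#' @param outputs Directory for trajectory/conflict CSVs and summary JSON
#'   (created if missing), or `NULL` to keep results in memory only.
#' @param record_every Timestep stride for the trajectory CSV (conflict is
#'   always recorded every timestep).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(model, interventions = NULL, replicates = 20,
                              base_seed = 1L, outputs = NULL,
                              record_every = 1) {
  stopifnot(inherits(model, "soam_params"), replicates >= 1,
            record_every >= 1)
  structure(list(model = model, interventions = interventions,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), outputs = outputs,
                 record_every = as.integer(record_every)),
            class = "experiment_config")
}

#' Run replicated simulations and summarize each run
#'
#' @param params A [soam_params()] object (its `seed` is ignored).
#' @param interventions Optional [intervention_config()].
#' @param replicates Number of runs.
#' @param base_seed Seed of the first run; subsequent runs use consecutive
#'   seeds.
#' @return Data frame with one row per replicate: `seed`, `final_conflict`,
#'   `max_conflict`, `max_abs_opinion`, `final_max_abs_opinion`,
#'   `extremity_1`, `extremity_2`, `n_clusters`, `n_replacements`.
#' @export
run_replicates <- function(params, interventions = NULL, replicates = 20,
                           base_seed = 1L) {
  rows <- lapply(seq_len(replicates), function(r) {
    p <- params
    p$seed <- as.integer(base_seed + r - 1)
    s <- summarize_trajectory(soam_run(p, interventions = interventions))
    c(list(seed = p$seed), s)
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Execute an experiment
#'
#' Runs every replicate, writes (when `outputs` is set) a long-format
#' trajectory CSV, a conflict-series CSV and a summary JSON per replicate,
#' and returns one result record per replicate.
#'
#' @param cfg An [experiment_config()].
#' @return List of per-replicate results: each has `seed`, `summary` (see
#'   [run_replicates()]), the `trajectory`, and file `paths` (or `NULL`).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  out <- cfg$outputs
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  lapply(seq_len(cfg$replicates), function(r) {
    p <- cfg$model
    p$seed <- as.integer(cfg$base_seed + r - 1)
    traj <- soam_run(p, interventions = cfg$interventions)
    summary <- summarize_trajectory(traj)
    paths <- NULL
    if (!is.null(out)) {
      stem <- file.path(out, sprintf("run_seed%d", p$seed))
      paths <- list(trajectory = paste0(stem, "_trajectory.csv"),
                    conflict = paste0(stem, "_conflict.csv"),
                    summary = paste0(stem, "_summary.json"))
      utils::write.csv(trajectory_df(traj, cfg$record_every),
                       paths$trajectory, row.names = FALSE)
      utils::write.csv(data.frame(timestep = seq_along(traj$conflict) - 1,
                                  conflict = traj$conflict),
                       paths$conflict, row.names = FALSE)
      jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                           digits = NA)
    }
    list(seed = p$seed, summary = summary, trajectory = traj, paths = paths)
  })
}

#' Parameter sweep
#'
#' Runs the Cartesian product of the supplied parameter values over the base
#' experiment and reports seed-averaged conflict per cell.
#'
#' @param grid Named list of parameter value vectors; names must be
#'   [soam_params()] fields (e.g. `list(epsilon = c(0.2, 0.5, 0.8))`). An
#'   empty list runs the base configuration alone.
#' @param base An [experiment_config()] providing all other settings.
#' @param at Timesteps at which to report seed-mean conflict, in addition to
#'   the final timestep.
#' @return Data frame with one row per grid cell: the swept parameter values,
#'   `conflict_final` (seed mean at `t_max`), `conflict_max` (seed mean of
#'   the per-run maximum), `conflict_t<at>` columns, and
#'   `max_abs_opinion` (seed mean). Written to `sweep.csv` under the base
#'   config's output directory when one is set.
#' @export
soam_sweep <- function(grid, base, at = c(100, 200)) {
  stopifnot(inherits(base, "experiment_config"))
  if (length(grid) > 0) {
    bad <- setdiff(names(grid), names(base$model))
    if (length(bad) > 0) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  } else {
    cells <- data.frame(row.names = 1)
  }
  at <- at[at < base$model$t_max]
  rows <- lapply(seq_len(max(1, nrow(cells))), function(ci) {
    p <- base$model
    for (nm in names(cells)) p[[nm]] <- cells[ci, nm]
    conf_at <- matrix(NA_real_, nrow = base$replicates, ncol = length(at))
    res <- vapply(seq_len(base$replicates), function(r) {
      p$seed <- as.integer(base$base_seed + r - 1)
      traj <- soam_run(p, interventions = base$interventions)
      conf_at[r, ] <<- traj$conflict[at + 1]
      c(final = traj$conflict[length(traj$conflict)],
        max = max(traj$conflict),
        max_abs = max(abs(traj$opinions)))
    }, numeric(3))
    row <- as.list(cells[ci, , drop = FALSE])
    row$conflict_final <- mean(res["final", ])
    row$conflict_max <- mean(res["max", ])
    for (j in seq_along(at)) {
      row[[sprintf("conflict_t%d", at[j])]] <- mean(conf_at[, j])
    }
    row$max_abs_opinion <- mean(res["max_abs", ])
    as.data.frame(row, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(base$outputs)) {
    if (!dir.exists(base$outputs)) dir.create(base$outputs, recursive = TRUE)
    utils::write.csv(tab, file.path(base$outputs, "sweep.csv"),
                     row.names = FALSE)
  }
  tab
}

# printed parameterizations of the reference experiment grid; "grid" entries
# are sweeps shown as panel families
PRESETS <- list(
  fig2a = list(epsilon = 0.8, pi = 0),
  fig2b = list(epsilon = 0.2, pi = 0),
  fig2c = list(epsilon = 0.8, pi = 0.2, p = 0.5, s = 0.5),
  fig2d = list(epsilon = 0.2, pi = 0.2, p = 0.5, s = 0.5),
  fig2e = list(epsilon = 0.8, pi = 0.5, p = 0.5, s = 0.5),
  fig2f = list(epsilon = 0.2, pi = 0.5, p = 0.5, s = 0.5),
  fig3a = list(pi = 0, grid = list(epsilon = c(0.2, 0.5, 0.8))),
  fig3b = list(pi = 0, epsilon = 0.8, grid = list(k = c(2, 5, 10))),
  fig3c = list(pi = 0.2, p = 0.5, s = 0.2,
               grid = list(epsilon = c(0.2, 0.5, 0.8))),
  fig3d = list(epsilon = 0.2, pi = 0.2, p = 0.5,
               grid = list(s = c(0.2, 0.5, 0.8))),
  fig3e = list(epsilon = 0.2, p = 0.5, s = 0.2,
               grid = list(pi = c(0.2, 0.5, 0.8))),
  fig3f = list(epsilon = 0.2, pi = 0.2, s = 0.2,
               grid = list(p = c(0.2, 0.5, 0.8))),
  fig4a = list(epsilon = 0.2, pi = 0.5, p = 0.5, s = 0.5),
  fig4b = list(epsilon = 0.2, pi = 0.5, p = 0.5, s = 0.5,
               intervention = "five_strike"),
  fig4c = list(epsilon = 0.8, pi = 0.5, p = 0.5, s = 0.5),
  fig4d = list(epsilon = 0.8, pi = 0.5, p = 0.5, s = 0.5,
               intervention = "five_strike"),
  fig5a = list(epsilon = 0.2, pi = 0.5, p = 0.5, s = 0.5),
  fig5b = list(epsilon = 0.2, pi = 0.5, p = 0.5, s = 0.5,
               intervention = "dissemination"),
  fig5c = list(epsilon = 0.8, pi = 0.5, p = 0.5, s = 0.5),
  fig5d = list(epsilon = 0.8, pi = 0.5, p = 0.5, s = 0.5,
               intervention = "dissemination")
)

#' Named experiment presets
#'
#' Returns the exact parameterization of one panel of the reference
#' experiment grid. All presets use `n = 100`, `k = 5` (unless `k` is the
#' swept parameter), `t_max = 400` on a directed Erdős–Rényi network.
#' Sweep panels carry the swept values in attribute `"grid"`; intervention
#' panels come with the matching [intervention_config()].
#'
#' @param name One of `fig2a`–`fig2f` (opinion trajectories), `fig3a`–`fig3f`
#'   (conflict under parameter sweeps), `fig4a`–`fig4d` (five-strike rule),
#'   `fig5a`–`fig5d` (balanced dissemination).
#' @param replicates,base_seed,outputs Passed to [experiment_config()].
#' @return An [experiment_config()], possibly with attribute `"grid"`.
#' @examples
#' cfg <- figure_presets("fig2f")
#' cfg$model$epsilon
#' @export
figure_presets <- function(name, replicates = 20, base_seed = 1L,
                           outputs = NULL) {
  if (!name %in% names(PRESETS)) stop("unknown preset: ", name,
                                      call. = FALSE)
  spec <- PRESETS[[name]]
  args <- spec[setdiff(names(spec), c("grid", "intervention"))]
  model <- do.call(soam_params, c(args, list(n = 100, t_max = 400)))
  iv <- switch(spec$intervention %||% "none",
               five_strike = intervention_config(max_amplify = 5),
               dissemination = intervention_config(dissemination = TRUE),
               none = NULL)
  cfg <- experiment_config(model, interventions = iv,
                           replicates = replicates, base_seed = base_seed,
                           outputs = outputs)
  attr(cfg, "grid") <- spec$grid
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
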