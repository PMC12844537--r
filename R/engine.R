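#' Run one full simulation
#'
#' Advances the lattice for `config$n_steps` steps under a fixed sub-step
#' order: primed T-cell spawning (relapse-aware), synchronous movement of
#' primed cells, PVMs and unengaged reactivated cells (including BBB crossing
#' and boundary rules), antigen presentation, myelin degradation and
#' engagement, delayed repair, oligodendrocyte stress-threshold updates, and
#' stochastic death. Chemotaxis bias switches on permanently at the first
#' recorded myelin damage. A single seeded RNG stream drives the whole run,
#' so identical `(config, plan, seed)` give bit-identical output.
#'
#' @param config A validated [ms_config()].
#' @param plan Optional [treatment_plan()] applied at its intervention day.
#' @param seed Integer RNG seed (defaults to `config$seed`).
#' @param snapshot_days Numeric vector of days at which to capture lattice
#'   snapshots (myelin state and block status matrices).
#' @return An object of class `"ms_sim"`: a list with
#'   \describe{
#'     \item{metrics}{data frame with one row per step (plus the initial
#'       state): agent counts, myelin fractions (intact/partial/damaged),
#'       oligodendrocyte fractions (myelinating/nonmyelinating/apoptotic),
#'       and the per-step book-keeping ledger (spawned, converted, deaths,
#'       right-boundary removals).}
#'     \item{behaviour_steps}{integer matrix, one row per oligodendrocyte
#'       block, of steps spent in each behaviour.}
#'     \item{snapshots}{list of requested lattice snapshots.}
#'     \item{config, plan, seed}{inputs, echoed.}
#'   }
#' @examples
#' cfg <- ms_config(lattice_width = 28, parenchyma_width = 20,
#'                  lattice_height = 40, n_steps = 144, pvm_count = 10)
#' sim <- run_simulation(cfg, seed = 1)
#' tail(sim$metrics[, c("step", "primed", "reactivated", "intact_frac")], 3)
#' @export
run_simulation <- function(config, plan = NULL, seed = config$seed,
                           snapshot_days = NULL) {
  config <- validate_config(config)
  if (!is.null(plan)) {
    plan <- validate_plan(plan, config)
  }
  snap_steps <- integer(0)
  if (!is.null(snapshot_days)) {
    snap_steps <- as.integer(round(snapshot_days * config$steps_per_day))
  }
  set.seed(as.integer(seed))
  res <- run_sim_cpp(config, if (is.null(plan)) list() else unclass(plan),
                     snap_steps)
  metrics <- as.data.frame(res$metrics)
  metrics$day <- metrics$step / config$steps_per_day
  metrics$relapse <- metrics$relapse == 1
  structure(list(metrics = metrics,
                 behaviour_steps = res$behaviour_steps,
                 snapshots = res$snapshots,
                 config = config, plan = plan, seed = as.integer(seed)),
            class = "ms_sim")
}

#' @export
print.ms_sim <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat("<ms_sim>\n")
  cat(sprintf("  %d steps (%.1f days), seed %d%s\n",
              x$config$n_steps, last$day, x$seed,
              if (is.null(x$plan)) "" else ", treated"))
  cat(sprintf("  final: intact myelin %.1f%%, apoptotic oligodendrocytes %.1f%%, %d reactivated T cells\n",
              100 * last$intact_frac, 100 * last$apoptotic_frac,
              as.integer(last$reactivated)))
  invisible(x)
}

#' Percentage of intact myelin lost at a given day
#'
#' Defined as `100 * (1 - intact-site fraction)`: partially damaged sites
#' count as lost.
#'
#' @param metrics A metrics data frame from [run_simulation()] or a mean
#'   series from [run_replicates()].
#' @param day Day at which to evaluate (default: the final row).
#' @return Percentage in `[0, 100]`.
#' @export
lost_myelin_pct <- function(metrics, day = NULL) {
  row <- if (is.null(day)) {
    metrics[nrow(metrics), ]
  } else {
    metrics[which.min(abs(metrics$day - day)), ]
  }
  100 * (1 - row$intact_frac)
}

#' Write the per-step metrics of a run to a delimited file
#'
#' @param sim An `ms_sim` object.
#' @param path Output path (comma-separated text).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(sim, path) {
  utils::write.csv(sim$metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write lattice snapshots to delimited text files
#'
#' One file per captured snapshot: `snapshot_day<D>.txt` holding the integer
#' myelin-state grid (rows by parenchyma columns) and
#' `snapshot_day<D>_oligo.txt` holding the block-status grid (0 myelinating,
#' 1 nonmyelinating, 2 apoptotic).
#'
#' @param sim An `ms_sim` object with snapshots.
#' @param dir Output directory (created if missing).
#' @return The written paths, invisibly.
#' @export
write_snapshots <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (snap in sim$snapshots) {
    d <- snap$step / sim$config$steps_per_day
    p1 <- file.path(dir, sprintf("snapshot_day%g.txt", d))
    p2 <- file.path(dir, sprintf("snapshot_day%g_oligo.txt", d))
    utils::write.table(snap$myelin_state, p1, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(snap$oligo_status, p2, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
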