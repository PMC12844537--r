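#' Run independent replicates and average their metrics
#'
#' Runs `n` independent seeded simulations of the same configuration and
#' treatment plan and returns the per-step mean together with the min/max
#' envelope across replicates. Replicate `i` uses seed `base_seed + i - 1`,
#' so two calls with the same `base_seed` are identical.
#'
#' @param config A validated [ms_config()].
#' @param plan Optional [treatment_plan()].
#' @param n Number of replicates (>= 1).
#' @param base_seed First replicate seed.
#' @param keep_runs Keep the individual `ms_sim` objects (default `FALSE`).
#' @return A list of class `"ms_replicates"` with data frames `mean`, `min`,
#'   `max` (same columns as a single run's metrics), the matrix
#'   `behaviour_steps` summed over nothing (a list, one matrix per replicate,
#'   only when `keep_runs`), `seeds`, and `n`.
#' @export
run_replicates <- function(config, plan = NULL, n = 10,
                           base_seed = config$seed, keep_runs = FALSE) {
  stopifnot(n >= 1)
  seeds <- as.integer(base_seed + seq_len(n) - 1L)
  runs <- lapply(seeds, function(s) run_simulation(config, plan, seed = s))
  num_cols <- vapply(runs[[1]]$metrics, is.numeric, logical(1))
  stack <- simplify2array(lapply(runs, function(r) {
    as.matrix(r$metrics[, num_cols])
  }))
  mk <- function(fun) {
    out <- as.data.frame(apply(stack, c(1, 2), fun))
    out$relapse <- runs[[1]]$metrics$relapse
    out
  }
  structure(list(mean = mk(mean), min = mk(min), max = mk(max),
                 behaviour = lapply(runs, function(r) r$behaviour_steps),
                 runs = if (keep_runs) runs else NULL,
                 seeds = seeds, n = n, config = config, plan = plan),
            class = "ms_replicates")
}

#' @export
print.ms_replicates <- function(x, ...) {
  last <- x$mean[nrow(x$mean), ]
  cat(sprintf("<ms_replicates> n = %d (seeds %d..%d)\n", x$n,
              min(x$seeds), max(x$seeds)))
  cat(sprintf("  final mean intact myelin %.1f%% (envelope %.1f-%.1f%%)\n",
              100 * last$intact_frac,
              100 * x$min[nrow(x$min), "intact_frac"],
              100 * x$max[nrow(x$max), "intact_frac"]))
  invisible(x)
}

window_table <- function(config, trailing_days = 7) {
  onsets <- sort(config$relapse_onsets)
  dur <- config$relapse_duration_days
  horizon <- config$n_days
  rel <- data.frame(window = paste0("relapse-", seq_along(onsets)),
                    type = "relapse",
                    from = onsets, to = pmin(onsets + dur + trailing_days,
                                             horizon))
  gaps_from <- onsets + dur
  gaps_to <- c(onsets[-1], horizon)
  keep <- gaps_to > gaps_from
  non <- data.frame(window = paste0("remission-", seq_len(sum(keep))),
                    type = "non-relapse",
                    from = gaps_from[keep], to = gaps_to[keep])
  rbind(rel, non)
}

#' Sensitivity sweep over the BBB permeability
#'
#' Runs replicate sets across a grid of rightward BBB permeabilities and, for
#' each relapse and non-relapse window, correlates (Pearson) the per-window
#' maximum of the replicate-mean reactivated T-cell count against the maximum
#' percentage of lost myelin across the permeability axis. "After each
#' relapse" is read as the relapse window plus `trailing_days` trailing days
#' (default 7, configurable).
#'
#' @param values Permeability values in `(0, 1]`.
#' @param config Base configuration (its `b_R` is overridden).
#' @param n Replicates per value.
#' @param base_seed First replicate seed (shared across values).
#' @param trailing_days Days appended to each relapse window.
#' @return A list of class `"ms_sweep_bR"`: `series` (long data frame of the
#'   mean reactivated count and lost-myelin percentage per step and value),
#'   `correlations` (one row per window), `values`, `n`.
#' @export
sweep_bR <- function(values, config = ms_config(), n = 10,
                     base_seed = config$seed, trailing_days = 7) {
  stopifnot(all(values > 0), all(values <= 1))
  per_value <- lapply(values, function(b) {
    cfg <- config; cfg$b_R <- b
    reps <- run_replicates(validate_config(cfg), n = n, base_seed = base_seed)
    m <- reps$mean
    data.frame(b_R = b, step = m$step, day = m$day,
               reactivated = m$reactivated,
               lost_myelin_pct = 100 * (1 - m$intact_frac))
  })
  series <- do.call(rbind, per_value)
  if (length(values) < 2) {
    warning("correlation undefined for fewer than two permeability values")
  }
  windows <- window_table(config, trailing_days)
  correlations <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    maxima <- t(vapply(per_value, function(df) {
      inw <- df$day >= w$from & df$day < w$to
      c(max_react = max(df$reactivated[inw]),
        max_lost = max(df$lost_myelin_pct[inw]))
    }, numeric(2)))
    r <- if (length(values) < 2) {
      NA_real_
    } else if (stats::sd(maxima[, 1]) == 0 || stats::sd(maxima[, 2]) == 0) {
      NA_real_
    } else {
      stats::cor(maxima[, 1], maxima[, 2])
    }
    data.frame(window = w$window, type = w$type, from = w$from, to = w$to,
               correlation = r)
  }))
  structure(list(series = series, correlations = correlations,
                 values = values, n = n),
            class = "ms_sweep_bR")
}

trapz <- function(y) {
  n <- length(y)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2)
}

#' Sensitivity sweep over the oligodendrocyte stress tolerances
#'
#' For every pair `(omega, lambda)` with `lambda >= omega` on the given grid,
#' runs `n` replicates and reports the normalised time-integral (trapezoidal
#' area under the per-step count curve, divided by block count x horizon) of
#' each oligodendrocyte behaviour, averaged over replicates. Each behaviour's
#' score is therefore its share of total oligodendrocyte-time and lies in
#' `[0, 1]`; the three scores sum to one.
#'
#' @param config Base configuration (its `omega`/`lambda_` are overridden).
#' @param omega_values,lambda_values Grid axes (defaults `1:25`).
#' @param n Replicates per cell (default 20).
#' @param base_seed First replicate seed (shared across cells).
#' @return A data frame of class `"ms_sweep_thresholds"` with columns
#'   `omega`, `lambda`, `auc_myelinating`, `auc_nonmyelinating`,
#'   `auc_apoptotic`, and the Day-300-equivalent `final_lost_myelin_pct`.
#' @export
sweep_thresholds <- function(config = ms_config(),
                             omega_values = 1:25,
                             lambda_values = 1:25,
                             n = 20, base_seed = config$seed) {
  cells <- expand.grid(omega = omega_values, lambda = lambda_values)
  cells <- cells[cells$lambda >= cells$omega, , drop = FALSE]
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$omega <- as.integer(cells$omega[i])
    cfg$lambda_ <- as.integer(cells$lambda[i])
    reps <- run_replicates(validate_config(cfg), n = n, base_seed = base_seed)
    m <- reps$mean
    horizon <- max(m$step)
    norm <- if (horizon > 0) horizon else 1
    data.frame(omega = cells$omega[i], lambda = cells$lambda[i],
               auc_myelinating = trapz(m$myelinating_frac) / norm,
               auc_nonmyelinating = trapz(m$nonmyelinating_frac) / norm,
               auc_apoptotic = trapz(m$apoptotic_frac) / norm,
               final_lost_myelin_pct = 100 * (1 - m$intact_frac[nrow(m)]))
  }))
  class(res) <- c("ms_sweep_thresholds", class(res))
  res
}

#' Per-oligodendrocyte time spent in each behaviour
#'
#' Converts per-block behaviour step counts (from [run_replicates()] or a
#' single run) into a long-format table of days spent myelinating,
#' non-myelinating, and post-apoptosis, one row per block, replicate and
#' behaviour, suitable for swarm-style plotting.
#'
#' @param reps An `ms_replicates` object, or a single `ms_sim`.
#' @return A data frame with columns `replicate`, `block`, `behaviour`,
#'   `days`. Per block and replicate the days sum to the simulated horizon.
#' @export
behaviour_time_swarm <- function(reps) {
  mats <- if (inherits(reps, "ms_sim")) {
    config <- reps$config
    list(reps$behaviour_steps)
  } else {
    config <- reps$config
    reps$behaviour
  }
  spd <- config$steps_per_day
  out <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    nb <- nrow(m)
    data.frame(replicate = i,
               block = rep(seq_len(nb), 3),
               behaviour = rep(c("myelinating", "nonmyelinating", "apoptotic"),
                               each = nb),
               days = c(m[, 1], m[, 2], m[, 3]) / spd)
  }))
  out
}

#' Compare end-of-course outcomes across the treatment scenarios
#'
#' Runs every scenario in [scenario_library()] for `n` replicates each and
#' summarises the final-day fraction of myelinating oligodendrocytes (the
#' bar-chart quantity) together with the final intact-myelin fraction.
#'
#' @param config Base configuration passed to [scenario_library()].
#' @param n Replicates per scenario.
#' @param base_seed First replicate seed (shared across scenarios).
#' @param scenarios Optional character subset of scenario names.
#' @return A data frame with one row per scenario: mean, min and max
#'   final myelinating fraction, and mean final intact fraction.
#' @export
treatment_comparison <- function(config = ms_config(), n = 10,
                                 base_seed = config$seed,
                                 scenarios = NULL) {
  lib <- scenario_library(config)
  if (!is.null(scenarios)) lib <- lib[scenarios]
  out <- do.call(rbind, lapply(lib, function(sc) {
    reps <- run_replicates(sc$config, sc$plan, n = n, base_seed = base_seed)
    last <- nrow(reps$mean)
    data.frame(scenario = sc$name,
               myelinating_frac = reps$mean$myelinating_frac[last],
               myelinating_min = reps$min$myelinating_frac[last],
               myelinating_max = reps$max$myelinating_frac[last],
               intact_frac = reps$mean$intact_frac[last])
  }))
  rownames(out) <- NULL
  out
}
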