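#' Build a validated simulation configuration
#'
#' Collects every model parameter in one record: lattice geometry, immune-cell
#' rates, blood-brain barrier (BBB) permeabilities, chemotaxis bias, myelin
#' state machine, oligodendrocyte stress thresholds, and the relapse schedule.
#' Defaults reproduce the untreated disease course: a 108 x 300 lattice at
#' 10 um spacing, 20-minute time steps over 300 days, and relapses every 100
#' days lasting four weeks.
#'
#' Coordinates are 1-based with column 1 at the left (blood) edge. Columns are
#' partitioned left to right into peripheral blood, perivascular space (PVS),
#' and parenchyma.
#'
#' @param lattice_width Total columns (default 108).
#' @param lattice_height Total rows (default 300); rows wrap (periodic).
#' @param delta Lattice spacing in micrometres (default 10).
#' @param blood_width,pvs_width,parenchyma_width Column widths of the three
#'   subdomains; they must sum to `lattice_width`.
#' @param tau Minutes per time step (default 20).
#' @param n_steps Number of steps to simulate (default 21600, i.e. 300 days).
#' @param rho_R Per-site per-step primed T-cell spawn probability in the blood
#'   during a relapse. The default 2.25/900 gives an average of 2.25 new primed
#'   T cells per step over the 900 blood sites.
#' @param rho_NR Spawn probability outside relapses (default 0.18/900).
#' @param rho_d Per-step death probability for primed and reactivated T cells
#'   (default 0.0049, from a 48-hour cytotoxic T-cell half-life; see
#'   [death_prob_from_decay()]).
#' @param b_R Rightward (blood to PVS) BBB crossing probability in \[0, 1\].
#' @param b_L Leftward (PVS to blood) crossing probability (default 0, i.e.
#'   the BBB reflects CNS-resident cells).
#' @param beta Maximum chemotaxis bias magnitude in \[0, 0.75\] (default 0.5).
#'   Values above 0.5 push individual direction probabilities negative; these
#'   are clamped at zero and renormalised.
#' @param k Bias decay constant per lattice unit (> 0, default 0.02): the bias
#'   felt by a reactivated T cell is `beta * exp(-k * D)` where `D` is the
#'   Euclidean distance to the nearest myelinated site. The default gives a
#'   chemotaxis range of roughly 50 lattice units (500 um).
#' @param n_myelin_states Number of myelin states S (>= 2, default 5). State S
#'   is fully intact, state 1 fully degraded.
#' @param repair_delay Steps of non-occupation required per repair increment
#'   (W >= 1, default 12): remyelinating one state takes 4 hours against 20
#'   minutes to degrade it, so full repair of a site takes 16 hours.
#' @param omega Remyelination threshold: a block whose count of fully damaged
#'   sites reaches `omega` stops repairing (default 10).
#' @param lambda_ Apoptosis threshold (`omega <= lambda_ <= oligo_block^2`,
#'   default 14).
#' @param oligo_block Side length of the square block of myelin sites that one
#'   oligodendrocyte maintains (default 5).
#' @param pvm_count Number of perivascular macrophages (default 45, i.e. 3%
#'   occupancy of the 0.15 mm^2 PVS at 300 cells/mm^2).
#' @param relapse_onsets Relapse onset days (default `c(0, 100, 200)`).
#' @param relapse_duration_days Length of each relapse window in days
#'   (default 28). Windows are half-open: `[onset, onset + duration)`.
#' @param seed Default RNG seed for [run_simulation()].
#' @param damage_per_agent If `TRUE`, every engaged reactivated T cell on a
#'   site decrements its state; the default `FALSE` applies one decrement per
#'   occupied site per step regardless of occupant multiplicity.
#'
#' @return A validated list of class `"ms_config"`, with derived quantities
#'   `steps_per_day` and `n_days` attached.
#' @seealso [validate_config()], [build_region_map()], [run_simulation()]
#' @examples
#' cfg <- ms_config(n_steps = 72)  # one simulated day
#' cfg$steps_per_day
#' @export
ms_config <- function(lattice_width = 108L,
                      lattice_height = 300L,
                      delta = 10,
                      blood_width = 3L,
                      pvs_width = 5L,
                      parenchyma_width = 100L,
                      tau = 20,
                      n_steps = 21600L,
                      rho_R = 2.25 / 900,
                      rho_NR = 0.18 / 900,
                      rho_d = 0.0049,
                      b_R = 0.1,
                      b_L = 0,
                      beta = 0.5,
                      k = 0.02,
                      n_myelin_states = 5L,
                      repair_delay = 12L,
                      omega = 10L,
                      lambda_ = 14L,
                      oligo_block = 5L,
                      pvm_count = 45L,
                      relapse_onsets = c(0, 100, 200),
                      relapse_duration_days = 28,
                      seed = 1L,
                      damage_per_agent = FALSE) {
  config <- list(
    lattice_width = as.integer(lattice_width),
    lattice_height = as.integer(lattice_height),
    delta = as.numeric(delta),
    blood_width = as.integer(blood_width),
    pvs_width = as.integer(pvs_width),
    parenchyma_width = as.integer(parenchyma_width),
    tau = as.numeric(tau),
    n_steps = as.integer(n_steps),
    rho_R = as.numeric(rho_R),
    rho_NR = as.numeric(rho_NR),
    rho_d = as.numeric(rho_d),
    b_R = as.numeric(b_R),
    b_L = as.numeric(b_L),
    beta = as.numeric(beta),
    k = as.numeric(k),
    n_myelin_states = as.integer(n_myelin_states),
    repair_delay = as.integer(repair_delay),
    omega = as.integer(omega),
    lambda_ = as.integer(lambda_),
    oligo_block = as.integer(oligo_block),
    pvm_count = as.integer(pvm_count),
    relapse_onsets = as.numeric(relapse_onsets),
    relapse_duration_days = as.numeric(relapse_duration_days),
    seed = as.integer(seed),
    damage_per_agent = isTRUE(damage_per_agent)
  )
  class(config) <- "ms_config"
  validate_config(config)
}

config_error <- function(class, message) {
  stop(structure(
    class = c(class, "ms_config_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of the model configuration and attaches
#' derived quantities (`steps_per_day`, `n_days`). Each violated invariant
#' raises a distinct, named condition inheriting from `"ms_config_error"`.
#'
#' @param config A list of class `"ms_config"` (see [ms_config()]).
#' @return The normalized configuration, invisibly identical in content.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "ms_config")) {
    config_error("ms_config_error_type", "`config` must be an `ms_config` object")
  }
  req <- setdiff(names(formals(ms_config)), "...")
  missing_fields <- setdiff(req, names(config))
  if (length(missing_fields) > 0) {
    config_error("ms_config_error_missing_field",
                 paste("missing configuration fields:",
                       paste(missing_fields, collapse = ", ")))
  }
  with(config, {
    if (blood_width + pvs_width + parenchyma_width != lattice_width) {
      config_error("ms_config_error_widths",
                   sprintf("region widths %d + %d + %d do not sum to lattice width %d",
                           blood_width, pvs_width, parenchyma_width, lattice_width))
    }
    if (blood_width < 1 || pvs_width < 1 || parenchyma_width < 1 ||
        lattice_height < 1) {
      config_error("ms_config_error_geometry", "all region widths and the lattice height must be >= 1")
    }
    if (!(rho_NR >= 0 && rho_NR <= rho_R && rho_R <= 1)) {
      config_error("ms_config_error_spawn_rates",
                   "spawn probabilities must satisfy 0 <= rho_NR <= rho_R <= 1")
    }
    if (rho_d < 0 || rho_d > 1) {
      config_error("ms_config_error_death_rate", "rho_d must lie in [0, 1]")
    }
    if (b_L < 0 || b_L > 1 || b_R < 0 || b_R > 1) {
      config_error("ms_config_error_bbb", "BBB permeabilities must lie in [0, 1]")
    }
    if (beta < 0 || beta > 0.75) {
      config_error("ms_config_error_beta", "beta must lie in [0, 0.75]")
    }
    if (k <= 0) {
      config_error("ms_config_error_k", "bias decay constant k must be > 0")
    }
    if (n_myelin_states < 2) {
      config_error("ms_config_error_states", "n_myelin_states must be >= 2")
    }
    if (repair_delay < 1) {
      config_error("ms_config_error_repair_delay", "repair_delay must be >= 1")
    }
    if (!(omega >= 1 && omega <= lambda_ && lambda_ <= oligo_block^2)) {
      config_error("ms_config_error_thresholds",
                   sprintf("thresholds must satisfy 1 <= omega <= lambda <= %d; got omega=%d, lambda=%d",
                           oligo_block^2, omega, lambda_))
    }
    if (parenchyma_width %% oligo_block != 0 || lattice_height %% oligo_block != 0) {
      config_error("ms_config_error_block_divisibility",
                   "parenchyma_width and lattice_height must be multiples of oligo_block")
    }
    if (pvm_count < 0 || pvm_count > pvs_width * lattice_height) {
      config_error("ms_config_error_pvm_count",
                   "pvm_count must lie between 0 and the number of PVS sites")
    }
    if (tau <= 0 || n_steps < 0) {
      config_error("ms_config_error_time", "tau must be > 0 and n_steps >= 0")
    }
    if (any(relapse_onsets < 0) || relapse_duration_days < 0) {
      config_error("ms_config_error_relapse",
                   "relapse onsets and duration must be non-negative")
    }
  })
  config$steps_per_day <- as.integer(round(24 * 60 / config$tau))
  config$n_days <- config$n_steps / config$steps_per_day
  config
}

#' @export
print.ms_config <- function(x, ...) {
  cat("<ms_config>\n")
  cat(sprintf("  lattice: %d x %d sites (%g um spacing); blood %d | PVS %d | parenchyma %d columns\n",
              x$lattice_width, x$lattice_height, x$delta,
              x$blood_width, x$pvs_width, x$parenchyma_width))
  cat(sprintf("  time: tau = %g min, %d steps (%g days)\n", x$tau, x$n_steps, x$n_days))
  cat(sprintf("  immune: rho_R = %.5g, rho_NR = %.5g, rho_d = %.4g, %d PVMs\n",
              x$rho_R, x$rho_NR, x$rho_d, x$pvm_count))
  cat(sprintf("  BBB: b_R = %g, b_L = %g; bias: beta = %g, k = %g\n",
              x$b_R, x$b_L, x$beta, x$k))
  cat(sprintf("  myelin: S = %d states, repair delay W = %d; thresholds omega = %d, lambda = %d (block %dx%d)\n",
              x$n_myelin_states, x$repair_delay, x$omega, x$lambda_,
              x$oligo_block, x$oligo_block))
  cat(sprintf("  relapses: onsets day {%s}, duration %g days\n",
              paste(x$relapse_onsets, collapse = ", "), x$relapse_duration_days))
  invisible(x)
}

#' Classify lattice columns into blood, PVS and parenchyma
#'
#' @param config A validated [ms_config()].
#' @return A data frame with one row per column (`column`, `region`), carrying
#'   attributes `bbb_column_pair` (the blood -> PVS interface columns) and
#'   `pvs_parenchyma_pair`.
#' @examples
#' rm <- build_region_map(ms_config())
#' table(rm$region)
#' @export
build_region_map <- function(config) {
  config <- validate_config(config)
  region <- rep(c("blood", "pvs", "parenchyma"),
                times = c(config$blood_width, config$pvs_width,
                          config$parenchyma_width))
  out <- data.frame(column = seq_len(config$lattice_width), region = region)
  attr(out, "bbb_column_pair") <- c(config$blood_width, config$blood_width + 1L)
  attr(out, "pvs_parenchyma_pair") <-
    c(config$blood_width + config$pvs_width,
      config$blood_width + config$pvs_width + 1L)
  out
}

#' Is a relapse active at a given step?
#'
#' A step belongs to a relapse iff its day lies in the half-open window
#' `[onset, onset + relapse_duration_days)` for some scheduled onset.
#'
#' @param step Zero-based step index (vectorized); `0 <= step < n_steps`.
#' @param config A validated [ms_config()].
#' @return Logical vector.
#' @examples
#' cfg <- ms_config()
#' relapse_active(10 * cfg$steps_per_day, cfg)   # day 10: TRUE
#' relapse_active(50 * cfg$steps_per_day, cfg)   # day 50: FALSE
#' @export
relapse_active <- function(step, config) {
  if (any(step < 0) || any(step >= max(config$n_steps, 1L))) {
    stop("`step` must satisfy 0 <= step < n_steps")
  }
  day <- floor(step / config$steps_per_day)
  vapply(day, function(d) {
    any(d >= config$relapse_onsets &
        d < config$relapse_onsets + config$relapse_duration_days)
  }, logical(1))
}

#' Per-step death probability from a continuous decay rate
#'
#' First-order discretisation of a per-day decay rate into the per-step
#' removal probability `rate * tau / 1440`. The default rate of 0.35/day
#' corresponds to the 48-hour half-life of cytotoxic T lymphocytes and yields
#' 0.0049 per 20-minute step (2 significant figures); at these rates the
#' exact exponential form differs only in the third significant figure.
#'
#' @param rate_per_day Decay rate per day.
#' @param tau Step length in minutes.
#' @return Per-step death probability.
#' @examples
#' signif(death_prob_from_decay(0.35, 20), 2)
#' @export
death_prob_from_decay <- function(rate_per_day = 0.35, tau = 20) {
  rate_per_day * tau / 1440
}

#' Read a configuration from a YAML file
#'
#' The file must be a flat key-value mapping whose keys are exactly the
#' arguments of [ms_config()] (any subset; missing keys take defaults).
#' Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated `ms_config`.
#' @export
read_ms_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(ms_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    config_error("ms_config_error_unknown_key",
                 paste("unknown configuration keys:", paste(unknown, collapse = ", ")))
  }
  do.call(ms_config, raw)
}

#' Write a configuration to a YAML file
#'
#' @param config A validated `ms_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms_config <- function(config, path) {
  config <- validate_config(config)
  fields <- config[intersect(names(formals(ms_config)), names(config))]
  yaml::write_yaml(fields, path)
  invisible(path)
}
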