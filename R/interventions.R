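#' Define a treatment plan
#'
#' A treatment is an atomic change of the live model parameters at a single
#' intervention day, optionally combined with (full or fractional)
#' re-establishment of the oligodendrocyte population and its myelin.
#'
#' When `restore_fraction = f` is given, every oligodendrocyte block is
#' independently selected with probability `f`; selected blocks become
#' myelinating with all their sites fully intact and repair counters reset,
#' and engaged T cells on restored sites are released. With
#' `restore_scope = "impaired"` only non-myelinating and apoptotic blocks are
#' eligible for restoration.
#'
#' When the stress tolerances are raised, non-myelinating blocks whose stress
#' now lies below the new `omega` resume myelinating (set
#' `relatch_nonmyelinating = TRUE` to keep their shutdown latched instead);
#' apoptosis is always absorbing.
#'
#' @param intervention_day Day at which the plan is applied (default 80).
#' @param new_b_R Optional replacement BBB permeability.
#' @param new_omega,new_lambda Optional replacement stress tolerances
#'   (`new_omega <= new_lambda <= 25` when both are given).
#' @param restore_fraction Optional re-establishment probability `f` in
#'   `[0, 1]`.
#' @param restore_scope `"all"` (default) or `"impaired"`.
#' @param relatch_nonmyelinating Keep existing non-myelinating blocks shut
#'   down when tolerances change (default `FALSE`).
#' @return A list of class `"ms_treatment_plan"`.
#' @examples
#' treatment_plan(new_b_R = 0.025, new_omega = 21, new_lambda = 24,
#'                restore_fraction = 1)
#' @export
treatment_plan <- function(intervention_day = 80,
                           new_b_R = NULL,
                           new_omega = NULL,
                           new_lambda = NULL,
                           restore_fraction = NULL,
                           restore_scope = c("all", "impaired"),
                           relatch_nonmyelinating = FALSE) {
  plan <- list(
    intervention_day = as.numeric(intervention_day),
    new_b_R = if (is.null(new_b_R)) NULL else as.numeric(new_b_R),
    new_omega = if (is.null(new_omega)) NULL else as.integer(new_omega),
    new_lambda = if (is.null(new_lambda)) NULL else as.integer(new_lambda),
    restore_fraction = if (is.null(restore_fraction)) NULL
                       else as.numeric(restore_fraction),
    restore_scope = match.arg(restore_scope),
    relatch_nonmyelinating = isTRUE(relatch_nonmyelinating)
  )
  class(plan) <- "ms_treatment_plan"
  plan
}

validate_plan <- function(plan, config) {
  if (!inherits(plan, "ms_treatment_plan")) {
    stop("`plan` must be created with treatment_plan()")
  }
  if (plan$intervention_day < 0 ||
      plan$intervention_day * config$steps_per_day > config$n_steps) {
    stop("intervention_day lies outside the simulation horizon")
  }
  max_sigma <- config$oligo_block^2
  om <- if (is.null(plan$new_omega)) config$omega else plan$new_omega
  la <- if (is.null(plan$new_lambda)) config$lambda_ else plan$new_lambda
  if (!(om >= 1 && om <= la && la <= max_sigma)) {
    stop(sprintf("treatment thresholds must satisfy 1 <= omega <= lambda <= %d",
                 max_sigma))
  }
  if (!is.null(plan$new_b_R) && (plan$new_b_R < 0 || plan$new_b_R > 1)) {
    stop("new_b_R must lie in [0, 1]")
  }
  if (!is.null(plan$restore_fraction) &&
      (plan$restore_fraction < 0 || plan$restore_fraction > 1)) {
    stop("restore_fraction must lie in [0, 1]")
  }
  plan
}

#' @export
print.ms_treatment_plan <- function(x, ...) {
  cat(sprintf("<ms_treatment_plan> day %g:", x$intervention_day))
  if (!is.null(x$new_b_R)) cat(sprintf(" b_R -> %g;", x$new_b_R))
  if (!is.null(x$new_omega)) cat(sprintf(" omega -> %d;", x$new_omega))
  if (!is.null(x$new_lambda)) cat(sprintf(" lambda -> %d;", x$new_lambda))
  if (!is.null(x$restore_fraction)) {
    cat(sprintf(" restore f = %g (%s);", x$restore_fraction, x$restore_scope))
  }
  cat("\n")
  invisible(x)
}

#' Apply a treatment plan to field and grid state
#'
#' Reference implementation of the intervention on explicit myelin/grid
#' structures (see [init_fields()]); [run_simulation()] performs the same
#' operation inside the compiled engine at the plan's intervention step.
#'
#' @param fields A list with `myelin` and `oligos` (see [init_fields()]).
#' @param plan A [treatment_plan()].
#' @param config A validated [ms_config()]; its `omega`/`lambda_` are treated
#'   as the pre-intervention live values.
#' @return A list with the updated `myelin`, `oligos`, and the post-treatment
#'   live parameters `omega`, `lambda_`, `b_R`.
#' @export
apply_treatment <- function(fields, plan, config) {
  myelin <- fields$myelin
  oligos <- fields$oligos
  S <- config$n_myelin_states
  B <- config$oligo_block
  om <- if (is.null(plan$new_omega)) config$omega else plan$new_omega
  la <- if (is.null(plan$new_lambda)) config$lambda_ else plan$new_lambda
  b_R <- if (is.null(plan$new_b_R)) config$b_R else plan$new_b_R
  changed <- !is.null(plan$new_omega) || !is.null(plan$new_lambda)
  if (changed && !plan$relatch_nonmyelinating) {
    revive <- oligos$status == "nonmyelinating" & oligos$sigma < om
    oligos$status[revive] <- "myelinating"
  }
  if (!is.null(plan$restore_fraction)) {
    sel <- stats::runif(length(oligos$status)) < plan$restore_fraction
    if (plan$restore_scope == "impaired") {
      sel <- sel & oligos$status != "myelinating"
    }
    for (b in which(sel)) {
      i <- (b - 1) %% nrow(oligos$status) + 1
      j <- (b - 1) %/% nrow(oligos$status) + 1
      rows <- ((i - 1) * B + 1):(i * B); cols <- ((j - 1) * B + 1):(j * B)
      myelin$state[rows, cols] <- S
      myelin$counter[rows, cols] <- 0L
      oligos$status[i, j] <- "myelinating"
      oligos$sigma[i, j] <- 0L
    }
  }
  list(myelin = myelin, oligos = oligos, omega = om, lambda_ = la, b_R = b_R)
}

#' The treatment scenarios compared in the study
#'
#' Returns the named scenario set spanning the untreated disease course, the
#' two BBB-targeted disease-modifying therapy (DMT) timings, the three
#' oligodendrocyte-targeted strategies, and the combined DMT + resilience +
#' restoration therapy with full or partial re-establishment. Every delayed
#' intervention occurs at Day 80, after the first relapse.
#'
#' @param config Base configuration (default [ms_config()]); scenario
#'   configurations are derived from it.
#' @return A named list of scenarios; each is a list with elements `name`,
#'   `config` (the configuration to run) and `plan` (a [treatment_plan()] or
#'   `NULL`).
#' @examples
#' names(scenario_library())
#' @export
scenario_library <- function(config = ms_config()) {
  config <- validate_config(config)
  with_bR <- function(b) {
    cfg <- config; cfg$b_R <- b; validate_config(cfg)
  }
  scen <- function(name, cfg = config, plan = NULL) {
    list(name = name, config = cfg, plan = plan)
  }
  out <- list(
    untreated = scen("untreated"),
    `delayed-DMT` = scen("delayed-DMT",
                         plan = treatment_plan(new_b_R = 0.025)),
    `immediate-DMT` = scen("immediate-DMT", cfg = with_bR(0.025)),
    `restore-only` = scen("restore-only",
                          plan = treatment_plan(restore_fraction = 1)),
    `resilience-only` = scen("resilience-only",
                             plan = treatment_plan(new_omega = 21,
                                                   new_lambda = 24)),
    `restore+resilience` = scen("restore+resilience",
                                plan = treatment_plan(new_omega = 21,
                                                      new_lambda = 24,
                                                      restore_fraction = 1)),
    combined = scen("combined",
                    plan = treatment_plan(new_b_R = 0.025, new_omega = 21,
                                          new_lambda = 24,
                                          restore_fraction = 1)),
    `combined-75` = scen("combined-75",
                         plan = treatment_plan(new_b_R = 0.025, new_omega = 21,
                                               new_lambda = 24,
                                               restore_fraction = 0.75)),
    `combined-50` = scen("combined-50",
                         plan = treatment_plan(new_b_R = 0.025, new_omega = 21,
                                               new_lambda = 24,
                                               restore_fraction = 0.5)),
    `combined-25` = scen("combined-25",
                         plan = treatment_plan(new_b_R = 0.025, new_omega = 21,
                                               new_lambda = 24,
                                               restore_fraction = 0.25))
  )
  out
}
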