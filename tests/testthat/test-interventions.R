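test_that("treatment plans validate their fields", {
  expect_s3_class(treatment_plan(new_b_R = 0.025), "ms_treatment_plan")
  cfg <- small_config()
  expect_error(run_simulation(cfg, treatment_plan(intervention_day = 1e6)),
               "horizon")
  expect_error(run_simulation(cfg, treatment_plan(intervention_day = 5,
                                                  new_omega = 20,
                                                  new_lambda = 10)),
               "omega")
  expect_error(run_simulation(cfg, treatment_plan(intervention_day = 5,
                                                  restore_fraction = 1.2)),
               "restore_fraction")
})

test_that("the scenario library encodes the study arms", {
  lib <- scenario_library()
  expect_named(lib, c("untreated", "delayed-DMT", "immediate-DMT",
                      "restore-only", "resilience-only", "restore+resilience",
                      "combined", "combined-75", "combined-50", "combined-25"))
  expect_null(lib$untreated$plan)
  expect_equal(lib$untreated$config$b_R, 0.1)
  expect_equal(lib$untreated$config$omega, 10L)
  expect_equal(lib$untreated$config$lambda_, 14L)
  expect_equal(lib$`immediate-DMT`$config$b_R, 0.025)
  expect_null(lib$`immediate-DMT`$plan)
  expect_equal(lib$`resilience-only`$plan$new_omega, 21L)
  expect_equal(lib$`resilience-only`$plan$new_lambda, 24L)
  expect_null(lib$`resilience-only`$plan$restore_fraction)
  expect_equal(lib$combined$plan$new_b_R, 0.025)
  expect_equal(lib$combined$plan$restore_fraction, 1)
  expect_equal(vapply(lib[c("combined-75", "combined-50", "combined-25")],
                      function(s) s$plan$restore_fraction, numeric(1)),
               c(0.75, 0.5, 0.25), ignore_attr = TRUE)
  expect_true(all(vapply(lib, function(s)
    is.null(s$plan) || s$plan$intervention_day == 80, logical(1))))
})

test_that("field-level treatment application restores and re-evaluates", {
  cfg <- small_config(omega = 3, lambda_ = 6)
  f <- init_fields(cfg)
  f$myelin$state[1:10, 1:5] <- 1L
  sig <- compute_sigma(f$myelin, cfg)
  f <- update_oligo_status(f$myelin, f$oligos, sig, cfg)
  names(f) <- c("myelin", "oligos")
  expect_true(any(f$oligos$status != "myelinating"))
  # full restoration: everything intact and myelinating
  out <- apply_treatment(f, treatment_plan(restore_fraction = 1), cfg)
  expect_true(all(out$myelin$state == cfg$n_myelin_states))
  expect_true(all(out$oligos$status == "myelinating"))
  expect_true(all(out$oligos$sigma == 0))
  # f = 0 with a permeability change leaves the fields untouched
  out0 <- apply_treatment(f, treatment_plan(new_b_R = 0.025,
                                            restore_fraction = 0), cfg)
  expect_identical(out0$myelin$state, f$myelin$state)
  expect_identical(out0$oligos$status, f$oligos$status)
  expect_equal(out0$b_R, 0.025)
  # raising omega above current stress revives non-myelinating blocks only
  g <- init_fields(cfg)
  g$myelin$state[1:4, 1] <- 1L           # sigma 4 in block (1,1)
  sig <- compute_sigma(g$myelin, cfg)
  g <- update_oligo_status(g$myelin, g$oligos, sig, cfg)
  names(g) <- c("myelin", "oligos")
  expect_equal(g$oligos$status[1, 1], "nonmyelinating")
  rev <- apply_treatment(g, treatment_plan(new_omega = 21, new_lambda = 24),
                         cfg)
  expect_equal(rev$oligos$status[1, 1], "myelinating")
  # ... but apoptosis is absorbing
  g$oligos$status[1, 1] <- "apoptotic"
  keep <- apply_treatment(g, treatment_plan(new_omega = 21, new_lambda = 24),
                          cfg)
  expect_equal(keep$oligos$status[1, 1], "apoptotic")
  # latched alternative keeps the shutdown
  lat <- apply_treatment(rev, treatment_plan(new_omega = 21, new_lambda = 24,
                                             relatch_nonmyelinating = TRUE),
                         cfg)
  expect_equal(lat$oligos$status[1, 1], "myelinating")  # already revived
})

test_that("fractional restoration selects about f of all blocks", {
  cfg <- small_config(omega = 3, lambda_ = 6)
  f <- init_fields(cfg)
  f$myelin$state[] <- 1L
  f$oligos$status[] <- "apoptotic"
  f$oligos$sigma[] <- 25L
  set.seed(10)
  n_runs <- 200
  restored <- replicate(n_runs, {
    out <- apply_treatment(f, treatment_plan(restore_fraction = 0.5), cfg)
    sum(out$oligos$status == "myelinating")
  })
  nb <- length(f$oligos$status)
  # binomial(nb, 0.5): check the mean within 4 standard errors
  se <- sqrt(nb * 0.25 / n_runs)
  expect_lt(abs(mean(restored) - nb * 0.5), 4 * se)
  # impaired-only scope never touches healthy blocks
  g <- init_fields(cfg)
  out <- apply_treatment(g, treatment_plan(restore_fraction = 1,
                                           restore_scope = "impaired"), cfg)
  expect_identical(out$oligos$status, g$oligos$status)
})

test_that("in-engine treatment is atomic at the intervention step", {
  cfg <- small_config(n_steps = 1440L, omega = 3, lambda_ = 5)
  day <- 10
  plan <- treatment_plan(intervention_day = day, new_b_R = 0.01,
                         restore_fraction = 1)
  treated <- run_simulation(cfg, plan, seed = 11)
  untreated <- run_simulation(cfg, NULL, seed = 11)
  s_int <- day * cfg$steps_per_day
  pre <- seq_len(s_int)   # rows before the intervention step
  expect_identical(treated$metrics[pre, c("primed", "reactivated",
                                          "intact_frac")],
                   untreated$metrics[pre, c("primed", "reactivated",
                                            "intact_frac")])
  # at the intervention step restoration is exact
  at <- treated$metrics[s_int + 1, ]
  expect_equal(at$intact_frac, 1)
  expect_equal(at$myelinating_frac, 1)
  # and the course diverges afterwards
  expect_false(isTRUE(all.equal(
    treated$metrics$intact_frac[(s_int + 2):(s_int + 300)],
    untreated$metrics$intact_frac[(s_int + 2):(s_int + 300)])))
})
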