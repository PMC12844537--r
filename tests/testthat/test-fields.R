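test_that("initial fields are fully intact with one block per 25 sites", {
  cfg <- ms_config()
  f <- init_fields(cfg)
  expect_equal(dim(f$myelin$state), c(300, 100))
  expect_true(all(f$myelin$state == cfg$n_myelin_states))
  expect_equal(length(f$oligos$status), 1200)      # 30000 sites / 25
  expect_true(all(f$oligos$status == "myelinating"))
  expect_true(all(f$oligos$sigma == 0))
  m <- myelin_metrics(f$myelin, f$oligos, cfg)
  expect_equal(unname(m$myelin), c(1, 0, 0))
  # block footprint: 25 sites x (10 um)^2 = 2500 um^2
  expect_equal(cfg$oligo_block^2 * cfg$delta^2, 2500)
  expect_error(init_fields(ms_config(lattice_height = 299,
                                     parenchyma_width = 100)),
               class = "ms_config_error")
})

test_that("occupation degrades one state per step down to the floor", {
  cfg <- one_block_config()     # S = 5
  f <- init_fields(cfg)
  occ <- cbind(row = 2L, col = 3L)
  for (i in 1:4) f$myelin <- degrade(f$myelin, occ)
  expect_equal(f$myelin$state[2, 3], 1L)           # intact -> floor in S-1 steps
  f$myelin <- degrade(f$myelin, occ)
  expect_equal(f$myelin$state[2, 3], 1L)           # floor is absorbing under attack
  # one decrement per site regardless of occupant multiplicity
  f2 <- init_fields(cfg)
  f2$myelin <- degrade(f2$myelin, rbind(occ, occ, occ))
  expect_equal(f2$myelin$state[2, 3], 4L)
  # untouched sites stay intact
  expect_equal(sum(f$myelin$state < 5), 1)
})

test_that("repair waits W unoccupied steps per state and respects shutdown", {
  cfg <- one_block_config(repair_delay = 3L, omega = 4, lambda_ = 5)
  f <- init_fields(cfg)
  f$myelin$state[2, 3] <- 1L
  none <- cbind(row = integer(), col = integer())
  # W = 3: three quiet steps per state increment, (S-1)*W = 12 steps to full
  for (i in 1:11) f$myelin <- repair(f$myelin, f$oligos, none, cfg)
  expect_equal(f$myelin$state[2, 3], 4L)
  f$myelin <- repair(f$myelin, f$oligos, none, cfg)
  expect_equal(f$myelin$state[2, 3], 5L)
  # occupation resets the counter
  f$myelin$state[2, 3] <- 2L
  f$myelin <- repair(f$myelin, f$oligos, none, cfg)
  f$myelin <- repair(f$myelin, f$oligos, none, cfg)
  f$myelin <- repair(f$myelin, f$oligos, cbind(row = 2L, col = 3L), cfg)
  expect_equal(f$myelin$counter[2, 3], 0L)
  expect_equal(f$myelin$state[2, 3], 2L)
  # a stressed block (sigma >= omega) repairs nothing
  g <- init_fields(cfg)
  g$myelin$state[1:4, 1] <- 1L
  sig <- compute_sigma(g$myelin, cfg)
  upd <- update_oligo_status(g$myelin, g$oligos, sig, cfg)
  expect_equal(upd$oligos$status[1, 1], "nonmyelinating")
  before <- upd$myelin$state
  for (i in 1:10) upd$myelin <- repair(upd$myelin, upd$oligos, none, cfg)
  expect_identical(upd$myelin$state, before)
})

test_that("sigma counts exactly the fully damaged sites of each block", {
  cfg <- small_config()
  f <- init_fields(cfg)
  set.seed(4)
  hit <- cbind(sample(1:40, 60, replace = TRUE), sample(1:20, 60, replace = TRUE))
  f$myelin$state[hit] <- sample(1:4, 60, replace = TRUE)
  sig <- compute_sigma(f$myelin, cfg)
  # recount oracle: direct tabulation per 5x5 block
  for (i in seq_len(nrow(sig))) {
    for (j in seq_len(ncol(sig))) {
      rows <- ((i - 1) * 5 + 1):(i * 5); cols <- ((j - 1) * 5 + 1):(j * 5)
      expect_identical(sig[i, j], sum(f$myelin$state[rows, cols] == 1L))
    }
  }
  expect_true(all(sig >= 0 & sig <= 25))
})

test_that("stress thresholds drive one-way transitions with absorbing apoptosis", {
  cfg <- small_config(omega = 10, lambda_ = 14)
  f <- init_fields(cfg)
  f$myelin$state[1:10, 1] <- 1L     # 10 floor sites inside the two top blocks
  sig <- compute_sigma(f$myelin, cfg)
  expect_equal(sig[1, 1], 5L)
  expect_equal(sig[2, 1], 5L)
  upd <- update_oligo_status(f$myelin, f$oligos, sig, cfg)
  expect_true(all(upd$oligos$status[1:2, 1] == "myelinating"))  # 5 < omega
  # push one block to sigma = 10: stops myelinating but keeps its states
  f$myelin$state[1:5, 2] <- 1L
  sig <- compute_sigma(f$myelin, cfg)
  expect_equal(sig[1, 1], 10L)
  upd <- update_oligo_status(f$myelin, upd$oligos, sig, cfg)
  expect_equal(upd$oligos$status[1, 1], "nonmyelinating")
  expect_equal(sum(upd$myelin$state[1:5, 1:5] == 1L), 10)
  # push to lambda: apoptosis wipes the whole block
  upd$myelin$state[1:5, 3:4] <- 1L
  sig <- compute_sigma(upd$myelin, cfg)
  expect_gte(sig[1, 1], 14)
  upd <- update_oligo_status(upd$myelin, upd$oligos, sig, cfg)
  expect_equal(upd$oligos$status[1, 1], "apoptotic")
  expect_true(all(upd$myelin$state[1:5, 1:5] == 1L))
  expect_equal(upd$oligos$sigma[1, 1], 25L)
  # a myelinating block crossing both thresholds in one step dies in that step
  g <- init_fields(cfg)
  g$myelin$state[1:15, 6] <- 1L    # 15 floor sites in blocks (1..3, 2)
  sig <- compute_sigma(g$myelin, cfg)
  expect_equal(sig[1, 2], 5L)
  g$myelin$state[1:5, 7:9] <- 1L   # block (1,2) now sigma = 20 >= lambda
  sig <- compute_sigma(g$myelin, cfg)
  out <- update_oligo_status(g$myelin, g$oligos, sig, cfg)
  expect_equal(out$oligos$status[1, 2], "apoptotic")
})

test_that("composition fractions partition the populations", {
  cfg <- small_config()
  f <- init_fields(cfg)
  f$myelin$state[1, 1] <- 3L
  m <- myelin_metrics(f$myelin, f$oligos, cfg)
  expect_equal(sum(m$myelin), 1)
  expect_equal(sum(m$oligos), 1)
  expect_equal(unname(m$myelin["partial"]), 1 / 800)   # one site of 40 x 20
  # all blocks apoptotic implies total loss
  f$oligos$status[] <- "apoptotic"
  f$myelin$state[] <- 1L
  m2 <- myelin_metrics(f$myelin, f$oligos, cfg)
  expect_equal(unname(m2$myelin["damaged"]), 1)
  expect_equal(unname(m2$oligos["apoptotic"]), 1)
})

test_that("a single block under sustained attack crosses both tolerances", {
  # one oligodendrocyte harness: healthy-site count falls through 25 - omega,
  # then 25 - lambda, and the block walks myelinating -> nonmyelinating ->
  # apoptotic
  cfg <- one_block_config(omega = 10, lambda_ = 14, repair_delay = 12L)
  f <- init_fields(cfg)
  trace_status <- character(0)
  trace_healthy <- integer(0)
  set.seed(8)
  for (step in 1:400) {
    if (f$oligos$status[1, 1] != "apoptotic") {
      # attack six random sites per step, faster than repair can clear
      occ <- cbind(row = sample(1:5, 6, TRUE), col = sample(1:5, 6, TRUE))
      f$myelin <- degrade(f$myelin, occ)
      f$myelin <- repair(f$myelin, f$oligos, occ, cfg)
    }
    sig <- compute_sigma(f$myelin, cfg)
    f <- setNames(update_oligo_status(f$myelin, f$oligos, sig, cfg),
                  c("myelin", "oligos"))
    trace_status <- c(trace_status, f$oligos$status[1, 1])
    trace_healthy <- c(trace_healthy, sum(f$myelin$state != 1L))
  }
  expect_equal(trace_status[length(trace_status)], "apoptotic")
  # ordered, one-way passage through the three behaviours
  runs <- rle(trace_status)$values
  expect_true(all(runs == c("myelinating", "nonmyelinating", "apoptotic")[
    seq_along(runs)]))
  # healthy count crosses 25 - omega before shutdown and 25 - lambda before death
  first_nonmyel <- match("nonmyelinating", trace_status)
  first_apop <- match("apoptotic", trace_status)
  expect_lte(trace_healthy[first_nonmyel], 25 - cfg$omega)
  expect_lte(trace_healthy[first_apop], 25 - cfg$lambda_)
  expect_equal(trace_healthy[length(trace_healthy)], 0)
})

test_that("state bounds and a no-attack fixed point hold", {
  cfg <- small_config(omega = 25, lambda_ = 25)
  f <- init_fields(cfg)
  none <- cbind(row = integer(), col = integer())
  for (i in 1:20) {
    f$myelin <- repair(f$myelin, f$oligos, none, cfg)
    sig <- compute_sigma(f$myelin, cfg)
    f <- setNames(update_oligo_status(f$myelin, f$oligos, sig, cfg),
                  c("myelin", "oligos"))
  }
  expect_true(all(f$myelin$state == cfg$n_myelin_states))
  expect_true(all(f$oligos$status == "myelinating"))
})
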