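#' Initialise the myelin field and oligodendrocyte grid
#'
#' All parenchyma sites start fully intact (state `S`) with repair counters at
#' zero; all oligodendrocyte blocks start myelinating with stress zero. Under
#' the defaults this is 30,000 myelin sites maintained by 1200 oligodendrocyte
#' blocks of 5 x 5 sites each.
#'
#' The myelin field is a list with integer matrices `state` and `counter`
#' (`lattice_height` rows by `parenchyma_width` columns); the oligodendrocyte
#' grid is a list with a character matrix `status` and an integer matrix
#' `sigma`, both `lattice_height / oligo_block` rows by
#' `parenchyma_width / oligo_block` columns. Site `(r, c)` belongs to block
#' `(ceiling(r / B), ceiling(c / B))`.
#'
#' @param config A validated [ms_config()].
#' @return A list with elements `myelin` and `oligos`.
#' @export
init_fields <- function(config) {
  config <- validate_config(config)
  H <- config$lattice_height; Wq <- config$parenchyma_width
  B <- config$oligo_block
  myelin <- list(
    state = matrix(config$n_myelin_states, nrow = H, ncol = Wq),
    counter = matrix(0L, nrow = H, ncol = Wq)
  )
  oligos <- list(
    status = matrix("myelinating", nrow = H / B, ncol = Wq / B),
    sigma = matrix(0L, nrow = H / B, ncol = Wq / B)
  )
  list(myelin = myelin, oligos = oligos)
}

#' Degrade myelin at sites occupied by engaged reactivated T cells
#'
#' Each occupied site with state above 1 is decremented by exactly one state
#' per step (independent of occupant multiplicity) and its repair counter is
#' reset. State-1 (fully degraded) sites are unchanged.
#'
#' @param field Myelin field (see [init_fields()]).
#' @param occupied Integer matrix with columns `row`, `col` (parenchyma
#'   coordinates) of sites occupied by at least one engaged reactivated T
#'   cell.
#' @return The updated field.
#' @export
degrade <- function(field, occupied) {
  if (NROW(occupied) == 0) return(field)
  idx <- unique(cbind(occupied[, "row"], occupied[, "col"]))
  above_floor <- field$state[idx] > 1L
  field$state[idx[above_floor, , drop = FALSE]] <-
    field$state[idx[above_floor, , drop = FALSE]] - 1L
  field$counter[idx] <- 0L
  field
}

#' Advance repair counters and remyelinate eligible sites
#'
#' A damaged site (state below `S`) sitting in a myelinating block and not
#' occupied by a reactivated T cell this step accrues one counter increment;
#' once the counter reaches the repair delay `W` the state increases by one
#' and the counter resets. Occupied sites have their counter reset instead,
#' and sites in non-myelinating or apoptotic blocks never repair (their
#' counters are held at zero).
#'
#' @param field Myelin field.
#' @param grid Oligodendrocyte grid.
#' @param occupied As in [degrade()], but for occupation by *any* reactivated
#'   T cell.
#' @param config A validated [ms_config()].
#' @return The updated field.
#' @export
repair <- function(field, grid, occupied, config) {
  S <- config$n_myelin_states; B <- config$oligo_block
  occ <- matrix(FALSE, nrow = nrow(field$state), ncol = ncol(field$state))
  if (NROW(occupied) > 0) {
    occ[cbind(occupied[, "row"], occupied[, "col"])] <- TRUE
  }
  block_status <- grid$status[cbind(
    as.vector((row(field$state) - 1L) %/% B + 1L),
    as.vector((col(field$state) - 1L) %/% B + 1L)
  )]
  dim(block_status) <- dim(field$state)
  damaged <- field$state < S
  shutdown <- block_status != "myelinating"
  field$counter[occ | shutdown] <- 0L
  tick <- damaged & !occ & !shutdown
  field$counter[tick] <- field$counter[tick] + 1L
  ready <- tick & field$counter >= config$repair_delay
  field$state[ready] <- field$state[ready] + 1L
  field$counter[ready] <- 0L
  field
}

#' Count fully damaged sites per oligodendrocyte block
#'
#' The stress level of an oligodendrocyte is the number of its sites at
#' state 1 (fully degraded); partial damage does not contribute.
#'
#' @param field Myelin field.
#' @param config A validated [ms_config()].
#' @return Integer matrix of per-block stress, block-rows by block-columns.
#' @export
compute_sigma <- function(field, config) {
  B <- config$oligo_block
  dam <- field$state == 1L
  nbr <- nrow(dam) / B; nbc <- ncol(dam) / B
  sig <- matrix(0L, nbr, nbc)
  for (i in seq_len(nbr)) {
    for (j in seq_len(nbc)) {
      sig[i, j] <- sum(dam[((i - 1) * B + 1):(i * B), ((j - 1) * B + 1):(j * B)])
    }
  }
  sig
}

#' Apply the integrated stress response transitions to oligodendrocytes
#'
#' Myelinating blocks whose stress reaches the remyelination threshold `omega`
#' become non-myelinating; non-myelinating blocks whose stress reaches the
#' apoptosis threshold `lambda` undergo apoptosis, which sets every site of
#' the block to state 1 permanently. Transitions are one-way: a block never
#' reverts even if its stress later falls (therapeutic re-evaluation is
#' handled separately by [apply_treatment()]). A block can pass both
#' thresholds in the same step.
#'
#' @param field Myelin field.
#' @param grid Oligodendrocyte grid.
#' @param sigma Freshly computed per-block stress (see [compute_sigma()]).
#' @param config A validated [ms_config()].
#' @return A list with the updated `myelin` field and `oligos` grid.
#' @export
update_oligo_status <- function(field, grid, sigma, config) {
  B <- config$oligo_block
  grid$sigma <- sigma
  to_nonmyel <- grid$status == "myelinating" & sigma >= config$omega
  grid$status[to_nonmyel] <- "nonmyelinating"
  to_apop <- grid$status == "nonmyelinating" & sigma >= config$lambda_
  if (any(to_apop)) {
    grid$status[to_apop] <- "apoptotic"
    for (b in which(to_apop)) {
      i <- (b - 1) %% nrow(grid$status) + 1
      j <- (b - 1) %/% nrow(grid$status) + 1
      rows <- ((i - 1) * B + 1):(i * B); cols <- ((j - 1) * B + 1):(j * B)
      field$state[rows, cols] <- 1L
      field$counter[rows, cols] <- 0L
    }
    grid$sigma[to_apop] <- B^2
  }
  list(myelin = field, oligos = grid)
}

#' Summarise myelin and oligodendrocyte composition
#'
#' @param field Myelin field.
#' @param grid Oligodendrocyte grid.
#' @param config A validated [ms_config()].
#' @return A list of two named numeric vectors: `myelin` with fractions
#'   `intact` (state `S`), `partial` (strictly between 1 and `S`) and
#'   `damaged` (state 1); and `oligos` with fractions `myelinating`,
#'   `nonmyelinating`, `apoptotic`. Each vector sums to one.
#' @export
myelin_metrics <- function(field, grid, config) {
  S <- config$n_myelin_states
  n <- length(field$state)
  m <- c(intact = sum(field$state == S) / n,
         partial = sum(field$state > 1L & field$state < S) / n,
         damaged = sum(field$state == 1L) / n)
  nb <- length(grid$status)
  o <- c(myelinating = sum(grid$status == "myelinating") / nb,
         nonmyelinating = sum(grid$status == "nonmyelinating") / nb,
         apoptotic = sum(grid$status == "apoptotic") / nb)
  list(myelin = m, oligos = o)
}
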