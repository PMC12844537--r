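#' Chemotaxis bias strength at a given distance
#'
#' The bias probability mass felt by a reactivated T cell decays exponentially
#' with its Euclidean distance `D` (in lattice units) to the nearest
#' myelinated site: `s_bias = beta * exp(-k * D)`.
#'
#' @param distance Euclidean distance in lattice units (vectorized).
#' @param beta Maximum bias magnitude.
#' @param k Decay constant per lattice unit.
#' @return Bias mass in `[0, beta]`.
#' @export
s_bias <- function(distance, beta = 0.5, k = 0.02) {
  stopifnot(all(distance >= 0), beta >= 0, k > 0)
  beta * exp(-k * distance)
}

#' Movement probabilities of a reactivated T cell under chemotactic bias
#'
#' Given the displacement `(dx, dy)` from the cell to its target myelin site
#' (`dx > 0`: target to the east, i.e. larger column; `dy > 0`: target at a
#' larger row index, "south"), the two directions pointing toward the target
#' gain bias proportional to the relative magnitude of their axis component,
#' and the two opposite directions each lose half the bias mass:
#' toward-axis probability `0.25 + s * |comp| / (|dx| + |dy|)`, away-axis
#' probability `0.25 - s / 2`, with `s = beta * exp(-k * sqrt(dx^2 + dy^2))`.
#'
#' When the target is axis-aligned the favoured direction on the zero
#' component axis is fixed by convention (east when `dx == 0`, south when
#' `dy == 0`) and keeps its unbiased 0.25 since its bias weight vanishes.
#' For `beta > 0.5` individual probabilities can go negative; they are clamped
#' at zero and the four probabilities renormalised. The result always sums to
#' one.
#'
#' @param dx,dy Integer displacement components to the target (not both zero).
#' @param beta Maximum bias magnitude.
#' @param k Decay constant per lattice unit.
#' @return Named numeric vector `c(E, W, N, S)` of direction probabilities,
#'   where `N` decreases and `S` increases the row index.
#' @examples
#' biased_move_probs(3, 4, beta = 0.5, k = 0.005)
#' biased_move_probs(1, 0, beta = 0)   # unbiased: all 0.25
#' @export
biased_move_probs <- function(dx, dy, beta = 0.5, k = 0.02) {
  if (dx == 0 && dy == 0) {
    stop("target coincides with the cell position; engaged agents do not move")
  }
  ax <- abs(dx); ay <- abs(dy)
  s <- s_bias(sqrt(ax^2 + ay^2), beta = beta, k = k)
  p <- c(E = 0.25, W = 0.25, N = 0.25, S = 0.25)
  fav_x <- if (dx < 0) "W" else "E"
  fav_y <- if (dy < 0) "N" else "S"
  opp <- c(E = "W", W = "E", N = "S", S = "N")
  p[fav_x] <- p[fav_x] + s * ax / (ax + ay)
  p[opp[fav_x]] <- p[opp[fav_x]] - s / 2
  p[fav_y] <- p[fav_y] + s * ay / (ax + ay)
  p[opp[fav_y]] <- p[opp[fav_y]] - s / 2
  p <- pmax(p, 0)
  p / sum(p)
}

#' Propose one unbiased random-walk step
#'
#' Each of the four Von Neumann neighbours (east, west, north, south) is
#' proposed with probability 0.25. Boundary and BBB rules are applied
#' separately by [apply_boundaries()] / [attempt_bbb_cross()].
#'
#' @param pos Length-2 integer vector `c(col, row)`.
#' @return Proposed `c(col, row)` (possibly off-lattice; resolve with
#'   [apply_boundaries()]).
#' @export
unbiased_step <- function(pos) {
  dir <- sample.int(4L, 1L)
  step <- switch(dir, c(1L, 0L), c(-1L, 0L), c(0L, -1L), c(0L, 1L))
  c(pos[1] + step[1], pos[2] + step[2])
}

#' Spawn primed T cells in the peripheral blood
#'
#' Each blood-region lattice site independently generates a primed T cell with
#' probability `rho_R` during a relapse and `rho_NR` otherwise. Under the
#' defaults this introduces on average 2.25 new cells per step during relapses
#' and 0.18 otherwise.
#'
#' @param config A validated [ms_config()].
#' @param relapse_flag Logical: is a relapse active this step?
#' @return Integer matrix with columns `col`, `row` of spawn positions
#'   (zero rows when nothing spawns).
#' @export
spawn_primed <- function(config, relapse_flag) {
  rho <- if (isTRUE(relapse_flag)) config$rho_R else config$rho_NR
  n_sites <- config$blood_width * config$lattice_height
  hit <- which(stats::runif(n_sites) < rho)
  cbind(col = ((hit - 1L) %/% config$lattice_height) + 1L,
        row = ((hit - 1L) %% config$lattice_height) + 1L)
}

#' Seed the perivascular macrophage population
#'
#' Samples `pvm_count` distinct lattice sites uniformly from the PVS.
#'
#' @param config A validated [ms_config()].
#' @return Integer matrix with columns `col`, `row`.
#' @export
seed_pvms <- function(config) {
  n_sites <- config$pvs_width * config$lattice_height
  if (config$pvm_count > n_sites) {
    stop("pvm_count exceeds the number of PVS sites")
  }
  sites <- sample.int(n_sites, config$pvm_count)
  cbind(col = config$blood_width + ((sites - 1L) %/% config$lattice_height) + 1L,
        row = ((sites - 1L) %% config$lattice_height) + 1L)
}

#' Attempt a crossing of the blood-brain barrier
#'
#' A rightward (blood to PVS) crossing attempt succeeds with probability
#' `b_R`; a leftward attempt with probability `b_L`. On failure the agent
#' stays at its current site for the step (the movement event is consumed).
#'
#' @param direction `"right"` or `"left"`.
#' @param config A validated [ms_config()].
#' @return Logical: did the crossing succeed?
#' @export
attempt_bbb_cross <- function(direction = c("right", "left"), config) {
  direction <- match.arg(direction)
  p <- if (direction == "right") config$b_R else config$b_L
  stats::runif(1) < p
}

#' Resolve a proposed move against the domain boundaries
#'
#' Top and bottom rows wrap (periodic) for all agents. The left edge reflects
#' (the agent stays put). The right edge removes the agent (Dirichlet).
#' PVMs attempting to leave the PVS in either direction are reflected. BBB
#' crossings between blood and PVS are *not* resolved here; use
#' [attempt_bbb_cross()].
#'
#' @param pos Current `c(col, row)`.
#' @param proposed Proposed `c(col, row)` from [unbiased_step()] or a biased
#'   draw.
#' @param agent_type `"primed"`, `"pvm"` or `"reactivated"`.
#' @param config A validated [ms_config()].
#' @return The resolved `c(col, row)`, or `NULL` if the agent is removed at
#'   the right boundary.
#' @export
apply_boundaries <- function(pos, proposed, agent_type, config) {
  stopifnot(agent_type %in% c("primed", "pvm", "reactivated"))
  col <- proposed[1]; row <- proposed[2]
  if (row < 1) row <- config$lattice_height
  if (row > config$lattice_height) row <- 1L
  if (col > config$lattice_width) return(NULL)
  if (col < 1) col <- pos[1]
  if (agent_type == "pvm") {
    pvs_lo <- config$blood_width + 1L
    pvs_hi <- config$blood_width + config$pvs_width
    if (col < pvs_lo || col > pvs_hi) col <- pos[1]
  }
  c(col = col, row = row)
}

#' Convert co-located primed T cells by antigen presentation
#'
#' For every lattice site simultaneously occupied by at least one primed T
#' cell and at least one PVM, each co-located primed T cell is removed and one
#' reactivated T cell is created in its place; PVMs persist.
#'
#' @param population A list with integer matrices `primed` and `pvms`
#'   (columns `col`, `row`) and a data frame `reactivated` (columns `col`,
#'   `row`, `engaged`).
#' @return The updated population list, with attribute `"n_converted"`.
#' @export
antigen_presentation <- function(population) {
  primed <- population$primed
  pvms <- population$pvms
  if (nrow(primed) == 0 || nrow(pvms) == 0) {
    attr(population, "n_converted") <- 0L
    return(population)
  }
  key <- function(m) paste(m[, 1], m[, 2], sep = ",")
  hit <- key(primed) %in% key(pvms)
  if (any(hit)) {
    new_react <- data.frame(col = primed[hit, 1], row = primed[hit, 2],
                            engaged = FALSE)
    population$reactivated <- rbind(population$reactivated, new_react)
    population$primed <- primed[!hit, , drop = FALSE]
  }
  attr(population, "n_converted") <- sum(hit)
  population
}

#' Apply per-step stochastic death to the T-cell populations
#'
#' Each primed and reactivated T cell is independently removed with
#' probability `rho_d`. PVMs never die.
#'
#' @param population Population list as in [antigen_presentation()].
#' @param config A validated [ms_config()].
#' @return The surviving population.
#' @export
apply_death <- function(population, config) {
  n_p <- nrow(population$primed)
  if (n_p > 0) {
    keep <- stats::runif(n_p) >= config$rho_d
    population$primed <- population$primed[keep, , drop = FALSE]
  }
  n_r <- nrow(population$reactivated)
  if (n_r > 0) {
    keep <- stats::runif(n_r) >= config$rho_d
    population$reactivated <- population$reactivated[keep, , drop = FALSE]
  }
  population
}

#' Locate the nearest eligible myelin site for a reactivated T cell
#'
#' Finds the parenchyma site with remaining myelin health (state >= 2) nearest
#' in Euclidean distance to `pos`. Ties are broken deterministically toward
#' the lowest row, then the lowest column. Fully degraded (state 1) sites,
#' including all sites of apoptotic blocks, are never targets.
#'
#' @param pos Global `c(col, row)` of the cell.
#' @param state Integer matrix of myelin states, `lattice_height` rows by
#'   `parenchyma_width` columns (parenchyma column 1 is global column
#'   `blood_width + pvs_width + 1`).
#' @param config A validated [ms_config()].
#' @return A list with `target` (global `c(col, row)`), `distance`, and
#'   `s_bias` evaluated at `distance`; or `NULL` when no eligible myelin
#'   remains.
#' @export
nearest_eligible_myelin <- function(pos, state, config) {
  offset <- config$blood_width + config$pvs_width
  res <- nearest_eligible_cpp(state, as.integer(pos[1] - offset),
                              as.integer(pos[2]))
  if (is.null(res)) return(NULL)
  d <- res$distance
  list(target = c(col = res$col + offset, row = res$row),
       distance = d,
       s_bias = s_bias(d, beta = config$beta, k = config$k))
}
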