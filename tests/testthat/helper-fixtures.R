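# Small-domain configurations used across the suite. Geometry keeps the
# default 3-column blood / 5-column PVS structure but shrinks the parenchyma
# and height so a few hundred steps run in well under a second.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(lattice_width = 28L, parenchyma_width = 20L,
                   lattice_height = 40L, pvm_count = 10L, n_steps = 720L,
                   seed = 42L)
  do.call(ms_config, utils::modifyList(defaults, args))
}

# A myelin/oligo field pair with a single 5x5 block (one oligodendrocyte),
# for threshold harnesses.
one_block_config <- function(...) {
  args <- list(...)
  defaults <- list(lattice_width = 13L, blood_width = 3L, pvs_width = 5L,
                   parenchyma_width = 5L, lattice_height = 5L,
                   pvm_count = 5L, n_steps = 10L)
  do.call(ms_config, utils::modifyList(defaults, args))
}

# Independent brute-force oracle for the nearest eligible myelin site:
# full scan over the state matrix with the documented tie-break.
nearest_oracle <- function(state, px, row) {
  best <- NULL
  for (cc in seq_len(ncol(state))) {
    for (rr in seq_len(nrow(state))) {
      if (state[rr, cc] < 2) next
      d2 <- (cc - px)^2 + (rr - row)^2
      if (is.null(best) || d2 < best$d2 ||
          (d2 == best$d2 && (rr < best$row ||
                             (rr == best$row && cc < best$col)))) {
        best <- list(col = cc, row = rr, d2 = d2)
      }
    }
  }
  best
}
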