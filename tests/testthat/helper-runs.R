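# Desk-scale study conditions shared across test files, computed once per
# session and cached. Sizes are the package's desk profile: 32 molecules,
# 8 beads, 300 K, 1 ps equilibration + 3 ps production.

.run_cache <- new.env(parent = emptyenv())

desk_settings <- function(seed = 11, ...) {
  integrator_settings(n_b = 8L, T = 300, n_equil = 4000L, n_steps = 12000L,
                      seed = as.integer(seed), stride_est = 20L,
                      stride_frame = 80L, stride_vel = 8L, ...)
}

desk_run <- function(composition, seed = 11) {
  key <- paste0(composition, "_", seed)
  if (is.null(.run_cache[[key]])) {
    sys <- isotope_system(composition, 32)
    .run_cache[[key]] <- run_simulation(sys, desk_settings(seed))
  }
  .run_cache[[key]]
}

monomer_run <- function(composition, seed = 11) {
  key <- paste0("mono_", composition, "_", seed)
  if (is.null(.run_cache[[key]])) {
    sys <- isotope_system(composition, 1)
    box <- list(positions = array(pimdwater:::monomer_geometry(),
                                  dim = c(3, 3, 1, 1)), L = -1)
    st <- ring_polymer_state(box$positions, sys, 300, -1, 8, seed = seed)
    set <- desk_settings(seed, stride_frame = 200L)
    .run_cache[[key]] <- run_simulation(sys, set, state = st)
  }
  .run_cache[[key]]
}
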