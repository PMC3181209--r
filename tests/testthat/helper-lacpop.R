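# shared fixtures; heavyweight objects are computed lazily and cached for
# the whole test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

nominal_params <- function(I_ex = 0, ...) lac_params(I_ex = I_ex, ...)

# continuum attractor cell states at 24 uM, both modes
attractor_24 <- function(which, mode) {
  fixture(paste0("attr24_", which, "_", mode), function() {
    attractor_state(which, 24e3, nominal_params(24e3), mode = mode)
  })
}

# stationary geometry-only population averages at the nominal parameters
# (shared between the population-average and bistability acceptance tests)
geometry_averages <- function() {
  fixture("geom_avg", function() {
    set.seed(4242)
    geometry_only_population(nominal_params(), t_end = 600,
                             N_cellsmax = 500, n_batches = 20)
  })
}

# unstable (separatrix) total LacY concentration at 24 uM
separatrix_24 <- function() {
  fixture("sep24", function() {
    ss <- continuum_steady_states(24e3, nominal_params(24e3))
    if (sum(!ss$stable) == 1) ss$Y_total_nM[!ss$stable] else 84.5
  })
}
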