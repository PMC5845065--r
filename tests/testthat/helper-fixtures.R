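# Shared fixtures: the validation-case tube (10 m, thin-wall), materials
# stated via their wave speeds, and the PDMS card.

validation_tube <- function(L = 10) {
  tube_geometry(r = 0.01, e = 0.001, L = L, rho = 1000)
}

pdms_card <- function() zener_material(E0 = 2.114e6, E1 = 0.9365e6,
                                       tau = 0.2611)

carotid_tube <- function(L = 1) tube_geometry(r = 0.004, e = 0.0005, L = L,
                                              rho = 1000)

# cache of expensive method-of-lines runs shared across test files
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

fig2a_field <- function() cached_sim("fig2a", {
  g <- validation_tube()
  simulate_maxwell(maxwell_from_speed(5, g, tau = 2), g, pulse_spec(1, 0.2),
                   simulation_grid(N = 512))
})

fig2c_field <- function() cached_sim("fig2c", {
  g <- validation_tube()
  simulate_zener(zener_from_speeds(4, 3, g, tau = 2), g, pulse_spec(1, 0.2),
                 simulation_grid(N = 512))
})
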