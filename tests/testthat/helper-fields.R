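# Shared solved fields, computed lazily and memoized so several test files
# can reuse the same PDE solutions.
.field_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .field_cache)) {
    assign(key, force(expr), envir = .field_cache)
  }
  get(key, envir = .field_cache)
}

# coarse but wake-resolving configuration used by most solver tests
test_config <- function(...) {
  solver_config(n_r = 180, n_theta = 72, R_out = 60, ...)
}

# pure-diffusion configuration (radiation outer BC kicks in at Pe = 0)
diffusion_config <- function(R_out = 40) {
  solver_config(n_r = 200, n_theta = 24, R_out = R_out)
}

field_diffusion <- function() cached("diff0", {
  solve_transport(transport_problem(0, 0, rdf_preset("uniform")), diffusion_config())
})

field_screened <- function() cached("scr16", {
  solve_transport(transport_problem(0, 1.6, rdf_preset("uniform")), diffusion_config())
})

field_pe20_ref <- function() cached("pe20ref", {
  solve_transport(transport_problem(20, 0, rdf_preset("strong")), test_config())
})

field_pe20_strong <- function() cached("pe20strong", {
  solve_transport(transport_problem(20, 1.6, rdf_preset("strong")), test_config(),
                  grid = field_pe20_ref()$grid)
})

field_pe20_uniform <- function() cached("pe20uniform", {
  solve_transport(transport_problem(20, 1.6, rdf_preset("uniform")), test_config(),
                  grid = field_pe20_ref()$grid)
})
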