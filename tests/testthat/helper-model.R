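# Shared fixtures. Expensive simulations are computed once per test run and
# cached in this environment (testthat sources helpers once per session).

.lw_cache <- new.env(parent = emptyenv())

lw_cached <- function(key, expr) {
  if (!exists(key, envir = .lw_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .lw_cache)
  }
  get(key, envir = .lw_cache, inherits = FALSE)
}

ref_model <- function() lw_cached("model", reference_model())

# full blockade run at the scenario defaults (600 s settle + 2400 s block)
ref_block <- function() lw_cached("block", run_ouabain_block(ref_model()))

# kappa scan over the spec grid; table always returned
ref_scan <- function() lw_cached("scan", {
  estimate_blocking_rate(ref_model(), seq(0.30, 0.60, by = 0.01),
                         must_qualify = FALSE)
})

# a fast-settling variant: cellular volumes scaled down 100x so steady state
# is reached within a short integration (used for solver-equivalence checks)
fast_model <- function() lw_cached("fast", {
  cfg <- reference_config()
  for (i in seq_along(cfg$compartments)) {
    id <- cfg$compartments[[i]]$id
    if (id %in% c("syncytium", "marginal_cell", "hair_cell", "intrastrial_space")) {
      cfg$compartments[[i]]$volume_l <- cfg$compartments[[i]]$volume_l / 100
    }
  }
  lateral_wall_model(cfg)
})

expect_rhs_zero <- function(model, y, factors = NULL, tol = 1e-8) {
  dy <- assemble_rhs(model, factors)(y)
  expect_lt(max(abs(dy) / (1 + abs(y))), tol)
}
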