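# Shared fixtures, generated once per test run and cached. All synthetic
# cells used in tests are built at coarser sampling than the 0.1 ms
# default purely to keep the suite inside its runtime budget; the
# stated-world defaults themselves are exercised by the protocol- and
# cardinality-level tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fx_params <- function() ikrfit:::default_fixture_params()

# protocol set used by the fitting tests: step protocols at 1 ms,
# sine-wave protocol at 0.2 ms (runtime scaling, documented above)
fx_protocols <- function(seed = 11) {
  prot <- default_protocols(dt = 1)
  prot$Pr7 <- build_pr7(list(dt = 0.2))
  prot$Pr6 <- generate_ap_waveform(seed = seed, dt = 1)
  prot
}

# noiseless synthetic cell (shared by summarize/objective tests)
fx_cell_noiseless <- function() cached("cell_noiseless", function() {
  spec <- synthetic_spec(seed = 5, protocols = fx_protocols(5))
  spec$noise_sigma <- 0
  generate_cell(spec, id = "noiseless")
})

# noisy synthetic cell at the default (2% of Pr7 range) noise level
fx_cell_noisy <- function() cached("cell_noisy", function() {
  generate_cell(synthetic_spec(seed = 11, protocols = fx_protocols(11)),
                id = "noisy")
})

# analytic summary (model curves on the default grids) plus a simulated
# IV curve -- the exact input that method 1 inverts exactly
fx_analytic_summary <- function(params,
                                conditions = ionic_conditions()) {
  cell <- fx_cell_noiseless()
  s <- analytic_summary(params, summary_grids(cell$summary))
  pr5 <- cell$protocols$Pr5
  tr5 <- simulate_step(params, pr5, conditions)
  s$iv <- ikrfit:::analyse_pr5_iv(tr5, pr5)
  s
}
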