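# Small shared simulations; expensive default runs are computed once per
# test session and cached.

.sim_cache <- new.env(parent = emptyenv())

small_params <- function(depth = 2000L, ...) {
  sim_params(n_sites = 4L, depth = depth, ...)
}

# default-condition run used by the geometry acceptance checks:
# full 35-site reporter, >= 20,000 reads, fixed seed
default_run <- function() {
  if (is.null(.sim_cache$run)) {
    set.seed(20240)
    params <- sim_params(depth = 20000L)
    reporter <- build_reporter(params, name = "reporter")
    fragments <- simulate_biogenesis(reporter, params)
    reads <- simulate_library(fragments, params)
    proc <- process_library(reads, reporter, params)
    .sim_cache$run <- list(params = params, reporter = reporter,
                           fragments = fragments, reads = reads, proc = proc)
  }
  .sim_cache$run
}
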