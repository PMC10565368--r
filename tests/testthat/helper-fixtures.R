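# Shared fixtures: small simulated data sets built in code at test time.

small_cfg <- function(seed = 11, ...) {
  sim_config(n_sites = 6, n_stations = 2, n_periods = 52,
             periods_per_year = 26, n_species = 12, seed = seed, ...)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_cfg())
    cache
  }
})

# A tiny deterministic activity table for exact-arithmetic checks.
toy_activity <- function() {
  expand_tab <- expand.grid(site = c("A", "B"), station = 1:2,
                            species = c("sp1", "sp2"), period = 1:3,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expand_tab$count <- seq_len(nrow(expand_tab))
  expand_tab
}
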