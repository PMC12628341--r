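# Shared, lazily built benchmark systems (cached across test files).

.sys_cache <- new.env(parent = emptyenv())

cached_system <- function(key, builder) {
  if (is.null(.sys_cache[[key]])) .sys_cache[[key]] <- builder()
  .sys_cache[[key]]
}

h2_sto3g_sys <- function(r = 1.7) {
  cached_system(paste0("h2_sto3g_", r), function() {
    hydrogen_ucj_system(h2_geometry(r), "sto-3g")
  })
}

h2_631g_sys <- function(r = 1.2) {
  cached_system(paste0("h2_631g_", r), function() {
    hydrogen_ucj_system(h2_geometry(r), "6-31g")
  })
}

h4_square_sys <- function(side = 1.1) {
  cached_system(paste0("h4_", side), function() {
    hydrogen_ucj_system(h4_square_geometry(side), "sto-3g",
                        homo_orientation = "diagonal")
  })
}

synthetic_sys <- function(M, n_alpha = 1, n_beta = 1, seed = 1) {
  cached_system(sprintf("syn_%d_%d_%d_%d", M, n_alpha, n_beta, seed), function() {
    ucj_system(make_synthetic_integrals(M, n_alpha, n_beta, seed = seed))
  })
}
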