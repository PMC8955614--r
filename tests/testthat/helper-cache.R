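# Shared fixtures, built lazily and cached for the whole test run.
# All fixtures are generated in code under fixed seeds.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# Small chromatin pool at full resolution (used by the heavier end-to-end
# tests); built once.
test_pool <- function() {
  cached("pool", {
    set.seed(424201)
    chromatin_pool(2)
  })
}

# Coarse, fast chromatin pool for cheap pipeline plumbing tests.
test_pool_coarse <- function() {
  cached("pool_coarse", {
    set.seed(424202)
    chromatin_pool(1, segments_per_Mbp = 25)
  })
}

# Calibrated DSB intensity for the default surrogate and the shared pool.
test_k <- function() {
  cached("k", {
    set.seed(424203)
    calibrate_k(histories = 300, pool = test_pool())$k
  })
}

# One full-pipeline run per beam and contribution at 1 Gy, reused across
# acceptance blocks.  Histories chosen per beam so each run sees at least
# 2000 primary tracks while keeping complex-exchange statistics usable.
test_run <- function(ion, contribution, histories) {
  key <- paste("run", ion, contribution, histories, sep = "_")
  cached(key, {
    set.seed(424204 + match(ion, c("H", "He", "C", "O", "Si", "Fe")) * 101 +
               match(contribution, c("tot", "dir", "ind")))
    simulate_aberrations(reference_beam(ion), 1, histories, contribution,
                         break_params = break_model_params(k = test_k()),
                         pool = test_pool(),
                         keep_track_energies = TRUE)
  })
}
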