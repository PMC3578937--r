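# shared fixtures and memoized heavy computations (built once per test run)

sv_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = sv_test_cache, inherits = FALSE)) {
    assign(key, expr, envir = sv_test_cache)
  }
  get(key, envir = sv_test_cache)
}

# small constant-size single-population model (theta fixed by N and mu)
constant_model <- function(N = 1e4, mu = 2.5e-8, r = 0) {
  demographic_model(N_afr_cur = N, N_afr_anc = N, mu = mu, r = r)
}

# tiny deterministic alignment: 3 EU + 3 AF + outgroup, mixed column kinds
toy_alignment <- function() {
  region_alignment(
    sequences = c("ACGTAAGT-T",
                  "ACGTAATTNT",
                  "ACGTAATT-T",
                  "ACCTAATTTT",
                  "ACCTAATTTT",
                  "ACCTAATTTT",
                  "ACGTCATTTT"),
    labels = c("E1", "E2", "E3", "A1", "A2", "A3", "sech"),
    population = c("EU", "EU", "EU", "AF", "AF", "AF", "outgroup"),
    region_offset = 1000L
  )
}

table1_model <- function() demographic_model()

shared_background <- function() {
  cached("background", neutral_background(table1_model(), c(AF = 12, EU = 12),
                                          L = 20011, reps = 100, seed = 101))
}

# null calibration shared between the threshold-regime and self-consistency
# checks: 1,000 neutral replicates of the full region, European subset scored
shared_calibration <- function() {
  cached("calibration", calibrate_thresholds(
    table1_model(), c(AF = 12, EU = 12), L = 20011,
    background = shared_background(), reps = 1000, q = 0.95, seed = 202,
    statistics = c("clr", "omega"), clr_grid = 200, clr_alphas = 32,
    omega_grid = 200))
}

scan_settings <- list(grid_size = 200, n_alpha = 32)

# CLR scan of a site table with the shared background, at the shared settings
scan_region_clr <- function(tab, bg = shared_background()) {
  clr_scan(tab, bg, population = "EU", grid_size = scan_settings$grid_size,
           n_alpha = scan_settings$n_alpha)
}

# a plain sv_sim_replicate built from explicit haplotypes (for oracle tests)
fake_replicate <- function(genotypes, positions, pop, L) {
  samples <- setNames(integer(3), c("AF", "EU", "AS"))
  tb <- table(pop)
  samples[names(tb)] <- as.integer(tb)
  structure(list(positions = positions, genotypes = genotypes, pop = pop,
                 samples = samples, L = as.integer(L), seed = NULL),
            class = "sv_sim_replicate")
}
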