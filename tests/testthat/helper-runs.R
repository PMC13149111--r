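# Shared simulated pipeline runs, generated once per test session.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, cfg, n_scrambles = 10000L) {
  if (!exists(name, envir = .run_cache)) {
    sim <- simulate_dataset(cfg, outdir = file.path(tempdir(), name))
    report <- suppressMessages(run_pipeline(
      sim$paths[["sj"]], sim$paths[["genome"]], sim$paths[["annotation"]],
      outdir = file.path(tempdir(), paste0(name, "_out")),
      n_scrambles = n_scrambles, seed = 42L))
    assign(name, list(sim = sim, report = report), envir = .run_cache)
  }
  get(name, envir = .run_cache)
}

# generator defaults: 1000 canonical / 150 + 150 non-canonical
default_run <- function() cached_run("sim_default", sim_config(seed = 1L))

# 500 junctions per planted class, for classifier parameter recovery
recovery_run <- function() {
  cached_run("sim_recovery",
             sim_config(n_canonical = 500L, n_nc_u2like = 500L,
                        n_nc_random = 500L, seed = 1L))
}

# small run with edge-case junctions, for fast structural checks
small_run <- function() {
  cached_run("sim_small",
             sim_config(n_canonical = 80L, n_nc_u2like = 30L,
                        n_nc_random = 30L, n_edge = 2L, seed = 7L),
             n_scrambles = 1000L)
}

confusion_rates <- function(confusion) {
  rate <- function(cls) {
    u2 <- confusion[cls, "u2u12_like"]
    non <- confusion[cls, "non_u2u12_like"]
    u2 / (u2 + non)
  }
  list(u2like_rate = rate("nc_u2like"), random_rate = rate("nc_random"))
}
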