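# Shared fixtures, built in code and memoised for the session.

.fx <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, expr, envir = .fx)
  get(key, envir = .fx)
}

# small two-element strain pair used across finder/classifier/pipeline tests
fx_small_pair <- function() {
  with_cache("small_pair", {
    cfg <- sim_config(
      seed = 42,
      replicons = list(list(name = "chr", length = 120000L, gc = 0.61)),
      implants = list(
        implant_spec("GI", 13719L, 77L, 77L, "Arg-CCG", modules = c("ta_vapC_phd")),
        implant_spec("IME", 9000L, 89L, 18L, "Ser-CGA",
                     modules = c("virD2", "virD4"))))
    simulate_strain_pair(cfg)
  })
}

fx_small_scan <- function() {
  with_cache("small_scan", {
    sp <- fx_small_pair()
    scan_genome(sp$A, companion = sp$B)
  })
}

# the full study-geometry pair (7 implants, ~1 Mb) used by acceptance tests
fx_study_pair <- function(seed = 1L) {
  with_cache(paste0("study_pair_", seed), {
    cfg <- sim_config(seed = seed,
                      replicons = list(list(name = "chr", length = 400000L, gc = 0.61)),
                      implants = study_implants())
    simulate_strain_pair(cfg)
  })
}

fx_study_scan <- function(seed = 1L) {
  with_cache(paste0("study_scan_", seed), {
    sp <- fx_study_pair(seed)
    scan_genome(sp$A, params = dr_params(min_len = 10L), companion = sp$B)
  })
}

# random protein helper for oracle tests
fx_random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE), collapse = "")
}
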