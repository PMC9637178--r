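# Shared fixtures. The reference dataset (seed 42, 10 Mb chromosome, 300
# peaks, 50 loops of 25-80 PETs, 200k background PETs, alpha = 1) is the one
# the acceptance criteria are stated against; it is generated once per test
# run and cached. Module tests use a lighter configuration.

.fix_cache <- new.env(parent = emptyenv())

cache_get <- function(key, maker) {
  if (!exists(key, .fix_cache)) assign(key, maker(), .fix_cache)
  get(key, .fix_cache)
}

# reference fixture (acceptance criteria scale)
ref_fixture <- function(seed = 42L, fold_changes = NULL, dup_rate = 0,
                        linker_rate = 1) {
  key <- paste("ref", seed, paste(fold_changes, collapse = ","), dup_rate,
               linker_rate, sep = "|")
  cache_get(key, function() {
    cfg <- sim_config(seed = seed, fold_changes = fold_changes,
                      dup_rate = dup_rate, linker_rate = linker_rate)
    simulate_dataset(cfg)
  })
}

ref_index <- function(seed = 42L) {
  key <- paste0("refidx|", seed)
  cache_get(key, function() {
    sim <- ref_fixture(seed = seed)
    pet_index(dedup_pets(sim$pets_a),
              chrom_lengths = c(chrS = sim$config$chrom_length))
  })
}

ref_loops <- function(seed = 42L) {
  key <- paste0("refloops|", seed)
  cache_get(key, function() {
    call_loops(ref_index(seed), eps_list = c(200, 500, 1000, 2000),
               minPts = 10L, cut = 5000, max_cut = Inf)
  })
}

# light fixture for module tests: 2 Mb, 12 loops, 20k background PETs
small_fixture <- function(seed = 7L, ...) {
  dots <- list(...)
  key <- paste("small", seed,
               paste(names(dots), vapply(dots, paste, "", collapse = ","),
                     sep = "=", collapse = ";"), sep = "|")
  cache_get(key, function() {
    cfg <- sim_config(chrom_length = 2e6, n_peaks = 80L, n_loops = 12L,
                      pets_per_loop = c(30L, 60L),
                      n_background_pets = 20000L, seed = seed, ...)
    simulate_dataset(cfg)
  })
}

small_index <- function(seed = 7L) {
  key <- paste0("smallidx|", seed)
  cache_get(key, function() {
    sim <- small_fixture(seed = seed)
    pet_index(dedup_pets(sim$pets_a),
              chrom_lengths = c(chrS = sim$config$chrom_length))
  })
}

# match called loops against truth anchors with 5 kb extension
truth_as_loops <- function(sim) {
  tl <- sim$truth$loops
  data.table::data.table(
    chrom = tl$chrom, start1 = tl$start1, end1 = tl$end1,
    start2 = tl$start2, end2 = tl$end2, pet_count = tl$true_count,
    p_value = 0, enrichment_score = NA_real_,
    distance = tl$c2 - tl$c1, id = tl$id)
}
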