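# Shared fixtures, memoized across test files (helpers are sourced once per
# test run). The "standard" fixture is the full-size synthetic study used by
# the criteria-recovery checks; the "small" fixture keeps unit tests fast.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# standard fixture: defaults (20 pass hairpins, 5 decoys per criterion
# class, 1e5 reads per library, seed 1), annotated and mapped
std_fixture <- function() {
  memo("std", {
    cfg <- sim_config(seed = 1)
    ref <- generate_reference(cfg)
    ct <- simulate_libraries(ref, cfg)
    lf <- length_filter(ct)
    hits <- map_exact(lf, ref$genome)
    ann <- classify(lf, hits, ref$references, ref$known_mirnas,
                    cds = ref$annotations)
    list(cfg = cfg, ref = ref, ct = ct, lf = lf, hits = hits, ann = ann)
  })
}

# discovery results on the standard fixture
std_discovery <- function() {
  memo("std_disc", {
    fx <- std_fixture()
    libs <- attr(fx$ann, "library_ids")
    cnt <- as.matrix(fx$ann[, libs])
    pool <- which(fx$ann$category == "other" & !fx$ann$cds_overlap &
                  apply(cnt, 1, max) >= 4)
    cands <- evaluate_candidates(fx$ann$sequence[pool],
                                 cnt[pool, , drop = FALSE], fx$hits,
                                 fx$ref$genome,
                                 all_reads = fx$ann$sequence)
    list(cands = cands, catalog = name_and_merge(cands))
  })
}

# small fixture for fast unit tests
small_fixture <- function() {
  memo("small", {
    cfg <- sim_config(genome_length = 60000L, n_known_mirnas = 3L,
                      n_novel_mirnas = 5L, n_decoy_hairpins = 4L,
                      reads_per_library = 8000L, n_transcripts = 8L,
                      seed = 11)
    ref <- generate_reference(cfg)
    ct <- simulate_libraries(ref, cfg)
    txp <- simulate_transcriptome(ref, cfg)
    tags <- simulate_degradome(txp, cfg)
    list(cfg = cfg, ref = ref, ct = ct, txp = txp, tags = tags)
  })
}
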