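small_cfg <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 60000L, n_known_mirnas = 3L,
         n_novel_mirnas = 5L, n_decoy_hairpins = 4L,
         reads_per_library = 8000L, n_transcripts = 8L, seed = 11),
    list(...))
  do.call(sim_config, args)
}

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(noise_fraction = 1.2), "fractions")
  expect_error(sim_config(size_class_mix = c("21" = 0.5, "24" = 0.5,
                                             other = 0.5)), "sum to 1")
  expect_error(sim_config(reads_per_library = 0), "reads_per_library")
  expect_error(sim_config(genome_length = 5000L, n_novel_mirnas = 50L),
               "genome too short")
})

test_that("the whole simulation is deterministic in the seed", {
  cfg <- small_cfg()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(unclass(r1$genome), unclass(r2$genome))
  expect_identical(r1$registry$mirnas, r2$registry$mirnas)
  expect_identical(r1$registry$planted_tpm, r2$registry$planted_tpm)
  c1 <- simulate_libraries(r1, cfg)
  c2 <- simulate_libraries(r2, cfg)
  expect_identical(c1$sequence, c2$sequence)
  expect_identical(c1$counts, c2$counts)
  t1 <- simulate_transcriptome(r1, cfg)
  t2 <- simulate_transcriptome(r2, cfg)
  expect_identical(unclass(t1$transcripts), unclass(t2$transcripts))
  expect_identical(t1$registry$planted_sites, t2$registry$planted_sites)
  d1 <- simulate_degradome(t1, cfg)
  d2 <- simulate_degradome(t2, cfg)
  expect_identical(d1, d2)
})

test_that("an empty novel/decoy request yields an empty novel registry", {
  cfg <- sim_config(genome_length = 40000L, n_known_mirnas = 3L,
                    n_novel_mirnas = 0L, n_decoy_hairpins = 0L,
                    reads_per_library = 2000L, seed = 2)
  ref <- generate_reference(cfg)
  expect_identical(sum(ref$registry$mirnas$category == "novel"), 0L)
  expect_identical(sum(ref$registry$mirnas$category == "decoy"), 0L)
})

test_that("planted hairpins fold back by an independent Nussinov check", {
  fx <- small_fixture()
  reg <- fx$ref$registry$mirnas
  g <- unclass(fx$ref$genome)[["chr1"]]
  pass_rows <- reg[reg$category == "novel", ]
  for (i in seq_len(nrow(pass_rows))) {
    r <- pass_rows[i, ]
    hp <- substr(g, r$hp_start + 1, r$hp_end)
    if (r$strand == "-") hp <- revcomp(hp)
    expect_gte(oracle_max_pairs(hp), 15)
  }
})

test_that("libraries conserve reads and honour fixed-count planting", {
  fx <- small_fixture()
  expect_equal(unname(colSums(fx$ct$counts)),
               rep(fx$cfg$reads_per_library, 3))
  reg <- fx$ref$registry$mirnas
  c3 <- reg[reg$category == "decoy" & reg$decoy_class == 3, ]
  for (m in c3$mature) {
    expect_identical(as.integer(fx$ct$counts[fx$ct$sequence == m, ]),
                     c(5L, 5L, 5L))
  }
  stars <- reg$star[reg$star_planted]
  expect_true(all(stars %in% fx$ct$sequence))
  star_counts <- fx$ct$counts[match(stars, fx$ct$sequence), , drop = FALSE]
  expect_true(all(star_counts <= 5))  # stars can never satisfy criterion 3
})

test_that("differential_fraction = 0 plants no >1.3-fold profile", {
  cfg <- small_cfg(differential_fraction = 0)
  ref <- generate_reference(cfg)
  tpm <- ref$registry$planted_tpm
  nz <- tpm[rowSums(tpm) > 0, , drop = FALSE]
  ratios <- apply(nz, 1, function(v) max(v) / min(v))
  expect_true(all(ratios <= 1.3 + 1e-9))
  expect_false(any(ref$registry$mirnas$differential))
})

test_that("differential profiles exceed 2-fold, others stay within 1.3", {
  fx <- small_fixture()
  reg <- fx$ref$registry
  tpm <- reg$planted_tpm
  for (i in seq_len(nrow(reg$mirnas))) {
    v <- tpm[i, ]
    if (all(v == 0)) next
    r <- max(v) / min(v)
    if (reg$mirnas$differential[i]) expect_gt(r, 2) else
      expect_lte(r, 1.3 + 1e-9)
  }
})

test_that("realized TPM tracks intended TPM within three standard errors", {
  cfg <- small_cfg(reads_per_library = 100000L)
  ref <- generate_reference(cfg)
  ct <- simulate_libraries(ref, cfg)
  tpm <- compute_tpm(ct)
  reg <- ref$registry
  N <- cfg$reads_per_library
  for (i in which(rowSums(reg$planted_tpm) > 0)) {
    m <- reg$mirnas$mature[i]
    for (j in 1:3) {
      intended <- reg$planted_tpm[i, j]
      mu <- intended * N / 1e6
      se_tpm <- sqrt(mu) / N * 1e6
      realized <- if (m %in% ct$sequence) tpm[match(m, ct$sequence), j] else 0
      expect_lt(abs(realized - intended), 3 * se_tpm + 1e-9)
    }
  }
})

test_that("pure-noise libraries avoid every planted precursor", {
  cfg <- small_cfg(noise_fraction = 1)
  ref <- generate_reference(cfg)
  ct <- simulate_libraries(ref, cfg)
  hits <- map_exact(ct, ref$genome)
  reg <- ref$registry$mirnas
  overlaps <- vapply(seq_len(nrow(hits)), function(i) {
    any(hits$start[i] < reg$hp_end & hits$end[i] > reg$hp_start)
  }, logical(1))
  expect_false(any(overlaps))
})

test_that("perfect site patterns are exact reverse complements", {
  fx <- small_fixture()
  sites <- fx$txp$registry$planted_sites
  txs <- unclass(fx$txp$transcripts)
  perf <- sites[sites$pattern == "perfect", ]
  expect_gt(nrow(perf), 0)
  for (i in seq_len(nrow(perf))) {
    s <- perf[i, ]
    expect_identical(substr(txs[[s$transcript]], s$start + 1, s$end),
                     revcomp(s$mature))
  }
  # a planted mm@10 site is intended to fail the position-10/11 rule
  mm10 <- sites[sites$pattern == "mm@10", ]
  expect_true(all(!mm10$i4))
  expect_error(germir:::.parse_pattern("mm@40", 21), "outside")
  expect_error(germir:::.parse_pattern("zz@3", 21), "unparseable")
})

test_that("degradome tags concentrate at the canonical slice as configured", {
  fx <- small_fixture()
  sites <- fx$txp$registry$planted_sites
  confirmed <- sites[sites$intended_pass, ]
  expect_gt(nrow(confirmed), 0)

  # signal_fraction = 1: every tag at the slice position
  cfg1 <- small_cfg(degradome_signal_fraction = 1)
  ref1 <- generate_reference(cfg1)
  t1 <- simulate_transcriptome(ref1, cfg1)
  d1 <- simulate_degradome(t1, cfg1)
  s1 <- t1$registry$planted_sites
  s1 <- s1[s1$intended_pass, ]
  slice_pos <- paste(s1$transcript, s1$cleavage_position + 1L)
  expect_true(all(paste(d1$transcript, d1$pos) %in% slice_pos))

  # signal_fraction = 0: uniform tags (chi-square goodness of fit)
  cfg0 <- small_cfg(degradome_signal_fraction = 0, tags_per_site = 10000L)
  ref0 <- generate_reference(cfg0)
  t0 <- simulate_transcriptome(ref0, cfg0)
  d0 <- simulate_degradome(t0, cfg0)
  tx <- d0$transcript[which.max(tapply(d0$count, d0$transcript, sum))]
  tt <- d0[d0$transcript == tx, ]
  L <- nchar(unclass(t0$transcripts)[[tx]])
  counts <- integer(L)
  counts[tt$pos + 1] <- tt$count
  nbin <- 10L
  bins <- cut(seq_len(L), nbin)
  gof <- suppressWarnings(stats::chisq.test(tapply(counts, bins, sum)))
  expect_gt(gof$p.value, 0.01)

  # signal_fraction = 0.5 with 200 tags: slice count inside binomial 99% CI
  d05 <- fx$tags  # fixture uses the 0.5 default
  s05 <- sites[sites$intended_pass, ][1, ]
  tt <- d05[d05$transcript == s05$transcript, ]
  at <- sum(tt$count[tt$pos %in% (s05$cleavage_position + 0:1)])
  ci <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(at, ci[1])
  expect_lte(at, ci[2])
})
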