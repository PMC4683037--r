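test_that("duplex alignment classifies every position against a manual checker", {
  m <- "TGGAAGCTAGCGTTGCACTGA"
  a <- align_duplex(m, revcomp(m))
  expect_true(all(a$states == "match"))
  expect_equal(a$mismatch_score, 0)
  expect_equal(a$duplex_energy, a$perfect_energy)

  # one G:U pair scores 0.5
  st <- rep("match", 21); st[5] <- "GU"
  rd <- realize_duplex(st, seed = 1)
  a2 <- align_duplex(rd$mirna, rd$site)
  expect_identical(a2$states, st)
  expect_equal(a2$mismatch_score, 0.5)

  # random pairs against a position-by-position manual checker
  set.seed(33)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in 1:20) {
    mi <- random_seq(21, 0.5)
    site <- random_seq(21, 0.5)
    a3 <- align_duplex(mi, site)
    mv <- strsplit(mi, "")[[1]]
    sv <- rev(strsplit(site, "")[[1]])
    manual <- vapply(1:21, function(i) {
      if (comp[[mv[i]]] == sv[i]) "match"
      else if ((mv[i] == "G" && sv[i] == "T") ||
               (mv[i] == "T" && sv[i] == "G")) "GU"
      else "mismatch"
    }, character(1))
    expect_identical(a3$states, manual)
  }
  expect_error(align_duplex("ACGT", "ACG"), "equal length")
})

test_that("the six rules behave on canonical cases", {
  perfect <- rep("match", 21)
  mk <- function(st) {
    rd <- realize_duplex(st, seed = 2)
    align_duplex(rd$mirna, rd$site)
  }
  v <- score_rules(mk(perfect))
  expect_true(v$pass)

  at10 <- perfect; at10[10] <- "mismatch"
  v <- score_rules(mk(at10))
  expect_false(v$r4)       # perfect match required at positions 10-11
  expect_false(v$pass)

  scatter5 <- perfect; scatter5[c(1, 4, 8, 14, 18)] <- "mismatch"
  v <- score_rules(mk(scatter5))
  expect_false(v$r1)       # 5 > 4 mismatches
})

test_that("score_rules matches the brute-force oracle on enumerated states", {
  set.seed(44)
  for (k in 1:400) {
    st <- sample(c("match", "GU", "mismatch"), 21, replace = TRUE,
                 prob = c(0.7, 0.15, 0.15))
    rd <- realize_duplex(st)
    a <- align_duplex(rd$mirna, rd$site)
    got <- score_rules(a)
    want <- oracle_rules(a$states, a$duplex_energy, a$perfect_energy)
    expect_identical(unlist(got), want)
  }
})

test_that("duplex energy degrades monotonically with added mismatches", {
  set.seed(55)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gu <- c(G = "T", T = "G")
  for (k in 1:5) {
    m <- random_seq(21, 0.5)
    site <- strsplit(revcomp(m), "")[[1]]
    prev_ratio <- 1
    for (p in sample(21)[1:10]) {
      b <- substr(m, p, p)
      bad <- setdiff(c("A", "C", "G", "T"),
                     c(comp[[b]], if (b %in% names(gu)) gu[[b]]))
      site[21 - p + 1] <- bad[1]
      a <- align_duplex(m, paste(site, collapse = ""))
      ratio <- duplex_energy(a)$ratio
      expect_lte(ratio, prev_ratio + 1e-9)
      prev_ratio <- ratio
    }
  }
  # all-mismatch duplex carries no stabilizing energy
  allmm <- realize_duplex(rep("mismatch", 21), seed = 3)
  a <- align_duplex(allmm$mirna, allmm$site)
  expect_equal(duplex_energy(a)$ratio, 0)
  expect_false(score_rules(a)$r6)
})

test_that("monotonicity under mismatches holds per fixed miRNA", {
  # replacing matches by mismatches one at a time never raises the ratio
  set.seed(66)
  m <- random_seq(21, 0.5)
  site <- strsplit(revcomp(m), "")[[1]]
  ratios <- numeric(0)
  for (p in c(5, 10, 15)) {
    idx <- 21 - p + 1
    b <- substr(m, p, p)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", b), c(G = "T", T = "G")[b]))
    site[idx] <- bad[1]
    a <- align_duplex(m, paste(site, collapse = ""))
    ratios <- c(ratios, duplex_energy(a)$ratio)
  }
  expect_true(all(diff(ratios) <= 1e-9))
})

test_that("transcript scanning finds planted sites and equals brute force", {
  set.seed(77)
  m <- c(mir1 = random_seq(21, 0.5))
  tx <- random_seq(200, 0.45)
  pos <- 80L
  substr(tx, pos + 1, pos + 21) <- revcomp(m[[1]])
  sites <- scan_transcripts(m, c(t1 = tx))
  expect_true(any(sites$start == pos & sites$transcript == "t1"))
  hit <- sites[sites$start == pos, ]
  expect_true(hit$pass)
  expect_identical(hit$cleavage_position, pos + 21L - 11L)

  # exhaustive-window equivalence on a toy transcript
  toy <- random_seq(60, 0.5)
  for (k in 1:10) {
    mi <- c(q = random_seq(21, 0.5))
    all_w <- scan_transcripts(mi, c(t = toy), all_windows = TRUE)
    expect_identical(nrow(all_w), 40L)
    for (w in seq_len(nrow(all_w))) {
      a <- align_duplex(mi[[1]], substr(toy, all_w$start[w] + 1,
                                        all_w$start[w] + 21))
      want <- score_rules(a)
      expect_identical(unname(unlist(all_w[w, c("r1", "r2", "r3", "r4",
                                                "r5", "r6", "pass")])),
                       unname(unlist(want)))
      expect_equal(all_w$energy[w], a$duplex_energy)
    }
  }
})

test_that("scanning is invariant under transcript order", {
  set.seed(88)
  m <- c(mir = random_seq(21, 0.5))
  txs <- c(t1 = random_seq(120, 0.5), t2 = random_seq(120, 0.5))
  substr(txs[["t1"]], 21, 41) <- revcomp(m[[1]])
  s1 <- scan_transcripts(m, txs, all_windows = TRUE)
  s2 <- scan_transcripts(m, rev(txs), all_windows = TRUE)
  s2 <- s2[order(match(s2$transcript, names(txs)), s2$start), ]
  rownames(s1) <- rownames(s2) <- NULL
  expect_identical(s1, s2)
})

test_that("planted site patterns score exactly as intended", {
  fx <- small_fixture()
  reg <- fx$txp$registry
  sites <- reg$planted_sites
  txs <- unclass(fx$txp$transcripts)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    window <- substr(txs[[s$transcript]], s$start + 1, s$end)
    a <- align_duplex(s$mature, window)
    v <- score_rules(a)
    expect_identical(unname(unlist(v)),
                     unname(unlist(s[c("i1", "i2", "i3", "i4", "i5", "i6",
                                       "intended_pass")])),
                     info = paste("pattern", s$pattern))
  }
})

test_that("degradome confirmation integrates tag evidence correctly", {
  site <- list(transcript = "t1", cleavage_position = 100L)
  # extreme signal
  tags <- data.frame(transcript = "t1", pos = c(100L, 101L),
                     count = c(60L, 40L))
  ev <- degradome_confirm(site, tags, transcript_length = 500)
  expect_identical(ev$tags_at_slice, 100L)
  expect_lt(ev$p_value, 1e-10)
  expect_true(ev$confirmed)
  # uniform tags, none at the slice
  tags2 <- data.frame(transcript = "t1", pos = seq(0, 490, by = 10),
                      count = 1L)
  tags2 <- tags2[!tags2$pos %in% c(100L, 101L), ]
  ev2 <- degradome_confirm(site, tags2, 500)
  expect_equal(ev2$p_value, 1)
  expect_false(ev2$confirmed)
  # no tags on the transcript: undefined evidence
  ev3 <- degradome_confirm(site, tags[0, ], 500)
  expect_false(ev3$confirmed)
  expect_true(is.na(ev3$p_value))
})

test_that("method overlap counts equal brute-force set algebra", {
  a <- data.frame(mirna = c("m1", "m2", "m3"), transcript = c("t1", "t2", "t3"))
  b <- data.frame(mirna = c("m1", "m2"), transcript = c("t1", "t2"))
  ve <- overlap_methods(list(A = a, B = b))
  expect_identical(ve$count[ve$methods == "A&B"], 2L)
  expect_identical(ve$count[ve$methods == "A"], 1L)
  expect_identical(ve$count[ve$methods == "B"], 0L)
  # identical sets
  ve2 <- overlap_methods(list(A = a, B = a))
  expect_identical(ve2$count[ve2$methods == "A&B"], 3L)
  expect_identical(sum(ve2$count), 3L)
  # random sets vs brute force over three methods
  set.seed(99)
  keys <- paste0("m", 1:20, "|t", 1:20)
  sets <- lapply(1:3, function(i) sample(keys, sample(5:15, 1)))
  names(sets) <- c("X", "Y", "Z")
  ve3 <- overlap_methods(sets)
  total <- length(unique(unlist(sets)))
  expect_identical(sum(ve3$count), total)  # totals conserved
  # spot check one exclusive region
  only_x <- setdiff(sets$X, union(sets$Y, sets$Z))
  expect_identical(ve3$count[ve3$methods == "X"], length(only_x))
})

test_that("relaxing rule thresholds never shrinks the passing set", {
  set.seed(101)
  m <- c(mir = random_seq(21, 0.5))
  tx <- c(t = random_seq(400, 0.45))
  strict <- scan_transcripts(m, tx)
  th <- target_rule_defaults()
  th$max_mismatch <- 6
  th$max_seed_score <- 3.5
  th$min_energy_fraction <- 0.5
  relaxed <- scan_transcripts(m, tx, thresholds = th)
  key <- function(s) paste(s$transcript, s$start)
  expect_true(all(key(strict) %in% key(relaxed)))
})
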