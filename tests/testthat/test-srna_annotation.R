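make_ct <- function(seqs, counts = NULL, lib = "L1") {
  n <- length(seqs)
  if (is.null(counts)) counts <- rep(1L, n)
  count_table(seqs, matrix(counts, ncol = 1, dimnames = list(NULL, lib)),
              clean_totals = sum(counts))
}

test_that("length filter keeps the inclusive 18-30 nt window", {
  seqs <- vapply(c(17, 18, 25, 30, 31), function(n) strrep("A", n) ,
                 character(1))
  seqs <- paste0(seqs, c("C", "G", "T", "AC", "GT"))  # make unique
  seqs <- c(strrep("C", 17), strrep("C", 18), strrep("C", 25),
            strrep("C", 30), strrep("C", 31))
  lf <- length_filter(make_ct(seqs))
  expect_setequal(nchar(lf$sequence), c(18, 25, 30))
  # brute-force oracle on random lengths
  set.seed(9)
  rand <- unique(vapply(sample(10:40, 60, TRUE), random_seq, character(1)))
  lf2 <- length_filter(make_ct(rand), 18, 30)
  expect_setequal(lf2$sequence, rand[nchar(rand) >= 18 & nchar(rand) <= 30])
})

test_that("exact mapping reports both strands with forward coordinates", {
  set.seed(5)
  g <- random_seq(2000, 0.5)
  genome <- seq_set(c(chr1 = g))
  plus_read <- substr(g, 101, 121)
  minus_read <- revcomp(substr(g, 51, 74))
  hits <- map_exact(c(plus_read, minus_read), genome)
  hp <- hits[hits$sequence == plus_read, ]
  expect_true(any(hp$start == 100 & hp$end == 121 & hp$strand == "+"))
  hm <- hits[hits$sequence == minus_read, ]
  expect_true(any(hm$start == 50 & hm$end == 74 & hm$strand == "-"))
})

test_that("mapping equals the naive all-positions scan on random reads", {
  set.seed(6)
  g <- random_seq(10000, 0.5)
  genome <- seq_set(c(chr1 = g))
  reads <- unique(c(
    vapply(1:30, function(i) {            # planted (multi-hit possible)
      p <- sample(1:(10000 - 21), 1)
      substr(g, p, p + 20)
    }, character(1)),
    vapply(1:20, function(i) random_seq(21, 0.5), character(1))
  ))
  hits <- map_exact(reads, genome)
  for (r in reads) {
    got <- hits[hits$sequence == r, c("start", "end", "strand")]
    want <- oracle_scan(r, g)
    got <- got[order(got$start, got$strand), ]
    want <- want[order(want$start, want$strand), ]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("reads containing N map nowhere", {
  g <- seq_set(c(chr1 = strrep("ACGT", 100)))
  hits <- map_exact("ACGTNACGTACGTACGTACG", g)
  expect_identical(nrow(hits), 0L)
})

test_that("classification follows precedence, Hamming and substring rules", {
  set.seed(7)
  rrna <- random_seq(200, 0.5)
  cat_mir <- "TGGATTGAAGGGAGCTCTACA"
  genome_str <- paste0(random_seq(100, 0.5), rrna, random_seq(50, 0.5),
                       cat_mir, random_seq(100, 0.5))
  genome <- seq_set(c(chr1 = genome_str))
  refs <- list(rRNA = seq_set(c(r1 = rrna)),
               tRNA = seq_set(c(t1 = random_seq(80, 0.5))),
               snoRNA = seq_set(c(sn1 = random_seq(100, 0.5))),
               snRNA = seq_set(c(u1 = random_seq(100, 0.5))))
  known <- seq_set(c(mir1 = cat_mir))

  exact <- cat_mir
  two_mm <- paste0("AC", substr(cat_mir, 3, 21))      # Hamming 2 at most
  rrna_frag <- substr(rrna, 11, 34)
  unmapped <- random_seq(22, 0.5)
  ct <- make_ct(c(exact, two_mm, rrna_frag, unmapped))
  hits <- map_exact(ct, genome)
  ann <- classify(ct, hits, refs, known)
  got <- setNames(ann$category, ann$sequence)
  expect_identical(unname(got[exact]), "known_miRNA")
  expect_identical(unname(got[rrna_frag]), "rRNA")
  expect_true(is.na(got[unmapped]))    # category only for mapped reads
  # Hamming 2 matches the catalog but the variant is not in the genome
  expect_true(is.na(got[two_mm]))

  # a read at Hamming distance 3 from the catalog but inside the rRNA gene
  # falls through to rRNA
  frag <- substr(rrna, 50, 70)
  ct2 <- make_ct(frag)
  ann2 <- classify(ct2, map_exact(ct2, genome), refs, known)
  expect_identical(ann2$category, "rRNA")

  expect_error(classify(ct, hits, refs["rRNA"], known), "missing reference")
})

test_that("classification is order-independent and a clean partition", {
  fx <- small_fixture()
  ann <- classify(length_filter(fx$ct),
                  map_exact(length_filter(fx$ct), fx$ref$genome),
                  fx$ref$references, fx$ref$known_mirnas,
                  cds = fx$ref$annotations)
  # partition: every mapped read has exactly one category
  mapped <- !is.na(ann$category)
  expect_true(all(ann$category[mapped] %in%
    c("known_miRNA", "rRNA", "tRNA", "snoRNA", "snRNA", "other")))
  # order independence
  ct <- length_filter(fx$ct)
  perm <- sample(seq_along(ct$sequence))
  ct2 <- count_table(ct$sequence[perm], ct$counts[perm, , drop = FALSE],
                     ct$clean_totals)
  ann2 <- classify(ct2, map_exact(ct2, fx$ref$genome), fx$ref$references,
                   fx$ref$known_mirnas, cds = fx$ref$annotations)
  m <- match(ann$sequence, ann2$sequence)
  expect_identical(ann$category, ann2$category[m])
})

test_that("planted categories are recovered perfectly on synthetic data", {
  fx <- small_fixture()
  lf <- length_filter(fx$ct)
  ann <- classify(lf, map_exact(lf, fx$ref$genome), fx$ref$references,
                  fx$ref$known_mirnas, cds = fx$ref$annotations)
  reg <- fx$ref$registry$mirnas
  known_seqs <- reg$mature[reg$category == "known"]
  got <- ann$category[match(known_seqs, ann$sequence)]
  expect_true(all(got == "known_miRNA"))
})

test_that("summary percentages follow the reporting conventions", {
  # printed-cell conventions: category % of the non-coding total (reads),
  # unique % of the same category's reads count, half-up one decimal
  expect_equal(library_stats_percent(22332607, 27075645), 82.5)
  expect_equal(library_stats_percent(1679, 5956), 28.2)
  expect_equal(library_stats_percent(0, 0), 0)        # no division error
  expect_equal(library_stats_percent(1, 800), 0.1)    # 0.125 rounds half-up
  expect_equal(round_half_up(0.25, 1), 0.3)    # half-up, not half-even
  expect_equal(round_half_up(86.25, 1), 86.3)
})

test_that("classification summary is internally consistent", {
  fx <- small_fixture()
  lf <- length_filter(fx$ct)
  ann <- classify(lf, map_exact(lf, fx$ref$genome), fx$ref$references,
                  fx$ref$known_mirnas, cds = fx$ref$annotations)
  s <- summarize_classification(ann)
  for (lib in unique(s$library)) {
    sl <- s[s$library == lib, ]
    cats <- sl[sl$row %in% c("known_miRNA", "rRNA", "tRNA", "snoRNA",
                             "snRNA", "other"), ]
    nc <- sl$reads[sl$row == "non-coding total"]
    expect_identical(sum(cats$reads), nc)   # category sums = non-coding
    # percentages recompute from the table's own counts
    expect_equal(cats$reads_pct, library_stats_percent(cats$reads, nc))
    expect_equal(cats$unique_pct, library_stats_percent(cats$unique, cats$reads))
  }
})
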