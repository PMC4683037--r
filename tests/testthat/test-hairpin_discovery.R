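test_that("window extraction flanks, clips and orients correctly", {
  set.seed(21)
  g <- random_seq(5000, 0.5)
  genome <- seq_set(c(chr1 = g))
  win <- extract_window(list(chrom = "chr1", start = 1000L, end = 1021L,
                             strand = "+"), genome)
  expect_identical(nchar(win$sequence), 321L)  # 150 + 21 + 150
  expect_identical(win$mature_offset, 150L)
  expect_identical(substr(win$sequence, 151, 171), substr(g, 1001, 1021))

  clipped <- extract_window(list(chrom = "chr1", start = 10L, end = 31L,
                                 strand = "+"), genome)
  expect_identical(clipped$window_start, 0L)
  expect_identical(clipped$mature_offset, 10L)

  minus <- extract_window(list(chrom = "chr1", start = 1000L, end = 1021L,
                               strand = "-"), genome)
  # double reverse-complement recovers the plus-strand slice
  expect_identical(revcomp(minus$sequence),
                   substr(g, 1000 - 150 + 1, 1021 + 150))
  m0 <- minus$mature_offset
  expect_identical(substr(minus$sequence, m0 + 1, m0 + 21),
                   revcomp(substr(g, 1001, 1021)))
})

test_that("star detection recovers the 2-nt-shifted reverse complement on a perfect stem", {
  mature <- "TGGAAGCTAGCGTTGCACTGA"
  hp <- paste0(mature, "GCAATC", "AAACAAA", revcomp(paste0(mature, "GCAATC")), "GT")
  st <- fold(hp)
  pt <- pair_table(st$dotbracket)
  fs <- find_star(hp, pt, 1, nchar(mature))
  # perfect duplex geometry: star = reverse complement shifted by 2 nt
  expect_identical(fs$star,
                   paste0(substr(revcomp(mature), 3, nchar(mature)), "GT"))
  expect_identical(nchar(fs$star), nchar(mature))
  expect_false(fs$star_observed)
  expect_true(find_star(hp, pt, 1, nchar(mature), reads = fs$star)$star_observed)
})

test_that("no star is defined for a mostly-unpaired mature", {
  hp <- paste0(strrep("GC", 10), strrep("A", 30), strrep("GC", 10))
  st <- fold(hp)
  pt <- pair_table(st$dotbracket)
  # a "mature" sitting inside the unpaired loop
  fs <- find_star(hp, pt, 25, 45)
  expect_true(is.na(fs$star))
})

test_that("the four novel-miRNA criteria implement their boundaries", {
  base <- list(mature_len = 21, precursor_len = 80, foldback = TRUE,
               mfei = 1.2, star_observed = FALSE)
  v <- apply_novel_criteria(21, 80, TRUE, c(5, 5, 5), 1.2, FALSE)
  expect_false(v$c3)   # "greater than five": 5 is not enough
  expect_false(v$pass)
  v <- apply_novel_criteria(21, 80, TRUE, c(6, 0, 0), 1.2, FALSE)
  expect_true(v$c3)    # one library suffices
  v <- apply_novel_criteria(21, 44, TRUE, c(10, 0, 0), 1.2, FALSE)
  expect_false(v$c2)   # "no less than 45 nt": 44 fails
  v <- apply_novel_criteria(21, 45, TRUE, c(10, 0, 0), 1.2, FALSE)
  expect_true(v$c2)
  v <- apply_novel_criteria(21, 80, TRUE, c(10, 0, 0), 0.84, TRUE)
  expect_true(v$c4)    # star rescues a sub-threshold MFEI
  v <- apply_novel_criteria(21, 80, TRUE, c(10, 0, 0), 0.85, FALSE)
  expect_false(v$c4)   # "greater than 0.85" is strict
  v <- apply_novel_criteria(19, 80, TRUE, c(10, 0, 0), 1.2, FALSE)
  expect_false(v$c1)
  v <- apply_novel_criteria(25, 80, TRUE, c(10, 0, 0), 1.2, FALSE)
  expect_false(v$c1)
})

test_that("naming merges identical matures and is order-independent", {
  cand <- function(mature, chrom, start, pass = TRUE) {
    data.frame(mature = mature, chrom = chrom, strand = "+",
               prec_start = start, prec_end = start + 80,
               pass = pass, stringsAsFactors = FALSE)
  }
  df <- rbind(cand("AAAACCCCGGGGTTTTAAAGG", "chr1", 5000),
              cand("AAAACCCCGGGGTTTTAAAGG", "chr1", 1000),
              cand("TTTTGGGGCCCCAAAATTTCC", "chr1", 200),
              cand("CCCCAAAATTTTGGGGCCCAA", "chr1", 9000, pass = FALSE))
  cat1 <- name_and_merge(df)
  expect_identical(nrow(cat1$mirnas), 2L)
  expect_identical(cat1$mirnas$name, c("OsmiR-1", "OsmiR-2"))
  # serial 1 goes to the first genomic coordinate (the 200 start)
  expect_identical(cat1$mirnas$mature[1], "TTTTGGGGCCCCAAAATTTCC")
  # two precursors of the same mature get -1/-2 suffixes in coordinate order
  two <- cat1$precursors[cat1$precursors$name == "OsmiR-2", ]
  expect_identical(two$precursor_name, c("OsmiR-2-1", "OsmiR-2-2"))
  expect_identical(two$prec_start, c(1000, 5000))
  # merging conserves precursors
  expect_identical(nrow(cat1$precursors), sum(df$pass))
  # shuffled input gives the identical catalog
  cat2 <- name_and_merge(df[c(3, 1, 4, 2), ])
  expect_identical(cat1$mirnas, cat2$mirnas)
  expect_identical(cat1$precursors, cat2$precursors)
  # empty input
  expect_identical(nrow(name_and_merge(df[df$mature == "x", ])$mirnas), 0L)
})

test_that("catalog summaries report sizes, first bases, locations and arms", {
  catalog <- list(
    mirnas = data.frame(name = c("OsmiR-1", "OsmiR-2"),
                        mature = c("ATTTGGGGCCCCAAAATTTTCCCC",
                                   "TGGAAGCTAGCGTTGCACTGA"),
                        n_precursors = c(1L, 1L), stringsAsFactors = FALSE),
    precursors = data.frame(name = c("OsmiR-1", "OsmiR-2"),
                            chrom = "chr1", prec_start = c(100L, 5000L),
                            prec_end = c(200L, 5100L), arm = c("5p", "3p"),
                            stringsAsFactors = FALSE))
  ann <- data.frame(chrom = "chr1", start = c(50L, 50L, 140L),
                    end = c(400L, 120L, 160L), strand = "+",
                    feature = c("gene", "exon", "exon"),
                    stringsAsFactors = FALSE)
  ms <- summarize_mirnas(catalog, ann)
  expect_identical(ms$size_distribution$count[
    ms$size_distribution$length == 24], 1L)
  fb24 <- ms$first_base[ms$first_base$class == "24nt", ]
  expect_equal(fb24$fraction[fb24$base == "A"], 1)   # single 24-nt mature, 5' A
  # OsmiR-1 overlaps an exon; OsmiR-2 is outside any gene
  expect_identical(as.integer(ms$location[c("exon", "intergenic")]),
                   c(1L, 1L))
  # a precursor inside the gene but outside exons is intronic
  catalog$precursors$prec_start <- c(200L, 5000L)
  catalog$precursors$prec_end <- c(230L, 5100L)
  ms2 <- summarize_mirnas(catalog, ann)
  expect_identical(as.integer(ms2$location["intron"]), 1L)
  expect_error(summarize_mirnas(list(mirnas = data.frame())), "empty")
})

test_that("the designed 5'-base bias is recovered at the configured rate", {
  set.seed(31)
  dist <- c(A = 0.662, C = 0.1, G = 0.1, T = 0.138)
  firsts <- vapply(1:500, function(i) {
    substr(germir:::.design_mature(24, 0.5, dist), 1, 1)
  }, character(1))
  expect_lt(abs(mean(firsts == "A") - 0.662), 0.04)  # binomial tolerance
})

test_that("MFEI is invariant under sequence reversal", {
  s <- "GGCCAAGGTTCCAAGGCCAATTGGCCAA"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  # same length and GC; identical MFE input gives identical MFEI
  m1 <- compute_mfei(-30, nchar(s), gc_percent(s))
  m2 <- compute_mfei(-30, nchar(rev_s), gc_percent(rev_s))
  expect_equal(m1$mfei, m2$mfei)
})
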