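## Novel miRNA discovery: extract genomic windows around unannotated mapped
## reads, fold them, trim to the maximal hairpin containing the mature read,
## compute MFE/AMFE/MFEI, look for the star strand, and apply the four
## novel-miRNA criteria (mature 20-24 nt; fold-back precursor >= 45 nt;
## more than five reads in at least one library; MFEI > 0.85 or an observed
## miRNA*).

#' Default thresholds for the novel-miRNA criteria
#'
#' @return list with elements mature_len (inclusive bounds, nt),
#'   min_precursor (nt), min_reads (criterion is "greater than" this),
#'   mfei (criterion is "greater than" this), foldback_min_paired
#'   (fraction of mature bases that must be paired).
#' @export
novel_criteria_defaults <- function() {
  list(mature_len = c(20L, 24L), min_precursor = 45L, min_reads = 5L,
       mfei = 0.85, foldback_min_paired = 0.6)
}

#' Extract a genomic window around a read hit
#'
#' The window is the hit extended by \code{flank} nt on each side, clipped to
#' the chromosome; minus-strand hits yield the reverse complement with the
#' mature offset recomputed on that strand.
#'
#' @param hit list or one-row data.frame with chrom, start, end, strand
#'   (0-based half-open, forward coordinates).
#' @param genome a \code{\link{seq_set}} of chromosomes.
#' @param flank flank size in nt (default 150).
#' @return list: sequence (oriented 5'->3' on the hit strand), chrom,
#'   window_start, window_end (forward 0-based half-open), strand,
#'   mature_offset (0-based within the oriented sequence).
#' @export
extract_window <- function(hit, genome, flank = 150L) {
  chrom_seq <- unclass(genome)[[hit$chrom]]
  if (is.null(chrom_seq)) stop("unknown chromosome: ", hit$chrom)
  clen <- nchar(chrom_seq)
  ws <- max(0L, hit$start - flank)
  we <- min(clen, hit$end + flank)
  s <- substr_many(chrom_seq, ws, we - ws)
  if (hit$strand == "-") {
    s <- revcomp(s)
    off <- we - hit$end
  } else {
    off <- hit$start - ws
  }
  list(sequence = s, chrom = hit$chrom, window_start = ws, window_end = we,
       strand = hit$strand, mature_offset = off)
}

## Trim a folded window to the maximal single hairpin (stem-loop) containing
## the mature read: walk outward over enclosing pairs as long as they stay a
## single stem-loop and continue the helix through interior loops of at most
## `max_gap` nt per side (a lone far-out pair across long unpaired flanks is
## not part of the precursor). Returns NULL when no mature base is paired or
## the mature's own pairing spans a multiloop. 1-based inclusive bounds.
trim_to_hairpin <- function(pt, mature_start, mature_end, max_gap = 8L) {
  midx <- mature_start:mature_end
  partners <- pt[midx]
  if (all(is.na(partners))) return(NULL)
  paired <- midx[!is.na(partners)]
  lo <- min(c(paired, pt[paired]))
  hi <- max(c(paired, pt[paired]))
  innermost <- function(a, b) {
    # number of terminal (hairpin) loops in [a, b]
    n <- 0L
    for (i in a:b) {
      j <- pt[i]
      if (!is.na(j) && j > i) {
        inner <- if (i + 1 <= j - 1) (i + 1):(j - 1) else integer(0)
        if (!length(inner) || all(is.na(pt[inner]))) n <- n + 1L
      }
    }
    n
  }
  if (innermost(lo, hi) != 1L) return(NULL)
  repeat {
    enc <- which(!is.na(pt) & seq_along(pt) < lo & pt > hi)
    if (!length(enc)) break
    cand <- max(enc)
    if (lo - cand > max_gap + 1L || pt[cand] - hi > max_gap + 1L) break
    if (innermost(cand, pt[cand]) != 1L) break
    lo <- cand
    hi <- pt[cand]
  }
  c(lo, hi)
}

#' Adjusted MFE and the minimal folding free energy index
#'
#' AMFE = |MFE| / length x 100 (kcal/mol per 100 nt); MFEI = AMFE / GC%.
#' By convention the length is the precursor length (a mature-length variant
#' is available via \code{length_nt}).
#'
#' @param mfe minimum free energy in kcal/mol (<= 0).
#' @param length_nt sequence length in nt.
#' @param gc_percent G+C percentage (0-100, must be > 0).
#' @return list with amfe and mfei, both non-negative.
#' @export
compute_mfei <- function(mfe, length_nt, gc_percent) {
  if (is.na(gc_percent) || gc_percent <= 0) {
    stop("MFEI undefined for GC percentage of zero")
  }
  amfe <- abs(mfe) / length_nt * 100
  list(amfe = amfe, mfei = amfe / gc_percent)
}

#' Locate the star strand of a mature read in a folded hairpin
#'
#' The star is the sequence pairing with the mature in the folded structure,
#' extended to the canonical 2-nt 3' overhang, and reported at the mature's
#' length. No star is defined when more than half the mature bases are
#' unpaired.
#'
#' @param window_seq the (oriented) folded sequence.
#' @param pt pair table of the fold (\code{\link{pair_table}}).
#' @param mature_start,mature_end 1-based inclusive mature position in
#'   \code{window_seq}.
#' @param reads optional character vector of observed read sequences used to
#'   set \code{star_observed} (exact match).
#' @return list: star (sequence or NA), star_start (1-based, or NA),
#'   star_observed.
#' @export
find_star <- function(window_seq, pt, mature_start, mature_end,
                      reads = character(0)) {
  midx <- mature_start:mature_end
  partners <- pt[midx]
  if (mean(is.na(partners)) > 0.5) {
    return(list(star = NA_character_, star_start = NA_integer_,
                star_observed = FALSE))
  }
  a <- midx[!is.na(partners)][1]                       # 5'-most paired base
  L <- length(midx)
  star_end <- pt[a] + 2L
  star_start <- star_end - L + 1L
  if (star_start < 1L || star_end > nchar(window_seq)) {
    star_start <- max(1L, star_start)
    star_end <- min(nchar(window_seq), star_end)
  }
  star <- substr(window_seq, star_start, star_end)
  list(star = star, star_start = star_start,
       star_observed = star %in% reads)
}

#' Apply the four novel-miRNA criteria to one precursor candidate
#'
#' Criterion 1: mature length within 20-24 nt. Criterion 2: classical
#' fold-back structure (at least 60\% of mature bases paired, all partners on
#' the opposite arm of a single stem-loop) and precursor length >= 45 nt.
#' Criterion 3: read count greater than five in at least one library.
#' Criterion 4: MFEI > 0.85 or the complementary miRNA* observed in the
#' reads.
#'
#' @param mature_len mature length (nt).
#' @param precursor_len trimmed precursor length (nt).
#' @param foldback logical: fold-back structure test result.
#' @param counts per-library read counts of the mature sequence.
#' @param mfei MFEI value.
#' @param star_observed logical.
#' @param thresholds see \code{\link{novel_criteria_defaults}}.
#' @return list: c1..c4 logical verdicts plus overall \code{pass}.
#' @export
apply_novel_criteria <- function(mature_len, precursor_len, foldback, counts,
                                 mfei, star_observed,
                                 thresholds = novel_criteria_defaults()) {
  c1 <- mature_len >= thresholds$mature_len[1] &&
        mature_len <= thresholds$mature_len[2]
  c2 <- isTRUE(foldback) && precursor_len >= thresholds$min_precursor
  c3 <- any(counts > thresholds$min_reads)
  c4 <- (!is.na(mfei) && mfei > thresholds$mfei) || isTRUE(star_observed)
  list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, pass = c1 && c2 && c3 && c4)
}

## Merge genomic hits of one sequence that lie closer than `min_gap` nt on
## the same strand, keeping the first hit of each cluster.
.merge_close_hits <- function(hits, min_gap = 50L) {
  out <- list()
  for (strand in unique(hits$strand)) {
    for (chrom in unique(hits$chrom)) {
      h <- hits[hits$strand == strand & hits$chrom == chrom, , drop = FALSE]
      if (!nrow(h)) next
      h <- h[order(h$start), , drop = FALSE]
      keep <- c(TRUE, diff(h$start) >= min_gap)
      out[[length(out) + 1L]] <- h[keep, , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

#' Evaluate precursor candidates for a set of mapped reads
#'
#' For every (sequence, merged genomic hit) pair: extract the flanked window,
#' fold it, trim to the maximal hairpin containing the read, compute
#' GC/AMFE/MFEI, search for the star strand, and score the four novel-miRNA
#' criteria.
#'
#' @param sequences character vector of candidate mature sequences.
#' @param counts integer matrix of per-library counts (rows follow
#'   \code{sequences}).
#' @param hits data.frame from \code{\link{map_exact}} (restricted or not).
#' @param genome \code{\link{seq_set}} of chromosomes.
#' @param all_reads character vector of every observed read sequence
#'   (used for star detection).
#' @param flank window flank in nt.
#' @param thresholds see \code{\link{novel_criteria_defaults}}.
#' @param engine folding engine passed to \code{\link{fold_many}}.
#' @param mfei_length "precursor" (default) or "mature": length used in the
#'   MFEI denominator.
#' @return data.frame of candidates with structure, metrics, per-criterion
#'   verdicts and \code{pass}.
#' @export
evaluate_candidates <- function(sequences, counts, hits, genome, all_reads,
                                flank = 150L,
                                thresholds = novel_criteria_defaults(),
                                engine = "rnafold",
                                mfei_length = c("precursor", "mature")) {
  mfei_length <- match.arg(mfei_length)
  cand <- list()
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    h <- hits[hits$sequence == s, , drop = FALSE]
    if (!nrow(h)) next
    h <- .merge_close_hits(h)
    for (k in seq_len(nrow(h))) {
      win <- extract_window(h[k, ], genome, flank = flank)
      cand[[length(cand) + 1L]] <- c(win, list(mature = s, idx = i))
    }
  }
  if (!length(cand)) return(.empty_candidates(colnames(counts)))
  folds <- fold_many(vapply(cand, `[[`, character(1), "sequence"),
                     engine = engine)
  # first pass: trim each window to its hairpin, collect precursors so the
  # precursor refolds go to the folding engine in one batch
  trims <- vector("list", length(cand))
  precs <- character(0)
  for (j in seq_along(cand)) {
    cd <- cand[[j]]
    pt <- pair_table(folds[[j]]$dotbracket)
    m1 <- cd$mature_offset + 1L
    m2 <- cd$mature_offset + nchar(cd$mature)
    hp <- trim_to_hairpin(pt, m1, m2)
    trims[[j]] <- list(pt = pt, m1 = m1, m2 = m2, hp = hp)
    if (!is.null(hp)) {
      precs[as.character(j)] <- substr(cd$sequence, hp[1], hp[2])
    }
  }
  prec_mfe <- if (length(precs) && engine == "rnafold") {
    vapply(fold_many(precs, engine = engine), `[[`, numeric(1), "mfe")
  } else stats::setNames(rep(NA_real_, length(precs)), names(precs))
  rows <- vector("list", length(cand))
  for (j in seq_along(cand)) {
    cd <- cand[[j]]
    st <- folds[[j]]
    tr <- trims[[j]]
    pt <- tr$pt; m1 <- tr$m1; m2 <- tr$m2; hp <- tr$hp
    cts <- counts[cd$idx, , drop = TRUE]
    if (is.null(hp)) {
      prec <- NA_character_; plen <- NA_integer_; gc <- NA_real_
      amfe <- NA_real_; mfei <- NA_real_; foldback <- FALSE
      arm <- NA_character_; star <- list(star = NA_character_,
                                         star_observed = FALSE)
      pg1 <- NA_integer_; pg2 <- NA_integer_; pdb <- NA_character_
      pmfe <- NA_real_
    } else {
      lo <- hp[1]; hi <- hp[2]
      prec <- substr(cd$sequence, lo, hi)
      pdb <- substr(st$dotbracket, lo, hi)
      plen <- hi - lo + 1L
      gc <- gc_percent(prec)
      pmfe <- unname(prec_mfe[as.character(j)])
      mm <- if (mfei_length == "precursor") plen else nchar(cd$mature)
      met <- if (!is.na(pmfe) && gc > 0) compute_mfei(pmfe, mm, gc) else
        list(amfe = NA_real_, mfei = NA_real_)
      amfe <- met$amfe; mfei <- met$mfei
      # fold-back: >= 60% mature bases paired, partners across one loop
      partners <- pt[m1:m2]
      paired_frac <- mean(!is.na(partners))
      loop_pairs <- which(!is.na(pt) & pt > seq_along(pt))
      inner <- loop_pairs[vapply(loop_pairs, function(i) {
        r <- if (i + 1 <= pt[i] - 1) (i + 1):(pt[i] - 1) else integer(0)
        (!length(r) || all(is.na(pt[r]))) && i >= lo && pt[i] <= hi
      }, logical(1))]
      loop_mid <- if (length(inner)) (inner[1] + pt[inner[1]]) / 2 else NA
      opposite <- !is.na(loop_mid) && {
        pp <- partners[!is.na(partners)]
        mc <- (m1 + m2) / 2
        if (mc < loop_mid) all(pp > loop_mid) else all(pp < loop_mid)
      }
      foldback <- paired_frac >= thresholds$foldback_min_paired && opposite
      arm <- if (!is.na(loop_mid) && (m1 + m2) / 2 < loop_mid) "5p" else "3p"
      star <- find_star(cd$sequence, pt, m1, m2, reads = all_reads)
      if (cd$strand == "+") {
        pg1 <- cd$window_start + lo - 1L
        pg2 <- cd$window_start + hi
      } else {
        pg1 <- cd$window_end - hi
        pg2 <- cd$window_end - lo + 1L
      }
    }
    verdict <- apply_novel_criteria(nchar(cd$mature), plen, foldback, cts,
                                    mfei, star$star_observed, thresholds)
    rows[[j]] <- data.frame(
      mature = cd$mature, chrom = cd$chrom, strand = cd$strand,
      prec_start = pg1, prec_end = pg2,
      window_start = cd$window_start, window_end = cd$window_end,
      precursor = prec, dotbracket = pdb,
      mfe = if (is.null(hp)) NA_real_ else pmfe,
      length = plen, gc = gc, amfe = amfe, mfei = mfei,
      arm = arm, star = star$star, star_observed = star$star_observed,
      foldback = foldback,
      t(cts),
      c1 = verdict$c1, c2 = verdict$c2, c3 = verdict$c3, c4 = verdict$c4,
      pass = verdict$pass,
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_candidates <- function(libs) {
  out <- data.frame(mature = character(0), chrom = character(0),
                    strand = character(0), prec_start = integer(0),
                    prec_end = integer(0), window_start = integer(0),
                    window_end = integer(0), precursor = character(0),
                    dotbracket = character(0), mfe = numeric(0),
                    length = integer(0), gc = numeric(0), amfe = numeric(0),
                    mfei = numeric(0), arm = character(0), star = character(0),
                    star_observed = logical(0), foldback = logical(0),
                    stringsAsFactors = FALSE)
  for (l in libs) out[[l]] <- integer(0)
  out$c1 <- logical(0); out$c2 <- logical(0); out$c3 <- logical(0)
  out$c4 <- logical(0); out$pass <- logical(0)
  out
}

#' Merge passing candidates into a named novel-miRNA catalog
#'
#' Candidates with identical mature sequences are merged into one miRNA with
#' multiple precursors. Serial numbers are assigned in order of first genomic
#' coordinate; when a miRNA has several precursors they get suffixes -1, -2,
#' ... in coordinate order. Deterministic for any input order.
#'
#' @param candidates data.frame from \code{\link{evaluate_candidates}}.
#' @param prefix name prefix (default "OsmiR").
#' @param passing_only keep only candidates with \code{pass} (default TRUE).
#' @return object of class \code{mirna_catalog}: list with \code{mirnas}
#'   (one row per mature sequence) and \code{precursors} (one row per
#'   precursor, with \code{precursor_name}).
#' @export
name_and_merge <- function(candidates, prefix = "OsmiR", passing_only = TRUE) {
  df <- if (passing_only) candidates[candidates$pass, , drop = FALSE] else
    candidates
  df <- df[order(df$chrom, df$prec_start, df$strand), , drop = FALSE]
  if (!nrow(df)) {
    return(structure(list(
      mirnas = data.frame(name = character(0), mature = character(0),
                          n_precursors = integer(0),
                          stringsAsFactors = FALSE),
      precursors = df), class = "mirna_catalog"))
  }
  first_pos <- tapply(seq_len(nrow(df)), df$mature, min)
  matures <- names(sort(first_pos))
  serial <- seq_along(matures)
  names(serial) <- matures
  df$name <- paste0(prefix, "-", serial[df$mature])
  df <- df[order(serial[df$mature], df$chrom, df$prec_start), , drop = FALSE]
  nprec <- table(df$mature)
  df$precursor_name <- df$name
  for (m in matures) {
    idx <- which(df$mature == m)
    if (length(idx) > 1) {
      df$precursor_name[idx] <- paste0(df$name[idx], "-", seq_along(idx))
    }
  }
  mirnas <- data.frame(
    name = paste0(prefix, "-", serial[matures]),
    mature = matures,
    n_precursors = as.integer(nprec[matures]),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  rownames(mirnas) <- NULL
  structure(list(mirnas = mirnas, precursors = df), class = "mirna_catalog")
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat(sprintf("mirna_catalog: %d miRNAs from %d precursors\n",
              nrow(x$mirnas), nrow(x$precursors)))
  if (nrow(x$mirnas)) {
    print(utils::head(x$mirnas, 10), row.names = FALSE)
    if (nrow(x$mirnas) > 10) cat("...\n")
  }
  invisible(x)
}

#' Summaries of a miRNA catalog: sizes, first bases, location, arms
#'
#' @param catalog a \code{mirna_catalog} (novel and/or known entries).
#' @param annotations optional annotation data.frame for genome location
#'   classes: a precursor overlapping an exon is "exon", otherwise inside a
#'   gene is "intron", otherwise "intergenic".
#' @param long_class length (nt) from which a miRNA counts as "long"
#'   (default 24) for the first-base breakdown.
#' @return list: size_distribution (data.frame length/count), first_base
#'   (data.frame class/base/fraction), location (table), arms (table of
#'   5p/3p fractions over precursors).
#' @export
summarize_mirnas <- function(catalog, annotations = NULL, long_class = 24L) {
  if (!nrow(catalog$mirnas)) stop("empty catalog")
  lens <- nchar(catalog$mirnas$mature)
  size_distribution <- as.data.frame(table(length = lens),
                                     stringsAsFactors = FALSE)
  size_distribution$length <- as.integer(size_distribution$length)
  names(size_distribution)[2] <- "count"
  first <- substr(catalog$mirnas$mature, 1, 1)
  cls <- ifelse(lens >= long_class, sprintf("%dnt", long_class), "short")
  fb <- do.call(rbind, lapply(unique(cls), function(cl) {
    tab <- table(factor(first[cls == cl], levels = c("A", "C", "G", "T")))
    data.frame(class = cl, base = names(tab),
               fraction = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  location <- NULL
  if (!is.null(annotations)) {
    exons <- annotations[annotations$feature == "exon", , drop = FALSE]
    genes <- annotations[annotations$feature == "gene", , drop = FALSE]
    loc <- vapply(seq_len(nrow(catalog$precursors)), function(i) {
      p <- catalog$precursors[i, ]
      hits_any <- function(df) {
        any(df$chrom == p$chrom & df$start < p$prec_end &
            df$end > p$prec_start)
      }
      if (nrow(exons) && hits_any(exons)) "exon"
      else if (nrow(genes) && hits_any(genes)) "intron"
      else "intergenic"
    }, character(1))
    location <- table(factor(loc, levels = c("intergenic", "exon", "intron")))
  }
  arms <- table(factor(catalog$precursors$arm, levels = c("5p", "3p")))
  list(size_distribution = size_distribution, first_base = fb,
       location = location, arms = arms / max(1, sum(arms)))
}
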