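## Length filtering, exact genome mapping and Rfam-style classification of
## collapsed small RNA reads, plus the classification summary table with the
## percentage conventions used for sRNA library statistics reporting.

#' Filter a count table by read length
#'
#' @param ct a \code{\link{count_table}}.
#' @param min_len,max_len inclusive length bounds in nt (defaults 18 and 30).
#' @return filtered \code{count_table}; counts and clean totals untouched.
#' @export
length_filter <- function(ct, min_len = 18L, max_len = 30L) {
  stopifnot(min_len <= max_len)
  keep <- nchar(ct$sequence) >= min_len & nchar(ct$sequence) <= max_len
  count_table(ct$sequence[keep], ct$counts[keep, , drop = FALSE],
              ct$clean_totals)
}

#' Map reads to a genome by exact matching on both strands
#'
#' Reports every exact occurrence of each sequence: plus-strand occurrences
#' directly, minus-strand occurrences as matches of the reverse complement
#' (coordinates are always on the forward strand). Reads containing N match
#' nothing.
#'
#' @param reads a \code{\link{count_table}} or character vector of sequences.
#' @param genome a \code{\link{seq_set}} of chromosomes.
#' @return data.frame of hits: sequence, chrom, start (0-based), end
#'   (exclusive), strand.
#' @export
map_exact <- function(reads, genome) {
  seqs <- if (inherits(reads, "count_table")) reads$sequence else
    unique(normalize_nt(reads))
  if (length(genome) == 0 || sum(nchar(unclass(genome))) == 0) {
    stop("genome is empty")
  }
  chroms <- Biostrings::DNAStringSet(unclass(genome))
  names(chroms) <- names(genome)
  out <- list()
  usable <- seqs[!grepl("N", seqs)]
  for (L in sort(unique(nchar(usable)))) {
    grp <- usable[nchar(usable) == L]
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") grp else revcomp(grp)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
      for (ci in seq_along(chroms)) {
        m <- Biostrings::matchPDict(pd, chroms[[ci]])
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0) next
        ir <- unlist(m)
        out[[length(out) + 1L]] <- data.frame(
          sequence = rep(grp, nh),
          chrom = names(chroms)[ci],
          start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir),
          strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits[order(hits$sequence, hits$chrom, hits$start, hits$strand), ,
       drop = FALSE]
}

## Exact-substring membership of each read in any sequence of `refs`.
.substring_of_any <- function(seqs, refs) {
  if (length(refs) == 0 || length(seqs) == 0) {
    return(rep(FALSE, length(seqs)))
  }
  subj <- Biostrings::DNAStringSet(unclass(refs))
  res <- rep(FALSE, length(seqs))
  usable <- which(!grepl("N", seqs))
  for (L in unique(nchar(seqs[usable]))) {
    idx <- usable[nchar(seqs[usable]) == L]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    hit <- rep(FALSE, length(idx))
    for (si in seq_along(subj)) {
      hit <- hit | S4Vectors::elementNROWS(Biostrings::matchPDict(pd, subj[[si]])) > 0
    }
    res[idx] <- hit
  }
  res
}

## Hamming-distance (<= max_mm, equal length, no indels) membership of each
## read against a catalog of mature miRNAs.
.hamming_match_any <- function(seqs, catalog, max_mm = 2L) {
  res <- rep(FALSE, length(seqs))
  if (length(catalog) == 0 || length(seqs) == 0) return(res)
  cat_seqs <- unclass(catalog)
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    cats <- cat_seqs[nchar(cat_seqs) == L]
    if (!length(cats)) next
    M <- matrix(utf8ToInt(paste(seqs[idx], collapse = "")), nrow = L)
    nint <- utf8ToInt("N")
    hit <- rep(FALSE, length(idx))
    for (q in cats) {
      qv <- utf8ToInt(q)
      mm <- colSums(M != qv | M == nint)
      hit <- hit | mm <= max_mm
    }
    res[idx] <- hit
  }
  res
}

#' Classify mapped reads into annotation categories
#'
#' Categories are assigned with a configurable precedence (default:
#' known_miRNA > rRNA > tRNA > snoRNA > snRNA > other). A known-miRNA match
#' is an equal-length Hamming-distance match with at most \code{max_mm}
#' substitutions (no indels) against any catalog mature sequence; an
#' rRNA/tRNA/snoRNA/snRNA match is an exact substring of the corresponding
#' reference set. Unmapped reads receive category NA. \code{cds_overlap} is
#' true when any genomic hit intersects a CDS interval.
#'
#' @param ct a length-filtered \code{\link{count_table}}.
#' @param hits data.frame from \code{\link{map_exact}}.
#' @param references named list of \code{\link{seq_set}}s with elements
#'   rRNA, tRNA, snoRNA, snRNA.
#' @param known_mirnas \code{\link{seq_set}} of known mature miRNAs.
#' @param cds annotation data.frame (only rows with feature "CDS" are used;
#'   if none are labelled CDS, all rows are treated as CDS intervals).
#' @param precedence category order; "known_miRNA" may also come after the
#'   Rfam categories (Rfam-first discard order).
#' @param max_mm mismatch allowance for known-miRNA matching.
#' @return \code{annotated_reads} data.frame: sequence, count columns,
#'   n_hits, category, cds_overlap.
#' @export
classify <- function(ct, hits, references, known_mirnas, cds = NULL,
                     precedence = c("known_miRNA", "rRNA", "tRNA",
                                    "snoRNA", "snRNA"),
                     max_mm = 2L) {
  needed <- c("rRNA", "tRNA", "snoRNA", "snRNA")
  if (!all(needed %in% names(references))) {
    stop("missing reference set(s): ",
         paste(setdiff(needed, names(references)), collapse = ", "))
  }
  seqs <- ct$sequence
  mapped <- seqs %in% hits$sequence
  match_mat <- cbind(
    known_miRNA = .hamming_match_any(seqs, known_mirnas, max_mm),
    rRNA = .substring_of_any(seqs, references$rRNA),
    tRNA = .substring_of_any(seqs, references$tRNA),
    snoRNA = .substring_of_any(seqs, references$snoRNA),
    snRNA = .substring_of_any(seqs, references$snRNA)
  )
  category <- rep(NA_character_, length(seqs))
  category[mapped] <- "other"
  for (cat in rev(precedence)) {
    category[mapped & match_mat[, cat]] <- cat
  }
  cds_overlap <- rep(FALSE, length(seqs))
  if (!is.null(cds) && nrow(hits) > 0) {
    cds_df <- cds[cds$feature == "CDS", , drop = FALSE]
    if (nrow(cds_df) == 0) cds_df <- cds
    ov_seq <- character(0)
    for (chrom in unique(cds_df$chrom)) {
      h <- hits[hits$chrom == chrom, , drop = FALSE]
      cd <- cds_df[cds_df$chrom == chrom, , drop = FALSE]
      if (nrow(h) == 0 || nrow(cd) == 0) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(h$start + 1L, h$end),
        IRanges::IRanges(cd$start + 1L, cd$end)
      )
      ov_seq <- c(ov_seq, h$sequence[unique(S4Vectors::queryHits(ov))])
    }
    cds_overlap <- seqs %in% ov_seq
  }
  n_hits <- integer(length(seqs))
  if (nrow(hits) > 0) {
    tab <- table(hits$sequence)
    n_hits <- as.integer(ifelse(is.na(tab[seqs]), 0L, tab[seqs]))
  }
  out <- data.frame(sequence = seqs, ct$counts, n_hits = n_hits,
                    category = category, cds_overlap = cds_overlap,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "library_ids") <- ct$library_ids
  attr(out, "clean_totals") <- ct$clean_totals
  class(out) <- c("annotated_reads", "data.frame")
  out
}

#' Summarize classified reads into a library-statistics table
#'
#' Reproduces the reporting conventions of sRNA library statistics tables:
#' the genome-mapped and CDS-matched rows are percentages of the 18-30 nt
#' totals (reads against the reads total, unique sequences against the
#' unique total); each non-coding category's reads percentage is relative to
#' the non-coding reads total, and its unique-sequence percentage is
#' relative to the reads count of the same category. All percentages are
#' rounded half-up to one decimal.
#'
#' @param annotated \code{annotated_reads} from \code{\link{classify}}.
#' @param raw_totals optional named vector of raw read totals per library
#'   (pre length-filter); defaults to the clean totals.
#' @return \code{classification_summary}: long data.frame with columns
#'   library, row, reads, reads_pct, unique, unique_pct.
#' @export
summarize_classification <- function(annotated, raw_totals = NULL) {
  libs <- attr(annotated, "library_ids")
  if (is.null(raw_totals)) raw_totals <- attr(annotated, "clean_totals")
  cats <- c("known_miRNA", "rRNA", "tRNA", "snoRNA", "snRNA", "other")
  rows <- list()
  for (lib in libs) {
    cnt <- annotated[[lib]]
    present <- cnt > 0
    mapped <- present & !is.na(annotated$category)
    noncoding <- mapped & !annotated$cds_overlap
    tot_reads <- sum(cnt[present])
    tot_uniq <- sum(present)
    map_reads <- sum(cnt[mapped]); map_uniq <- sum(mapped)
    cds_reads <- sum(cnt[mapped & annotated$cds_overlap])
    cds_uniq <- sum(mapped & annotated$cds_overlap)
    nc_reads <- sum(cnt[noncoding])
    add <- function(row, reads, rpct, uniq, upct) {
      rows[[length(rows) + 1L]] <<- data.frame(
        library = lib, row = row, reads = reads, reads_pct = rpct,
        unique = uniq, unique_pct = upct, stringsAsFactors = FALSE)
    }
    add("raw", unname(raw_totals[lib]), NA, NA, NA)
    add("18-30 nt", tot_reads, 100.0, tot_uniq, 100.0)
    add("mapped", map_reads, library_stats_percent(map_reads, tot_reads),
        map_uniq, library_stats_percent(map_uniq, tot_uniq))
    add("CDS", cds_reads, library_stats_percent(cds_reads, tot_reads),
        cds_uniq, library_stats_percent(cds_uniq, tot_uniq))
    add("non-coding total", nc_reads, 100.0, NA, NA)
    for (cat in cats) {
      sel <- noncoding & annotated$category == cat
      r <- sum(cnt[sel]); u <- sum(sel)
      add(cat, r, library_stats_percent(r, nc_reads), u, library_stats_percent(u, r))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("classification_summary", "data.frame")
  out
}

#' Percentage with the summary table's rounding convention
#'
#' 100 * numerator / denominator, rounded half-up to one decimal; 0.0 when
#' the denominator is zero.
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimals (default 1).
#' @return percentage on the 0-100 scale.
#' @export
library_stats_percent <- function(num, den, digits = 1L) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  ifelse(den > 0, round_half_up(100 * num / den, digits), 0)
}

#' @export
print.classification_summary <- function(x, ...) {
  for (lib in unique(x$library)) {
    cat("library", lib, "\n")
    sub <- x[x$library == lib, -1]
    print.data.frame(sub, row.names = FALSE)
  }
  invisible(x)
}
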