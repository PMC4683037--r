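## Readers/writers for the standard formats the pipeline touches, and the
## shared sequence/coordinate containers used by every other module.
##
## Conventions: all internal coordinates are 0-based half-open on the forward
## strand (minus-strand features keep forward coordinates plus a strand flag);
## U is normalized to T on input and restored on output where the original
## alphabet was RNA.

# ---------------------------------------------------------------------------
# sequence sets

#' Construct a sequence set
#'
#' A named character vector of nucleotide sequences with unique ids. T and U
#' are treated as equivalent: residues are stored on the DNA alphabet and the
#' original alphabet is remembered for output.
#'
#' @param residues character vector of sequences.
#' @param ids character vector of unique ids.
#' @param desc optional description strings.
#' @return object of class \code{seq_set}.
#' @export
seq_set <- function(residues, ids = names(residues), desc = NULL) {
  if (is.null(ids)) stop("sequence ids are required")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(residues))) stop("empty sequence(s) in set")
  if (!all(.valid_nt(residues))) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(ids[!.valid_nt(residues)], collapse = ", "))
  }
  rna <- grepl("[Uu]", residues)
  x <- normalize_nt(residues)
  names(x) <- ids
  attr(x, "rna") <- rna
  attr(x, "desc") <- if (is.null(desc)) rep("", length(x)) else desc
  class(x) <- "seq_set"
  x
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", length(x), "sequences\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %s (%d nt) %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  idx <- if (is.character(i)) match(i, names(x)) else i
  seq_set(unclass(x)[idx], names(x)[idx],
          desc = attr(x, "desc")[if (is.logical(idx)) which(idx) else idx])
}

#' Read a FASTA file
#'
#' One record per header, order preserved. U is normalized to T internally;
#' the original alphabet is remembered so \code{\link{write_fasta}} restores
#' it. Malformed headers, empty sequences and duplicate ids are errors naming
#' the offending line.
#'
#' @param path path to a FASTA file.
#' @return a \code{\link{seq_set}}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(seq_set(character(0), character(0)))
  if (!startsWith(lines[[1]], ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("^>\\s*(\\S*).*$", "\\1", lines[hdr])
  bad <- hdr[!nzchar(ids)]
  if (length(bad)) stop("malformed FASTA header at line ", bad[[1]], ": ", path)
  desc <- trimws(sub("^>\\s*\\S*", "", lines[hdr]))
  ends <- c(hdr[-1] - 1L, length(lines))
  res <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  empty <- which(!nzchar(res))
  if (length(empty)) {
    stop("empty sequence for record at line ", hdr[empty[[1]]], ": ", path)
  }
  seq_set(res, ids, desc = desc)
}

#' Write a sequence set as FASTA
#'
#' Restores U for records that were read from the RNA alphabet.
#'
#' @param x a \code{\link{seq_set}} (or named character vector).
#' @param path output path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  rna <- attr(x, "rna")
  if (is.null(rna)) rna <- rep(FALSE, length(x))
  desc <- attr(x, "desc")
  if (is.null(desc)) desc <- rep("", length(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    s <- unclass(x)[[i]]
    if (rna[i]) s <- chartr("T", "U", s)
    writeLines(paste0(">", names(x)[i],
                      if (nzchar(desc[i])) paste0(" ", desc[i]) else ""),
               con)
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(nchar(s), seq(1, nchar(s), width) + width - 1L)),
               con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# count tables

#' Construct a count table of collapsed reads
#'
#' @param sequence character vector of unique read sequences (DNA alphabet).
#' @param counts integer matrix, one row per sequence, one column per library.
#' @param clean_totals positive integer vector of total clean reads per
#'   library (the TPM denominators).
#' @return object of class \code{count_table} with elements \code{sequence},
#'   \code{counts}, \code{library_ids}, \code{clean_totals}.
#' @export
count_table <- function(sequence, counts, clean_totals) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(sequence) != nrow(counts)) stop("sequence/count length mismatch")
  if (is.null(colnames(counts))) stop("count columns must be named by library")
  if (length(clean_totals) != ncol(counts)) {
    stop("clean_totals must have one entry per library")
  }
  if (any(counts < 0)) stop("negative counts")
  if (anyDuplicated(sequence)) stop("duplicate sequences in count table")
  keep <- any(clean_totals > 0)  # allow all-zero empty tables
  if (nrow(counts) > 0 && any(colSums(counts) > clean_totals)) {
    stop("per-library counts exceed clean totals")
  }
  structure(list(sequence = as.character(sequence), counts = counts,
                 library_ids = colnames(counts),
                 clean_totals = stats::setNames(as.numeric(clean_totals),
                                                colnames(counts))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d unique sequences x %d libraries (%s)\n",
              length(x$sequence), length(x$library_ids),
              paste(x$library_ids, collapse = ", ")))
  cat("clean totals:", paste(x$clean_totals, collapse = ", "), "\n")
  invisible(x)
}

#' Collapse raw reads into unique sequences with counts
#'
#' Identical sequences are merged; the count is the multiplicity and the
#' clean total is the number of input reads. FASTQ (Phred+33; qualities are
#' parsed but otherwise ignored) is detected by the .fastq/.fq extension,
#' everything else is read as FASTA.
#'
#' @param path reads file (FASTA or FASTQ).
#' @param library_id name for the single count column.
#' @return a single-library \code{\link{count_table}}.
#' @export
collapse_reads <- function(path, library_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  reads <- if (file.size(path) == 0) {
    character(0)
  } else if (fastq) {
    as.character(Biostrings::readBStringSet(path, format = "fastq"))
  } else {
    as.character(Biostrings::readBStringSet(path, format = "fasta"))
  }
  collapse_read_vector(reads, library_id)
}

#' Collapse an in-memory read vector (see \code{\link{collapse_reads}})
#' @param reads character vector of raw reads.
#' @param library_id name for the count column.
#' @return a single-library \code{\link{count_table}}.
#' @export
collapse_read_vector <- function(reads, library_id) {
  reads <- normalize_nt(reads)
  bad <- !.valid_nt(reads)
  if (any(bad)) {
    stop("non-nucleotide characters in read(s), e.g.: ", reads[bad][[1]])
  }
  tab <- table(reads)
  counts <- matrix(as.integer(tab), ncol = 1,
                   dimnames = list(NULL, library_id))
  count_table(names(tab), counts, clean_totals = length(reads))
}

#' Merge single-library count tables into one multi-library table
#'
#' @param ... \code{count_table} objects with disjoint library ids.
#' @return a merged \code{\link{count_table}} over the union of sequences.
#' @export
merge_count_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "count_table")) tabs <- tabs[[1]]
  libs <- unlist(lapply(tabs, function(t) t$library_ids))
  if (anyDuplicated(libs)) stop("duplicate library ids across tables")
  seqs <- sort(unique(unlist(lapply(tabs, function(t) t$sequence))))
  counts <- matrix(0L, nrow = length(seqs), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (t in tabs) {
    counts[match(t$sequence, seqs), t$library_ids] <- t$counts
  }
  count_table(seqs, counts,
              clean_totals = unlist(lapply(tabs, function(t) t$clean_totals)))
}

# ---------------------------------------------------------------------------
# annotations

#' Read genomic annotations (GFF3 or BED)
#'
#' The dialect is auto-detected from the extension (GFF3 is 1-based
#' inclusive, BED is 0-based half-open); all intervals are converted to the
#' internal 0-based half-open convention.
#'
#' @param path a .gff3/.gff or .bed file.
#' @return data.frame with columns chrom, start (0-based), end (exclusive),
#'   strand, feature.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path)
  feature <- if (!is.null(gr$type)) as.character(gr$type)
             else if (!is.null(gr$name)) as.character(gr$name)
             else rep("region", length(gr))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based
    end = GenomicRanges::end(gr),            # inclusive -> exclusive
    strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
    feature = feature,
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) {
    stop("invalid interval(s) after coordinate conversion in ", path)
  }
  out
}

#' Write annotations as GFF3
#'
#' The inverse of \code{\link{read_annotations}} for the GFF3 dialect:
#' internal 0-based half-open intervals are converted back to 1-based
#' inclusive coordinates.
#'
#' @param ann annotation data.frame (chrom, start, end, strand, feature).
#' @param path output .gff3 path.
#' @param source value for the GFF3 source column.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(ann, path, source = "germir") {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  gr$source <- source
  gr$type <- ann$feature
  if (!is.null(ann$id)) gr$ID <- ann$id
  # rtracklayer warns that CDS rows carry no phase; phase is not modelled
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

# ---------------------------------------------------------------------------
# tabular results

#' Write a tabular result as TSV
#'
#' Tab-separated with a header row; missing values are rendered as "NA";
#' floating point columns are rendered with an explicit number of significant
#' digits so that written tables are reproducible byte-for-byte.
#'
#' @param x data.frame or matrix (matrix rownames become an `id` column).
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return \code{path}, invisibly.
#' @export
write_results_tsv <- function(x, path, digits = 10L) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), as.data.frame(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (is.null(colnames(x)) || any(!nzchar(colnames(x)))) {
    stop("column names must be defined")
  }
  fmt <- x
  num <- vapply(fmt, function(col) is.double(col), logical(1))
  fmt[num] <- lapply(fmt[num], function(col) {
    out <- formatC(col, digits = digits, format = "g")
    out[is.na(col)] <- NA
    out
  })
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by \code{\link{write_results_tsv}}
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a TSV expression matrix (first column = row ids)
#' @param path TSV path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_results_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
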