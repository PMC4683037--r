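## RNA secondary structure: thermodynamic MFE folding is delegated to
## ViennaRNA's RNAfold command-line tool (nearest-neighbor model, 37 degC);
## a built-in Nussinov maximum-base-pairing engine is available as an
## energy-free fallback. Structures are exchanged as dot-bracket strings.

#' Construct a secondary structure
#'
#' @param dotbracket balanced dot-bracket string over "(", ")", ".".
#' @param mfe minimum free energy in kcal/mol (NA for the energy-free
#'   Nussinov engine).
#' @return object of class \code{secondary_structure}.
#' @export
secondary_structure <- function(dotbracket, mfe) {
  if (grepl("[^().]", dotbracket)) stop("invalid dot-bracket characters")
  depth <- cumsum((strsplit(dotbracket, "")[[1]] == "(") -
                  (strsplit(dotbracket, "")[[1]] == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    stop("unbalanced dot-bracket string")
  }
  npairs <- sum(strsplit(dotbracket, "")[[1]] == "(")
  if (!is.na(mfe)) {
    if (npairs >= 1 && mfe > 0) stop("mfe must be <= 0 for a paired structure")
    if (npairs == 0) mfe <- 0
  }
  structure(list(dotbracket = dotbracket, mfe = mfe),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$dotbracket, "\n")
  cat("MFE:", if (is.na(x$mfe)) "NA (pairing-only engine)"
      else sprintf("%.2f kcal/mol", x$mfe), "\n")
  invisible(x)
}

#' Pair table of a dot-bracket structure
#'
#' @param dotbracket dot-bracket string.
#' @return integer vector: \code{pt[i]} is the 1-based partner of base i, or
#'   NA if unpaired.
#' @export
pair_table <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pt
}

.rnafold_path <- function() {
  p <- Sys.which("RNAfold")
  if (!nzchar(p)) {
    stop("RNAfold (ViennaRNA) not found on PATH; use engine = \"nussinov\" ",
         "for pairing-only folding")
  }
  p
}

## Fold many sequences in one RNAfold invocation. Returns a list of
## secondary_structure objects named like `seqs`.
fold_many <- function(seqs, engine = c("rnafold", "nussinov")) {
  engine <- match.arg(engine)
  if (length(seqs) == 0) return(list())
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  nfrac <- vapply(seqs, function(s) {
    mean(strsplit(normalize_nt(s), "")[[1]] == "N")
  }, numeric(1))
  if (any(nfrac > 0.10)) {
    stop("refusing to fold sequence(s) with >10% N: ",
         paste(names(seqs)[nfrac > 0.10], collapse = ", "))
  }
  if (engine == "nussinov") {
    return(lapply(stats::setNames(seqs, names(seqs)), function(s) {
      secondary_structure(nussinov_structure(s), NA_real_)
    }))
  }
  infile <- tempfile(fileext = ".fa")
  on.exit(unlink(infile))
  writeLines(paste0(">", names(seqs), "\n", normalize_nt(unname(seqs))), infile)
  out <- system2(.rnafold_path(), c("--noPS", "--infile", infile),
                 stdout = TRUE, stderr = FALSE)
  hdr <- which(startsWith(out, ">"))
  if (length(hdr) != length(seqs)) stop("unexpected RNAfold output")
  res <- lapply(hdr, function(h) {
    sl <- out[h + 2L]
    m <- regmatches(sl, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", sl))[[1]]
    if (length(m) != 3) stop("cannot parse RNAfold structure line: ", sl)
    secondary_structure(m[2], as.numeric(m[3]))
  })
  names(res) <- sub("^>", "", out[hdr])
  res[names(seqs)]
}

#' Fold an RNA/DNA sequence into its MFE secondary structure
#'
#' The default engine is ViennaRNA's RNAfold (standard nearest-neighbor
#' thermodynamic model at 37 degC). The "nussinov" engine is a built-in
#' maximum-base-pairing folder without an energy model (MFE is NA); it keeps
#' structure-level functionality available without ViennaRNA.
#'
#' @param sequence nucleotide string (length >= 10).
#' @param engine "rnafold" or "nussinov".
#' @return a \code{\link{secondary_structure}}.
#' @export
fold <- function(sequence, engine = c("rnafold", "nussinov")) {
  if (nchar(sequence) < 10) stop("sequence too short to fold (< 10 nt)")
  fold_many(c(x = sequence), engine = match.arg(engine))[[1]]
}

#' Nussinov maximum-pairing structure
#'
#' Dynamic-programming maximum Watson-Crick/G:U pairing with a minimum
#' hairpin loop of 3 nt. No energy model: used as a pairing-score fallback
#' and for structural sanity checks.
#'
#' @param sequence nucleotide string.
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return dot-bracket string.
#' @export
nussinov_structure <- function(sequence, min_loop = 3L) {
  s <- strsplit(normalize_nt(sequence), "")[[1]]
  n <- length(s)
  can_pair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  M <- matrix(0L, n, n)
  for (span in seq_len(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1, j]                      # i unpaired
      if (j - 1 >= i) best <- max(best, M[i, j - 1])
      if (j - i > min_loop && can_pair(s[i], s[j])) {
        inner <- if (i + 1 <= j - 1) M[i + 1, j - 1] else 0L
        best <- max(best, inner + 1L)
      }
      if (j - i >= 3) {
        for (k in (i + 1):(j - 2)) {
          best <- max(best, M[i, k] + M[k + 1, j])
        }
      }
      M[i, j] <- best
    }
  }
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      if (M[i, j] == M[i + 1, j]) { i <- i + 1; next }
      if (M[i, j] == M[i, j - 1]) { j <- j - 1; next }
      inner <- if (i + 1 <= j - 1) M[i + 1, j - 1] else 0L
      if (j - i > min_loop && can_pair(s[i], s[j]) && M[i, j] == inner + 1L) {
        db[i] <<- "("; db[j] <<- ")"
        i <- i + 1; j <- j - 1; next
      }
      done <- FALSE
      for (k in (i + 1):(j - 2)) {
        if (M[i, j] == M[i, k] + M[k + 1, j]) {
          trace(i, k); i <- k + 1; done <- TRUE; break
        }
      }
      if (!done) break
    }
  }
  if (n > 1) trace(1L, n)
  paste(db, collapse = "")
}
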