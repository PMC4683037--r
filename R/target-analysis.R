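## miRNA target prediction: ungapped antiparallel duplex alignment, the
## six-rule complementarity filter (G:U wobble = 0.5 mismatches), a
## nearest-neighbor duplex energy for the 75%-of-perfect rule, transcriptome
## scanning, degradome confirmation with a per-site binomial test, and
## method-overlap (Venn) counts.

## RNA Watson-Crick nearest-neighbor stack free energies (kcal/mol, 37 degC,
## Xia et al. parameter set), indexed by the miRNA-strand dinucleotide
## (partner strand is determined by complementarity). T alphabet.
.nn_stack <- c(
  AA = -0.93, AC = -2.24, AG = -2.08, AT = -1.10,
  CA = -2.11, CC = -3.26, CG = -2.36, CT = -2.08,
  GA = -2.35, GC = -3.42, GG = -3.26, GT = -2.24,
  TA = -1.33, TC = -2.35, TG = -2.11, TT = -0.93
)

## Per-miRNA stack energy vector e[i] for dinucleotide (i, i+1).
.stack_vector <- function(mirna) {
  s <- strsplit(normalize_nt(mirna), "")[[1]]
  L <- length(s)
  if (L < 2) return(numeric(0))
  din <- paste0(s[-L], s[-1])
  e <- unname(.nn_stack[din])
  e[is.na(e)] <- 0  # dinucleotides containing N stack nothing
  e
}

#' Align a miRNA against a candidate target site (ungapped, antiparallel)
#'
#' miRNA position i (counted from the miRNA 5' end) pairs with site position
#' L+1-i; each position is classified as Watson-Crick match, G:U wobble, or
#' mismatch. The mismatch score counts a G:U pair as 0.5.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site equal-length target site, 5'->3' on the transcript.
#' @return object of class \code{duplex_alignment}: mirna, site, states
#'   (character vector over miRNA positions), mismatch_score,
#'   duplex_energy, perfect_energy.
#' @export
align_duplex <- function(mirna, site) {
  m <- normalize_nt(mirna); s <- normalize_nt(site)
  if (nchar(m) != nchar(s)) stop("miRNA and site must have equal length")
  L <- nchar(m)
  mv <- strsplit(m, "")[[1]]
  sv <- rev(strsplit(s, "")[[1]])  # position i of site partner for miRNA i
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = -10L)
  tot <- code[mv] + code[sv]
  states <- ifelse(tot == 5L, "match", ifelse(tot == 7L, "GU", "mismatch"))
  e <- .stack_vector(m)
  isM <- states == "match"
  dup <- if (L >= 2) sum(e[isM[-L] & isM[-1]]) else 0
  structure(list(mirna = m, site = s, states = unname(states),
                 mismatch_score = sum(states == "mismatch") +
                   0.5 * sum(states == "GU"),
                 duplex_energy = dup, perfect_energy = sum(e)),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  sym <- c(match = "|", GU = "o", mismatch = " ")
  cat("miRNA 5'", x$mirna, "3'\n")
  cat("        ", paste(sym[x$states], collapse = ""), "\n")
  cat("site  3'", paste(rev(strsplit(x$site, "")[[1]]), collapse = ""), "5'\n")
  cat(sprintf("mismatch score %.1f; energy %.2f / perfect %.2f (ratio %.2f)\n",
              x$mismatch_score, x$duplex_energy, x$perfect_energy,
              ifelse(x$perfect_energy == 0, 0,
                     x$duplex_energy / x$perfect_energy)))
  invisible(x)
}

#' Default thresholds for the six target-site rules
#' @return list: max_mismatch (4), max_adjacent (2), seed_window (positions
#'   2-12 for the adjacency rule), perfect_positions (10-11), max_seed_score
#'   (2.5 over positions 1-12), min_energy_fraction (0.75).
#' @export
target_rule_defaults <- function() {
  list(max_mismatch = 4, max_adjacent = 2L, seed_window = c(2L, 12L),
       perfect_positions = c(10L, 11L), max_seed_score = 2.5,
       min_energy_fraction = 0.75)
}

#' Score the six target-site rules on a duplex alignment
#'
#' Rule 1: mismatch score (G:U = 0.5) at most 4. Rule 2: no more than two
#' adjacent non-matches anywhere. Rule 3: no adjacent non-matches within
#' positions 2-12 from the miRNA 5' end. Rule 4: perfect matches at
#' positions 10 and 11. Rule 5: mismatch score over positions 1-12 at most
#' 2.5. Rule 6: duplex energy at least 75% of the perfect-complement energy
#' (magnitudes). G:U counts as a non-match for the adjacency rules.
#'
#' @param a a \code{duplex_alignment}.
#' @param thresholds see \code{\link{target_rule_defaults}}.
#' @return list: r1..r6 logical, pass (AND of all six).
#' @export
score_rules <- function(a, thresholds = target_rule_defaults()) {
  st <- a$states
  L <- length(st)
  nm <- st != "match"
  th <- thresholds
  r1 <- a$mismatch_score <= th$max_mismatch
  runs <- rle(nm)
  r2 <- !any(runs$values & runs$lengths > th$max_adjacent)
  w <- th$seed_window
  hi <- min(w[2], L)
  r3 <- !any(nm[w[1]:(hi - 1)] & nm[(w[1] + 1):hi])
  pp <- th$perfect_positions
  r4 <- all(pp <= L) && all(st[pp] == "match")
  sw <- seq_len(min(12L, L))
  r5 <- sum(st[sw] == "mismatch") + 0.5 * sum(st[sw] == "GU") <=
    th$max_seed_score
  r6 <- abs(a$duplex_energy) >= th$min_energy_fraction * abs(a$perfect_energy)
  list(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5, r6 = r6,
       pass = r1 && r2 && r3 && r4 && r5 && r6)
}

#' Nearest-neighbor duplex energy of an alignment
#'
#' Sum of Watson-Crick nearest-neighbor stack energies over consecutive
#' matched positions; mismatched and G:U positions contribute no stabilizing
#' stack. The perfect energy is the same sum for the miRNA against its exact
#' complement.
#'
#' @param a a \code{duplex_alignment}.
#' @return list: duplex_energy, perfect_energy, ratio (of magnitudes).
#' @export
duplex_energy <- function(a) {
  list(duplex_energy = a$duplex_energy, perfect_energy = a$perfect_energy,
       ratio = ifelse(a$perfect_energy == 0, 0,
                      abs(a$duplex_energy) / abs(a$perfect_energy)))
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every window of miRNA length on every transcript is evaluated against the
#' six rules. The cleavage position is the transcript coordinate opposite
#' miRNA position 11, so that (cleavage_position, cleavage_position + 1)
#' covers the bases opposite miRNA positions 11 and 10.
#'
#' @param mirnas named character vector or \code{\link{seq_set}} of mature
#'   miRNAs.
#' @param transcripts named character vector or \code{\link{seq_set}}.
#' @param thresholds see \code{\link{target_rule_defaults}}.
#' @param all_windows return every window with its verdicts instead of only
#'   passing sites (default FALSE).
#' @return data.frame of sites: mirna, transcript, start, end (0-based
#'   half-open on the transcript), r1..r6, pass, mismatch_score,
#'   energy, perfect_energy, energy_ratio, cleavage_position.
#' @export
scan_transcripts <- function(mirnas, transcripts,
                             thresholds = target_rule_defaults(),
                             all_windows = FALSE) {
  mir <- stats::setNames(normalize_nt(unclass(mirnas)), names(mirnas))
  txs <- stats::setNames(normalize_nt(unclass(transcripts)), names(transcripts))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = -10L)
  th <- thresholds
  out <- list()
  for (mi in seq_along(mir)) {
    m <- mir[[mi]]
    L <- nchar(m)
    mcode <- code[strsplit(m, "")[[1]]]
    e <- .stack_vector(m)
    perfect <- sum(e)
    for (ti in seq_along(txs)) {
      tx <- txs[[ti]]
      n <- nchar(tx)
      if (n < L) next
      tcode <- code[strsplit(tx, "")[[1]]]
      W <- n - L + 1L
      # S[w, i]: pairing state of miRNA position i in window w
      # (0 = match, 1 = GU, 2 = mismatch)
      idx <- outer(seq_len(W) - 1L, L - seq_len(L), "+") + 1L
      tot <- matrix(tcode[idx], nrow = W) +
        matrix(mcode, nrow = W, ncol = L, byrow = TRUE)
      S <- matrix(2L, nrow = W, ncol = L)
      S[tot == 5L] <- 0L
      S[tot == 7L] <- 1L
      NM <- S > 0L
      score <- rowSums(S == 2L) + 0.5 * rowSums(S == 1L)
      r1 <- score <= th$max_mismatch
      r2 <- if (L >= 3) {
        adj3 <- NM[, 1:(L - 2), drop = FALSE] &
                NM[, 2:(L - 1), drop = FALSE] & NM[, 3:L, drop = FALSE]
        rowSums(adj3) == 0
      } else rep(TRUE, W)
      w12 <- th$seed_window
      hi <- min(w12[2], L)
      adj <- NM[, w12[1]:(hi - 1), drop = FALSE] &
             NM[, (w12[1] + 1):hi, drop = FALSE]
      r3 <- rowSums(adj) == 0
      pp <- th$perfect_positions
      r4 <- !NM[, pp[1]] & !NM[, pp[2]]
      sw <- seq_len(min(12L, L))
      r5 <- rowSums(S[, sw, drop = FALSE] == 2L) +
        0.5 * rowSums(S[, sw, drop = FALSE] == 1L) <= th$max_seed_score
      M <- S == 0L
      stacked <- M[, 1:(L - 1), drop = FALSE] & M[, 2:L, drop = FALSE]
      energy <- as.numeric(stacked %*% e)
      r6 <- abs(energy) >= th$min_energy_fraction * abs(perfect)
      pass <- r1 & r2 & r3 & r4 & r5 & r6
      keep <- if (all_windows) rep(TRUE, W) else pass
      if (!any(keep)) next
      wi <- which(keep)
      out[[length(out) + 1L]] <- data.frame(
        mirna = names(mir)[mi], transcript = names(txs)[ti],
        start = wi - 1L, end = wi - 1L + L,
        r1 = r1[wi], r2 = r2[wi], r3 = r3[wi], r4 = r4[wi], r5 = r5[wi],
        r6 = r6[wi], pass = pass[wi],
        mismatch_score = score[wi], energy = energy[wi],
        perfect_energy = perfect,
        energy_ratio = if (perfect == 0) 0 else abs(energy[wi]) / abs(perfect),
        cleavage_position = wi - 1L + L - 11L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0), r1 = logical(0),
                      r2 = logical(0), r3 = logical(0), r4 = logical(0),
                      r5 = logical(0), r6 = logical(0), pass = logical(0),
                      mismatch_score = numeric(0), energy = numeric(0),
                      perfect_energy = numeric(0), energy_ratio = numeric(0),
                      cleavage_position = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Confirm a target site against degradome tags
#'
#' Counts tag 5' ends at the two-base slice window (cleavage_position and
#' cleavage_position + 1, the bases opposite miRNA positions 10-11) and
#' computes the binomial tail probability of at least that many tags among
#' all tags on the transcript with success probability 2 / transcript
#' length. Confirmed when p < alpha. With zero tags on the transcript the
#' evidence is undefined and the site is unconfirmed.
#'
#' @param site list or one-row data.frame with transcript and
#'   cleavage_position.
#' @param tags data.frame: transcript, pos (0-based 5'-end position), count.
#' @param transcript_length length of the site's transcript in nt.
#' @param alpha significance level (default 0.05).
#' @return list: tags_at_slice, tags_total, p_value, confirmed.
#' @export
degradome_confirm <- function(site, tags, transcript_length, alpha = 0.05) {
  tt <- tags[tags$transcript == site$transcript, , drop = FALSE]
  total <- sum(tt$count)
  if (total == 0) {
    return(list(tags_at_slice = 0L, tags_total = 0L, p_value = NA_real_,
                confirmed = FALSE))
  }
  slice <- c(site$cleavage_position, site$cleavage_position + 1L)
  at <- sum(tt$count[tt$pos %in% slice])
  p <- stats::pbinom(at - 1, total, 2 / transcript_length,
                     lower.tail = FALSE)
  list(tags_at_slice = at, tags_total = total, p_value = p,
       confirmed = p < alpha)
}

#' Overlap (Venn) counts of target-pair sets across methods
#'
#' Sites are keyed by (miRNA, transcript); for every non-empty method
#' combination the count of pairs found by exactly those methods is
#' reported. Totals are conserved.
#'
#' @param site_sets named list; each element a data.frame with columns
#'   mirna and transcript (or a character vector of ready-made keys).
#' @return data.frame: methods (e.g. "rules_strict&degradome"), count.
#' @export
overlap_methods <- function(site_sets) {
  keys <- lapply(site_sets, function(s) {
    if (is.character(s)) unique(s) else
      unique(paste(s$mirna, s$transcript, sep = "\r"))
  })
  all_keys <- unique(unlist(keys))
  mem <- vapply(keys, function(k) all_keys %in% k,
                logical(length(all_keys)))
  if (length(all_keys) == 1L) mem <- matrix(mem, nrow = 1,
                                            dimnames = list(NULL, names(keys)))
  combo <- apply(mem, 1, function(row) {
    paste(names(keys)[row], collapse = "&")
  })
  combos <- unlist(lapply(seq_along(keys), function(k) {
    utils::combn(names(keys), k, paste, collapse = "&")
  }))
  tab <- table(factor(combo, levels = combos))
  data.frame(methods = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
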