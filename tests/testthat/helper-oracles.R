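# Independent oracles, deliberately coded apart from the package internals.

# Maximum base-pairing count by Nussinov dynamic programming (no traceback,
# no energy model). Watson-Crick + G:U, minimum hairpin loop of 3 nt.
oracle_max_pairs <- function(sequence, min_loop = 3L) {
  s <- strsplit(toupper(chartr("u", "T", chartr("U", "T", sequence))),
                "")[[1]]
  pairs_ok <- matrix(FALSE, 4, 4,
                     dimnames = list(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")))
  pairs_ok["A", "T"] <- pairs_ok["T", "A"] <- TRUE
  pairs_ok["G", "C"] <- pairs_ok["C", "G"] <- TRUE
  pairs_ok["G", "T"] <- pairs_ok["T", "G"] <- TRUE
  n <- length(s)
  M <- matrix(0L, n, n)
  for (span in seq_len(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      for (k in i:(j - 1L)) {
        if (j - k > min_loop && s[k] %in% rownames(pairs_ok) &&
            s[j] %in% rownames(pairs_ok) && pairs_ok[s[k], s[j]]) {
          left <- if (k > i) M[i, k - 1L] else 0L
          best <- max(best, left + M[k + 1L, j - 1L] + 1L)
        }
      }
      M[i, j] <- best
    }
  }
  M[1, n]
}

# Brute-force checker for the six target rules, working directly on a state
# vector over miRNA positions ("match"/"GU"/"mismatch") plus the duplex and
# perfect energies. Written rule by rule from first principles.
oracle_rules <- function(states, duplex_energy, perfect_energy) {
  L <- length(states)
  score_of <- function(v) sum(v == "mismatch") + 0.5 * sum(v == "GU")
  r1 <- score_of(states) <= 4
  # longest run of consecutive non-matches
  run <- 0L; maxrun <- 0L
  for (i in seq_len(L)) {
    run <- if (states[i] != "match") run + 1L else 0L
    maxrun <- max(maxrun, run)
  }
  r2 <- maxrun <= 2
  r3 <- TRUE
  for (i in 2:11) {
    if (states[i] != "match" && states[i + 1] != "match") r3 <- FALSE
  }
  r4 <- states[10] == "match" && states[11] == "match"
  r5 <- score_of(states[1:12]) <= 2.5
  r6 <- abs(duplex_energy) >= 0.75 * abs(perfect_energy)
  c(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5, r6 = r6,
    pass = r1 && r2 && r3 && r4 && r5 && r6)
}

# Naive O(n*m) exact-occurrence scan of one read against a genome string,
# both strands, returning 0-based half-open hits.
oracle_scan <- function(read, genome) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", read), "")[[1]]),
              collapse = "")
  out <- list()
  L <- nchar(read)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read else rc
    for (i in seq_len(nchar(genome) - L + 1L)) {
      if (substr(genome, i, i + L - 1L) == pat) {
        out[[length(out) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Construct a (miRNA, site) pair realizing a given state vector: the site is
# the reverse complement with substitutions realizing GU or mismatch states.
realize_duplex <- function(states, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(states)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gu <- c(G = "T", T = "G")
  repeat {
    m <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (all(states != "GU" | m %in% c("G", "T"))) break
  }
  site_rev <- character(L)  # site base opposite miRNA position i
  for (i in seq_len(L)) {
    b <- m[i]
    site_rev[i] <- switch(states[i],
      match = comp[[b]],
      GU = gu[[b]],
      mismatch = {
        bad <- c(comp[[b]], if (b %in% names(gu)) gu[[b]])
        sample(setdiff(c("A", "C", "G", "T"), bad), 1)
      })
  }
  list(mirna = paste(m, collapse = ""),
       site = paste(rev(site_rev), collapse = ""))
}
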