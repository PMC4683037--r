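## Expression quantification and comparison: TPM (reads per million clean
## reads), log2 and max-normalized views, the >2-fold differential rule,
## miRNA-target correlation screening, hierarchical clustering / PCA
## reporting, and the efficiency-corrected stem-loop RT-PCR ratio.

#' Compute TPM (reads per million clean reads)
#'
#' TPM = count / total clean reads x 1e6, per library.
#'
#' @param x a \code{\link{count_table}}, or an integer matrix with
#'   \code{clean_totals} supplied.
#' @param clean_totals per-library totals when \code{x} is a matrix.
#' @param ids optional row ids (defaults to sequences for a count table).
#' @return numeric matrix of TPM values (rows = ids, columns = libraries).
#' @export
compute_tpm <- function(x, clean_totals = NULL, ids = NULL) {
  if (inherits(x, "count_table")) {
    counts <- x$counts
    clean_totals <- x$clean_totals
    if (is.null(ids)) ids <- x$sequence
  } else {
    counts <- as.matrix(x)
    if (is.null(clean_totals)) stop("clean_totals required for matrix input")
    if (is.null(ids)) ids <- rownames(counts)
  }
  if (any(clean_totals <= 0)) stop("clean totals must be positive")
  tpm <- sweep(counts, 2, clean_totals, "/") * 1e6
  rownames(tpm) <- ids
  tpm
}

#' Log2-transform an expression matrix with a pseudocount
#'
#' @param m numeric matrix (e.g. TPM).
#' @param pseudocount added before the log (must be > 0; default 1).
#' @return log2(m + pseudocount).
#' @export
log2_matrix <- function(m, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2(m + pseudocount)
}

#' Max-normalize each row of an expression matrix to [0, 1]
#'
#' Each row is divided by its own maximum. All-zero rows remain zero and are
#' flagged in the \code{"zero_rows"} attribute.
#'
#' @param m numeric matrix.
#' @return normalized matrix with attribute \code{zero_rows}.
#' @export
max_normalize <- function(m) {
  mx <- apply(m, 1, max)
  zero <- mx == 0
  out <- m
  out[!zero, ] <- m[!zero, , drop = FALSE] / mx[!zero]
  attr(out, "zero_rows") <- rownames(m)[zero]
  out
}

#' Call differentially expressed rows from a max-normalized matrix
#'
#' A row detected in at least one library (TPM >= \code{detection}) whose
#' minimum normalized value is below 0.5 (equivalently max/min ratio > 2) is
#' called differential.
#'
#' @param tpm TPM matrix (used for the detection threshold).
#' @param detection minimum TPM in at least one library (default 1).
#' @param cutoff normalized-value cutoff (default 0.5).
#' @return data.frame: id, detected, is_differential, max_library, plus the
#'   normalized profile columns.
#' @export
call_differential <- function(tpm, detection = 1, cutoff = 0.5) {
  norm <- max_normalize(tpm)
  detected <- apply(tpm, 1, max) >= detection
  is_diff <- detected & apply(norm, 1, min) < cutoff
  max_lib <- colnames(tpm)[max.col(tpm, ties.method = "first")]
  out <- data.frame(id = rownames(tpm), detected = detected,
                    is_differential = unname(is_diff),
                    max_library = max_lib,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(norm, optional = TRUE))
}

#' Correlate a miRNA profile with a target profile
#'
#' Both profiles must cover identical libraries. The inverse-pair flag is
#' raised when both profiles change more than 2-fold (max/min on the raw
#' profiles) and the Pearson correlation is below -0.5.
#'
#' @param mirna,target numeric vectors over the same libraries (raw TPM or
#'   abundance units; fold changes are computed on these, the correlation on
#'   their max-normalized form is identical to the raw correlation up to
#'   scaling and is computed directly).
#' @param fold_cutoff fold-change threshold (default 2).
#' @param cor_cutoff correlation threshold (default -0.5).
#' @param method correlation type (default "pearson").
#' @return list: correlation, fold_mirna, fold_target, inverse_pair.
#' @export
correlate_pairs <- function(mirna, target, fold_cutoff = 2,
                            cor_cutoff = -0.5, method = "pearson") {
  if (length(mirna) != length(target)) stop("profiles over different libraries")
  fold <- function(v) {
    if (min(v) == 0) Inf else max(v) / min(v)
  }
  r <- if (stats::sd(mirna) == 0 || stats::sd(target) == 0) NA_real_ else
    stats::cor(mirna, target, method = method)
  fm <- fold(mirna); ft <- fold(target)
  list(correlation = r, fold_mirna = fm, fold_target = ft,
       inverse_pair = !is.na(r) && fm > fold_cutoff && ft > fold_cutoff &&
         r < cor_cutoff)
}

#' Efficiency-corrected relative expression ratio (Pfaffl method)
#'
#' ratio = E_target^dCt_target / E_ref^dCt_ref, with dCt = Ct(control) -
#' Ct(sample). Efficiencies outside the ideal window (default 1.8-2.05) are
#' flagged, not rejected.
#'
#' @param e_target,e_ref amplification efficiencies (in (1, 3); 2 = perfect
#'   doubling).
#' @param dct_target,dct_ref threshold-cycle differences (control - sample).
#' @param ideal ideal efficiency window.
#' @return list: ratio, efficiency_flagged.
#' @export
pfaffl_ratio <- function(e_target, e_ref, dct_target, dct_ref,
                         ideal = c(1.8, 2.05)) {
  if (any(c(e_target, e_ref) <= 1) || any(c(e_target, e_ref) >= 3)) {
    stop("amplification efficiencies must lie in (1, 3)")
  }
  flagged <- any(c(e_target, e_ref) < ideal[1] | c(e_target, e_ref) > ideal[2])
  list(ratio = e_target^dct_target / e_ref^dct_ref,
       efficiency_flagged = flagged)
}

#' Apply the Pfaffl ratio to a qPCR measurement table
#'
#' @param df data.frame with columns id, E_target, E_ref, dCt_target,
#'   dCt_ref (e.g. from \code{\link{read_results_tsv}}).
#' @return the table with ratio and efficiency_flagged columns appended.
#' @export
pfaffl_table <- function(df) {
  need <- c("id", "E_target", "E_ref", "dCt_target", "dCt_ref")
  if (!all(need %in% names(df))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(df)), function(i) {
    pfaffl_ratio(df$E_target[i], df$E_ref[i], df$dCt_target[i],
                 df$dCt_ref[i])
  })
  df$ratio <- vapply(res, `[[`, numeric(1), "ratio")
  df$efficiency_flagged <- vapply(res, `[[`, logical(1),
                                  "efficiency_flagged")
  df
}

#' Hierarchical clustering and PCA of an expression matrix
#'
#' Columns (libraries) and rows are clustered with Euclidean distance and
#' average linkage; the principal components are those of the column
#' profiles. Deterministic for fixed input.
#'
#' @param m numeric matrix (typically log2 TPM), >= 2 rows and columns.
#' @return list: col_hclust, row_hclust (hclust objects), col_order,
#'   row_order, pca (prcomp of column profiles), variance_share.
#' @export
cluster_and_project <- function(m) {
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2 x 2 matrix")
  ch <- stats::hclust(stats::dist(t(m)), method = "average")
  rh <- stats::hclust(stats::dist(m), method = "average")
  pca <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  vs <- pca$sdev^2 / sum(pca$sdev^2)
  list(col_hclust = ch, row_hclust = rh,
       col_order = colnames(m)[ch$order], row_order = rownames(m)[rh$order],
       pca = pca, variance_share = vs)
}
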