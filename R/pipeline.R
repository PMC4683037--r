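## Pipeline orchestration: a validated hierarchical configuration with the
## published defaults, staged execution (simulate -> annotate -> discover ->
## express -> targets -> report) with on-disk intermediates and resume, and
## a run manifest with config/input checksums and per-stage record counts.

#' Default pipeline configuration
#'
#' Every stage threshold is present with its default: 18-30 nt length
#' window, two mismatches for known-miRNA matching, 150-nt precursor flanks,
#' MFEI > 0.85 and the other three novel-miRNA criteria, TPM detection
#' threshold 1, 0.5 max-normalized differential cutoff, the six target rules
#' (4 mismatches, G:U = 0.5, perfect 10-11, 2.5 over 1-12, 75\% energy),
#' and degradome alpha 0.05.
#'
#' @param simulate use the synthetic generator (TRUE) or user inputs.
#' @param sim list of \code{\link{sim_config}} overrides.
#' @param inputs named list of input paths (genome_fasta, reads_tsv,
#'   annotations, rRNA/tRNA/snoRNA/snRNA FASTAs, known_mirnas,
#'   transcripts_fasta, degradome_tsv) when \code{simulate} is FALSE.
#' @param seed integer seed for the whole run.
#' @return nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulate = TRUE, sim = list(), inputs = list(),
                            seed = 1L) {
  cfg <- list(
    simulate = simulate,
    seed = as.integer(seed),
    sim = sim,
    inputs = inputs,
    annotate = list(min_len = 18L, max_len = 30L, known_mm = 2L,
                    precedence = c("known_miRNA", "rRNA", "tRNA",
                                   "snoRNA", "snRNA")),
    discover = list(flank = 150L, candidate_min_reads = 4L,
                    prefix = "OsmiR", engine = "rnafold",
                    thresholds = novel_criteria_defaults()),
    express = list(detection_tpm = 1, diff_cutoff = 0.5, pseudocount = 1,
                   fold_cutoff = 2, cor_cutoff = -0.5),
    targets = list(rules = target_rule_defaults(),
                   relaxed = utils::modifyList(target_rule_defaults(),
                                               list(max_mismatch = 5,
                                                    max_seed_score = 3)),
                   degradome_alpha = 0.05)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are errors (a silent typo would corrupt threshold
#' semantics); missing keys keep their defaults. The configuration
#' round-trips losslessly through \code{\link{write_pipeline_config}}.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- unclass(pipeline_config())
  check <- function(u, b, prefix = "") {
    extra <- setdiff(names(u), names(b))
    if (length(extra)) {
      stop("unknown configuration key(s): ",
           paste0(prefix, extra, collapse = ", "))
    }
    for (k in names(u)) {
      if (is.list(u[[k]]) && is.list(b[[k]]) &&
          !k %in% c("sim", "inputs")) {
        check(u[[k]], b[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check(user, base)
  cfg <- utils::modifyList(base, user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration as YAML
#' @param config a \code{pipeline_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

.stage_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the analysis pipeline end to end
#'
#' Executes simulate (optional), annotate, discover, express, targets and
#' report, writing each stage's TSV outputs under \code{outdir}. With
#' \code{resume = TRUE} a stage whose outputs already exist is loaded from
#' disk instead of recomputed, and resumed runs are byte-identical to
#' uninterrupted ones on all TSV outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir output directory (created if needed).
#' @param resume reuse existing stage outputs.
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a result bundle: count table, annotated reads,
#'   classification summary, catalog, expression matrices, differential
#'   calls, target sites, venn counts, registry (when simulated) and the
#'   run manifest.
#' @export
run_pipeline <- function(config, outdir, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = .config_hash(config),
                   seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  counts_n <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], list(...))
  }

  # ---- stage: simulate / load inputs
  simdir <- file.path(outdir, "sim")
  if (config$simulate) {
    dir.create(simdir, showWarnings = FALSE)
    reg_file <- file.path(simdir, "registry.json")
    if (resume && file.exists(reg_file)) {
      .stage_log(quiet, "simulate", "resuming from ", simdir)
      sim <- .load_simulation(simdir)
    } else {
      scfg <- do.call(sim_config, utils::modifyList(
        config$sim, list(seed = config$seed)))
      .stage_log(quiet, "simulate", "generating synthetic study (seed ",
                 scfg$seed, ")")
      ref <- generate_reference(scfg)
      ct <- simulate_libraries(ref, scfg)
      txp <- simulate_transcriptome(ref, scfg)
      tags <- simulate_degradome(txp, scfg)
      sim <- list(reference = ref, counts = ct,
                  transcripts = txp$transcripts,
                  registry = txp$registry, degradome = tags, config = scfg)
      .write_simulation(sim, simdir)
    }
    genome <- sim$reference$genome
    references <- sim$reference$references
    known <- sim$reference$known_mirnas
    annotations <- sim$reference$annotations
    ct <- sim$counts
    transcripts <- sim$transcripts
    tags <- sim$degradome
    registry <- sim$registry
  } else {
    inp <- config$inputs
    need <- function(key, stage) {
      f <- inp[[key]]
      if (is.null(f) || !all(file.exists(unlist(f)))) {
        stop("stage '", stage, "': missing input file for '", key, "'",
             if (!is.null(f)) paste0(": ", paste(unlist(f), collapse = ", ")))
      }
      f
    }
    genome <- read_fasta(need("genome_fasta", "annotate"))
    references <- list(
      rRNA = read_fasta(need("rRNA_fasta", "annotate")),
      tRNA = read_fasta(need("tRNA_fasta", "annotate")),
      snoRNA = read_fasta(need("snoRNA_fasta", "annotate")),
      snRNA = read_fasta(need("snRNA_fasta", "annotate")))
    known <- read_fasta(need("known_mirnas_fasta", "annotate"))
    annotations <- read_annotations(need("annotations", "annotate"))
    ct <- .read_counts_tsv(need("reads_tsv", "annotate"))
    transcripts <- if (!is.null(inp$transcripts_fasta)) {
      read_fasta(need("transcripts_fasta", "targets"))
    } else NULL
    tags <- if (!is.null(inp$degradome_tsv)) {
      read_results_tsv(need("degradome_tsv", "targets"))
    } else NULL
    registry <- NULL
  }
  counts_n("input", libraries = length(ct$library_ids),
           unique_reads = length(ct$sequence))

  # ---- stage: annotate
  acfg <- config$annotate
  lf <- length_filter(ct, acfg$min_len, acfg$max_len)
  hits <- map_exact(lf, genome)
  ann <- classify(lf, hits, references, known, cds = annotations,
                  precedence = acfg$precedence, max_mm = acfg$known_mm)
  summ <- summarize_classification(ann)
  write_results_tsv(summ, file.path(outdir, "classification_summary.tsv"))
  write_results_tsv(ann, file.path(outdir, "annotated_reads.tsv"))
  .stage_log(quiet, "annotate", nrow(ann), " reads classified")
  counts_n("annotate", reads = nrow(ann), mapped = sum(!is.na(ann$category)))

  # ---- stage: discover
  dcfg <- config$discover
  libs <- attr(ann, "library_ids")
  cnt <- as.matrix(ann[, libs, drop = FALSE])
  pool <- which(ann$category == "other" & !ann$cds_overlap &
                apply(cnt, 1, max) >= dcfg$candidate_min_reads)
  cands <- evaluate_candidates(ann$sequence[pool],
                               cnt[pool, , drop = FALSE], hits, genome,
                               all_reads = ann$sequence,
                               flank = dcfg$flank,
                               thresholds = dcfg$thresholds,
                               engine = dcfg$engine)
  catalog <- name_and_merge(cands, prefix = dcfg$prefix)
  write_results_tsv(cands, file.path(outdir, "candidates.tsv"))
  write_results_tsv(catalog$precursors, file.path(outdir, "catalog.tsv"))
  if (nrow(catalog$precursors)) {
    write_fasta(seq_set(stats::setNames(catalog$precursors$precursor,
                                        catalog$precursors$precursor_name)),
                file.path(outdir, "precursors.fa"))
    write_annotations(data.frame(
      chrom = catalog$precursors$chrom,
      start = catalog$precursors$prec_start,
      end = catalog$precursors$prec_end,
      strand = catalog$precursors$strand,
      feature = "miRNA_primary_transcript",
      id = catalog$precursors$precursor_name,
      stringsAsFactors = FALSE), file.path(outdir, "catalog.gff3"))
    writeLines(paste0(">", catalog$precursors$precursor_name, "\n",
                      catalog$precursors$precursor, "\n",
                      catalog$precursors$dotbracket),
               file.path(outdir, "precursors.dotbracket"))
  }
  .stage_log(quiet, "discover", nrow(cands), " candidates, ",
             nrow(catalog$mirnas), " novel miRNAs")
  counts_n("discover", candidates = nrow(cands),
           novel = nrow(catalog$mirnas))

  # ---- stage: express
  ecfg <- config$express
  mir_seqs <- c(stats::setNames(unclass(known), names(known)),
                stats::setNames(catalog$mirnas$mature, catalog$mirnas$name))
  midx <- match(mir_seqs, ct$sequence)
  mir_counts <- ct$counts[midx, , drop = FALSE]
  mir_counts[is.na(midx), ] <- 0L
  tpm <- compute_tpm(mir_counts, ct$clean_totals, ids = names(mir_seqs))
  l2 <- log2_matrix(tpm, ecfg$pseudocount)
  diff <- call_differential(tpm, detection = ecfg$detection_tpm,
                            cutoff = ecfg$diff_cutoff)
  write_results_tsv(tpm, file.path(outdir, "expression_tpm.tsv"))
  write_results_tsv(l2, file.path(outdir, "expression_log2tpm.tsv"))
  write_results_tsv(diff, file.path(outdir, "differential.tsv"))
  clust <- if (nrow(tpm) >= 2 && ncol(tpm) >= 2) cluster_and_project(l2)
           else NULL
  .stage_log(quiet, "express", sum(diff$is_differential),
             " differential of ", nrow(diff), " miRNAs")
  counts_n("express", mirnas = nrow(tpm),
           differential = sum(diff$is_differential))

  # ---- stage: targets
  tcfg <- config$targets
  sites <- venn <- NULL
  if (!is.null(transcripts) && length(transcripts)) {
    sites <- scan_transcripts(mir_seqs, transcripts,
                              thresholds = tcfg$rules)
    relaxed <- scan_transcripts(mir_seqs, transcripts,
                                thresholds = tcfg$relaxed)
    if (!is.null(tags) && nrow(sites)) {
      txlen <- stats::setNames(nchar(unclass(transcripts)),
                               names(transcripts))
      ev <- lapply(seq_len(nrow(sites)), function(i) {
        degradome_confirm(sites[i, ], tags, txlen[[sites$transcript[i]]],
                          alpha = tcfg$degradome_alpha)
      })
      sites$tags_at_slice <- vapply(ev, `[[`, numeric(1), "tags_at_slice")
      sites$tags_total <- vapply(ev, `[[`, numeric(1), "tags_total")
      sites$p_value <- vapply(ev, `[[`, numeric(1), "p_value")
      sites$confirmed <- vapply(ev, `[[`, logical(1), "confirmed")
    } else if (nrow(sites)) {
      sites$tags_at_slice <- NA_integer_
      sites$tags_total <- NA_integer_
      sites$p_value <- NA_real_
      sites$confirmed <- FALSE
    }
    write_results_tsv(sites, file.path(outdir, "target_sites.tsv"))
    venn <- overlap_methods(list(
      rules_strict = sites,
      rules_relaxed = relaxed,
      degradome = sites[sites$confirmed, , drop = FALSE]))
    write_results_tsv(venn, file.path(outdir, "method_overlap.tsv"))
    .stage_log(quiet, "targets", nrow(sites), " sites (",
               sum(sites$confirmed), " degradome-confirmed)")
    counts_n("targets", sites = nrow(sites),
             confirmed = sum(sites$confirmed))
  }

  # ---- stage: report
  report <- write_report(list(summary = summ, catalog = catalog,
                              annotations = annotations, tpm = tpm,
                              diff = diff, sites = sites, venn = venn),
                         outdir)
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(counts = ct, annotated = ann, summary = summ,
                 hits = hits, candidates = cands, catalog = catalog,
                 tpm = tpm, log2 = l2, differential = diff,
                 clustering = clust, sites = sites, venn = venn,
                 registry = registry, manifest = manifest))
}

#' Write figure-style report tables for a pipeline bundle
#'
#' Emits the classification summary (already shaped like a library
#' statistics table), the miRNA size distribution, first-base fractions by
#' length class, genome location classes and arm distribution.
#'
#' @param bundle list with summary, catalog, annotations (and optionally
#'   tpm/diff/sites/venn, which are written by their own stages).
#' @param outdir output directory.
#' @return invisibly, the list of written files.
#' @export
write_report <- function(bundle, outdir) {
  files <- character(0)
  if (nrow(bundle$catalog$mirnas)) {
    ms <- summarize_mirnas(bundle$catalog, bundle$annotations)
    write_results_tsv(ms$size_distribution,
                      f <- file.path(outdir, "size_distribution.tsv"))
    files <- c(files, f)
    write_results_tsv(ms$first_base,
                      f <- file.path(outdir, "first_base.tsv"))
    files <- c(files, f)
    if (!is.null(ms$location)) {
      write_results_tsv(data.frame(location = names(ms$location),
                                   count = as.integer(ms$location)),
                        f <- file.path(outdir, "genome_location.tsv"))
      files <- c(files, f)
    }
    write_results_tsv(data.frame(arm = names(ms$arms),
                                 fraction = as.numeric(ms$arms)),
                      f <- file.path(outdir, "arm_distribution.tsv"))
    files <- c(files, f)
  }
  invisible(files)
}

## -- simulation (de)serialization -------------------------------------------

.write_counts_tsv <- function(ct, path) {
  df <- data.frame(sequence = ct$sequence, ct$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_results_tsv(df, path)
}

.read_counts_tsv <- function(path) {
  df <- read_results_tsv(path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  count_table(df$sequence, counts, clean_totals = colSums(counts))
}

.write_simulation <- function(sim, simdir) {
  write_fasta(sim$reference$genome, file.path(simdir, "genome.fa"))
  for (k in names(sim$reference$references)) {
    write_fasta(sim$reference$references[[k]],
                file.path(simdir, paste0(k, ".fa")))
  }
  write_fasta(sim$reference$known_mirnas,
              file.path(simdir, "known_mirnas.fa"))
  write_annotations(sim$reference$annotations,
                    file.path(simdir, "annotations.gff3"))
  .write_counts_tsv(sim$counts, file.path(simdir, "reads.tsv"))
  write_fasta(sim$transcripts, file.path(simdir, "transcripts.fa"))
  write_results_tsv(sim$degradome, file.path(simdir, "degradome.tsv"))
  reg <- sim$registry
  reg$config <- unclass(reg$config)
  jsonlite::write_json(
    lapply(unclass(reg), function(x) {
      if (is.matrix(x)) {
        data.frame(id = rownames(x), x, check.names = FALSE)
      } else x
    }),
    file.path(simdir, "registry.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(simdir)
}

.load_simulation <- function(simdir) {
  refs <- list()
  for (k in c("rRNA", "tRNA", "snoRNA", "snRNA")) {
    refs[[k]] <- read_fasta(file.path(simdir, paste0(k, ".fa")))
  }
  regj <- jsonlite::read_json(file.path(simdir, "registry.json"),
                              simplifyVector = TRUE)
  to_matrix <- function(df) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  regj$planted_tpm <- to_matrix(regj$planted_tpm)
  if (!is.null(regj$transcript_profiles)) {
    regj$transcript_profiles <- to_matrix(regj$transcript_profiles)
  }
  cfg <- do.call(sim_config, regj$config[names(regj$config) %in%
                                           names(formals(sim_config))])
  regj$config <- cfg
  class(regj) <- "ground_truth"
  list(reference = list(
         genome = read_fasta(file.path(simdir, "genome.fa")),
         references = refs,
         known_mirnas = read_fasta(file.path(simdir, "known_mirnas.fa")),
         annotations = read_annotations(file.path(simdir,
                                                  "annotations.gff3")),
         registry = regj),
       counts = .read_counts_tsv(file.path(simdir, "reads.tsv")),
       transcripts = read_fasta(file.path(simdir, "transcripts.fa")),
       registry = regj,
       degradome = read_results_tsv(file.path(simdir, "degradome.tsv")),
       config = cfg)
}
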