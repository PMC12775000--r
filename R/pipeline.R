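#' Run the fine-mapping pipeline end to end
#'
#' Orchestrates the three evidence stages over one locus:
#' \enumerate{
#'   \item \strong{prioritize} — filter the variant block by LD and
#'     intersect with accessibility peaks (needs `variants` + `peaks`);
#'   \item \strong{motif scan} — allele-aware PWM scoring of the
#'     prioritized variants with efficiency and p-value fold changes
#'     (needs `pfm` + `genome`);
#'   \item \strong{imbalance} — per-donor and pooled exact binomial tests
#'     of the allelic count table, plus a ploidy-null sensitivity sweep
#'     (needs `counts`).
#' }
#' A stage runs iff its inputs are configured; a later stage that depends
#' on a missing one degrades gracefully (the motif scan falls back to all
#' variants if prioritization did not run). Before any stage runs, the
#' chromosome names of variants, peaks and genome are checked for
#' consistency (after optional `chrom_normalize`); disjoint naming is an
#' error.
#'
#' @param config Path to a YAML config, or an equivalent nested list with
#'   elements `inputs` (`variants`, `dialect`, `peaks`, `genome`, `pfm`,
#'   `counts`; paths relative to the config file) and `params` (`r2_min`,
#'   `flank`, `pseudocount`, `background`, `grid_step`, `method`, `null_p`
#'   or `ploidy` + `ref_copies`, `sensitivity_nulls`, `counts_variant`,
#'   `chrom_normalize`).
#' @param output_dir Optional directory to write `evidence.json`,
#'   `prioritized.tsv`, `motif_report.tsv`, `imbalance.tsv` and
#'   `run_manifest.json`. Reports are byte-stable across reruns with the
#'   same config.
#' @param quiet Suppress progress messages.
#' @return A list of class `evidence_summary`: per-candidate evidence
#'   (`candidates`), the annotated block, the imbalance results, and the
#'   parameters used.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) fm_stop("config file not found: ", config)
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  inputs <- config$inputs %||% list()
  params <- config$params %||% list()
  say <- function(...) if (!quiet) message(...)

  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  paths <- lapply(inputs[c("variants", "peaks", "genome", "pfm", "counts")],
                  resolve)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      fm_stop("input file for '", nm, "' not found: ", paths[[nm]])
    }
  }
  if (all(vapply(paths, is.null, logical(1)))) {
    fm_stop("config names no inputs; at least one stage must be runnable")
  }

  chrom_mode <- params$chrom_normalize %||% "none"
  variants <- peaks <- genome <- NULL
  if (!is.null(paths$variants)) {
    variants <- read_variants(paths$variants, dialect = inputs$dialect %||% "vcf")
    variants$chrom <- norm_chrom(variants$chrom, chrom_mode)
  }
  if (!is.null(paths$peaks)) {
    peaks <- read_bed(paths$peaks)
    peaks$chrom <- norm_chrom(peaks$chrom, chrom_mode)
  }
  if (!is.null(paths$genome)) {
    genome <- Biostrings::readDNAStringSet(paths$genome)
    names(genome) <- norm_chrom(sub("\\s.*$", "", names(genome)), chrom_mode)
  }

  # pre-flight: inputs must share a chromosome namespace before any stage runs
  if (!is.null(variants) && nrow(variants) > 0) {
    if (!is.null(peaks) && nrow(peaks) > 0 &&
        length(intersect(variants$chrom, peaks$chrom)) == 0) {
      fm_stop("chromosome naming mismatch between variants (",
              paste(unique(variants$chrom), collapse = ","), ") and peaks (",
              paste(unique(peaks$chrom), collapse = ","),
              "); set params$chrom_normalize to 'strip' or 'add'")
    }
    if (!is.null(genome) &&
        length(intersect(variants$chrom, names(genome))) == 0) {
      fm_stop("chromosome naming mismatch between variants and genome contigs")
    }
  }

  summary <- list(params = params, stages = character(0))

  # --- stage 1: prioritize -------------------------------------------------
  annotated <- prioritized <- NULL
  if (!is.null(variants) && !is.null(peaks)) {
    r2_min <- params$r2_min %||% 0.8
    if (!is.null(variants$r2_to_lead)) {
      res <- prioritize_variants(variants, peaks, r2_min, quiet = quiet)
    } else {
      res <- list(annotated = intersect_variants_peaks(variants, peaks,
                                                       quiet = quiet))
      res$prioritized <- res$annotated[res$annotated$in_peak, , drop = FALSE]
    }
    annotated <- res$annotated
    prioritized <- res$prioritized
    summary$stages <- c(summary$stages, "prioritize")
    say(sprintf("prioritize: %d/%d variants in peaks", nrow(prioritized),
                nrow(annotated)))
  }

  # --- stage 2: motif scan -------------------------------------------------
  motif_reports <- NULL
  if (!is.null(paths$pfm) && !is.null(genome) && !is.null(variants)) {
    scan_set <- prioritized %||% variants
    if (nrow(scan_set) > 0) {
      motif <- read_pfm(paths$pfm)
      pwm <- pfm_to_pwm(motif,
                        pseudocount = params$pseudocount %||% 0.01,
                        background = unlist(params$background %||% rep(0.25, 4)))
      dist <- score_distribution(pwm, params$grid_step %||% 0.001)
      motif_reports <- lapply(seq_len(nrow(scan_set)), function(i) {
        pair <- extract_windows(genome, scan_set[i, ],
                                flank = params$flank %||% 25)
        binding_report(pwm, pair, dist = dist)
      })
      names(motif_reports) <- scan_set$id
      summary$stages <- c(summary$stages, "scan")
      say(sprintf("scan: %d variant(s) scored against motif %s",
                  length(motif_reports), pwm$motif_id))
    }
  }

  # --- stage 3: allelic imbalance -----------------------------------------
  imbalance <- sensitivity <- NULL
  if (!is.null(paths$counts)) {
    counts <- read_counts(paths$counts)
    null_p <- params$null_p %||%
      ploidy_null(params$ploidy %||% 2, params$ref_copies %||% 1)
    method <- params$method %||% "minlike"
    imbalance <- test_samples(counts, null_p, method = method)
    nulls <- unlist(params$sensitivity_nulls %||% numeric(0))
    if (length(nulls) > 0) {
      sensitivity <- null_sensitivity(imbalance$pooled$k, imbalance$pooled$n,
                                      nulls, method = method,
                                      sample_id = "pooled")
    }
    summary$stages <- c(summary$stages, "imbalance")
    say(sprintf("imbalance: pooled fraction %.3f, p = %.3g (%s)",
                imbalance$pooled_fraction, imbalance$pooled$pvalue,
                imbalance$pooled$direction))
  }

  # --- combine into per-candidate evidence --------------------------------
  counts_variant <- params$counts_variant %||%
    (if (!is.null(prioritized) && nrow(prioritized) > 0) prioritized$id[1] else NULL)
  cand_ids <- if (!is.null(prioritized) && nrow(prioritized) > 0) prioritized$id
              else if (!is.null(motif_reports)) names(motif_reports)
              else counts_variant
  candidates <- lapply(cand_ids, function(id) {
    ev <- list(variant_id = id)
    if (!is.null(annotated)) {
      row <- annotated[annotated$id == id, ]
      ev$in_peak <- isTRUE(row$in_peak[1])
      if (!is.null(row$r2_to_lead)) ev$r2_to_lead <- row$r2_to_lead[1]
    }
    rep <- motif_reports[[id]]
    if (!is.null(rep)) {
      ev$efficiency_fold_change <- rep$efficiency_fold_change
      ev$log2_efficiency_fold_change <- log2(rep$efficiency_fold_change)
      ev$favored_allele <- rep$favored_allele
      ev$pvalue_ref <- rep$pvalue_ref
      ev$pvalue_alt <- rep$pvalue_alt
      ev$pvalue_fold_change <- rep$pvalue_fold_change
    }
    if (!is.null(imbalance) && !is.null(counts_variant) && id == counts_variant) {
      ev$imbalance_pooled_p <- imbalance$pooled$pvalue
      ev$imbalance_direction <- imbalance$pooled$direction
      ev$imbalance_pooled_fraction <- imbalance$pooled_fraction
      if (!is.null(sensitivity)) {
        ev$null_sensitivity <- sensitivity[, c("null_p", "pvalue", "direction")]
      }
    }
    ev
  })
  names(candidates) <- cand_ids

  summary$candidates <- candidates
  summary$annotated <- annotated
  summary$motif_reports <- motif_reports
  summary$imbalance <- imbalance
  summary$sensitivity <- sensitivity
  class(summary) <- "evidence_summary"

  if (!is.null(output_dir)) write_evidence(summary, output_dir, paths)
  summary
}

write_evidence <- function(summary, output_dir, paths = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(summary$annotated)) {
    utils::write.table(summary$annotated,
                       file.path(output_dir, "prioritized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(summary$motif_reports)) {
    write_motif_report(summary$motif_reports,
                       file.path(output_dir, "motif_report.tsv"))
  }
  if (!is.null(summary$imbalance)) {
    imb <- rbind(summary$imbalance$per_sample, summary$imbalance$pooled)
    if (!is.null(summary$sensitivity)) imb <- rbind(imb, summary$sensitivity)
    utils::write.table(imb, file.path(output_dir, "imbalance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(summary$candidates, evidence_to_json),
    file.path(output_dir, "evidence.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE
  )
  manifest <- list(
    stages = summary$stages,
    params = summary$params,
    inputs = if (!is.null(paths)) {
      lapply(Filter(Negate(is.null), paths), function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    }
  )
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

evidence_to_json <- function(ev) {
  if (!is.null(ev$null_sensitivity)) {
    ev$null_sensitivity <- lapply(seq_len(nrow(ev$null_sensitivity)), function(i) {
      as.list(ev$null_sensitivity[i, ])
    })
  }
  ev
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat("Fine-mapping evidence summary\n")
  cat("  stages run:", paste(x$stages, collapse = " -> "), "\n")
  for (ev in x$candidates) {
    cat(sprintf("  %s:", ev$variant_id))
    if (!is.null(ev$in_peak)) cat(sprintf(" in_peak=%s", ev$in_peak))
    if (!is.null(ev$efficiency_fold_change)) {
      cat(sprintf(" eff_fc=%.4g (favoring %s) p_fc=%.4g",
                  ev$efficiency_fold_change, ev$favored_allele,
                  ev$pvalue_fold_change))
    }
    if (!is.null(ev$imbalance_pooled_p)) {
      cat(sprintf(" imbalance_p=%.3g (%s)", ev$imbalance_pooled_p,
                  ev$imbalance_direction))
    }
    cat("\n")
  }
  invisible(x)
}
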