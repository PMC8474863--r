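# End-to-end pipeline: FASTQ pair -> preprocessing -> classification ->
# counts -> ratios -> error profile -> report -> genotype call.

#' Pipeline configuration
#'
#' @param fastq1,fastq2 Paths to the paired FASTQ files.
#' @param ref_fasta,ref_meta Paths to the reference spec; `NULL` uses the
#'   synthetic default panel.
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   artifact writing.
#' @param params A [filter_params()] object.
#' @param thresholds A [call_thresholds()] object.
#' @param max_mismatch Classification mismatch cutoff, see
#'   [classify_reads()].
#' @param write_merged Logical; also write the surviving merged reads as
#'   FASTQ.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fastq1, fastq2, ref_fasta = NULL, ref_meta = NULL,
                            out_dir = NULL, params = filter_params(),
                            thresholds = call_thresholds(),
                            max_mismatch = 3L, write_merged = FALSE) {
  structure(
    list(
      fastq1 = fastq1, fastq2 = fastq2,
      ref_fasta = ref_fasta, ref_meta = ref_meta,
      out_dir = out_dir, params = params, thresholds = thresholds,
      max_mismatch = as.integer(max_mismatch),
      write_merged = isTRUE(write_merged)
    ),
    class = "pipeline_config"
  )
}

# the analysis core shared by run_pipeline() and in-memory callers
.analyze_reads <- function(pairs, refs, params, thresholds, max_mismatch = 3L) {
  pp <- preprocess_reads(pairs, refs, params)
  if (!nrow(pp$reads)) {
    .rhd_error("no reads survived preprocessing", "rhdamp_error_no_reads")
  }
  assignments <- classify_reads(pp$reads, refs, max_mismatch)
  matrices <- count_bases(pp$reads, assignments, refs)
  diagnostics <- extract_diagnostics(matrices, refs)
  ratios <- allele_ratios(diagnostics)
  profiles <- error_ratio_profile(matrices, refs)
  report <- summarize_run(ratios, profiles, pp$dedup_stats, pp$ledger, thresholds)
  list(
    preprocess = pp,
    assignments = assignments,
    matrices = matrices,
    diagnostics = diagnostics,
    ratios = ratios,
    profiles = profiles,
    report = report
  )
}

#' Run the full genotyping pipeline on a FASTQ pair
#'
#' Executes preprocessing (with optional UMI deduplication),
#' classification, base counting, ratio and error statistics, and the
#' maternal/fetal genotype call; optionally writes the wiggle counts,
#' assignment and error tables, run report and call as artifacts. An
#' unrecognized maternal pattern is reported in the call rather than
#' raised, so an inconclusive outcome is still a successful run.
#'
#' @param config A [pipeline_config()] object.
#' @return List with `result` (the analysis bundle: preprocessing ledger,
#'   assignments, matrices, diagnostics, ratios, profiles, report),
#'   `maternal`, `call` and `paths`.
#' @export
run_pipeline <- function(config) {
  refs <- if (is.null(config$ref_fasta)) {
    default_reference_panel()
  } else {
    load_reference_spec(config$ref_fasta, config$ref_meta)
  }
  pairs <- read_fastq_pair(config$fastq1, config$fastq2)
  if (!nrow(pairs)) {
    .rhd_error("input FASTQ pair contains no reads", "rhdamp_error_empty_input")
  }
  res <- .analyze_reads(pairs, refs, config$params, config$thresholds, config$max_mismatch)

  maternal <- tryCatch(
    call_maternal(res$ratios, tolerance = config$thresholds$maternal_match_tolerance),
    rhdamp_error_maternal_pattern = function(e) e
  )
  call <- if (inherits(maternal, "condition")) {
    structure(
      list(
        maternal_genotype = NULL,
        fetal_status = "inconclusive",
        evidence = list(),
        mixture_fraction_estimate = NA_real_,
        thresholds = unclass(config$thresholds),
        notes = conditionMessage(maternal)
      ),
      class = "genotype_call"
    )
  } else {
    call_fetal(res$ratios, maternal$genotype, config$thresholds)
  }

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      wig = file.path(config$out_dir, "base_counts.wig"),
      assignments = file.path(config$out_dir, "assignments.tsv"),
      error_profile = file.path(config$out_dir, "error_profile.tsv"),
      ledger = file.path(config$out_dir, "ledger.tsv"),
      report = file.path(config$out_dir, "report.json"),
      call = file.path(config$out_dir, "call.json")
    )
    write_wig(res$matrices, refs, paths$wig)
    utils::write.table(res$assignments, paths$assignments,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_error_profile_tsv(res$profiles, paths$error_profile)
    utils::write.table(res$preprocess$ledger, paths$ledger,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_run_report(res$report, paths$report)
    write_genotype_call(call, paths$call)
    if (config$write_merged) {
      paths$merged <- file.path(config$out_dir, "merged.fastq")
      write_merged_fastq(res$preprocess$reads, paths$merged)
    }
  }

  list(
    result = res,
    maternal = if (inherits(maternal, "condition")) NULL else maternal,
    call = call,
    paths = paths
  )
}
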