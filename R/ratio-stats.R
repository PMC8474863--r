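# Allele ratios and the pooled per-position error-ratio statistic.

# Table-style percentage rendering: minor fractions are rounded to two
# decimals (three when below 0.005%), and the largest fraction of a group is
# rendered as 100 minus the rounded minor fractions so displayed values
# total exactly 100%.
.display_pct <- function(counts) {
  total <- sum(counts)
  if (total == 0) {
    return(rep(NA_real_, length(counts)))
  }
  pct <- 100 * counts / total
  out <- numeric(length(pct))
  major <- which.max(pct)
  minor <- setdiff(seq_along(pct), major)
  out[minor] <- ifelse(pct[minor] > 0 & pct[minor] < 0.005,
    round(pct[minor], 3), round(pct[minor], 2)
  )
  out[major] <- round(100 - sum(out[minor]), 2)
  out
}

#' Observed allele ratios from diagnostic counts
#'
#' Computes the upstream/downstream fractions among Rhesus-box reads and the
#' RHD-wild-type / c.1227G>A / RHCE fractions among exon-9 reads. Exact
#' fractions are carried alongside display percentages rendered the way the
#' assay reports them (two decimals, sub-0.005% signals at three decimals,
#' groups totalling 100%). A group with zero total reads yields an `NA`
#' ("no data") result rather than an error.
#'
#' @param d Named counts over the five counting classes, see
#'   [extract_diagnostics()].
#' @return An `allele_ratios` object: per group, `counts`, exact `frac`
#'   (summing to 1) and display `pct`.
#' @export
allele_ratios <- function(d) {
  d <- d[UNIT_NAMES]
  if (any(is.na(d)) || any(d < 0)) {
    .rhd_error("diagnostic counts must be non-negative and complete", "rhdamp_error_counts")
  }
  group <- function(classes) {
    counts <- d[classes]
    total <- sum(counts)
    list(
      counts = counts,
      total = total,
      frac = if (total > 0) counts / total else stats::setNames(rep(NA_real_, length(classes)), classes),
      pct = stats::setNames(.display_pct(counts), classes)
    )
  }
  structure(
    list(box = group(BOX_CLASSES), exon9 = group(EXON9_CLASSES)),
    class = "allele_ratios"
  )
}

#' @export
print.allele_ratios <- function(x, ...) {
  fmt <- function(g, label) {
    if (g$total == 0) {
      cat(sprintf("%s: no data\n", label))
    } else {
      cat(sprintf(
        "%s: %s (%s)\n", label,
        paste(sprintf("%g%%", g$pct), collapse = "/"),
        paste(format(g$counts, big.mark = ",", trim = TRUE), collapse = "/")
      ))
    }
  }
  fmt(x$box, "Rhesus boxes (upstream/downstream)")
  fmt(x$exon9, "RHD/RHCE exon 9 (RHD_wt/RHD_var/RHCE)")
  invisible(x)
}

#' Pooled per-position error-ratio profile of a co-amplified group
#'
#' For each amplicon position, the error ratio is the number of reads whose
#' base differs from their own region's reference base, summed over the two
#' co-amplified regions, divided by the pooled read count at that position.
#' Paralog-diagnostic positions therefore contribute correctly: each
#' region's own base is the reference. Primer footprints and the c.1227
#' variant site (which legitimately varies between alleles of the same
#' region) are excluded from the analyzable range; so are positions without
#' data. Summary `max`, `median` and the pooled ratio are taken over the
#' analyzable positions.
#'
#' @param matrices Output of [count_bases()].
#' @param refs Reference panel.
#' @param group `"rhesus_box"`, `"exon9"`, or `NULL` for all groups.
#' @return Named list per group: `profile` data.frame (`position`, `total`,
#'   `errors`, `ratio`, `excluded_reason`) and `summary` list (`max`,
#'   `median`, `pooled`, `n_analyzable`).
#' @export
error_ratio_profile <- function(matrices, refs, group = NULL) {
  groups <- if (is.null(group)) {
    unique(vapply(refs, `[[`, character(1), "group"))
  } else {
    group
  }
  out <- list()
  for (grp in groups) {
    members <- Filter(function(r) r$group == grp, refs)
    if (!length(members)) {
      .rhd_error(sprintf("no references in group '%s'", grp), "rhdamp_error_group")
    }
    miss <- setdiff(vapply(members, `[[`, character(1), "name"), names(matrices))
    if (length(miss)) {
      .rhd_error(
        sprintf("group '%s': missing base-count matrices for %s", grp, paste(miss, collapse = ", ")),
        "rhdamp_error_contract"
      )
    }
    len <- nchar(members[[1]]$sequence)
    total <- numeric(len)
    errors <- numeric(len)
    for (ref in members) {
      mat <- matrices[[ref$name]]
      ref_base <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
      row_tot <- rowSums(mat)
      own <- mat[cbind(seq_len(len), match(ref_base, colnames(mat)))]
      total <- total + row_tot
      errors <- errors + (row_tot - own)
    }
    spans <- members[[1]]$primer_spans
    primer_pos <- c(
      seq(spans$forward[1], spans$forward[2]),
      seq(spans$reverse[1], spans$reverse[2])
    )
    variant_pos <- .variant_site_offsets(refs, grp)
    reason <- rep(NA_character_, len)
    reason[total == 0] <- "no_data"
    reason[variant_pos] <- "variant_site"
    reason[primer_pos] <- "primer"
    ratio <- ifelse(total > 0, errors / total, NA_real_)
    analyzable <- is.na(reason)
    out[[grp]] <- list(
      profile = data.frame(
        position = seq_len(len),
        total = total,
        errors = errors,
        ratio = ratio,
        excluded_reason = reason,
        stringsAsFactors = FALSE
      ),
      summary = list(
        max = if (any(analyzable)) max(ratio[analyzable]) else NA_real_,
        median = if (any(analyzable)) stats::median(ratio[analyzable]) else NA_real_,
        pooled = if (sum(total[analyzable]) > 0) {
          sum(errors[analyzable]) / sum(total[analyzable])
        } else {
          NA_real_
        },
        n_analyzable = sum(analyzable)
      )
    )
  }
  out
}

#' Bundle a run into a single machine-readable report
#'
#' Collects diagnostic counts, allele ratios, error-ratio summaries, the
#' preprocessing ledger and QC flags into one list ready for JSON output.
#' A diagnostic class whose signal sits above the run's own interior
#' background error ceiling but below the positive-call threshold is
#' flagged as possible carry-over contamination.
#'
#' @param ratios An [allele_ratios()] object.
#' @param profiles Output of [error_ratio_profile()].
#' @param dedup_stats Optional `dedup_stats` from [dedup_umi()].
#' @param ledger Optional preprocessing ledger data.frame.
#' @param thresholds A [call_thresholds()] object (used for the
#'   contamination band).
#' @return A `run_report` list. Its JSON serialization follows the schema
#'   shipped at `system.file("extdata", "run_report_schema.json",
#'   package = "rhdamp")`.
#' @export
summarize_run <- function(ratios, profiles, dedup_stats = NULL, ledger = NULL,
                          thresholds = call_thresholds()) {
  class_group <- c(
    stats::setNames(rep("rhesus_box", length(BOX_CLASSES)), BOX_CLASSES),
    stats::setNames(rep("exon9", length(EXON9_CLASSES)), EXON9_CLASSES)
  )
  qc_flags <- list()
  for (cls in UNIT_NAMES) {
    grp <- class_group[[cls]]
    part <- if (grp == "rhesus_box") ratios$box else ratios$exon9
    frac <- part$frac[[cls]]
    bg <- profiles[[grp]]$summary$max
    if (!is.na(frac) && !is.na(bg) && frac > bg &&
      100 * frac < thresholds$min_positive_frac && frac > 0) {
      qc_flags[[length(qc_flags) + 1L]] <- list(
        flag = "possible_contamination",
        class = cls,
        observed_pct = 100 * frac,
        background_max_pct = 100 * bg
      )
    }
  }
  structure(
    list(
      diagnostic_counts = as.list(c(ratios$box$counts, ratios$exon9$counts)),
      ratios = list(
        box = list(pct = as.list(ratios$box$pct), counts = as.list(ratios$box$counts)),
        exon9 = list(pct = as.list(ratios$exon9$pct), counts = as.list(ratios$exon9$counts))
      ),
      error_ratios = lapply(profiles, function(p) p$summary),
      preprocess_ledger = if (is.null(ledger)) NULL else as.list(ledger),
      dedup = if (is.null(dedup_stats)) NULL else unclass(dedup_stats),
      qc_flags = qc_flags
    ),
    class = "run_report"
  )
}

#' Write a run report as JSON
#'
#' @param report A `run_report` from [summarize_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Write the per-position error-ratio table as TSV
#'
#' @param profiles Output of [error_ratio_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_profile_tsv <- function(profiles, path) {
  tabs <- lapply(names(profiles), function(grp) {
    cbind(group = grp, profiles[[grp]]$profile)
  })
  utils::write.table(do.call(rbind, tabs), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
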