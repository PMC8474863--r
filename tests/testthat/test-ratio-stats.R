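# Allele-ratio rendering, the pooled error-ratio statistic and the run
# report.

test_that("observed ratios render the published cfDNA values exactly", {
  r46_box <- allele_ratios(dcounts(416, 21694, 0, 0, 0))
  expect_equal(unname(r46_box$box$pct), c(1.88, 98.12))
  r46_ex9 <- allele_ratios(dcounts(0, 0, 281, 0, 20914))
  expect_equal(unname(r46_ex9$exon9$pct), c(1.33, 0, 98.67))
  r59_box <- allele_ratios(dcounts(813, 21754, 0, 0, 0))
  expect_equal(unname(r59_box$box$pct), c(3.60, 96.40))
  r59_ex9 <- allele_ratios(dcounts(0, 0, 1253, 1, 59758))
  expect_equal(unname(r59_ex9$exon9$pct), c(2.05, 0.002, 97.95))
  # exact fractions are carried alongside the rendered percentages
  expect_equal(unname(r46_box$box$frac[["upstream_box"]]), 416 / 22110)
  expect_equal(sum(r59_ex9$exon9$frac), 1)
})

test_that("degenerate ratio inputs are data, not errors", {
  none <- allele_ratios(dcounts(0, 0, 0, 0, 0))
  expect_true(all(is.na(none$box$pct)))
  expect_true(all(is.na(none$exon9$frac)))
  one_sided <- allele_ratios(dcounts(0, 500, 0, 0, 0))
  expect_equal(unname(one_sided$box$pct), c(0, 100))
  expect_error(allele_ratios(dcounts(-1, 2, 3, 4, 5)), class = "rhdamp_error_counts")
})

test_that("a single planted substitution yields error ratio 1/1000 at its site", {
  refs <- default_reference_panel()
  reads <- do.call(rbind, c(
    lapply(1:599, function(i) merged_read(refs[[1]]$sequence, paste0("u", i))),
    list(merged_read(sub_base(refs[[1]]$sequence, 37L), "mut")),
    lapply(1:400, function(i) merged_read(refs[[2]]$sequence, paste0("d", i)))
  ))
  mats <- count_bases(reads, classify_reads(reads, refs), refs)
  prof <- error_ratio_profile(mats, refs, "rhesus_box")$rhesus_box
  expect_equal(prof$profile$ratio[37L], 1 / 1000)
  expect_equal(prof$summary$max, 1 / 1000)
  other <- prof$profile$ratio[setdiff(21:80, 37L)]
  expect_true(all(other == 0))
})

test_that("error-free data yields an all-zero profile", {
  refs <- default_reference_panel()
  sim <- simulate_reads(
    sim_config(
      seed = 3L, molecules_per_group = 300L,
      substitution_error_rate = 0, pcr_error_rate = 0
    ),
    refs
  )
  res <- rhdamp:::.analyze_reads(sim$pairs, refs, filter_params(umi = TRUE), call_thresholds())
  expect_equal(res$profiles$rhesus_box$summary$max, 0)
  expect_equal(res$profiles$exon9$summary$max, 0)
})

test_that("the profile matches a per-read recount oracle and pools linearly", {
  refs <- default_reference_panel()
  set.seed(77)
  mk_reads <- function(ref, n, prefix) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      s <- ref$sequence
      k <- sample(0:2, 1)
      for (at in sample(nchar(s), k)) s <- sub_base(s, at)
      merged_read(s, paste0(prefix, i))
    }))
  }
  reads <- rbind(
    mk_reads(refs[[1]], 60, "u"), mk_reads(refs[[2]], 40, "d")
  )
  a <- classify_reads(reads, refs, max_mismatch = 3L)
  mats <- count_bases(reads, a, refs)
  prof <- error_ratio_profile(mats, refs, "rhesus_box")$rhesus_box$profile

  # oracle: recount mismatches per position directly from the assigned reads
  per_region <- list()
  for (nm in c("upstream_box", "downstream_box")) {
    ref_chars <- strsplit(refs[[match(nm, c("upstream_box", "downstream_box"))]]$sequence, "")[[1]]
    seqs <- reads$seq[a$region == nm]
    errs <- totals <- numeric(105)
    for (s in seqs) {
      ch <- strsplit(s, "")[[1]]
      totals <- totals + 1
      errs <- errs + (ch != ref_chars)
    }
    per_region[[nm]] <- list(errs = errs, totals = totals)
  }
  oracle_err <- per_region[[1]]$errs + per_region[[2]]$errs
  oracle_tot <- per_region[[1]]$totals + per_region[[2]]$totals
  expect_equal(prof$errors, oracle_err)
  expect_equal(prof$total, oracle_tot)
  expect_equal(prof$ratio, oracle_err / oracle_tot)

  # pooling: the pooled ratio is the count-weighted mean of per-region ratios
  for (p in 21:80) {
    w <- c(per_region[[1]]$totals[p], per_region[[2]]$totals[p])
    r <- c(
      per_region[[1]]$errs[p] / max(w[1], 1),
      per_region[[2]]$errs[p] / max(w[2], 1)
    )
    expect_equal(prof$ratio[p], sum(w * r) / sum(w))
  }
})

test_that("analyzable ranges match the primer and variant-site exclusions", {
  refs <- default_reference_panel()
  reads <- rbind(
    merged_read(refs[[1]]$sequence, "u"), merged_read(refs[[2]]$sequence, "d"),
    merged_read(refs[[3]]$sequence, "r"), merged_read(refs[[4]]$sequence, "e")
  )
  mats <- count_bases(reads, classify_reads(reads, refs), refs)
  prof <- error_ratio_profile(mats, refs)

  box <- prof$rhesus_box$profile
  expect_equal(box$excluded_reason[c(1, 20, 81, 105)], rep("primer", 4))
  expect_true(all(is.na(box$excluded_reason[21:80])))
  expect_equal(prof$rhesus_box$summary$n_analyzable, 60L)

  ex9 <- prof$exon9$profile
  expect_equal(ex9$excluded_reason[c(1, 22, 120, 148)], rep("primer", 4))
  expect_equal(ex9$excluded_reason[57L], "variant_site")
  # interior span nt 23-119 holds 97 positions; the c.1227 site inside it is
  # excluded, leaving 96 analyzable
  expect_equal(sum(!ex9$excluded_reason[23:119] %in% "primer", na.rm = FALSE), 97L)
  expect_equal(prof$exon9$summary$n_analyzable, 96L)
})

test_that("positions without data are excluded from the summaries", {
  refs <- default_reference_panel()
  empty_mats <- count_bases(
    merged_read(strrep("A", 105))[0, ],
    data.frame(id = character(0), region = character(0)), refs
  )
  prof <- error_ratio_profile(empty_mats, refs)
  expect_true(is.na(prof$rhesus_box$summary$max))
  expect_equal(prof$rhesus_box$summary$n_analyzable, 0L)
  expect_true(all(prof$exon9$profile$excluded_reason[23:56] == "no_data"))
})

test_that("signals between background and the positive threshold are flagged", {
  mk_profiles <- function(box_max, ex9_max) {
    list(
      rhesus_box = list(summary = list(max = box_max)),
      exon9 = list(summary = list(max = ex9_max))
    )
  }
  # the carry-over pattern: 0.19% of box reads against a 0.06% background
  ratios <- allele_ratios(dcounts(19, 9981, 0, 0, 10000))
  rep1 <- summarize_run(ratios, mk_profiles(6e-4, 6e-4))
  flags <- vapply(rep1$qc_flags, `[[`, character(1), "class")
  expect_true("upstream_box" %in% flags)

  # a 0.002%-style single-read signal below background is not flagged
  ratios59 <- allele_ratios(dcounts(813, 21754, 1253, 1, 59758))
  rep2 <- summarize_run(ratios59, mk_profiles(6e-4, 11e-4))
  flags2 <- vapply(rep2$qc_flags, function(f) f$class, character(1))
  expect_false("RHD_var" %in% flags2)
  # strong true signals are never contamination-flagged
  expect_false("RHD_wt" %in% flags2)
  expect_false("upstream_box" %in% flags2)
})

test_that("run reports serialize with their core sections", {
  refs <- default_reference_panel()
  sim <- simulate_reads(sim_config(seed = 5L, molecules_per_group = 300L), refs)
  res <- rhdamp:::.analyze_reads(sim$pairs, refs, filter_params(umi = TRUE), call_thresholds())
  path <- tempfile(fileext = ".json")
  write_run_report(res$report, path)
  back <- jsonlite::fromJSON(path)
  expect_setequal(
    names(back),
    c(
      "diagnostic_counts", "ratios", "error_ratios", "preprocess_ledger",
      "dedup", "qc_flags"
    )
  )
  expect_equal(back$diagnostic_counts$RHCE, unname(res$diagnostics[["RHCE"]]))
  expect_equal(back$dedup$n_molecules, res$preprocess$dedup_stats$n_molecules)
  # the written report carries every field the shipped schema requires
  schema <- jsonlite::fromJSON(
    system.file("extdata", "run_report_schema.json", package = "rhdamp")
  )
  expect_true(all(schema$required %in% names(back)))
  expect_true(all(schema$properties$diagnostic_counts$required %in%
    names(back$diagnostic_counts)))
})
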