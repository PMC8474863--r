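# Adaptor trimming, overlap merging, UMI handling, filters and the
# stage-conservation ledger.

test_that("read-through adaptors are trimmed at the insert boundary", {
  refs <- default_reference_panel()
  insert <- refs[[1]]$sequence # 105 bp
  p <- make_pair(insert)
  t <- trim_adaptors(p)
  expect_equal(t$seq1, insert)
  expect_equal(nchar(t$qual1), 105L)
  expect_equal(t$seq2, rc(insert))

  # a read without any adaptor content is unchanged
  clean <- data.frame(
    id = "c", seq1 = insert, qual1 = phred_str(35, 105),
    seq2 = rc(insert), qual2 = phred_str(35, 105), stringsAsFactors = FALSE
  )
  expect_equal(trim_adaptors(clean), clean)

  # one mismatch inside the adaptor seed is tolerated
  mm <- p
  mm$seq1 <- sub_base(mm$seq1, 110L) # within the adaptor, position 5 of the seed
  expect_equal(trim_adaptors(mm)$seq1, insert)

  # adaptor starting at position 1 leaves an empty read
  allad <- data.frame(
    id = "a",
    seq1 = substring(strrep(default_adaptors()[["read1"]], 6L), 1L, 151L),
    qual1 = phred_str(35, 151),
    seq2 = rc(insert), qual2 = phred_str(35, 105), stringsAsFactors = FALSE
  )
  expect_equal(nchar(trim_adaptors(allad)$seq1), 0L)
})

test_that("short terminal adaptor prefixes are trimmed by exact match", {
  refs <- default_reference_panel()
  insert <- refs[[3]]$sequence # 148 bp
  ad <- default_adaptors()
  p <- data.frame(
    id = "s",
    seq1 = paste0(insert, substr(ad[["read1"]], 1, 3)),
    qual1 = phred_str(35, 151),
    seq2 = paste0(rc(insert), substr(ad[["read2"]], 1, 3)),
    qual2 = phred_str(35, 151), stringsAsFactors = FALSE
  )
  t <- trim_adaptors(p)
  expect_equal(t$seq1, insert)
  expect_equal(t$seq2, rc(insert))
})

test_that("full-insert pairs merge to the insert with per-base max quality", {
  refs <- default_reference_panel()
  insert <- refs[[1]]$sequence
  p <- data.frame(
    id = "m",
    seq1 = insert, qual1 = phred_str(30, 105),
    seq2 = rc(insert), qual2 = phred_str(38, 105), stringsAsFactors = FALSE
  )
  m <- merge_pairs(p)
  expect_equal(nrow(m$merged), 1L)
  expect_equal(nrow(m$rejected), 0L)
  expect_equal(m$merged$seq, insert)
  expect_equal(m$merged$qual, phred_str(38, 105)) # max of the two mates
})

test_that("a single overlap mismatch rejects the pair under zero density", {
  refs <- default_reference_panel()
  insert <- refs[[1]]$sequence
  for (at in c(1L, 52L, 105L)) {
    p <- data.frame(
      id = "x",
      seq1 = sub_base(insert, at), qual1 = phred_str(35, 105),
      seq2 = rc(insert), qual2 = phred_str(35, 105), stringsAsFactors = FALSE
    )
    m <- merge_pairs(p)
    expect_equal(nrow(m$merged), 0L)
    expect_equal(m$rejected$reason, "no_acceptable_overlap")
  }
})

test_that("the minimum-overlap boundary is enforced at exactly 10 bases", {
  insert <- "AAAAACCCCCGGGGGTTTTT" # 20 bp, block structure avoids spurious overlaps
  ten <- data.frame(
    id = "ov10",
    seq1 = substring(insert, 1, 15), qual1 = phred_str(35, 15),
    seq2 = rc(substring(insert, 6, 20)), qual2 = phred_str(35, 15),
    stringsAsFactors = FALSE
  )
  m10 <- merge_pairs(ten)
  expect_equal(m10$merged$seq, insert)

  nine <- data.frame(
    id = "ov9",
    seq1 = substring(insert, 1, 14), qual1 = phred_str(35, 14),
    seq2 = rc(substring(insert, 6, 20)), qual2 = phred_str(35, 15),
    stringsAsFactors = FALSE
  )
  m9 <- merge_pairs(nine)
  expect_equal(nrow(m9$merged), 0L)
})

test_that("merging is idempotent on its own output", {
  refs <- default_reference_panel()
  for (ref in refs) {
    m1 <- merge_pairs(data.frame(
      id = "i", seq1 = ref$sequence, qual1 = phred_str(33, nchar(ref$sequence)),
      seq2 = rc(ref$sequence), qual2 = phred_str(36, nchar(ref$sequence)),
      stringsAsFactors = FALSE
    ))
    m2 <- merge_pairs(data.frame(
      id = "i", seq1 = m1$merged$seq, qual1 = m1$merged$qual,
      seq2 = rc(m1$merged$seq), qual2 = m1$merged$qual,
      stringsAsFactors = FALSE
    ))
    expect_equal(m2$merged$seq, m1$merged$seq)
    expect_equal(m2$merged$qual, m1$merged$qual)
  }
})

test_that("UMI extraction splits the 12-base prefix before size filtering", {
  refs <- default_reference_panel()
  insert <- refs[[1]]$sequence
  umi <- "ACGTACGTACGT"
  r <- merged_read(paste0(umi, insert))
  out <- extract_umi(r)
  expect_equal(out$kept$umi, umi)
  expect_equal(out$kept$seq, insert)
  expect_equal(nchar(out$kept$qual), 105L)

  # a 12-base read yields an empty amplicon, to be size-rejected later
  short <- extract_umi(merged_read(umi))
  expect_equal(short$kept$seq, "")
  expect_equal(nrow(short$rejected), 0L)

  # shorter than the UMI: rejected with a reason
  tiny <- extract_umi(merged_read("ACGT"))
  expect_equal(nrow(tiny$kept), 0L)
  expect_equal(tiny$rejected$reason, "shorter_than_umi")
})

test_that("size filter accepts exactly the panel lengths", {
  refs <- default_reference_panel()
  reads <- rbind(
    merged_read(strrep("A", 105), id = "ok105"),
    merged_read(strrep("A", 104), id = "no104"),
    merged_read(strrep("A", 148), id = "ok148"),
    merged_read(strrep("A", 160), id = "no160"),
    merged_read("", id = "empty")
  )
  out <- size_filter(reads, refs)
  expect_setequal(out$kept$id, c("ok105", "ok148"))
  expect_setequal(out$rejected$id, c("no104", "no160", "empty"))
})

test_that("mean-quality filter is boundary-inclusive at Q25", {
  reads <- rbind(
    merged_read(strrep("A", 100), id = "q30", q = 30),
    merged_read(strrep("A", 100), id = "q20", q = 20)
  )
  halfhalf <- data.frame(
    id = "q25", seq = strrep("A", 100),
    qual = paste0(phred_str(20, 50), phred_str(30, 50)),
    umi = NA_character_, stringsAsFactors = FALSE
  )
  out <- quality_filter(rbind(reads, halfhalf))
  expect_setequal(out$kept$id, c("q30", "q25"))
  expect_equal(out$rejected$id, "q20")
})

test_that("UMI deduplication emits the plurality sequence per molecule", {
  refs <- default_reference_panel()
  x <- refs[[1]]$sequence
  y <- sub_base(x, 40L)

  # three identical reads, one UMI: one molecule, two duplicates removed
  r <- rbind(
    merged_read(x, "a", umi = "AAAAAAAAAAAA"),
    merged_read(x, "b", umi = "AAAAAAAAAAAA"),
    merged_read(x, "c", umi = "AAAAAAAAAAAA")
  )
  d <- dedup_umi(r)
  expect_equal(nrow(d$reads), 1L)
  expect_equal(d$stats$duplicates_removed, 2L)
  expect_equal(d$stats$family_size_histogram, c("3" = 1L))

  # plurality: x twice beats y once
  r2 <- rbind(
    merged_read(y, "a", umi = "CCCCCCCCCCCC"),
    merged_read(x, "b", umi = "CCCCCCCCCCCC"),
    merged_read(x, "c", umi = "CCCCCCCCCCCC")
  )
  expect_equal(dedup_umi(r2)$reads$seq, x)

  # tie: lexicographically smallest sequence wins
  r3 <- rbind(
    merged_read(x, "a", umi = "GGGGGGGGGGGG"),
    merged_read(y, "b", umi = "GGGGGGGGGGGG")
  )
  expect_equal(dedup_umi(r3)$reads$seq, min(x, y))

  # distinct UMIs are distinct molecules even with identical sequences
  r4 <- rbind(
    merged_read(x, "a", umi = "AAAAAAAAAAAA"),
    merged_read(x, "b", umi = "TTTTTTTTTTTT")
  )
  d4 <- dedup_umi(r4)
  expect_equal(nrow(d4$reads), 2L)
  expect_equal(d4$stats$duplicates_removed, 0L)

  # a missing UMI violates the contract
  expect_error(dedup_umi(merged_read(x, "z")), class = "rhdamp_error_contract")
})

test_that("every preprocessing stage ledger sums exactly", {
  refs <- default_reference_panel()
  sim <- simulate_reads(
    sim_config(seed = 11L, molecules_per_group = 500L, duplication_mean = 2),
    refs
  )
  pp <- preprocess_reads(sim$pairs, refs, filter_params(umi = TRUE))
  led <- pp$ledger
  expect_equal(led$n_in - led$n_kept, led$n_rejected)
  expect_equal(led$n_in[-1], led$n_kept[-nrow(led)])
  expect_equal(led$n_in[1], nrow(sim$pairs))
  expect_equal(led$n_kept[nrow(led)], nrow(pp$reads))
  # per-read rejection records match the ledger (dedup removals are not
  # rejections)
  expect_equal(nrow(pp$rejections), sum(led$n_rejected[led$stage != "dedup_umi"]))
  expect_equal(pp$dedup_stats$n_input - pp$dedup_stats$n_molecules,
               led$n_rejected[led$stage == "dedup_umi"])
})
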