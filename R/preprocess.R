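# Preprocessing: adaptor trimming, overlap merging, UMI extraction,
# size/quality filtering and UMI-based PCR-duplicate removal.
#
# Read sets are plain data.frames. A pair set has columns
# id/seq1/qual1/seq2/qual2; a merged set has id/seq/qual/umi. Filters return
# list(kept, rejected) where `rejected` carries a `reason` column, so every
# stage ledger sums exactly.

#' Default Illumina read-through adaptors
#'
#' Standard TruSeq adaptor prefixes searched for at the 3' end of read 1 and
#' read 2 respectively.
#'
#' @return Named character vector with elements `read1` and `read2`.
#' @export
default_adaptors <- function() {
  c(
    read1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    read2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"
  )
}

#' Preprocessing filter parameters
#'
#' @param base_quality_cutoff Minimum mean Phred quality of a merged read
#'   (default 25, boundary inclusive).
#' @param max_mismatch_density Maximum tolerated mismatches per overlap base
#'   when merging read pairs (default 0: any mismatch rejects the pair).
#' @param min_overlap Minimum read1/read2 overlap in bases (default 10).
#' @param expected_sizes Merged amplicon lengths accepted by the size filter
#'   (default 105 and 148).
#' @param umi Logical; extract a unique molecular identifier from the start
#'   of the merged read (read 1's 5' end) and deduplicate on it.
#' @param umi_length UMI length in bases (default 12).
#' @param adaptors Read-through adaptor sequences, see [default_adaptors()].
#' @return A `filter_params` list.
#' @export
filter_params <- function(base_quality_cutoff = 25,
                          max_mismatch_density = 0,
                          min_overlap = 10L,
                          expected_sizes = unname(GROUP_LENGTHS),
                          umi = FALSE,
                          umi_length = 12L,
                          adaptors = default_adaptors()) {
  if (base_quality_cutoff < 0 || max_mismatch_density < 0 || min_overlap < 1L) {
    .rhd_error("filter cutoffs must be non-negative (min_overlap >= 1)", "rhdamp_error_params")
  }
  structure(
    list(
      base_quality_cutoff = base_quality_cutoff,
      max_mismatch_density = max_mismatch_density,
      min_overlap = as.integer(min_overlap),
      expected_sizes = as.integer(expected_sizes),
      umi = isTRUE(umi),
      umi_length = as.integer(umi_length),
      adaptors = adaptors
    ),
    class = "filter_params"
  )
}

#' Read a paired-end FASTQ file pair
#'
#' @param fastq1,fastq2 Paths to the read 1 and read 2 FASTQ files (plain or
#'   gzipped), Phred+33.
#' @return A pair set data.frame with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
read_fastq_pair <- function(fastq1, fastq2) {
  if (!file.exists(fastq1) || !file.exists(fastq2)) {
    .rhd_error("FASTQ file not found", "rhdamp_error_io")
  }
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    .rhd_error("read 1 and read 2 files differ in read count", "rhdamp_error_io")
  }
  ids <- sub("[/ ].*$", "", names(r1))
  data.frame(
    id = ids,
    seq1 = as.character(r1),
    qual1 = as.character(S4Vectors::mcols(r1)$qualities),
    seq2 = as.character(r2),
    qual2 = as.character(S4Vectors::mcols(r2)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write merged reads as FASTQ
#'
#' @param reads Merged read set (columns `id`, `seq`, `qual`).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_merged_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$id
  Biostrings::writeXStringSet(dss,
    filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

# find the adaptor cut point per read: earliest <=1-mismatch hit of the
# adaptor's 12-base seed, else the longest exact terminal overlap with the
# adaptor prefix (k < seed length). NA when no adaptor is found.
.adaptor_cut <- function(seqs, adaptor, seed_len = 12L) {
  n <- length(seqs)
  cut <- rep(NA_integer_, n)
  if (!n) {
    return(cut)
  }
  # seed search with <= 1 mismatch by pigeonhole: any such hit contains an
  # exact occurrence of one seed half; candidates are then verified by
  # counting mismatches over the full seed window
  seed <- substr(adaptor, 1L, seed_len)
  half <- seed_len %/% 2L
  h1 <- substr(seed, 1L, half)
  h2 <- substr(seed, half + 1L, seed_len)
  w <- nchar(seqs)
  verify <- function(cand_read, cand_pos) {
    # earliest verified seed window (<= 1 mismatch) per read
    keep <- cand_pos >= 1L & cand_pos + seed_len - 1L <= w[cand_read]
    cand_read <- cand_read[keep]
    cand_pos <- cand_pos[keep]
    if (!length(cand_read)) {
      return(NULL)
    }
    dup <- duplicated(cand_read * (max(w) + 1) + cand_pos)
    cand_read <- cand_read[!dup]
    cand_pos <- cand_pos[!dup]
    windows <- substring(seqs[cand_read], cand_pos, cand_pos + seed_len - 1L)
    ok <- .hamming(windows, seed) <= 1L
    cand_read <- cand_read[ok]
    cand_pos <- cand_pos[ok]
    ord <- order(cand_read, cand_pos)
    cand_read <- cand_read[ord]
    cand_pos <- cand_pos[ord]
    first <- !duplicated(cand_read)
    list(read = cand_read[first], pos = cand_pos[first])
  }
  # fast path: first exact occurrence of each seed half
  r1 <- regexpr(h1, seqs, fixed = TRUE)
  r2 <- regexpr(h2, seqs, fixed = TRUE)
  any_half <- r1 > 0L | r2 > 0L
  hit <- verify(
    c(which(r1 > 0L), which(r2 > 0L)),
    c(r1[r1 > 0L], r2[r2 > 0L] - half)
  )
  if (!is.null(hit)) {
    cut[hit$read] <- hit$pos
  }
  # slow path: reads with half-hits whose first candidate did not verify
  # may still carry a later adaptor occurrence
  unresolved <- which(any_half & is.na(cut))
  if (length(unresolved)) {
    cand_read <- integer(0)
    cand_pos <- integer(0)
    for (probe in 1:2) {
      hits <- gregexpr(if (probe == 1L) h1 else h2, seqs[unresolved], fixed = TRUE)
      pos <- unlist(hits, use.names = FALSE)
      reads <- rep.int(unresolved, lengths(hits))
      keep <- pos > 0L
      pos <- pos[keep]
      if (probe == 2L) pos <- pos - half
      cand_read <- c(cand_read, reads[keep])
      cand_pos <- c(cand_pos, pos)
    }
    hit <- verify(cand_read, cand_pos)
    if (!is.null(hit)) {
      cut[hit$read] <- hit$pos
    }
  }
  # terminal partial adaptor (shorter than the seed): longest exact match of
  # at least 3 bases, so that a chance 1-2 base agreement at a read end is
  # not mistaken for read-through
  todo <- which(is.na(cut))
  for (k in seq(min(seed_len - 1L, max(w, 3L)), 3L)) {
    if (!length(todo)) break
    ok <- w[todo] >= k &
      substring(seqs[todo], w[todo] - k + 1L, w[todo]) == substr(adaptor, 1L, k)
    hit <- todo[ok]
    cut[hit] <- w[hit] - k + 1L
    todo <- todo[!ok]
  }
  cut
}

#' Trim 3' read-through adaptor sequences from a read pair set
#'
#' Each mate is scanned for its adaptor: a 12-base adaptor seed with at most
#' one mismatch anywhere in the read, or a shorter exact adaptor prefix (at
#' least 3 bases) at the very 3' end. Sequence and quality are cut in
#' lockstep at the earliest
#' hit; reads without a hit are returned unchanged.
#'
#' @param pairs Pair set data.frame.
#' @param adaptors Named adaptor vector, see [default_adaptors()].
#' @return The trimmed pair set.
#' @export
trim_adaptors <- function(pairs, adaptors = default_adaptors()) {
  trim_one <- function(seqs, quals, adaptor) {
    cut <- .adaptor_cut(seqs, adaptor)
    keep <- ifelse(is.na(cut), nchar(seqs), cut - 1L)
    list(seq = substring(seqs, 1L, keep), qual = substring(quals, 1L, keep))
  }
  t1 <- trim_one(pairs$seq1, pairs$qual1, adaptors[["read1"]])
  t2 <- trim_one(pairs$seq2, pairs$qual2, adaptors[["read2"]])
  pairs$seq1 <- t1$seq
  pairs$qual1 <- t1$qual
  pairs$seq2 <- t2$seq
  pairs$qual2 <- t2$qual
  pairs
}

#' Merge read pairs by 3' overlap
#'
#' Finds, per pair, the maximal-length overlap between read 1 and the
#' reverse complement of read 2 that is at least `min_overlap` bases long
#' and contains no more than `floor(overlap * max_mismatch_density)`
#' mismatches (with the default density of 0, the overlap must be exact).
#' The merged quality at overlapped positions is the per-base maximum of the
#' two contributing qualities. Pairs with no acceptable overlap are returned
#' as rejections, not errors.
#'
#' @param pairs Pair set data.frame (adaptor-trimmed).
#' @param params A [filter_params()] object.
#' @return `list(merged, rejected)`: a merged read set (`id`, `seq`, `qual`,
#'   `umi = NA`) and a rejection data.frame (`id`, `reason`).
#' @export
merge_pairs <- function(pairs, params = filter_params()) {
  n <- nrow(pairs)
  rc2 <- .rev_comp(pairs$seq2)
  rq2 <- .str_rev(pairs$qual2)
  n1 <- nchar(pairs$seq1)
  n2 <- nchar(rc2)
  ov <- rep(NA_integer_, n)
  max_o <- pmin(n1, n2)
  todo <- which(max_o >= params$min_overlap)
  o <- if (length(todo)) max(max_o[todo]) else 0L
  while (length(todo) && o >= params$min_overlap) {
    cand <- todo[max_o[todo] >= o]
    if (length(cand)) {
      allowed <- floor(o * params$max_mismatch_density)
      if (allowed == 0L && o > 8L) {
        # cheap probe on the first 8 overlap characters before paying for
        # the full-width comparison
        maybe <- substring(pairs$seq1[cand], n1[cand] - o + 1L, n1[cand] - o + 8L) ==
          substring(rc2[cand], 1L, 8L)
        cand <- cand[maybe]
      }
    }
    if (length(cand)) {
      s1 <- substring(pairs$seq1[cand], n1[cand] - o + 1L, n1[cand])
      s2 <- substring(rc2[cand], 1L, o)
      hit <- if (allowed == 0L) {
        s1 == s2
      } else {
        mism <- integer(length(cand))
        neq <- s1 != s2
        if (any(neq)) {
          m <- .raw_mat(s1[neq], o) != .raw_mat(s2[neq], o)
          mism[neq] <- as.integer(colSums(m))
        }
        mism <= allowed
      }
      ov[cand[hit]] <- o
      todo <- setdiff(todo, cand[hit])
    }
    o <- o - 1L
  }
  merged_idx <- which(!is.na(ov))
  rejected_idx <- setdiff(seq_len(n), merged_idx)
  o <- ov[merged_idx]
  p1 <- n1[merged_idx]
  seq <- paste0(
    substring(pairs$seq1[merged_idx], 1L, p1 - o),
    rc2[merged_idx]
  )
  qual <- paste0(
    substring(pairs$qual1[merged_idx], 1L, p1 - o),
    .str_pmax(
      substring(pairs$qual1[merged_idx], p1 - o + 1L, p1),
      substring(rq2[merged_idx], 1L, o)
    ),
    substring(rq2[merged_idx], o + 1L, n2[merged_idx])
  )
  list(
    merged = data.frame(
      id = pairs$id[merged_idx], seq = seq, qual = qual,
      umi = rep(NA_character_, length(merged_idx)),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    rejected = data.frame(
      id = pairs$id[rejected_idx],
      reason = rep("no_acceptable_overlap", length(rejected_idx)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' Extract the UMI prefix from merged reads
#'
#' Moves the first `umi_length` bases (read 1's 5' end) from the sequence to
#' the `umi` column. Runs before the size filter, since the UMI prefix is
#' not part of the amplicon.
#'
#' @param reads Merged read set.
#' @param params A [filter_params()] object (uses `umi_length`).
#' @return `list(kept, rejected)`; reads shorter than the UMI are rejected
#'   with reason `"shorter_than_umi"`.
#' @export
extract_umi <- function(reads, params = filter_params(umi = TRUE)) {
  k <- params$umi_length
  ok <- nchar(reads$seq) >= k
  kept <- reads[ok, , drop = FALSE]
  kept$umi <- substring(kept$seq, 1L, k)
  kept$seq <- substring(kept$seq, k + 1L)
  kept$qual <- substring(kept$qual, k + 1L)
  bad_umi <- grepl("[^ACGTN]", kept$umi)
  rejected <- rbind(
    data.frame(
      id = reads$id[!ok], reason = rep("shorter_than_umi", sum(!ok)),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    data.frame(
      id = kept$id[bad_umi], reason = rep("invalid_umi", sum(bad_umi)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
  list(
    kept = kept[!bad_umi, , drop = FALSE],
    rejected = rejected
  )
}

#' Filter merged reads by expected amplicon size
#'
#' Keeps reads whose length is one of the group lengths of the reference
#' panel (105 bases for Rhesus boxes, 148 for exon 9), removing primer
#' dimers, artefacts and failed merges.
#'
#' @param reads Merged read set.
#' @param refs Reference panel (its sequence lengths define the accepted
#'   sizes), or `NULL` to use `params$expected_sizes`.
#' @param params A [filter_params()] object.
#' @return `list(kept, rejected)` with reason `"unexpected_size"`.
#' @export
size_filter <- function(reads, refs = NULL, params = filter_params()) {
  sizes <- if (!is.null(refs)) {
    sort(unique(vapply(refs, function(r) nchar(r$sequence), integer(1))))
  } else {
    params$expected_sizes
  }
  ok <- nchar(reads$seq) %in% sizes
  list(
    kept = reads[ok, , drop = FALSE],
    rejected = data.frame(
      id = reads$id[!ok], reason = rep("unexpected_size", sum(!ok)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' Filter merged reads by mean base quality
#'
#' A read passes iff its mean Phred quality over all positions is at least
#' `base_quality_cutoff` (boundary inclusive).
#'
#' @param reads Merged read set.
#' @param params A [filter_params()] object.
#' @return `list(kept, rejected)` with reason `"low_quality"`.
#' @export
quality_filter <- function(reads, params = filter_params()) {
  means <- .phred_means(reads$qual)
  ok <- !is.nan(means) & means >= params$base_quality_cutoff
  list(
    kept = reads[ok, , drop = FALSE],
    rejected = data.frame(
      id = reads$id[!ok], reason = rep("low_quality", sum(!ok)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' Collapse PCR duplicates by UMI
#'
#' Reads are grouped by exact UMI within each amplicon length class; each
#' group is one original template molecule. The group's plurality sequence
#' is emitted once (ties broken by the lexicographically smallest sequence),
#' with the id and quality string of the first read carrying that sequence.
#'
#' @param reads Merged read set whose `umi` column is fully populated
#'   (a missing UMI is a contract violation and raises an error).
#' @return `list(reads, stats)`: one read per molecule (with a
#'   `reads_in_family` column) and a `dedup_stats` list recording input
#'   reads, unique UMI families, duplicates removed and the family-size
#'   histogram.
#' @export
dedup_umi <- function(reads) {
  if (nrow(reads) && (any(is.na(reads$umi)) || any(!nzchar(reads$umi)))) {
    .rhd_error("dedup_umi requires a UMI on every read", "rhdamp_error_contract")
  }
  if (!nrow(reads)) {
    return(list(
      reads = reads,
      stats = structure(
        list(
          n_input = 0L, n_molecules = 0L, duplicates_removed = 0L,
          family_size_histogram = integer(0)
        ),
        class = "dedup_stats"
      )
    ))
  }
  key <- paste0(reads$umi, "#", nchar(reads$seq))
  ord <- order(key, reads$seq, method = "radix")
  k <- key[ord]
  s <- reads$seq[ord]
  r <- rle(paste0(k, "\x01", s))
  first_in_run <- cumsum(r$lengths) - r$lengths + 1L
  run_key <- k[first_in_run]
  run_seq <- s[first_in_run]
  run_n <- r$lengths
  # per family: highest read count wins, ties to the smallest sequence
  sel <- order(run_key, -run_n, run_seq, method = "radix")
  pick <- sel[!duplicated(run_key[sel])]
  rep_idx <- ord[first_in_run[pick]] # first read carrying the winning sequence
  fam_sizes <- as.integer(table(key)[run_key[pick]])
  out <- reads[rep_idx, , drop = FALSE]
  out$reads_in_family <- fam_sizes
  out <- out[order(rep_idx), , drop = FALSE]
  row.names(out) <- NULL
  hist <- table(factor(fam_sizes))
  stats <- structure(
    list(
      n_input = nrow(reads),
      n_molecules = nrow(out),
      duplicates_removed = nrow(reads) - nrow(out),
      family_size_histogram = stats::setNames(as.integer(hist), names(hist))
    ),
    class = "dedup_stats"
  )
  list(reads = out, stats = stats)
}

#' Run the full preprocessing chain
#'
#' Adaptor trimming, overlap merging, optional UMI extraction, size filter,
#' mean-quality filter and optional UMI deduplication, with an exact
#' per-stage ledger.
#'
#' @param pairs Pair set data.frame, see [read_fastq_pair()].
#' @param refs Reference panel (defines the accepted amplicon sizes).
#' @param params A [filter_params()] object.
#' @return List with `reads` (the surviving merged read set), `ledger`
#'   (data.frame of per-stage input/kept/rejected counts), `rejections`
#'   (per-read reasons) and `dedup_stats` (`NULL` without UMIs).
#' @export
preprocess_reads <- function(pairs, refs, params = filter_params()) {
  ledger <- list()
  rejections <- list()
  note <- function(stage, n_in, n_kept) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_kept = n_kept, n_rejected = n_in - n_kept,
      stringsAsFactors = FALSE
    )
  }

  trimmed <- trim_adaptors(pairs, params$adaptors)
  note("trim_adaptors", nrow(pairs), nrow(trimmed))

  m <- merge_pairs(trimmed, params)
  note("merge_pairs", nrow(trimmed), nrow(m$merged))
  rejections$merge <- m$rejected
  reads <- m$merged

  if (params$umi) {
    u <- extract_umi(reads, params)
    note("extract_umi", nrow(reads), nrow(u$kept))
    rejections$umi <- u$rejected
    reads <- u$kept
  }

  sf <- size_filter(reads, refs, params)
  note("size_filter", nrow(reads), nrow(sf$kept))
  rejections$size <- sf$rejected
  reads <- sf$kept

  qf <- quality_filter(reads, params)
  note("quality_filter", nrow(reads), nrow(qf$kept))
  rejections$quality <- qf$rejected
  reads <- qf$kept

  dedup_stats <- NULL
  if (params$umi) {
    dd <- dedup_umi(reads)
    note("dedup_umi", nrow(reads), nrow(dd$reads))
    reads <- dd$reads
    dedup_stats <- dd$stats
  }

  list(
    reads = reads,
    ledger = do.call(rbind, ledger),
    rejections = do.call(rbind, unname(rejections)),
    dedup_stats = dedup_stats
  )
}
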