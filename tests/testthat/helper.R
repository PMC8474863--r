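# Shared fixtures: everything is built in code at test time.

phred_str <- function(q, len) {
  strrep(rawToChar(as.raw(q + 33L)), len)
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# a full-read-through pair for one amplicon insert, as the sequencer
# would emit it: read1 = (umi +) insert + adaptor fill, read2 = reverse
# complement + adaptor fill, both clipped to read_len
make_pair <- function(insert, id = "r1", umi = NULL, read_len = 151L, q = 35L,
                      adaptors = default_adaptors()) {
  fill <- vapply(adaptors, function(a) strrep(a, ceiling(read_len / nchar(a)) + 1L), character(1))
  s1 <- substring(paste0(if (is.null(umi)) "" else umi, insert, fill[["read1"]]), 1L, read_len)
  s2 <- substring(paste0(rc(insert), fill[["read2"]]), 1L, read_len)
  data.frame(
    id = id,
    seq1 = s1, qual1 = phred_str(q, nchar(s1)),
    seq2 = s2, qual2 = phred_str(q, nchar(s2)),
    stringsAsFactors = FALSE
  )
}

pair_set <- function(...) {
  do.call(rbind, list(...))
}

merged_read <- function(seq, id = "m1", q = 35L, umi = NA_character_) {
  data.frame(
    id = id, seq = seq, qual = phred_str(q, nchar(seq)), umi = umi,
    stringsAsFactors = FALSE
  )
}

# substitute one base at `at` (1-based) with a different fixed base
sub_base <- function(seq, at, to = NULL) {
  cur <- substring(seq, at, at)
  if (is.null(to)) {
    to <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  substring(seq, at, at) <- to
  seq
}

# two toy same-length references for oracle tests (not a valid panel; used
# only where validation is not involved)
toy_refs <- function(len = 20L, seed = 5L) {
  set.seed(seed)
  a <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  b <- sub_base(sub_base(a, 5L), 15L)
  spans <- list(forward = c(1L, 2L), reverse = c(len - 1L, len))
  list(
    amplicon_ref("toyA", "toy", a, "toyA", 1000L, "+", spans),
    amplicon_ref("toyB", "toy", b, "toyB", 2000L, "+", spans)
  )
}

# position-wise mismatch count, independent of the packaged .hamming
oracle_mismatches <- function(x, ref) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  rs <- strsplit(ref, "", fixed = TRUE)[[1]]
  sum(xs != rs)
}

# brute-force classifier: score every reference by direct comparison
oracle_classify <- function(seq, refs, max_mismatch = 3L) {
  d <- vapply(refs, function(r) oracle_mismatches(seq, r$sequence), numeric(1))
  best <- min(d)
  if (best > max_mismatch) {
    return("unassigned")
  }
  if (sum(d == best) > 1L) {
    return("ambiguous")
  }
  refs[[which.min(d)]]$name
}

del_del <- c("RHD*01N.01", "RHD*01N.01")
pos_het <- c("RHD*01", "RHD*01N.01")

# diagnostic count vector shorthand
dcounts <- function(up, down, wt, var, rhce) {
  c(
    upstream_box = up, downstream_box = down,
    RHD_wt = wt, RHD_var = var, RHCE = rhce
  )
}
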