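# Read classification and per-position base counting.
#
# After size filtering, every read is a full-length ungapped amplicon, so
# alignment reduces to Hamming distance against the references of its length
# class. Unique assignment (the role of the original mapping-score cutoffs)
# is enforced by requiring the best reference to beat the second best.

#' Assign merged reads to amplicon regions by Hamming distance
#'
#' Each read is compared position-wise against every reference of matching
#' length. It is assigned to the unique closest reference iff the distance
#' is at most `max_mismatch` and the second-best reference is strictly
#' worse (margin >= 1); ties yield `"ambiguous"`, distances above the cutoff
#' `"unassigned"`. Reads whose length matches no reference are a contract
#' violation (the size filter guarantees it upstream).
#'
#' @param reads Merged read set (columns `id`, `seq`).
#' @param refs Reference panel.
#' @param max_mismatch Maximum accepted distance to the best reference
#'   (default 3).
#' @return Assignment data.frame: `id`, `region`, `mismatches`, `margin`.
#' @export
classify_reads <- function(reads, refs, max_mismatch = 3L) {
  n <- nrow(reads)
  out <- data.frame(
    id = reads$id,
    region = character(n),
    mismatches = integer(n),
    margin = integer(n),
    stringsAsFactors = FALSE
  )
  if (!n) {
    return(out)
  }
  ref_len <- vapply(refs, function(r) nchar(r$sequence), integer(1))
  ref_name <- vapply(refs, `[[`, character(1), "name")
  w <- nchar(reads$seq)
  if (any(!w %in% ref_len)) {
    .rhd_error("read length matches no reference; size filtering violated", "rhdamp_error_contract")
  }
  for (len in unique(w)) {
    idx <- which(w == len)
    cand <- which(ref_len == len)
    useq <- unique(reads$seq[idx])
    d <- vapply(cand, function(j) .hamming(useq, refs[[j]]$sequence), integer(length(useq)))
    d <- matrix(d, nrow = length(useq))
    best_j <- max.col(-d, ties.method = "first")
    best <- d[cbind(seq_along(useq), best_j)]
    second <- apply(d, 1L, function(v) if (length(v) > 1L) sort(v, partial = 2)[2] else Inf)
    tied <- rowSums(d == best) > 1L
    region <- ref_name[cand[best_j]]
    region[tied] <- "ambiguous"
    region[best > max_mismatch] <- "unassigned"
    margin <- ifelse(is.infinite(second), NA_integer_, as.integer(second - best))
    pos <- match(reads$seq[idx], useq)
    out$region[idx] <- region[pos]
    out$mismatches[idx] <- best[pos]
    out$margin[idx] <- margin[pos]
  }
  out
}

#' Per-position base-count matrices per region
#'
#' For every read with a definite region assignment, the observed base at
#' each amplicon position increments that region's count matrix; ambiguous
#' and unassigned reads are excluded. All panel regions are present in the
#' output (all-zero when no read was assigned).
#'
#' @param reads Merged read set.
#' @param assignments Output of [classify_reads()] for `reads`.
#' @param refs Reference panel.
#' @return Named list of `length x 5` integer matrices with columns
#'   `A, C, G, T, other`, one per region, each carrying `group`,
#'   `genomic_start` and `strand` attributes.
#' @export
count_bases <- function(reads, assignments, refs) {
  out <- list()
  base_raw <- vapply(.BASES, charToRaw, raw(1))
  for (ref in refs) {
    len <- nchar(ref$sequence)
    mat <- matrix(0L, nrow = len, ncol = 5L, dimnames = list(NULL, c(.BASES, "other")))
    idx <- which(assignments$region == ref$name)
    if (length(idx)) {
      seqs <- reads$seq[idx]
      useq <- unique(seqs)
      wts <- as.integer(table(factor(seqs, levels = useq)))
      m <- .raw_mat(useq, len)
      for (b in seq_along(.BASES)) {
        hit <- m == base_raw[[b]]
        mat[, b] <- as.integer(hit %*% wts)
      }
      mat[, "other"] <- sum(wts) - as.integer(rowSums(mat[, .BASES, drop = FALSE]))
    }
    attr(mat, "group") <- ref$group
    attr(mat, "genomic_start") <- ref$genomic_start
    attr(mat, "strand") <- ref$strand
    out[[ref$name]] <- mat
  }
  out
}

# (ref, site, base, offset) lookups for each counting class. A class is
# counted in the matrix of the region that carries it (RHD_var in the RHD
# exon-9 matrix), at the most discriminating of that region's sites: the
# one whose base map separates the largest number of sources (for exon 9
# that is the c.1227-homologous site, where wild type, variant and RHCE
# all differ).
.diagnostic_lookup <- function(refs) {
  out <- list()
  score <- list()
  for (ref in refs) {
    for (site in ref$diagnostic_sites) {
      m <- site$expected_base_by_source
      n_distinct <- length(unique(m))
      for (cls in names(m)) {
        owns <- identical(cls, ref$source_class) ||
          (identical(cls, "RHD_var") && identical(ref$source_class, "RHD_wt"))
        if (owns && (is.null(score[[cls]]) || n_distinct > score[[cls]])) {
          out[[cls]] <- list(region = ref$name, offset = site$amplicon_offset, base = m[[cls]])
          score[[cls]] <- n_distinct
        }
      }
    }
  }
  out
}

#' Extract diagnostic read counts from base-count matrices
#'
#' Pulls, per counting class, the count of the class's expected base at its
#' diagnostic offset from the matrix of the region that carries it (the
#' c.1227 wild-type/variant classes both live in the RHD exon-9 matrix).
#'
#' @param matrices Output of [count_bases()]; all panel regions must be
#'   present (possibly all-zero), else a contract violation is raised.
#' @param refs Reference panel.
#' @return Named integer vector over the five counting classes.
#' @export
extract_diagnostics <- function(matrices, refs) {
  lookup <- .diagnostic_lookup(refs)
  missing <- setdiff(
    unique(vapply(lookup, `[[`, character(1), "region")),
    names(matrices)
  )
  if (length(missing)) {
    .rhd_error(
      sprintf("base-count matrix missing for region(s): %s", paste(missing, collapse = ", ")),
      "rhdamp_error_contract"
    )
  }
  counts <- vapply(UNIT_NAMES, function(cls) {
    lk <- lookup[[cls]]
    if (is.null(lk)) {
      return(0L)
    }
    matrices[[lk$region]][lk$offset, lk$base]
  }, integer(1))
  counts
}

#' Write per-position base counts as a wiggle-style track file
#'
#' One `fixedStep`-style track per region in amplicon coordinates, five
#' tab-separated count columns (`A C G T other`) per position, with a
#' comment line carrying the genomic anchor. Output is byte-stable across
#' runs on identical input.
#'
#' @param matrices Output of [count_bases()].
#' @param refs Reference panel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(matrices, refs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ref_by_name <- stats::setNames(refs, vapply(refs, `[[`, character(1), "name"))
  for (nm in names(matrices)) {
    mat <- matrices[[nm]]
    ref <- ref_by_name[[nm]]
    writeLines(sprintf('track type=wiggle_0 name="%s" description="per-base read counts"', nm), con)
    writeLines(sprintf(
      "#genomic_start=%d strand=%s group=%s",
      ref$genomic_start, ref$strand, ref$group
    ), con)
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", nm), con)
    writeLines("#A\tC\tG\tT\tother", con)
    writeLines(apply(mat, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a wiggle-style track file written by [write_wig()]
#'
#' @param path Path to the `.wig` file.
#' @return Named list of count matrices (columns `A, C, G, T, other`).
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  out <- list()
  current <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(current) && length(rows)) {
      mat <- do.call(rbind, rows)
      dimnames(mat) <- list(NULL, c(.BASES, "other"))
      out[[current]] <<- mat
    }
  }
  for (line in lines) {
    if (startsWith(line, "track ")) {
      flush()
      current <- sub('.*name="([^"]+)".*', "\\1", line)
      rows <- list()
    } else if (startsWith(line, "#") || startsWith(line, "fixedStep")) {
      next
    } else if (nzchar(line)) {
      rows[[length(rows) + 1L]] <- as.integer(strsplit(line, "\t", fixed = TRUE)[[1]])
    }
  }
  flush()
  out
}
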