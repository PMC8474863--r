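# Internal byte/string helpers. All heavy per-base work in the package goes
# through raw-byte matrices built from equal-width strings: R-level loops are
# kept to the number of distinct string widths, never the number of reads.

.BASES <- c("A", "C", "G", "T")

.rhd_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rhdamp_error")))
}

# width x n raw matrix from equal-width strings
.raw_mat <- function(x, width) {
  if (!length(x)) {
    return(matrix(raw(0), nrow = width, ncol = 0))
  }
  matrix(charToRaw(paste(x, collapse = "")), nrow = width)
}

# split one long string into n windows of equal width
.chunk_string <- function(big, width, n) {
  if (n == 0L) {
    return(character(0))
  }
  first <- (seq_len(n) - 1L) * width + 1L
  substring(big, first, first + width - 1L)
}

# mismatch counts of equal-length strings against one reference string
.hamming <- function(x, ref) {
  w <- nchar(ref)
  if (any(nchar(x) != w)) {
    .rhd_error("all sequences must have the reference length", "rhdamp_error_length")
  }
  m <- .raw_mat(x, w)
  as.integer(colSums(m != charToRaw(ref)))
}

.rev_comp <- function(x) {
  if (!length(x)) {
    return(character(0))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.str_rev <- function(x) {
  if (!length(x)) {
    return(character(0))
  }
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

# mean Phred+33 quality per string (NaN for empty strings)
.phred_means <- function(qual) {
  out <- numeric(length(qual))
  w <- nchar(qual)
  for (len in unique(w)) {
    i <- which(w == len)
    if (len == 0L) {
      out[i] <- NaN
      next
    }
    m <- matrix(as.integer(.raw_mat(qual[i], len)), nrow = len)
    out[i] <- colMeans(m) - 33
  }
  out
}

# element-wise per-character maximum of two quality strings
.str_pmax <- function(a, b) {
  w <- nchar(a)
  if (any(w != nchar(b))) {
    .rhd_error("quality strings must have matching lengths", "rhdamp_error_length")
  }
  out <- character(length(a))
  for (len in unique(w)) {
    i <- which(w == len)
    if (len == 0L) {
      out[i] <- ""
      next
    }
    ra <- .raw_mat(a[i], len)
    rb <- .raw_mat(b[i], len)
    lower <- ra < rb
    ra[lower] <- rb[lower]
    out[i] <- .chunk_string(rawToChar(as.vector(ra)), len, length(i))
  }
  out
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# n random DNA strings of the given width, uniform over {A,C,G,T}^width
.random_dna <- function(n, width) {
  if (n == 0L) {
    return(character(0))
  }
  bytes <- as.raw(sample(c(65L, 67L, 71L, 84L), n * width, replace = TRUE))
  .chunk_string(rawToChar(bytes), width, n)
}
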