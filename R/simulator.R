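# Synthetic-data generator: reference panels and paired-end reads with
# ground truth, emulating the statistical structure of the amplicon assay
# (mixture sampling, PCR duplication with per-molecule UMIs, PCR and
# sequencing substitution errors, adaptor read-through).

#' Simulation configuration
#'
#' @param seed Integer seed driving all randomness of a run.
#' @param mixture A [mixture_spec()]; defaults to the 10:1 genomic DNA
#'   mixture of a del/del mother and an `RHD*01`/del fetus.
#' @param molecules_per_group Template molecules drawn per co-amplified
#'   group (default 20000).
#' @param duplication_mean Mean of the per-molecule duplicate-count
#'   distribution, `1 + Geometric` with this mean (default 3; 1 means no
#'   duplication).
#' @param substitution_error_rate Per-base sequencing substitution rate,
#'   applied independently to each read (default 0.001).
#' @param pcr_error_rate Per-base substitution rate per PCR duplication
#'   event; such errors are inherited by both mates of the duplicate
#'   (default 1e-4).
#' @param umi Logical; prefix read 1 with a random 12-base UMI per molecule.
#' @param umi_length UMI length (default 12).
#' @param read_length Read length of both mates (default 151).
#' @param amplification_bias Optional named per-class multiplier on the
#'   expected class probabilities (e.g. `c(RHCE = 1.5)` to emulate the
#'   amplification bias towards RHCE exon 9).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       mixture = mixture_spec(
                         c("RHD*01N.01", "RHD*01N.01"),
                         c("RHD*01", "RHD*01N.01")
                       ),
                       molecules_per_group = 20000L,
                       duplication_mean = 3,
                       substitution_error_rate = 0.001,
                       pcr_error_rate = 1e-4,
                       umi = TRUE,
                       umi_length = 12L,
                       read_length = 151L,
                       amplification_bias = NULL) {
  rates <- c(substitution_error_rate, pcr_error_rate)
  if (any(rates < 0 | rates > 1)) {
    .rhd_error("error rates must lie in [0, 1]", "rhdamp_error_params")
  }
  if (molecules_per_group <= 0 || duplication_mean < 1 || read_length < 1) {
    .rhd_error("molecules_per_group, duplication_mean and read_length must be positive (mean >= 1)", "rhdamp_error_params")
  }
  structure(
    list(
      seed = as.integer(seed),
      mixture = mixture,
      molecules_per_group = as.integer(molecules_per_group),
      duplication_mean = duplication_mean,
      substitution_error_rate = substitution_error_rate,
      pcr_error_rate = pcr_error_rate,
      umi = isTRUE(umi),
      umi_length = as.integer(umi_length),
      read_length = as.integer(read_length),
      amplification_bias = amplification_bias
    ),
    class = "sim_config"
  )
}

# inject `n_err[i]` random substitutions into seqs[i]
.mutate_seqs <- function(seqs, n_err) {
  rounds <- max(n_err, 0L)
  if (rounds == 0L) {
    return(seqs)
  }
  w <- nchar(seqs)
  for (r in seq_len(rounds)) {
    idx <- which(n_err >= r)
    if (!length(idx)) break
    pos <- ceiling(runif(length(idx)) * w[idx])
    cur <- substring(seqs[idx], pos, pos)
    ci <- match(cur, .BASES)
    shift <- floor(runif(length(idx)) * 3) + 1
    new <- .BASES[((ci - 1L + shift) %% 4L) + 1L]
    substring(seqs[idx], pos, pos) <- new
  }
  seqs
}

#' Generate a synthetic amplicon reference panel
#'
#' Random sequences satisfying every structural invariant of the real
#' panel: 105-base Rhesus-box references differing at one interior
#' diagnostic base (upstream G / downstream A), and 148-base exon-9
#' references differing at two interior paralog-diagnostic bases plus the
#' c.1227 site (RHD wild type G / variant A / RHCE C). Genomic anchors are
#' chosen so the diagnostic offsets land on the published hg19 coordinates
#' (RHCE descends, hence its minus strand). Sequences containing a
#' near-match of an adaptor seed are re-drawn so adaptor trimming cannot
#' truncate genuine amplicon reads.
#'
#' @param seed RNG seed (the panel is a deterministic function of it).
#' @return A validated list of [amplicon_ref()] objects.
#' @export
make_synthetic_references <- function(seed = 20210926L) {
  .with_seed(seed, {
    seeds12 <- substr(default_adaptors(), 1L, 12L)
    clean <- function(seq) {
      targets <- Biostrings::DNAStringSet(c(seq, .rev_comp(seq)))
      hits <- vapply(seeds12, function(s) {
        sum(Biostrings::vcountPattern(s, targets, max.mismatch = 1, fixed = TRUE))
      }, numeric(1))
      sum(hits) == 0
    }
    draw <- function(width, patches) {
      repeat {
        s <- .random_dna(1L, width)
        for (i in seq_along(patches)) {
          substring(s, patches[[i]]$at, patches[[i]]$at) <- patches[[i]]$base
        }
        if (clean(s)) {
          return(s)
        }
      }
    }

    box_site_map <- c(upstream_box = "G", downstream_box = "A")
    box_off <- 50L
    up_seq <- draw(105L, list(list(at = box_off, base = "G")))
    down_seq <- up_seq
    substring(down_seq, box_off, box_off) <- "A"

    ex9_maps <- list(
      list(at = 23L, map = c(RHD_wt = "A", RHD_var = "A", RHCE = "T")),
      list(at = 57L, map = c(RHD_wt = "G", RHD_var = "A", RHCE = "C")),
      list(at = 119L, map = c(RHD_wt = "A", RHD_var = "A", RHCE = "G"))
    )
    rhd_seq <- draw(148L, lapply(ex9_maps, function(s) list(at = s$at, base = s$map[["RHD_wt"]])))
    rhce_seq <- rhd_seq
    for (s in ex9_maps) {
      substring(rhce_seq, s$at, s$at) <- s$map[["RHCE"]]
    }

    site <- function(ref_start, strand, off, map) {
      gpos <- if (strand == "+") ref_start + off - 1L else ref_start - off + 1L
      diagnostic_site(off, gpos, map)
    }
    refs <- list(
      amplicon_ref(
        "upstream_box", "rhesus_box", up_seq, "upstream_box",
        genomic_start = 25592579L, strand = "+",
        diagnostic_sites = list(site(25592579L, "+", box_off, box_site_map))
      ),
      amplicon_ref(
        "downstream_box", "rhesus_box", down_seq, "downstream_box",
        genomic_start = 25662906L, strand = "+",
        diagnostic_sites = list(site(25662906L, "+", box_off, box_site_map))
      ),
      amplicon_ref(
        "RHD_ex9", "exon9", rhd_seq, "RHD_wt",
        genomic_start = 25648397L, strand = "+",
        diagnostic_sites = lapply(ex9_maps, function(s) site(25648397L, "+", s$at, s$map))
      ),
      amplicon_ref(
        "RHCE_ex9", "exon9", rhce_seq, "RHCE",
        genomic_start = 25697014L, strand = "-",
        diagnostic_sites = lapply(ex9_maps, function(s) site(25697014L, "-", s$at, s$map))
      )
    )
    validate_reference_panel(refs)
    refs
  })
}

# class -> emitted amplicon sequence (the RHD_var class is the RHD
# reference with the variant base at the c.1227 site)
.class_sequences <- function(refs) {
  lookup <- .diagnostic_lookup(refs)
  ref_by_name <- stats::setNames(refs, vapply(refs, `[[`, character(1), "name"))
  out <- c(
    upstream_box = ref_by_name[["upstream_box"]]$sequence,
    downstream_box = ref_by_name[["downstream_box"]]$sequence,
    RHD_wt = ref_by_name[["RHD_ex9"]]$sequence,
    RHCE = ref_by_name[["RHCE_ex9"]]$sequence
  )
  var <- lookup[["RHD_var"]]
  var_seq <- out[["RHD_wt"]]
  substring(var_seq, var$offset, var$offset) <- var$base
  out[["RHD_var"]] <- var_seq
  out[UNIT_NAMES]
}

#' Simulate paired-end amplicon reads with ground truth
#'
#' Template molecules are drawn per group with class probabilities
#' proportional to [expected_ratios()] of the mixture (times any
#' amplification bias); each molecule receives a unique random UMI (if
#' enabled) and a `1 + Geometric` number of PCR duplicates; PCR errors are
#' injected per duplication event (inherited by both mates), sequencing
#' errors per read. Read 1 is (UMI +) amplicon + adaptor read-through,
#' read 2 the reverse complement + adaptor, both clipped to the read
#' length, with Phred qualities around Q35. Identical configurations
#' produce identical output.
#'
#' @param config A [sim_config()] object.
#' @param refs Reference panel (default [default_reference_panel()]).
#' @param alleles Allele unit-vector model.
#' @param out_dir Optional directory; when given, writes `R1.fastq`,
#'   `R2.fastq`, `truth.json`, `provenance.tsv` and the reference spec
#'   there.
#' @return List with `pairs` (a pair set data.frame), `truth` (class
#'   counts, per-molecule table, per-read provenance, config echo) and
#'   `paths` (when `out_dir` was given).
#' @export
simulate_reads <- function(config, refs = default_reference_panel(),
                           alleles = default_allele_model(), out_dir = NULL) {
  .with_seed(config$seed, {
    er <- expected_ratios(config$mixture, alleles)
    probs <- c(er$box, er$exon9)
    if (!is.null(config$amplification_bias)) {
      b <- config$amplification_bias
      probs[names(b)] <- probs[names(b)] * b
    }
    class_seq <- .class_sequences(refs)

    draw_group <- function(classes) {
      p <- probs[classes]
      as.vector(rmultinom(1L, config$molecules_per_group, p / sum(p)))
    }
    counts <- stats::setNames(
      c(draw_group(BOX_CLASSES), draw_group(EXON9_CLASSES)),
      UNIT_NAMES
    )
    M <- sum(counts)
    mol_class <- rep(UNIT_NAMES, counts)
    mol_umi <- if (config$umi) .random_dna(M, config$umi_length) else rep(NA_character_, M)
    n_dup <- 1L + rgeom(M, prob = 1 / config$duplication_mean)

    mol_idx <- rep(seq_len(M), n_dup)
    dup_idx <- sequence(n_dup)
    N <- length(mol_idx)
    insert <- unname(class_seq[mol_class[mol_idx]])

    n_pcr <- rbinom(N, nchar(insert), config$pcr_error_rate)
    insert <- .mutate_seqs(insert, n_pcr)

    RL <- config$read_length
    adaptors <- default_adaptors()
    fill <- vapply(adaptors, function(a) strrep(a, ceiling(RL / nchar(a)) + 1L), character(1))
    read1 <- substring(
      paste0(if (config$umi) mol_umi[mol_idx] else "", insert, fill[["read1"]]),
      1L, RL
    )
    read2 <- substring(paste0(.rev_comp(insert), fill[["read2"]]), 1L, RL)

    n_sub1 <- rbinom(N, RL, config$substitution_error_rate)
    n_sub2 <- rbinom(N, RL, config$substitution_error_rate)
    read1 <- .mutate_seqs(read1, n_sub1)
    read2 <- .mutate_seqs(read2, n_sub2)

    # per-base Phred qualities ~ Q30-Q40, drawn as windows of a random pool
    pool_len <- 65536L
    qpool <- rawToChar(as.raw(33L + sample(30:40, pool_len, replace = TRUE)))
    qwin <- function(n) {
      at <- sample.int(pool_len - RL, n, replace = TRUE)
      substring(qpool, at, at + RL - 1L)
    }

    ids <- paste0("read", seq_len(N))
    pairs <- data.frame(
      id = ids,
      seq1 = read1, qual1 = qwin(N),
      seq2 = read2, qual2 = qwin(N),
      row.names = NULL, stringsAsFactors = FALSE
    )
    truth <- list(
      class_counts = counts,
      group_counts = c(
        rhesus_box = sum(counts[BOX_CLASSES]),
        exon9 = sum(counts[EXON9_CLASSES])
      ),
      molecules = data.frame(
        molecule = seq_len(M), class = mol_class, umi = mol_umi,
        n_duplicates = n_dup, row.names = NULL, stringsAsFactors = FALSE
      ),
      reads = data.frame(
        id = ids, molecule = mol_idx, duplicate_index = dup_idx,
        n_pcr_errors = n_pcr, n_seq_errors_read1 = n_sub1,
        n_seq_errors_read2 = n_sub2,
        row.names = NULL, stringsAsFactors = FALSE
      ),
      config = config
    )
    out <- list(pairs = pairs, truth = truth)

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- list(
        fastq1 = file.path(out_dir, "R1.fastq"),
        fastq2 = file.path(out_dir, "R2.fastq"),
        truth = file.path(out_dir, "truth.json"),
        provenance = file.path(out_dir, "provenance.tsv"),
        ref_fasta = file.path(out_dir, "refs.fasta"),
        ref_meta = file.path(out_dir, "refs.json")
      )
      write_fq <- function(seqs, quals, ids, path) {
        dss <- Biostrings::DNAStringSet(seqs)
        names(dss) <- ids
        Biostrings::writeXStringSet(dss,
          filepath = path, format = "fastq",
          qualities = Biostrings::BStringSet(quals)
        )
      }
      write_fq(pairs$seq1, pairs$qual1, pairs$id, p$fastq1)
      write_fq(pairs$seq2, pairs$qual2, pairs$id, p$fastq2)
      jsonlite::write_json(
        list(
          class_counts = as.list(truth$class_counts),
          group_counts = as.list(truth$group_counts),
          n_molecules = M, n_reads = N,
          config = list(
            seed = config$seed,
            maternal = config$mixture$maternal,
            fetal = config$mixture$fetal,
            maternal_weight = config$mixture$maternal_weight,
            fetal_weight = config$mixture$fetal_weight,
            molecules_per_group = config$molecules_per_group,
            duplication_mean = config$duplication_mean,
            substitution_error_rate = config$substitution_error_rate,
            pcr_error_rate = config$pcr_error_rate,
            umi = config$umi
          )
        ),
        p$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      utils::write.table(truth$reads, p$provenance,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      write_reference_spec(refs, p$ref_fasta, p$ref_meta)
      out$paths <- p
    }
    out
  })
}

#' Simulate the twelve-combination genotype panel
#'
#' Enumerates the 3 x 4 design used to validate the assay: maternal
#' genotype A is each of the three common RhD-negative genotypes, fetal
#' genotype B is `RHD*01`/del or any of the same three negatives, mixed at
#' 10:1. One simulated run per combination, with per-run seeds derived from
#' the base configuration's seed.
#'
#' @param base_config A [sim_config()] whose mixture is replaced per
#'   combination.
#' @param refs Reference panel.
#' @param alleles Allele unit-vector model.
#' @param out_dir Optional directory; one subdirectory per combination.
#' @return List of 12 runs, each with `name`, `maternal`, `fetal`,
#'   `rhd_positive_truth` and the [simulate_reads()] output.
#' @export
simulate_twelve_panel <- function(base_config = sim_config(),
                                  refs = default_reference_panel(),
                                  alleles = default_allele_model(),
                                  out_dir = NULL) {
  a_genotypes <- default_maternal_candidates()
  b_genotypes <- c(list(c("RHD*01", "RHD*01N.01")), a_genotypes)
  tag <- function(g) gsub("[*.]", "", paste(g, collapse = "-"))
  runs <- list()
  i <- 0L
  for (a in a_genotypes) {
    for (b in b_genotypes) {
      i <- i + 1L
      cfg <- base_config
      cfg$seed <- base_config$seed + i
      cfg$mixture <- mixture_spec(a, b, maternal_weight = 10, fetal_weight = 1)
      name <- sprintf("combo%02d_%s_x_%s", i, tag(a), tag(b))
      run_dir <- if (is.null(out_dir)) NULL else file.path(out_dir, name)
      sim <- simulate_reads(cfg, refs, alleles, out_dir = run_dir)
      runs[[name]] <- list(
        name = name,
        maternal = a,
        fetal = b,
        rhd_positive_truth = "RHD*01" %in% b,
        sim = sim
      )
    }
  }
  runs
}
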