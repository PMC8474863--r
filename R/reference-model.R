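# Reference model: amplicon references, diagnostic sites, allele unit
# vectors, and closed-form expected allele ratios for maternal/fetal
# mixtures.

#' Describe a diagnostic site within an amplicon
#'
#' A diagnostic site is a 1-based amplicon position at which the co-amplified
#' references (and, for the c.1227 site, the two RHD alleles) carry different
#' bases, so the base observed in a read assigns it to its genomic source.
#'
#' @param amplicon_offset 1-based position within the amplicon.
#' @param genomic_pos 1-based hg19 coordinate on chromosome 1 of this
#'   position in the reference that carries the site.
#' @param expected_base_by_source Named character vector mapping source
#'   labels (counting classes such as `"upstream_box"`, `"RHD_wt"`,
#'   `"RHD_var"`, `"RHCE"`) to the single base A/C/G/T each source carries
#'   at this position.
#' @return A `diagnostic_site` list.
#' @export
diagnostic_site <- function(amplicon_offset, genomic_pos, expected_base_by_source) {
  bases <- unlist(expected_base_by_source)
  if (is.null(names(bases)) || any(!nzchar(names(bases)))) {
    .rhd_error("expected_base_by_source must be a named base map", "rhdamp_error_diagnostic_site")
  }
  if (any(!bases %in% .BASES)) {
    .rhd_error("diagnostic bases must be one of A/C/G/T", "rhdamp_error_diagnostic_site")
  }
  if (length(unique(bases)) < 2L && length(bases) > 1L) {
    .rhd_error("diagnostic bases must differ between at least two sources", "rhdamp_error_diagnostic_site")
  }
  structure(
    list(
      amplicon_offset = as.integer(amplicon_offset),
      genomic_pos = as.integer(genomic_pos),
      expected_base_by_source = bases
    ),
    class = "diagnostic_site"
  )
}

#' Construct one amplicon reference
#'
#' @param name Region identifier (e.g. `"upstream_box"`, `"RHD_ex9"`).
#' @param group Co-amplified group: `"rhesus_box"` (105 bp) or `"exon9"`
#'   (148 bp).
#' @param sequence Amplicon DNA sequence (A/C/G/T).
#' @param source_class The counting class whose bases this reference
#'   sequence carries (for the RHD exon-9 reference this is `"RHD_wt"`; the
#'   c.1227G>A class shares the same reference).
#' @param genomic_start 1-based hg19 coordinate of amplicon position 1.
#' @param strand `"+"` or `"-"`; on the minus strand genomic positions run
#'   `genomic_start - offset + 1`.
#' @param primer_spans List with `forward` and `reverse` 1-based closed
#'   intervals of the primer footprints; defaults to the canonical spans for
#'   the group (nt 1-20/81-105 for Rhesus boxes, nt 1-22/120-148 for exon 9).
#' @param diagnostic_sites List of [diagnostic_site()] objects.
#' @return An `amplicon_ref` list.
#' @export
amplicon_ref <- function(name, group, sequence, source_class, genomic_start,
                         strand = "+", primer_spans = NULL,
                         diagnostic_sites = list()) {
  if (is.null(primer_spans)) {
    if (!group %in% names(PRIMER_SPANS)) {
      .rhd_error(sprintf("no default primer spans for group '%s'", group), "rhdamp_error_group")
    }
    primer_spans <- PRIMER_SPANS[[group]]
  }
  structure(
    list(
      name = as.character(name),
      group = as.character(group),
      sequence = toupper(as.character(sequence)),
      source_class = as.character(source_class),
      genomic_start = as.integer(genomic_start),
      strand = match.arg(strand, c("+", "-")),
      primer_spans = lapply(primer_spans, as.integer),
      diagnostic_sites = diagnostic_sites
    ),
    class = "amplicon_ref"
  )
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat(sprintf(
    "<amplicon_ref> %s (%s, %d bp, %s strand, chr1:%d)\n",
    x$name, x$group, nchar(x$sequence), x$strand, x$genomic_start
  ))
  invisible(x)
}

# genomic coordinate of a 1-based amplicon offset
.genomic_pos <- function(ref, offset) {
  if (ref$strand == "+") {
    ref$genomic_start + offset - 1L
  } else {
    ref$genomic_start - offset + 1L
  }
}

# offsets of sites that distinguish two alleles of the SAME region
# (the c.1227-style intra-paralog variant sites)
.variant_site_offsets <- function(refs, group) {
  offs <- integer(0)
  for (ref in refs) {
    if (ref$group != group) next
    for (site in ref$diagnostic_sites) {
      m <- site$expected_base_by_source
      if (all(c("RHD_wt", "RHD_var") %in% names(m)) && m[["RHD_wt"]] != m[["RHD_var"]]) {
        offs <- c(offs, site$amplicon_offset)
      }
    }
  }
  sort(unique(offs))
}

#' Validate a panel of amplicon references
#'
#' Enforces the structural invariants the pipeline relies on: unique names,
#' canonical group lengths and primer spans, diagnostic bases that agree with
#' the sequences, coherent genomic coordinates, and within-group sequence
#' divergence restricted to exactly the declared diagnostic offsets.
#'
#' @param refs List of [amplicon_ref()] objects.
#' @return `refs`, invisibly. Raises a classed validation error naming the
#'   offending record otherwise.
#' @export
validate_reference_panel <- function(refs) {
  nms <- vapply(refs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    .rhd_error(
      sprintf("duplicate amplicon name(s): %s", paste(unique(nms[duplicated(nms)]), collapse = ", ")),
      "rhdamp_error_duplicate_name"
    )
  }
  for (ref in refs) {
    len <- nchar(ref$sequence)
    if (ref$group %in% names(GROUP_LENGTHS) && len != GROUP_LENGTHS[[ref$group]]) {
      .rhd_error(
        sprintf(
          "record '%s': %s amplicons must be %d bases, got %d",
          ref$name, ref$group, GROUP_LENGTHS[[ref$group]], len
        ),
        "rhdamp_error_length"
      )
    }
    if (grepl("[^ACGT]", ref$sequence)) {
      .rhd_error(sprintf("record '%s': sequence contains non-ACGT characters", ref$name), "rhdamp_error_sequence")
    }
    if (ref$group %in% names(PRIMER_SPANS) &&
      !identical(lapply(ref$primer_spans, as.integer), lapply(PRIMER_SPANS[[ref$group]], as.integer))) {
      .rhd_error(sprintf("record '%s': primer spans do not match the %s layout", ref$name, ref$group), "rhdamp_error_primer_span")
    }
    for (site in ref$diagnostic_sites) {
      off <- site$amplicon_offset
      if (off < 1L || off > len) {
        .rhd_error(sprintf("record '%s': diagnostic offset %d outside [1, %d]", ref$name, off, len), "rhdamp_error_diagnostic_site")
      }
      if (site$genomic_pos != .genomic_pos(ref, off)) {
        .rhd_error(
          sprintf("record '%s': genomic position %d inconsistent with anchor at offset %d", ref$name, site$genomic_pos, off),
          "rhdamp_error_coordinates"
        )
      }
      own <- site$expected_base_by_source[ref$source_class]
      if (!is.na(own) && substring(ref$sequence, off, off) != own) {
        .rhd_error(
          sprintf(
            "record '%s': sequence base %s at offset %d disagrees with declared %s base %s",
            ref$name, substring(ref$sequence, off, off), off, ref$source_class, own
          ),
          "rhdamp_error_diagnostic_base"
        )
      }
    }
  }
  # within-group invariants
  for (grp in unique(vapply(refs, `[[`, character(1), "group"))) {
    members <- Filter(function(r) r$group == grp, refs)
    lens <- vapply(members, function(r) nchar(r$sequence), integer(1))
    if (length(unique(lens)) > 1L) {
      .rhd_error(sprintf("group '%s': amplicon lengths differ (%s)", grp, paste(lens, collapse = ", ")), "rhdamp_error_length")
    }
    site_offsets <- lapply(members, function(r) {
      sort(vapply(r$diagnostic_sites, `[[`, integer(1), "amplicon_offset"))
    })
    if (length(unique(site_offsets)) > 1L) {
      .rhd_error(sprintf("group '%s': members declare different diagnostic offsets", grp), "rhdamp_error_diagnostic_site")
    }
    if (length(members) >= 2L) {
      for (i in seq_len(length(members) - 1L)) {
        for (j in seq((i + 1L), length(members))) {
          a <- members[[i]]
          b <- members[[j]]
          diff_pos <- which(charToRaw(a$sequence) != charToRaw(b$sequence))
          expected <- integer(0)
          for (site in a$diagnostic_sites) {
            m <- site$expected_base_by_source
            if (all(c(a$source_class, b$source_class) %in% names(m)) &&
              m[[a$source_class]] != m[[b$source_class]]) {
              expected <- c(expected, site$amplicon_offset)
            }
          }
          if (!identical(sort(diff_pos), sort(unique(expected)))) {
            .rhd_error(
              sprintf(
                "group '%s': '%s' and '%s' differ at position(s) %s but diagnostic sites declare %s",
                grp, a$name, b$name,
                paste(diff_pos, collapse = ","),
                if (length(expected)) paste(sort(unique(expected)), collapse = ",") else "none"
              ),
              "rhdamp_error_sequence_divergence"
            )
          }
        }
      }
    }
  }
  invisible(refs)
}

#' Load an amplicon reference specification from FASTA + JSON
#'
#' The FASTA file holds the amplicon sequences; the JSON metadata supplies,
#' per record, the group, primer spans, genomic anchor, strand, source class
#' and diagnostic sites. Records are matched by name and the assembled panel
#' is validated with [validate_reference_panel()].
#'
#' @param fasta_path Path to the amplicon FASTA file.
#' @param meta_path Path to the JSON metadata file.
#' @return A validated list of [amplicon_ref()] objects.
#' @export
load_reference_spec <- function(fasta_path, meta_path) {
  if (!file.exists(fasta_path) || !file.exists(meta_path)) {
    .rhd_error("reference FASTA or metadata file not found", "rhdamp_error_io")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = FALSE)
  records <- meta$amplicons
  if (is.null(records) || !length(records)) {
    .rhd_error("metadata has no 'amplicons' records", "rhdamp_error_io")
  }
  refs <- lapply(records, function(r) {
    if (!r$name %in% names(seqs)) {
      .rhd_error(sprintf("record '%s': no matching FASTA sequence", r$name), "rhdamp_error_io")
    }
    sites <- lapply(r$diagnostic_sites, function(s) {
      diagnostic_site(
        amplicon_offset = s$amplicon_offset,
        genomic_pos = s$genomic_pos,
        expected_base_by_source = unlist(s$expected_base_by_source)
      )
    })
    amplicon_ref(
      name = r$name, group = r$group,
      sequence = as.character(seqs[[r$name]]),
      source_class = r$source_class,
      genomic_start = r$genomic_start,
      strand = r$strand,
      primer_spans = list(
        forward = unlist(r$primer_spans$forward),
        reverse = unlist(r$primer_spans$reverse)
      ),
      diagnostic_sites = sites
    )
  })
  validate_reference_panel(refs)
  refs
}

#' Write an amplicon reference specification to FASTA + JSON
#'
#' Inverse of [load_reference_spec()].
#'
#' @param refs List of [amplicon_ref()] objects.
#' @param fasta_path,meta_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_reference_spec <- function(refs, fasta_path, meta_path) {
  dss <- Biostrings::DNAStringSet(vapply(refs, `[[`, character(1), "sequence"))
  names(dss) <- vapply(refs, `[[`, character(1), "name")
  Biostrings::writeXStringSet(dss, filepath = fasta_path)
  records <- lapply(refs, function(r) {
    list(
      name = r$name,
      group = r$group,
      source_class = r$source_class,
      genomic_start = r$genomic_start,
      strand = r$strand,
      primer_spans = r$primer_spans,
      diagnostic_sites = lapply(r$diagnostic_sites, function(s) {
        list(
          amplicon_offset = s$amplicon_offset,
          genomic_pos = s$genomic_pos,
          expected_base_by_source = as.list(s$expected_base_by_source)
        )
      })
    )
  })
  jsonlite::write_json(list(amplicons = records), meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fasta = fasta_path, meta = meta_path))
}

#' Default (synthetic) amplicon reference panel
#'
#' Loads the synthetic reference panel shipped with the package. The real
#' amplicon sequences are not public; these satisfy every structural
#' invariant (lengths, primer spans, diagnostic offsets/bases, genomic
#' anchors) and can be swapped for real references via
#' [load_reference_spec()].
#'
#' @return A validated list of [amplicon_ref()] objects.
#' @export
default_reference_panel <- function() {
  load_reference_spec(
    system.file("extdata", "synthetic_refs.fasta", package = "rhdamp"),
    system.file("extdata", "synthetic_refs.json", package = "rhdamp")
  )
}

#' Allele unit-vector model
#'
#' Each RHD allele contributes a fixed number of amplifiable copies of each
#' of the five counting classes per allele copy: the wild-type allele
#' `RHD*01` contributes one upstream box, one downstream box, one RHD
#' wild-type exon 9 and one RHCE exon 9; the whole-gene deletion
#' `RHD*01N.01` carries a single hybrid box (modeled as downstream-type) and
#' only RHCE exon 9; the D-el allele `RHD*01EL.01` is `RHD*01` with the
#' c.1227G>A variant exon 9; the RHD-CE hybrid `RHD*01N.04` keeps both boxes
#' but carries two RHCE-type exon-9 copies.
#'
#' @param path Optional path to a JSON file mapping allele names to unit
#'   vectors; defaults to the table shipped with the package.
#' @return Named list of named numeric unit vectors over
#'   `upstream_box, downstream_box, RHD_wt, RHD_var, RHCE`.
#' @export
default_allele_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "allele_units.json", package = "rhdamp")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  model <- lapply(raw, function(u) {
    v <- unlist(u)[UNIT_NAMES]
    names(v) <- UNIT_NAMES
    v
  })
  for (nm in names(model)) {
    v <- model[[nm]]
    if (any(is.na(v)) || any(v < 0)) {
      .rhd_error(sprintf("allele '%s': unit vector must be complete and non-negative", nm), "rhdamp_error_allele_model")
    }
  }
  model
}

# summed unit vector of a two-allele genotype
.genotype_units <- function(genotype, alleles) {
  if (length(genotype) != 2L) {
    .rhd_error("a genotype is a pair of allele names", "rhdamp_error_genotype")
  }
  missing <- setdiff(genotype, names(alleles))
  if (length(missing)) {
    .rhd_error(sprintf("unknown allele name(s): %s", paste(missing, collapse = ", ")), "rhdamp_error_unknown_allele")
  }
  alleles[[genotype[[1]]]] + alleles[[genotype[[2]]]]
}

#' Specify a maternal/fetal genotype mixture
#'
#' @param maternal,fetal Character vectors of two allele names each.
#' @param maternal_weight,fetal_weight Relative genome-equivalent weights
#'   (e.g. 10 and 1 for the 10:1 genomic DNA mixtures). Ignored when
#'   `fetal_fraction` is given.
#' @param fetal_fraction Alternatively, the fetal fraction f in \[0, 1\];
#'   weights are then `1 - f` and `f`.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(maternal, fetal, maternal_weight = 10, fetal_weight = 1,
                         fetal_fraction = NULL) {
  if (!is.null(fetal_fraction)) {
    if (fetal_fraction < 0 || fetal_fraction > 1) {
      .rhd_error("fetal_fraction must lie in [0, 1]", "rhdamp_error_mixture")
    }
    maternal_weight <- 1 - fetal_fraction
    fetal_weight <- fetal_fraction
  }
  if (maternal_weight < 0 || fetal_weight < 0 || maternal_weight + fetal_weight <= 0) {
    .rhd_error("mixture weights must be non-negative with a positive sum", "rhdamp_error_mixture")
  }
  structure(
    list(
      maternal = as.character(maternal),
      fetal = as.character(fetal),
      maternal_weight = maternal_weight,
      fetal_weight = fetal_weight,
      fetal_fraction = fetal_weight / (maternal_weight + fetal_weight)
    ),
    class = "mixture_spec"
  )
}

#' Expected allele ratios of a maternal/fetal mixture
#'
#' Sums the per-allele unit vectors of both genotypes weighted by mixture
#' weight and normalizes within each co-amplified group, giving the expected
#' fraction of upstream-box reads among Rhesus-box reads and of
#' RHD-wild-type / c.1227G>A / RHCE reads among exon-9 reads.
#'
#' @param mix A [mixture_spec()].
#' @param alleles Allele unit-vector model, see [default_allele_model()].
#' @return List with components `box` (named fractions over the two box
#'   classes), `exon9` (named fractions over the three exon-9 classes) and
#'   `units` (the combined weighted unit vector).
#' @export
expected_ratios <- function(mix, alleles = default_allele_model()) {
  gm <- .genotype_units(mix$maternal, alleles)
  gf <- .genotype_units(mix$fetal, alleles)
  units <- mix$maternal_weight * gm + mix$fetal_weight * gf
  box_total <- sum(units[BOX_CLASSES])
  ex_total <- sum(units[EXON9_CLASSES])
  if (box_total <= 0 || ex_total <= 0) {
    .rhd_error("mixture contributes no amplifiable copies in one group", "rhdamp_error_mixture")
  }
  list(
    box = units[BOX_CLASSES] / box_total,
    exon9 = units[EXON9_CLASSES] / ex_total,
    units = units
  )
}

#' Invert the upstream-box fraction to a fetal-fraction estimate
#'
#' For a mother whose genotype contributes no upstream-box copies (the
#' RhD-negative del/del pattern), the expected upstream fraction among box
#' reads is a monotone function of the fetal fraction f; this solves it for
#' f in closed form. For a del/del mother and an `RHD*01`/del fetus the
#' inverse is `f = 2u / (1 - u)`.
#'
#' @param u Observed upstream-box fraction (of box reads), in \[0, 1).
#' @param maternal_genotype,fetal_genotype Pairs of allele names; the
#'   maternal genotype must have zero upstream-box units, else the inversion
#'   is not identifiable and a classed error is raised.
#' @param alleles Allele unit-vector model.
#' @return The fetal-fraction estimate f.
#' @export
fetal_fraction_from_upstream <- function(u, maternal_genotype, fetal_genotype,
                                         alleles = default_allele_model()) {
  if (!is.numeric(u) || is.na(u) || u < 0 || u >= 1) {
    .rhd_error("u must be a fraction in [0, 1)", "rhdamp_error_fraction")
  }
  gm <- .genotype_units(maternal_genotype, alleles)
  gf <- .genotype_units(fetal_genotype, alleles)
  if (gm[["upstream_box"]] != 0) {
    .rhd_error(
      "maternal genotype contributes upstream-box copies; fetal fraction is not identifiable from u",
      "rhdamp_error_unsupported"
    )
  }
  u_f <- gf[["upstream_box"]]
  d_f <- gf[["downstream_box"]]
  d_m <- gm[["downstream_box"]]
  if (u == 0) {
    return(0)
  }
  if (u_f == 0) {
    .rhd_error(
      "fetal genotype contributes no upstream-box copies but u > 0 was observed",
      "rhdamp_error_unsupported"
    )
  }
  denom <- u_f - u * (u_f + d_f - d_m)
  f <- u * d_m / denom
  if (!is.finite(f) || denom <= 0 || f < 0 || f > 1) {
    .rhd_error(
      sprintf("observed u = %g is incompatible with the assumed genotypes", u),
      "rhdamp_error_fraction"
    )
  }
  f
}
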