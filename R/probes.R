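# Probe design for RNA events.
#
# Mutation probes: for each variant, a mutant probe carrying (k-1)-nt
# flanks around the ALT allele and its wildtype counterpart with the REF
# allele.  For a SNV with k = 31 both are 61 nt and every k-mer of the
# mutant probe covers the variant base, so a single read carrying the
# mutation can light up any of its k-mers.
#
# Junction probes: a short sequence centered on a fusion or splice
# breakpoint (default 51 nt: 25 nt ending at the left breakpoint + 26 nt
# starting at the right one), deliberately shorter than 2k-1 so that every
# k-mer spans the junction with at least 5 nt on each side.

#' Read variants from a VCF file
#'
#' Parses a VCF into the tidy variant table used by
#' [design_mutation_probes()].  Multi-allelic records must be split
#' beforehand (e.g. with `bcftools norm -m-`).
#'
#' @param path Path to a VCF file.
#' @return A tibble with columns `variant_id` (`chrom:pos:ref>alt`),
#'   `chrom`, `pos`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) {                     # single-record VCF
    fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  }
  tibble(
    chrom = as.character(fx[, "CHROM"]),
    pos = as.integer(fx[, "POS"]),
    ref = toupper(as.character(fx[, "REF"])),
    alt = toupper(as.character(fx[, "ALT"]))
  ) |>
    mutate(variant_id = sprintf("%s:%d:%s>%s", .data$chrom, .data$pos,
                                .data$ref, .data$alt)) |>
    select("variant_id", "chrom", "pos", "ref", "alt")
}

#' Design mutant/wildtype probe pairs for variants
#'
#' For each variant the mutant probe is the (k-1)-nt left flank, the ALT
#' allele, and the (k-1)-nt right flank; the wildtype probe carries REF
#' between the same flanks.  SNV probes are therefore `2k - 1` nt (61 for
#' k = 31) and differ from their wildtype counterpart at exactly the
#' center base.  Indel probes keep the same flanks, so their length is
#' `2(k - 1) + nchar(allele)`; this allele-aware construction preserves
#' the guarantee that every mutant-probe k-mer overlaps the ALT allele.
#' Flanks are truncated at contig edges (with a warning); a probe that
#' would end up shorter than `k` is an error.
#'
#' @param variants A data frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `ref`, `alt` and optionally `variant_id`; or a VCF path
#'   (passed through [read_variants()]).
#' @param genome Reference sequences: a named character vector or a FASTA
#'   path.  Soft-masked lowercase is uppercased.
#' @param k K-mer length the probes will be queried with (default 31).
#' @return A tibble with columns `variant_id`, `kind` (`snv`,
#'   `insertion`, `deletion`, `mnv`), `mutant_seq`, `wildtype_seq`.
#' @export
design_mutation_probes <- function(variants, genome, k = 31L) {
  if (is.character(variants) && length(variants) == 1L) {
    variants <- read_variants(variants)
  }
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  genome <- resolve_genome(genome)
  k <- as.integer(k)
  n <- nrow(variants)
  ids <- if ("variant_id" %in% names(variants)) {
    as.character(variants$variant_id)
  } else {
    sprintf("%s:%d:%s>%s", variants$chrom, variants$pos,
            toupper(variants$ref), toupper(variants$alt))
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    chrom <- as.character(variants$chrom[i])
    pos <- as.integer(variants$pos[i])
    ref <- toupper(variants$ref[i])
    alt <- toupper(variants$alt[i])
    if (grepl(",", alt, fixed = TRUE)) {
      abort(sprintf(
        "variant %s is multi-allelic; split it into one record per ALT first",
        ids[i]))
    }
    if (!chrom %in% names(genome)) {
      abort(sprintf("variant %s: contig '%s' not in genome", ids[i], chrom))
    }
    ctg <- genome[[chrom]]
    L <- nchar(ctg)
    ref_obs <- substr(ctg, pos, pos + nchar(ref) - 1L)
    if (ref_obs != ref) {
      abort(sprintf(
        "variant %s: REF is '%s' but genome has '%s' at %s:%d",
        ids[i], ref, ref_obs, chrom, pos))
    }
    left <- substr(ctg, max(1L, pos - (k - 1L)), pos - 1L)
    right_start <- pos + nchar(ref)
    right <- substr(ctg, right_start, min(L, right_start + k - 2L))
    if (nchar(left) < k - 1L || nchar(right) < k - 1L) {
      warn(sprintf("variant %s: flank truncated at contig edge", ids[i]))
    }
    mutant <- paste0(left, alt, right)
    wildtype <- paste0(left, ref, right)
    if (nchar(mutant) < k || nchar(wildtype) < k) {
      abort(sprintf("variant %s: probe shorter than k after truncation",
                    ids[i]))
    }
    kind <- if (nchar(ref) == 1L && nchar(alt) == 1L) "snv"
      else if (nchar(ref) < nchar(alt)) "insertion"
      else if (nchar(ref) > nchar(alt)) "deletion"
      else "mnv"
    out[[i]] <- tibble(variant_id = ids[i], kind = kind,
                       mutant_seq = mutant, wildtype_seq = wildtype)
  }
  dplyr::bind_rows(out)
}

resolve_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (!is.character(genome) || is.null(names(genome))) {
    abort("`genome` must be a named character vector or a FASTA path")
  }
  toupper(genome)
}

#' Design junction probes for fusions and neo-splicing events
#'
#' Builds a probe of `total_len` nt centered on each junction: the
#' upstream side contributes `floor(total_len / 2)` nt ending at the left
#' breakpoint (reverse-complemented when its strand is `-`), the
#' downstream side `ceiling(total_len / 2)` nt starting at the right
#' breakpoint (reverse-complemented when `-`).  With the 51-nt default
#' and k = 31, the probe yields 21 k-mers, each overlapping both sides of
#' the junction by at least 5 nt.  Flanks truncated by a contig edge are
#' accepted down to 5 nt per side, below which the junction is an error.
#'
#' @param junctions A data frame with columns `junction_id`, `chrom_left`,
#'   `end_left`, `strand_left`, `chrom_right`, `start_right`,
#'   `strand_right` (coordinates 1-based inclusive); or a path to such a
#'   TSV.  An optional `support` column is carried through.
#' @param genome Named character vector of contigs or a FASTA path.
#' @param total_len Probe length (default 51).
#' @return A tibble with columns `junction_id`, `seq` and the input
#'   coordinate columns.
#' @export
design_junction_probes <- function(junctions, genome, total_len = 51L) {
  if (is.character(junctions) && length(junctions) == 1L) {
    junctions <- read_junctions(junctions)
  }
  need <- c("junction_id", "chrom_left", "end_left", "strand_left",
            "chrom_right", "start_right", "strand_right")
  stopifnot(is.data.frame(junctions))
  if (!all(need %in% names(junctions))) {
    abort(sprintf("junction table is missing column(s): %s",
                  paste(setdiff(need, names(junctions)), collapse = ", ")))
  }
  genome <- resolve_genome(genome)
  up_len <- as.integer(floor(total_len / 2))
  down_len <- as.integer(ceiling(total_len / 2))

  n <- nrow(junctions)
  seqs <- character(n)
  for (i in seq_len(n)) {
    id <- junctions$junction_id[i]
    up <- flank_seq(genome, junctions$chrom_left[i],
                    as.integer(junctions$end_left[i]),
                    junctions$strand_left[i], up_len, side = "up", id = id)
    down <- flank_seq(genome, junctions$chrom_right[i],
                      as.integer(junctions$start_right[i]),
                      junctions$strand_right[i], down_len, side = "down",
                      id = id)
    if (nchar(up) < 5L || nchar(down) < 5L) {
      abort(sprintf("junction %s: flank shorter than 5 nt", id))
    }
    seqs[i] <- paste0(up, down)
  }
  dplyr::bind_cols(tibble(junction_id = junctions$junction_id, seq = seqs),
                   junctions[setdiff(names(junctions), "junction_id")])
}

# Extract one side of a junction probe.  "up" takes `len` nt ending at
# `pos` on the + strand (or starting at `pos`, reverse-complemented, on
# -); "down" is the mirror image.
flank_seq <- function(genome, chrom, pos, strand, len, side, id) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("junction %s: contig '%s' not in genome", id, chrom))
  }
  ctg <- genome[[chrom]]
  L <- nchar(ctg)
  if (pos < 1L || pos > L) {
    abort(sprintf("junction %s: position %d off contig '%s' (1..%d)",
                  id, pos, chrom, L))
  }
  fwd <- (side == "up") == (strand == "+")
  s <- if (fwd) {
    substr(ctg, max(1L, pos - len + 1L), pos)
  } else {
    substr(ctg, pos, min(L, pos + len - 1L))
  }
  if (strand == "-") revcomp(s) else s
}

#' Read a junction table
#'
#' Reads the tab-separated junction dialect used by
#' [design_junction_probes()] (1-based inclusive breakpoint coordinates;
#' comment lines starting with `#` ignored).
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_junctions <- function(path) {
  as_tibble(utils::read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE))
}

#' Filter junctions by read support
#'
#' Drops junctions whose supporting read count falls below `min_reads`
#' (default 4, a conservative floor below which putative fusions are
#' mostly noise).
#'
#' @param junctions A data frame with a numeric `support` column.
#' @param min_reads Minimum support retained.
#' @return The filtered table.
#' @export
filter_junctions_min_support <- function(junctions, min_reads = 4) {
  stopifnot(is.data.frame(junctions))
  if (!"support" %in% names(junctions)) {
    abort("junction table has no `support` column")
  }
  junctions[junctions$support >= min_reads, , drop = FALSE]
}

#' Write probes to FASTA
#'
#' Writes a probe table as FASTA.  Mutation probe pairs (columns
#' `mutant_seq` / `wildtype_seq`) become paired records `<id>|mut` and
#' `<id>|wt`; tables with a `seq` column are written as-is.
#'
#' @param probes A probe tibble from [design_mutation_probes()] or
#'   [design_junction_probes()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probes_fasta <- function(probes, path) {
  if (all(c("mutant_seq", "wildtype_seq") %in% names(probes))) {
    seqs <- setNames(
      c(rbind(probes$mutant_seq, probes$wildtype_seq)),
      c(rbind(paste0(probes$variant_id, "|mut"),
              paste0(probes$variant_id, "|wt")))
    )
  } else if ("seq" %in% names(probes)) {
    ids <- probes$probe_id %||% probes$junction_id
    seqs <- setNames(probes$seq, ids)
  } else {
    abort("unrecognised probe table layout")
  }
  write_fasta(seqs, path)
}
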