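# Synthetic ground-truth data: random transcriptomes, read sets with known
# transcript abundances, spiked variants at set allele fractions, and
# fusion transcripts.  Everything is deterministic given its seed, so the
# whole validation suite runs from code with no external data.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Small deterministic sub-seed kept inside the 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + i * 10007) %% 2147483647)
}

#' Generate a random transcriptome
#'
#' I.i.d. uniform A/C/G/T sequences.  With `shared_segment`, a segment of
#' that length is copied from the first transcript into the second, which
#' plants deliberately non-unique k-mers for masking tests.
#'
#' @param n Number of transcripts.
#' @param length_range Two integers, min and max transcript length
#'   (uniform; both ends inclusive).
#' @param seed RNG seed (mandatory; same seed, same FASTA).
#' @param shared_segment Optional segment length to duplicate between
#'   transcripts 1 and 2.
#' @return A tibble with columns `transcript_id`, `seq`.
#' @export
#' @examples
#' make_transcriptome(3, c(200, 300), seed = 1)
make_transcriptome <- function(n, length_range = c(500L, 1000L), seed,
                               shared_segment = NULL) {
  stopifnot(n >= 1, length(length_range) == 2)
  with_seed(seed, {
    # sample.int avoids the sample(x, n) scalar pitfall when min == max
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n,
                 replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    if (!is.null(shared_segment)) {
      if (n < 2) abort("`shared_segment` needs at least 2 transcripts")
      len <- as.integer(shared_segment)
      if (len > min(lens[1:2])) abort("`shared_segment` longer than transcripts")
      from <- sample(nchar(seqs[1]) - len + 1L, 1L)
      seg <- substr(seqs[1], from, from + len - 1L)
      at <- sample(nchar(seqs[2]) - len + 1L, 1L)
      substr(seqs[2], at, at + len - 1L) <- seg
    }
    tibble(transcript_id = sprintf("t%02d", seq_len(n)), seq = seqs)
  })
}

#' Simulate an RNA-seq read set
#'
#' Each read picks a transcript with probability proportional to
#' `abundance * (length - read_len + 1)` (abundances are relative
#' weights; a transcript's expected coverage is its weight share times
#' `n_reads * read_len` over its length), then a uniform start, then
#' i.i.d. per-base substitution errors at `error_rate`.  Transcripts
#' shorter than `read_len` are excluded with a warning.
#'
#' @param transcripts A tibble from [make_transcriptome()] or a named
#'   character vector.
#' @param abundances Numeric relative weights, one per transcript (named
#'   or positional).
#' @param read_len Read length (default 75).
#' @param n_reads Number of reads.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed RNG seed (mandatory).
#' @return A named character vector of reads with attribute `origin`
#'   giving each read's source transcript id.
#' @export
simulate_reads <- function(transcripts, abundances, read_len = 75L, n_reads,
                           error_rate = 0, seed) {
  tx <- resolve_transcripts(transcripts)
  if (length(abundances) != length(tx)) {
    abort("need one abundance per transcript")
  }
  ab <- if (!is.null(names(abundances))) abundances[names(tx)] else abundances
  lens <- nchar(tx)
  short <- lens < read_len
  if (any(short & ab > 0)) {
    warn(sprintf("%d transcript(s) shorter than read_len excluded",
                 sum(short & ab > 0)))
  }
  w <- ab * pmax(lens - read_len + 1, 0)
  if (sum(w) <= 0) abort("abundances sum to zero over usable transcripts")
  with_seed(seed, {
    pick <- sample.int(length(tx), n_reads, replace = TRUE, prob = w)
    starts <- floor(runif(n_reads) * (lens[pick] - read_len + 1)) + 1L
    reads <- substr(tx[pick], starts, starts + read_len - 1L)
    if (error_rate > 0) reads <- add_substitutions(reads, error_rate)
    structure(setNames(reads, sprintf("read%06d", seq_len(n_reads))),
              origin = names(tx)[pick])
  })
}

resolve_transcripts <- function(transcripts) {
  if (is.data.frame(transcripts)) {
    return(setNames(toupper(transcripts$seq), transcripts$transcript_id))
  }
  if (is.character(transcripts) && !is.null(names(transcripts))) {
    return(toupper(transcripts))
  }
  abort("`transcripts` must be a transcript tibble or named character vector")
}

add_substitutions <- function(reads, rate) {
  L <- nchar(reads[1L])
  total <- length(reads) * L
  hit <- which(runif(total) < rate)
  if (length(hit) == 0L) return(reads)
  read_i <- ((hit - 1L) %/% L) + 1L
  pos <- ((hit - 1L) %% L) + 1L
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(hit)) {
    cur <- substr(reads[read_i[j]], pos[j], pos[j])
    substr(reads[read_i[j]], pos[j], pos[j]) <-
      sample(setdiff(bases, cur), 1L)
  }
  reads
}

#' Apply a variant to a transcript sequence
#'
#' @param seq Transcript sequence.
#' @param pos 1-based position of the REF allele.
#' @param ref,alt REF and ALT alleles (VCF convention).
#' @return The mutated sequence.
#' @export
apply_variant <- function(seq, pos, ref, alt) {
  seq <- toupper(seq)
  if (pos < 1 || pos + nchar(ref) - 1 > nchar(seq)) {
    abort(sprintf("variant position %d off transcript (1..%d)", pos, nchar(seq)))
  }
  obs <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (obs != toupper(ref)) {
    abort(sprintf("REF '%s' does not match transcript ('%s') at %d",
                  ref, obs, pos))
  }
  paste0(substr(seq, 1L, pos - 1L), toupper(alt),
         substr(seq, pos + nchar(ref), nchar(seq)))
}

#' Simulate a sample carrying variants at set allele fractions
#'
#' Like [simulate_reads()], but each transcript may carry one variant at
#' a given `vaf`: a read drawn from that transcript comes from the mutant
#' haplotype with probability `vaf`, else from the wildtype.
#'
#' @inheritParams simulate_reads
#' @param variants A tibble with columns `transcript_id`, `pos`, `ref`,
#'   `alt`, `vaf` (at most one variant per transcript), or `NULL`.
#' @return A named character vector of reads (attribute `origin` as in
#'   [simulate_reads()]; mutant-haplotype reads are labelled
#'   `<transcript_id>|mut`).
#' @export
simulate_sample <- function(transcripts, abundances, variants = NULL,
                            read_len = 75L, n_reads, error_rate = 0, seed) {
  tx <- resolve_transcripts(transcripts)
  if (is.null(variants) || nrow(variants) == 0L) {
    return(simulate_reads(tx, abundances, read_len, n_reads, error_rate, seed))
  }
  if (anyDuplicated(variants$transcript_id)) {
    abort("at most one variant per transcript per sample")
  }
  if (any(variants$vaf < 0 | variants$vaf > 1)) {
    abort("`vaf` must be within [0, 1]")
  }
  # split each variant transcript into a wildtype and a mutant haplotype
  # whose weights sum to the original weight
  ab <- if (!is.null(names(abundances))) abundances[names(tx)] else
    setNames(abundances, names(tx))
  mut_ids <- paste0(variants$transcript_id, "|mut")
  mut_seq <- vapply(seq_len(nrow(variants)), function(i) {
    apply_variant(tx[[variants$transcript_id[i]]], variants$pos[i],
                  variants$ref[i], variants$alt[i])
  }, character(1))
  tx2 <- c(tx, setNames(mut_seq, mut_ids))
  ab2 <- c(ab, setNames(ab[variants$transcript_id] * variants$vaf, mut_ids))
  ab2[variants$transcript_id] <- ab[variants$transcript_id] * (1 - variants$vaf)
  simulate_reads(tx2, ab2, read_len, n_reads, error_rate, seed)
}

#' Create a fusion transcript and its truth junction record
#'
#' The fused sequence is `tA[1..posA]` followed by `tB[posB..end]`; the
#' returned junction row uses the package's 1-based inclusive junction
#' dialect, so a probe designed from it matches the fused sequence
#' exactly around the breakpoint.
#'
#' @param transcripts Transcript tibble or named character vector.
#' @param tA,tB Transcript ids of the 5' and 3' partners.
#' @param posA Last base of `tA` retained (1-based).
#' @param posB First base of `tB` retained (1-based).
#' @param id Junction id (default `"<tA>_<posA>_<tB>_<posB>"`).
#' @param support Read-support value recorded in the junction row
#'   (default 10).
#' @return A list with elements `transcript` (tibble row: fused
#'   `transcript_id`, `seq`) and `junction` (tibble row in the junction
#'   TSV dialect).
#' @export
make_fusion <- function(transcripts, tA, posA, tB, posB, id = NULL,
                        support = 10) {
  tx <- resolve_transcripts(transcripts)
  if (!all(c(tA, tB) %in% names(tx))) abort("unknown transcript id")
  if (posA < 1 || posA > nchar(tx[[tA]]) || posB < 1 || posB > nchar(tx[[tB]])) {
    abort("fusion position off transcript")
  }
  id <- id %||% sprintf("%s_%d_%s_%d", tA, posA, tB, posB)
  fused <- paste0(substr(tx[[tA]], 1L, posA),
                  substr(tx[[tB]], posB, nchar(tx[[tB]])))
  list(
    transcript = tibble(transcript_id = paste0("fusion|", id), seq = fused),
    junction = tibble(junction_id = id,
                      chrom_left = tA, end_left = as.integer(posA),
                      strand_left = "+",
                      chrom_right = tB, start_right = as.integer(posB),
                      strand_right = "+", support = support)
  )
}

#' Simulate a full validation cohort
#'
#' Generates the standard synthetic study used throughout the package's
#' validation: a random transcriptome, a cohort of samples at uniform
#' transcript abundance, SNVs spiked into designated carrier samples at a
#' fixed allele fraction, and fusion transcripts expressed only in their
#' carrier samples.  Variant `i` is carried by sample `(i - 1) %% n_samples + 1`,
#' and likewise for fusions, so every sample carries some events and every
#' event has negative samples.
#'
#' @param n_samples Number of samples (default 3).
#' @param n_transcripts Number of transcripts (default 20).
#' @param length_range Transcript length range (default 400-600 nt).
#' @param n_snvs Number of spiked SNVs (default 10).
#' @param vaf Allele fraction of spiked SNVs in carrier samples
#'   (default 0.5, heterozygous-like).
#' @param n_fusions Number of fusion transcripts (default 5).
#' @param coverage Mean fold-coverage per sample (default 100).
#' @param read_len Read length (default 75).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed RNG seed (mandatory).
#' @return A list of class `kprobe_cohort`: `transcripts` (wildtype
#'   transcriptome tibble), `fusion_transcripts`, `junctions` (truth
#'   junction table), `variants` (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`), `truth_vaf` (`variant_id`, `sample`, `vaf`),
#'   `truth_mutation_pairs` and `truth_fusion_pairs` (positive
#'   (probe, sample) pairs), `reads` (named list of read vectors), and
#'   the simulation parameters.
#' @export
simulate_cohort <- function(n_samples = 3L, n_transcripts = 20L,
                            length_range = c(400L, 600L), n_snvs = 10L,
                            vaf = 0.5, n_fusions = 5L, coverage = 100,
                            read_len = 75L, error_rate = 0, seed) {
  stopifnot(n_transcripts >= n_snvs, n_transcripts >= 2 * n_fusions || n_fusions == 0)
  tx <- make_transcriptome(n_transcripts, length_range,
                           seed = derive_seed(seed, 1))
  samples <- sprintf("s%02d", seq_len(n_samples))

  # spiked SNVs: variant i sits on transcript i, away from the ends so
  # full-length probes exist, and is carried by one sample
  variants <- with_seed(derive_seed(seed, 2), {
    out <- vector("list", n_snvs)
    for (i in seq_len(n_snvs)) {
      s <- tx$seq[i]
      pos <- sample(seq(50L, nchar(s) - 50L), 1L)
      ref <- substr(s, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      out[[i]] <- tibble(chrom = tx$transcript_id[i], pos = pos,
                         ref = ref, alt = alt)
    }
    dplyr::bind_rows(out) |>
      mutate(variant_id = sprintf("%s:%d:%s>%s", .data$chrom, .data$pos,
                                  .data$ref, .data$alt)) |>
      select("variant_id", "chrom", "pos", "ref", "alt")
  })
  variants$carrier <- samples[(seq_len(n_snvs) - 1L) %% n_samples + 1L]

  # fusions between disjoint transcript pairs not carrying variants when
  # possible (pairs taken from the tail of the transcriptome)
  fusion_tx <- tibble(transcript_id = character(0), seq = character(0))
  junctions <- NULL
  if (n_fusions > 0L) {
    fus <- with_seed(derive_seed(seed, 3), {
      lapply(seq_len(n_fusions), function(i) {
        a <- n_transcripts - 2L * i + 1L
        b <- n_transcripts - 2L * i + 2L
        tA <- tx$transcript_id[a]
        tB <- tx$transcript_id[b]
        posA <- sample(seq(50L, nchar(tx$seq[a]) - 50L), 1L)
        posB <- sample(seq(50L, nchar(tx$seq[b]) - 50L), 1L)
        make_fusion(tx, tA, posA, tB, posB)
      })
    })
    fusion_tx <- dplyr::bind_rows(lapply(fus, `[[`, "transcript"))
    junctions <- dplyr::bind_rows(lapply(fus, `[[`, "junction"))
    junctions$carrier <- samples[(seq_len(n_fusions) - 1L) %% n_samples + 1L]
  }

  total_len <- sum(nchar(tx$seq))
  n_reads <- as.integer(round(coverage * total_len / read_len))

  reads <- vector("list", n_samples)
  names(reads) <- samples
  for (j in seq_len(n_samples)) {
    vj <- variants[variants$carrier == samples[j], ]
    var_spec <- if (nrow(vj)) {
      tibble(transcript_id = vj$chrom, pos = vj$pos, ref = vj$ref,
             alt = vj$alt, vaf = vaf)
    } else NULL
    fj <- if (!is.null(junctions)) junctions[junctions$carrier == samples[j], ] else NULL
    pool <- tx
    if (!is.null(fj) && nrow(fj) > 0L) {
      pool <- dplyr::bind_rows(
        tx, fusion_tx[match(paste0("fusion|", fj$junction_id),
                            fusion_tx$transcript_id), ])
    }
    ab <- rep(1, nrow(pool))
    reads[[j]] <- simulate_sample(pool, ab, variants = var_spec,
                                  read_len = read_len, n_reads = n_reads,
                                  error_rate = error_rate,
                                  seed = derive_seed(seed, 100 + j))
  }

  structure(list(
    transcripts = tx,
    fusion_transcripts = fusion_tx,
    junctions = if (is.null(junctions)) NULL else
      select(junctions, -"carrier"),
    variants = select(variants, -"carrier"),
    truth_vaf = tibble(variant_id = variants$variant_id,
                       sample = variants$carrier, vaf = vaf),
    truth_mutation_pairs = tibble(probe_id = variants$variant_id,
                                  sample = variants$carrier),
    truth_fusion_pairs = if (is.null(junctions)) NULL else
      tibble(probe_id = junctions$junction_id, sample = junctions$carrier),
    reads = reads,
    params = list(n_samples = n_samples, n_transcripts = n_transcripts,
                  n_snvs = n_snvs, vaf = vaf, n_fusions = n_fusions,
                  coverage = coverage, read_len = read_len,
                  error_rate = error_rate, seed = seed)
  ), class = "kprobe_cohort")
}

#' @export
print.kprobe_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<kprobe_cohort> %d samples, %d transcripts, %d SNVs (VAF %.2f), %d fusions, %gx coverage, error rate %g, seed %s\n",
    p$n_samples, p$n_transcripts, p$n_snvs, p$vaf, p$n_fusions,
    p$coverage, p$error_rate, format(p$seed)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `transcripts.fa`, one `reads_<sample>.fastq.gz` per sample,
#' `truth_variants.vcf`, `truth_vaf.tsv` and `truth_junctions.tsv` under
#' `dir`.
#'
#' @param cohort A `kprobe_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "kprobe_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(cohort$transcripts$seq,
                       cohort$transcripts$transcript_id),
              file.path(dir, "transcripts.fa"))
  for (s in names(cohort$reads)) {
    write_fastq(cohort$reads[[s]],
                file.path(dir, sprintf("reads_%s.fastq.gz", s)))
  }
  write_vcf(cohort$variants, file.path(dir, "truth_variants.vcf"))
  utils::write.table(cohort$truth_vaf, file.path(dir, "truth_vaf.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$junctions)) {
    utils::write.table(cohort$junctions,
                       file.path(dir, "truth_junctions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write a minimal VCF
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `variant_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  ids <- variants$variant_id %||% rep(".", nrow(variants))
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
            variants$chrom, as.integer(variants$pos), ids,
            variants$ref, variants$alt)
  )
  writeLines(lines, path)
  invisible(path)
}
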