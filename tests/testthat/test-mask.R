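test_that("reference k-mer counting is canonical and exact", {
  contig <- rand_seq(33, seed = 51)
  rc <- reference_kmer_counts(c(c1 = contig), 31)
  expect_length(rc$kmers, 3L)
  expect_true(all(rc$counts == 1L))

  # a 40-nt segment present twice: its 10 k-mers count 2
  seg <- rand_seq(40, seed = 52)
  dup <- c(c1 = paste0(rand_seq(50, seed = 53), seg,
                       rand_seq(50, seed = 54), seg))
  rcd <- reference_kmer_counts(dup, 31)
  seg_kmers <- canonical_kmer(seq_kmers(seg, 31))
  expect_true(all(kprobe:::ref_count(rcd, seg_kmers) >= 2))

  # contig plus its reverse complement doubles every count
  both <- c(f = contig, r = revcomp(contig))
  rc2 <- reference_kmer_counts(both, 31)
  expect_true(all(rc2$counts == 2L))

  expect_error(reference_kmer_counts(character(0), 31), "empty")
})

test_that("default unicity masking removes repeated-region k-mers", {
  seg <- rand_seq(100, seed = 61)
  genome <- c(c1 = paste0(rand_seq(80, seed = 62), seg,
                          rand_seq(80, seed = 63), seg,
                          rand_seq(80, seed = 64)))
  gc <- reference_kmer_counts(genome, 31)

  # probe inside a unique region survives whole
  uniq_probe <- substr(genome[["c1"]], 10, 70)
  m1 <- unicity_mask(c(p = uniq_probe), gc)
  expect_false(m1$fully_deleted)
  expect_equal(m1$fragments[[1]], uniq_probe)

  # probe fully inside the duplicated segment is fully deleted
  m2 <- unicity_mask(c(p = substr(seg, 20, 80)), gc)
  expect_true(m2$fully_deleted)
  expect_length(m2$fragments[[1]], 0L)
})

test_that("chimera masking keeps exactly the event-specific k-mers", {
  genome <- c(c1 = rand_seq(300, seed = 71))
  gc <- reference_kmer_counts(genome, 31)
  ref <- substr(genome[["c1"]], 150, 150)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  pp <- design_mutation_probes(
    tibble::tibble(chrom = "c1", pos = 150L, ref = ref, alt = alt),
    genome, k = 31)
  m <- unicity_mask(c(p = pp$mutant_seq), gc, mode = "chimera",
                    transcriptome_counts = gc)
  # every k-mer covers the ALT base, so all 31 are retained
  expect_equal(m$n_retained_kmers, 31L)
  expect_equal(m$fragments[[1]], pp$mutant_seq)
  # the wildtype probe, by contrast, is wiped out by chimera masking
  mw <- unicity_mask(c(p = pp$wildtype_seq), gc, mode = "chimera",
                     transcriptome_counts = gc)
  expect_true(mw$fully_deleted)
})

test_that("max-on-transcriptome mode caps transcriptome occurrences", {
  seg <- rand_seq(60, seed = 81)
  genome <- c(g1 = paste0(rand_seq(60, seed = 82), seg))
  # transcriptome holds the segment three times
  tx <- c(t1 = seg, t2 = seg, t3 = seg)
  gc <- reference_kmer_counts(genome, 31)
  tc <- reference_kmer_counts(tx, 31)
  probe <- seg
  keep_all <- unicity_mask(c(p = probe), gc, mode = "max_on_transcriptome",
                           transcriptome_counts = tc,
                           max_on_transcriptome = 3)
  drop_all <- unicity_mask(c(p = probe), gc, mode = "max_on_transcriptome",
                           transcriptome_counts = tc,
                           max_on_transcriptome = 2)
  expect_false(keep_all$fully_deleted)
  expect_true(drop_all$fully_deleted)
  # X = 0 demands absence from the transcriptome
  x0 <- unicity_mask(c(p = probe), gc, mode = "max_on_transcriptome",
                     transcriptome_counts = tc, max_on_transcriptome = 0)
  expect_true(x0$fully_deleted)
  expect_error(unicity_mask(c(p = probe), gc, mode = "chimera"),
               "transcriptome")
})

test_that("low-complexity rules match their worked values", {
  expect_true(homopolymer_rule(paste0("ACGT", strrep("A", 6),
                                      rand_seq(21, seed = 1))))
  expect_true(homopolymer_rule(strrep("G", 31)))
  # maximum run of 5 is not a homopolymer hit
  ok <- paste0(strrep("A", 5), "C", rand_seq(25, seed = 91))
  if (!grepl("A{6}|C{6}|G{6}|T{6}", ok)) {
    expect_false(homopolymer_rule(ok))
  }

  expect_equal(complexity_3mer(strrep("A", 31)), 1 / 29)
  acgt <- substr(strrep("ACGT", 8), 1, 31)
  expect_equal(complexity_3mer(acgt), 4 / 29)
  expect_lt(complexity_3mer(strrep("A", 31)), 0.55)
  expect_lt(complexity_3mer(acgt), 0.55)
})

test_that("low-complexity masking deletes the right k-mers", {
  # a random 61-nt probe of full complexity is unchanged
  set.seed(95)
  repeat {
    probe <- rand_seq(61)
    kms <- seq_kmers(probe, 31)
    if (all(!homopolymer_rule(kms) & complexity_3mer(kms) >= 0.55)) break
  }
  m <- low_complexity_mask(c(p = probe))
  expect_equal(m$fragments[[1]], probe)

  # a central 10-nt poly-A removes every k-mer containing a 6-A run
  mid <- paste0(substr(probe, 1, 25), strrep("A", 10), substr(probe, 36, 61))
  mm <- low_complexity_mask(c(p = mid))
  kms <- seq_kmers(mid, 31)
  bad <- homopolymer_rule(kms) | complexity_3mer(kms) < 0.55
  expect_equal(mm$n_retained_kmers, sum(!bad))
  expect_gte(length(mm$fragments[[1]]), 1L)

  # all-A probe disappears entirely
  expect_true(low_complexity_mask(c(p = strrep("A", 31)))$fully_deleted)
})

test_that("masking soundness: retained pass all rules, deleted fail one", {
  set.seed(97)
  seg <- rand_seq(80)
  genome <- c(c1 = paste0(rand_seq(100), seg, rand_seq(60), seg),
              c2 = rand_seq(150))
  gc <- reference_kmer_counts(genome, 31)
  for (i in 1:12) {
    src <- sample(names(genome), 1)
    start <- sample(nchar(genome[[src]]) - 70, 1)
    probe <- substr(genome[[src]], start, start + 69)
    if (runif(1) < 0.4) {                      # plant low-complexity patch
      at <- sample(10:40, 1)
      substr(probe, at, at + 7) <- strrep("A", 8)
    }
    m <- mask_probes(c(p = probe), gc, mode = "default")
    kms <- seq_kmers(probe, 31)
    violates <- kprobe:::ref_count(gc, kms) > 1 |
      homopolymer_rule(kms) | complexity_3mer(kms) < 0.55
    retained_kms <- unlist(lapply(m$fragments[[1]], seq_kmers, k = 31))
    expect_setequal(retained_kms, kms[!violates])
    expect_equal(m$n_retained_kmers, sum(!violates))
  }
})

test_that("fragment reassembly yields the retained k-mers in order", {
  set.seed(99)
  genome <- c(c1 = rand_seq(200))
  gc <- reference_kmer_counts(genome, 31)
  probe <- paste0(substr(genome[["c1"]], 1, 40), strrep("T", 9),
                  substr(genome[["c1"]], 50, 100))
  m <- low_complexity_mask(c(p = probe))
  frag_kms <- unlist(lapply(m$fragments[[1]], seq_kmers, k = 31))
  kms <- seq_kmers(probe, 31)
  keep <- !(homopolymer_rule(kms) | complexity_3mer(kms) < 0.55)
  expect_identical(frag_kms, kms[keep])
  expect_false(anyDuplicated(frag_kms) > 0)
  expect_true(all(nchar(m$fragments[[1]]) >= 31))
})

test_that("masking is idempotent", {
  set.seed(103)
  genome <- c(c1 = rand_seq(200))
  gc <- reference_kmer_counts(genome, 31)
  probe <- paste0(substr(genome[["c1"]], 1, 40), strrep("A", 10),
                  substr(genome[["c1"]], 60, 120))
  m1 <- mask_probes(c(p = probe), gc, mode = "default")
  frags <- m1$fragments[[1]]
  m2 <- mask_probes(setNames(frags, paste0("f", seq_along(frags))), gc,
                    mode = "default")
  expect_equal(unlist(m2$fragments), frags, ignore_attr = TRUE)
  expect_equal(sum(m2$n_retained_kmers), m1$n_retained_kmers)
})

test_that("chimera masking of a junction probe keeps spanning k-mers only", {
  genome <- c(cA = rand_seq(300, seed = 105), cB = rand_seq(300, seed = 106))
  gc <- reference_kmer_counts(genome, 31)
  # long junction probe (2k-1) so that some k-mers lie wholly in one locus
  j <- tibble::tibble(junction_id = "f", chrom_left = "cA",
                      end_left = 150L, strand_left = "+",
                      chrom_right = "cB", start_right = 150L,
                      strand_right = "+")
  jp <- design_junction_probes(j, genome, total_len = 81)
  m <- unicity_mask(c(f = jp$seq), gc, mode = "chimera",
                    transcriptome_counts = gc)
  kms <- seq_kmers(jp$seq, 31)
  in_ref <- kprobe:::ref_count(gc, kms) > 0
  retained <- unlist(lapply(m$fragments[[1]], seq_kmers, k = 31))
  expect_setequal(retained, kms[!in_ref])
  # k-mers crossing the 40|41 breakpoint (starts 11..40) are retained
  expect_true(all(kms[11:40] %in% retained))
})
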