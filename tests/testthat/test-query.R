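test_that("query triplets reproduce brute-force per-k-mer counts", {
  s <- rand_seq(40, seed = 7)
  reads <- rep(s, 5)
  idx <- build_index(list(s1 = reads), index_config(k = 31))

  q <- query_probes(idx, c(p = s))
  trip <- q$triplets[[1]]
  expect_equal(nrow(trip), 1L)
  expect_equal(trip$begin, 1L)
  expect_equal(trip$end, 10L)
  expect_equal(trip$count, 5)
  expect_equal(expand_triplets(trip), brute_probe_counts(reads, s, 31))

  # a probe sharing no k-mer -> one all-zero run covering every ordinal
  stranger <- strrep("ACGTG", 7)
  q0 <- query_probes(idx, c(x = substr(stranger, 1, 35)))
  expect_equal(q0$triplets[[1]],
               tibble::tibble(begin = 1L, end = 5L, count = 0,
                              starred = FALSE))
  expect_equal(q0$value, 0)
})

test_that("triplet runs are contiguous, non-overlapping and cover the query", {
  set.seed(12)
  reads <- replicate(8, rand_seq(70))
  idx <- build_index(list(s1 = reads), index_config(k = 31))
  for (probe in c(reads[1], paste0(substr(reads[2], 1, 40), rand_seq(20)))) {
    trip <- query_probes(idx, c(p = probe))$triplets[[1]]
    expect_equal(trip$begin[1], 1L)
    expect_equal(trip$end[nrow(trip)], nchar(probe) - 31L + 1L)
    if (nrow(trip) > 1) {
      expect_equal(trip$begin[-1], trip$end[-nrow(trip)] + 1L)
    }
  }
})

test_that("probes shorter than k are a hard error", {
  idx <- build_index(list(s1 = rand_seq(40, seed = 1)), index_config(k = 31))
  expect_error(query_probes(idx, c(p = "ACGTACGT")), "shorter than k")
})

test_that("lossless queries never star, for any presence threshold", {
  s <- rand_seq(80, seed = 13)
  idx <- build_index(list(s1 = c(s, substr(s, 1, 50))), index_config(k = 31))
  for (P in c(1, 40, 100)) {
    q <- query_probes(idx, c(p = s), query_config(presence_threshold = P))
    expect_false(any(q$triplets[[1]]$starred))
  }
})

test_that("aggregation equals direct multiset computation", {
  trip <- tibble::tibble(begin = c(1L, 3L), end = c(2L, 3L),
                         count = c(10, 4), starred = FALSE)
  # expansion is {10, 10, 4}
  expect_equal(aggregate_counts(trip, "mean"), 8)
  expect_equal(aggregate_counts(trip, "sum"), 24)
  expect_equal(aggregate_counts(trip, "median"), 10)
  expect_equal(aggregate_counts(trip, "max"), 10)

  one <- tibble::tibble(begin = 1L, end = 3L, count = 5, starred = FALSE)
  expect_equal(aggregate_counts(one, "mean"), 5)
  expect_equal(aggregate_counts(one, "sum"), 15)
  expect_equal(aggregate_counts(one, "max"), 5)

  zero <- tibble::tibble(begin = c(1L, 4L), end = c(3L, 6L), count = 0,
                         starred = FALSE)
  expect_equal(aggregate_counts(zero, "mean"), 0)
  expect_equal(aggregate_counts(zero, "sum"), 0)
  expect_equal(aggregate_counts(zero, "max"), 0)

  # weighted median takes the lower middle element on even total weight
  even <- tibble::tibble(begin = c(1L, 3L), end = c(2L, 4L),
                         count = c(2, 8), starred = FALSE)
  expect_equal(aggregate_counts(even, "median"), 2)

  # random cases against explicit expansion
  set.seed(5)
  for (i in 1:25) {
    nruns <- sample(1:6, 1)
    lens <- sample(1:5, nruns, replace = TRUE)
    ends <- cumsum(lens)
    trip <- tibble::tibble(begin = ends - lens + 1L, end = ends,
                           count = sample(0:20, nruns, replace = TRUE),
                           starred = FALSE)
    xs <- rep(trip$count, lens)
    expect_equal(aggregate_counts(trip, "mean"), mean(xs))
    expect_equal(aggregate_counts(trip, "sum"), sum(xs))
    expect_equal(aggregate_counts(trip, "max"), max(xs))
    expect_equal(aggregate_counts(trip, "median"),
                 sort(xs)[floor((length(xs) + 1) / 2)])
  }
})

test_that("all-starred results are missing, not zero", {
  trip <- tibble::tibble(begin = 1L, end = 5L, count = 7, starred = TRUE)
  expect_true(is.na(aggregate_counts(trip, "mean", "exclude")))
  expect_equal(aggregate_counts(trip, "mean", "as_zero"), 0)
})

test_that("mean times n_kmers equals sum, and aggregates survive compression", {
  set.seed(17)
  reads <- replicate(10, rand_seq(sample(50:90, 1)))
  idx <- build_index(list(s1 = reads), index_config(k = 31))
  for (probe in reads[1:4]) {
    q <- query_probes(idx, c(p = probe))
    qs <- query_probes(idx, c(p = probe),
                       query_config(aggregation = "sum"))
    expect_equal(q$value * q$n_kmers[1], qs$value)
    # compression invariance: same result from raw per-k-mer counts
    percount <- brute_probe_counts(reads, probe, 31)
    expect_equal(q$value, mean(percount))
    expect_equal(qs$value, sum(percount))
    expect_equal(q$n_positive_kmers, sum(percount > 0))
  }
})

test_that("querying a probe and its reverse complement agree", {
  set.seed(19)
  reads <- replicate(6, rand_seq(60))
  idx <- build_index(list(s1 = reads), index_config(k = 31))
  for (probe in reads[1:3]) {
    f <- query_probes(idx, c(p = probe))
    r <- query_probes(idx, c(p = revcomp(probe)))
    expect_equal(f$value, r$value)
    expect_equal(f$n_positive_kmers, r$n_positive_kmers)
  }
})

test_that("N-containing probe k-mers are treated as absent", {
  s <- rand_seq(60, seed = 23)
  idx <- build_index(list(s1 = s), index_config(k = 31))
  probe <- paste0(substr(s, 1, 35), "N", substr(s, 37, 60))
  trip <- query_probes(idx, c(p = probe))$triplets[[1]]
  # windows touching the N form a zero run between two present runs
  expect_true(any(trip$count == 0))
  expect_true(any(trip$count > 0))
})

test_that("masked-fragment merge is the pooled weighted mean", {
  merged <- merge_masked_query(tibble::tibble(
    probe_id = c("p|frag1", "p|frag2"), sample = "s1",
    value = c(6, 3), n_positive_kmers = c(10L, 5L),
    n_kmers = c(10L, 5L)))
  expect_equal(merged$value, 5)               # (10*6 + 5*3) / 15
  expect_equal(merged$n_kmers, 15L)

  single <- merge_masked_query(tibble::tibble(
    probe_id = "p|frag1", sample = "s1", value = 7,
    n_positive_kmers = 3L, n_kmers = 4L))
  expect_equal(single$value, 7)

  # empty fragments are skipped; all-empty is missing
  skipped <- merge_masked_query(tibble::tibble(
    probe_id = c("p|frag1", "p|frag2"), sample = "s1",
    value = c(6, NA), n_positive_kmers = c(10L, 0L),
    n_kmers = c(10L, 0L)))
  expect_equal(skipped$value, 6)
  allempty <- merge_masked_query(tibble::tibble(
    probe_id = "p|frag1", sample = "s1", value = NA_real_,
    n_positive_kmers = 0L, n_kmers = 0L))
  expect_true(is.na(allempty$value))

  expect_error(merge_masked_query(tibble::tibble(), scheme = "sum"),
               "mean")
})

test_that("raw-read estimation applies the linear k-mer correction", {
  expect_equal(estimate_raw_reads(300, 100, 31), 300 / 70)
  expect_equal(estimate_raw_reads(0, 80, 31), 0)
  expect_error(estimate_raw_reads(10, 20, 31), "read_len")
})

test_that("starred runs appear in quantized indexes under the -P rule", {
  s <- rand_seq(150, seed = 29)
  # sample A covers all of s, sample B only the first half; the quantized
  # (structural) monotig spans both regions, so B's presence over a
  # full-probe run is fractional
  idx <- build_index(list(A = s, B = substr(s, 1, 75)),
                     index_config(k = 31, quantized = TRUE))
  frac_present <- (75 - 31 + 1) / (150 - 31 + 1)   # B's share of s's k-mers
  qb_lo <- query_probes(idx, c(p = s),
                        query_config(presence_threshold = 100 * frac_present - 5))
  qb_hi <- query_probes(idx, c(p = s),
                        query_config(presence_threshold = 100 * frac_present + 5))
  tb_lo <- qb_lo$triplets[[which(qb_lo$sample == "B")]]
  tb_hi <- qb_hi$triplets[[which(qb_hi$sample == "B")]]
  expect_false(any(tb_lo$starred))            # above threshold: reported
  expect_true(any(tb_hi$starred))             # below threshold: starred
  # sample A is fully present and never starred
  expect_false(any(qb_hi$triplets[[which(qb_hi$sample == "A")]]$starred))
  # starred runs do not count toward positive k-mers
  expect_lt(qb_hi$n_positive_kmers[qb_hi$sample == "B"],
            qb_lo$n_positive_kmers[qb_lo$sample == "B"])
})
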