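# Length distributions, normalisation, annotation, sharing, correlation,
# composition and coverage.

test_that("length distribution reports modes with smallest-length tie-break", {
  d <- length_distribution(c(26, 26, 27, 22))
  expect_equal(attr(d, "modal_length"), 26L)
  expect_equal(modal_length(30L), 30L)
  expect_equal(modal_length(c(24, 25, 25, 24)), 24L)  # tie -> smaller
  expect_true(is.na(modal_length(integer(0))))
  expect_equal(sum(length_distribution(c(1, 2, 2))$fraction), 1)
})

test_that("simulated length peaks match the expected piRNA and miRNA modes", {
  run <- default_run()
  a <- run$proc$assigned
  pirna <- a[a$call %in% c("secondary_piRNA", "trail_piRNA"), ]
  expect_equal(modal_length(pirna$length), 26L)
  unmapped <- run$proc$trimmed[!(run$proc$trimmed$read_id %in%
                                   run$proc$aligned$read_id), ]
  expect_equal(modal_length(nchar(unmapped$sequence)), 22L)
})

test_that("normalisation modes divide as documented", {
  expect_equal(normalize_counts(5, "rpm", total_mapped = 2e6), 2.5)
  expect_equal(normalize_counts(8, "per_normalizer", normalizer_count = 4), 2)
  expect_equal(normalize_counts(0, "rpm", total_mapped = 100), 0)
  expect_equal(normalize_counts(0, "per_normalizer", normalizer_count = 3), 0)
  expect_error(normalize_counts(1, "per_normalizer", normalizer_count = 0), "rpm")
  expect_error(normalize_counts(1, "rpm", total_mapped = 0), "total_mapped")
})

test_that("annotation picks the highest-priority class and conserves reads", {
  ann <- data.frame(
    reference_id = "chr", start = c(0L, 50L, 90L), end = c(100L, 80L, 120L),
    strand = c("+", "+", "-"),
    class = c("repeat_LINE", "gene_exon", "cluster"),
    priority = c(2L, 1L, 3L))
  aln <- data.frame(
    read_id = c("in_exon_sense", "in_exon_anti", "repeat_only", "outside",
                "cluster_anti"),
    reference_id = "chr", strand = c("+", "-", "+", "+", "+"),
    start = c(55L, 55L, 10L, 300L, 95L), end = c(75L, 75L, 36L, 326L, 119L),
    n_mismatch = 0L, mismatch_positions = "",
    length = c(20L, 20L, 26L, 26L, 24L))
  res <- annotate_reads(aln, ann)
  r <- res$reads
  expect_equal(r$anno_class[r$read_id == "in_exon_sense"], "gene_exon")
  expect_equal(r$orientation[r$read_id == "in_exon_sense"], "sense")
  expect_equal(r$orientation[r$read_id == "in_exon_anti"], "antisense")
  expect_equal(r$anno_class[r$read_id == "repeat_only"], "repeat_LINE")
  expect_equal(r$anno_class[r$read_id == "outside"], "non_annotated")
  expect_equal(r$anno_class[r$read_id == "cluster_anti"], "cluster")
  expect_equal(r$orientation[r$read_id == "cluster_anti"], "antisense")
  # conservation: every read gets exactly one class
  expect_equal(sum(res$summary$count), nrow(aln))
})

test_that("a read covered less than half by a feature stays non_annotated", {
  ann <- data.frame(reference_id = "chr", start = 0L, end = 10L, strand = "+",
                    class = "gene_exon", priority = 1L)
  aln <- data.frame(read_id = "r", reference_id = "chr", strand = "+",
                    start = 5L, end = 31L, n_mismatch = 0L,
                    mismatch_positions = "", length = 26L)
  res <- annotate_reads(aln, ann)   # overlap 5/26 < 50%
  expect_equal(res$reads$anno_class, "non_annotated")
})

test_that("feature comparison filters at 10 rpm and reports ratios", {
  a <- c(f1 = 3, f2 = 5, f3 = 0, f4 = 20)
  b <- c(f1 = 12, f2 = 5, f3 = 15, f4 = 20)
  res <- compare_features(a, b)        # ratio = b / a
  expect_true(all(c("f1", "f3", "f4") %in% res$table$feature))
  expect_false("f2" %in% res$table$feature)  # 5 vs 5 below 10 rpm
  expect_equal(res$table$ratio[res$table$feature == "f1"], 4)
  expect_true(is.infinite(res$table$ratio[res$table$feature == "f3"]))
  expect_true(res$table$zero_denominator[res$table$feature == "f3"])
  # identical libraries -> median ratio 1
  expect_equal(compare_features(a, a)$median_ratio, 1)
})

test_that("gene-library simulation recovers the configured enrichment", {
  sim <- simulate_gene_libraries(n_genes = 400L, enrichment = 5, depth = 1e5,
                                 seed = 81)
  norm_a <- setNames(sim$features$count_a / sim$normalizer_a, sim$features$feature)
  norm_b <- setNames(sim$features$count_b / sim$normalizer_b, sim$features$feature)
  rpm_a <- setNames(sim$features$count_a * 1e6 / sim$total_a, sim$features$feature)
  rpm_b <- setNames(sim$features$count_b * 1e6 / sim$total_b, sim$features$feature)
  res <- compare_features(norm_a, norm_b, min_rpm = 10,
                          rpm_a = rpm_a, rpm_b = rpm_b)
  expect_lt(abs(res$median_ratio - 5) / 5, 0.10)
})

test_that("sharing classification reproduces the printed criteria", {
  # worked examples
  got <- classify_sharing(data.frame(mili = 0.9, miwi = 0.2, mvh = 0))
  expect_equal(got$sharing_class, "MILI_specific")
  got <- classify_sharing(data.frame(mili = 0.5, miwi = 0.5, mvh = 0))
  expect_equal(got$sharing_class, "MILI_and_MIWI")
  got <- classify_sharing(data.frame(mili = 0.1, miwi = 0.1, mvh = 0.3))
  expect_equal(got$sharing_class, "MVH_specific")
  expect_error(classify_sharing(data.frame(mili = 1, miwi = 1)), "mvh")

  # exhaustive small grid against a literal transcription of the criteria
  vals <- c(0, 0.1, 0.25, 0.4, 0.76, 3)
  grid <- expand.grid(mili = vals, miwi = vals, mvh = vals)
  got <- classify_sharing(grid)$sharing_class
  want <- mapply(bf_sharing, grid$mili, grid$miwi, grid$mvh)
  expect_equal(got, unname(want))
})

test_that("pcc100 behaves on identical, anti-proportional and known vectors", {
  g <- data.frame(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(pcc100(g, "a", "b"), 100)
  g2 <- data.frame(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(pcc100(g2, "a", "b"), -100)
  # hand-computed Pearson: cov = 5, sd products sqrt(2 * 114/9)
  g3 <- data.frame(a = c(1, 2, 3), b = c(2, 4, 7))
  expect_equal(pcc100(g3, "a", "b"), 100 * 5 / sqrt(2 * 114 / 9),
               tolerance = 1e-12)
  # symmetry and positive-rescaling invariance
  expect_equal(pcc100(g3, "a", "b"), pcc100(g3, "b", "a"))
  g4 <- g3; g4$b <- g4$b * 1000
  expect_equal(pcc100(g4, "a", "b"), pcc100(g3, "a", "b"))
  # degenerate inputs
  expect_warning(v <- pcc100(data.frame(a = c(1, 1), b = c(1, 2)), "a", "b"),
                 "variance")
  expect_true(is.na(v))
  expect_warning(v2 <- pcc100(data.frame(a = 0.1, b = 0.1), "a", "b",
                              presence_threshold = 0.25), "threshold")
  expect_true(is.na(v2))
})

test_that("positions below the presence threshold are excluded from pcc100", {
  g <- data.frame(a = c(5, 3, 0.1, 0.1), b = c(5, 3, 0.1, 9))
  # row 3 excluded (both < 0.25), row 4 included via b
  expect_equal(pcc100(g, "a", "b"),
               100 * cor(c(5, 3, 0.1), c(5, 3, 9)))
})

test_that("nucleotide bias reports positions 1 and 10", {
  seqs <- c("TACGTACGTA", "TTTTTTTTTT", "TACGTACGTC")
  nb <- nucleotide_bias(seqs)
  expect_equal(nb$u1, 1)
  expect_equal(nb$a10, 1 / 3)
  expect_equal(nb$n_short, 0L)
  nb2 <- nucleotide_bias(c("TACG", "TACGTACGTA"))
  expect_equal(nb2$n_short, 1L)
  expect_equal(sum(nb2$pos10), 1)
  # uniform random composition ~ 0.25 per base within binomial error
  set.seed(91)
  rnd <- vapply(1:2000, function(i) random_dna_str(12), "")
  nb3 <- nucleotide_bias(rnd)
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_true(all(abs(nb3$pos1 - 0.25) < 4 * se))
  expect_true(all(abs(nb3$pos10 - 0.25) < 4 * se))
})

test_that("signed consensus coverage accumulates sense minus antisense", {
  mk <- function(strand, start, end) data.frame(
    read_id = paste0(strand, start), reference_id = "cons", strand = strand,
    start = start, end = end, n_mismatch = 0L, mismatch_positions = "",
    length = end - start)
  one <- coverage_consensus(mk("+", 4L, 12L), 20L)
  expect_equal(one$coverage, c(rep(0, 4), rep(1, 8), rep(0, 8)))
  anti <- coverage_consensus(mk("-", 4L, 12L), 20L)
  expect_equal(anti$coverage, c(rep(0, 4), rep(-1, 8), rep(0, 8)))

  # mixed set equals brute-force per-read accumulation
  set.seed(92)
  alns <- do.call(rbind, lapply(1:40, function(i) {
    s <- sample(0:14, 1); e <- s + sample(3:6, 1)
    mk(sample(c("+", "-"), 1), s, e)
  }))
  got <- coverage_consensus(alns, 20L)$coverage
  want <- numeric(20)
  for (i in seq_len(nrow(alns))) {
    w <- if (alns$strand[i] == "+") 1 else -1
    for (pos in (alns$start[i] + 1):alns$end[i]) want[pos] <- want[pos] + w
  }
  expect_equal(got, want)

  # 5'-end-only mode places mass at start (+) or end - 1 (-)
  five <- coverage_consensus(rbind(mk("+", 4L, 12L), mk("-", 2L, 9L)), 20L,
                             mode = "five_prime")
  expect_equal(five$coverage[5], 1)   # position 4
  expect_equal(five$coverage[9], -1)  # position 8
  # rpm weighting
  w <- coverage_consensus(mk("+", 0L, 2L), 5L, total_mapped = 2e6)
  expect_equal(w$coverage[1], 0.5)
})
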