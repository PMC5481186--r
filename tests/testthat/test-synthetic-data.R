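# Reporter construction and biogenesis simulation.

test_that("sim_params enforces its invariants", {
  p <- sim_params()
  expect_equal(p$byproduct_length, p$guide_length - p$cleavage_offset)
  expect_equal(p$byproduct_length, 16L)
  expect_error(sim_params(cleavage_offset = 26), "cleavage_offset")
  expect_error(sim_params(n_sites = 0), "n_sites")
  expect_error(sim_params(conversion_efficiency = 1.2), "probability")
  expect_error(sim_params(secondary_length_probs = c("31" = 1)), "24-30")
  expect_error(sim_params(mirna_length_probs = c("21" = 1)), "23 nt")
  expect_error(sim_params(barcode_map = c(a = "ACGT", b = "ACGT")), "duplicated")
})

test_that("build_reporter embeds each guide's reverse complement once", {
  set.seed(11)
  p <- sim_params(n_sites = 35L)
  rep <- build_reporter(p)
  expect_s3_class(rep, "reporter_spec")
  expect_equal(nrow(rep$sites), 35L)
  # invariant: precursor[q - g + 1 .. q] is the guide's reverse complement
  emb <- substring(rep$sequence, rep$sites$q - p$guide_length + 2L,
                   rep$sites$q + 1L)
  expect_equal(emb, revcomp(rep$sites$guide_seq))
  expect_equal(rep$sites$cleavage_coord, rep$sites$q - 9L)
  expect_equal(rep$sites$origin, rep$sites$q + 1L)
  # scan the emitted sequence: each reverse complement occurs exactly once
  for (i in sample(35, 5)) {
    hits <- gregexpr(revcomp(rep$sites$guide_seq[i]), rep$sequence,
                     fixed = TRUE)[[1]]
    expect_equal(length(hits), 1L)
    expect_equal(hits[1] - 1L, rep$sites$site_start[i])
  }
})

test_that("supplied guides are honoured and site spacing holds", {
  set.seed(3)
  p <- sim_params(n_sites = 1L)
  g <- paste0("T", random_dna_str(25))
  rep1 <- build_reporter(p, guides = g)
  expect_equal(rep1$sites$cleavage_coord, rep1$sites$q - 9L)

  p2 <- sim_params(n_sites = 2L, spacer_length = 60L)
  rep2 <- build_reporter(p2)
  # origins of consecutive sites differ by at least spacer + guide length
  expect_gte(diff(rep2$sites$origin), 60L + 26L)

  expect_error(build_reporter(p2, guides = c(g, g)), "duplicate")
  expect_error(build_reporter(p2, guides = g), "expected 2 guides")
})

test_that("biogenesis geometry: secondary starts, by-products, phased trails", {
  set.seed(5)
  p <- small_params()
  rep <- build_reporter(p)
  fr <- simulate_biogenesis(rep, p)
  site <- rep$sites[match(fr$site_id, rep$sites$site_id), ]

  sec <- fr$true_class == "secondary"
  expect_true(any(sec))
  # secondary 5' coordinate - origin = -10 exactly
  expect_true(all(fr$start[sec] - site$origin[sec] == -10L))

  by <- fr$true_class == "byproduct16"
  expect_true(all(fr$end[by] - fr$start[by] == 16L))
  expect_true(all(fr$end[by] == site$cleavage_coord[by]))

  # phased trails: every trail's 5' coordinate equals some fragment's
  # one-past-3' coordinate at the same site, with no overlap
  tr <- fr[fr$true_class == "trail", ]
  prev_ends <- paste(fr$site_id, fr$end)
  expect_true(all(paste(tr$site_id, tr$start) %in% prev_ends))

  # the chain never leaves the downstream cleavage fragment
  conv <- fr$true_class %in% c("secondary", "trail")
  expect_true(all(fr$end[conv] <= site$cleavage_coord[conv] + p$intermediate_length))
})

test_that("conversion efficiency controls the intermediate branch", {
  set.seed(6)
  p1 <- small_params(conversion_efficiency = 1)
  rep <- build_reporter(p1)
  fr1 <- simulate_biogenesis(rep, p1)
  expect_equal(sum(fr1$true_class == "intermediate"), 0L)

  p0 <- small_params(conversion_efficiency = 0)
  fr0 <- simulate_biogenesis(rep, p0)
  expect_equal(sum(fr0$true_class %in% c("secondary", "trail")), 0L)
  expect_gt(sum(fr0$true_class == "intermediate"), 0L)
})

test_that("library reads are insert + barcode + adapter truncated to max length", {
  p <- sim_params(n_sites = 1L, adapter_seq = strrep("ACGTA", 4),  # 20 nt
                  barcode_map = c(lib1 = ""))
  frag <- function(seq) data.frame(read_id = "r1", true_class = "x",
                                   site_id = NA, start = NA, end = NA,
                                   sequence = seq, truncated = FALSE,
                                   untruncated_length = nchar(seq))
  # 16-nt insert + 20-nt adapter -> 36-nt read (insert + full adapter)
  r <- simulate_library(frag(random_dna_str(16)), p)
  expect_equal(nchar(r$sequence), 36L)
  # 80-nt insert -> 51-nt read, no adapter present
  long <- random_dna_str(80)
  r <- simulate_library(frag(long), p)
  expect_equal(nchar(r$sequence), 51L)
  expect_equal(r$sequence, substr(long, 1, 51))
  # 26-nt insert + 30-nt adapter -> 51-nt read ending in a 25-nt adapter prefix
  p30 <- sim_params(n_sites = 1L, adapter_seq = strrep("ACGTAG", 5),
                    barcode_map = c(lib1 = ""))
  ins <- random_dna_str(26)
  r <- simulate_library(frag(ins), p30)
  expect_equal(nchar(r$sequence), 51L)
  expect_equal(r$sequence, paste0(ins, substr(p30$adapter_seq, 1, 25)))
})

test_that("simulated FASTQ is byte-identical under a fixed seed", {
  make <- function() {
    set.seed(99)
    p <- small_params(depth = 500L)
    rep <- build_reporter(p)
    fr <- simulate_biogenesis(rep, p)
    simulate_library(fr, p)
  }
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  lib <- make()
  write_fastq(lib, f1)
  write_fastq(make(), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # FASTQ round-trip preserves ids and sequences
  back <- read_fastq(f1)
  expect_equal(nrow(back), nrow(lib))
  ord <- match(lib$read_id, back$read_id)
  expect_equal(back$sequence[ord], lib$sequence)
})

test_that("class fractions converge to the configured mixture", {
  set.seed(77)
  p <- sim_params(n_sites = 10L, depth = 50000L)
  rep <- build_reporter(p)
  fr <- simulate_biogenesis(rep, p)
  n <- nrow(fr)
  # contaminant fraction is within 3 SE of the configured value
  phat <- mean(fr$true_class == "mirna")
  se <- sqrt(p$mirna_fraction * (1 - p$mirna_fraction) / n)
  expect_lt(abs(phat - p$mirna_fraction), max(3 * se, 2 / n))
  # intermediates vs converted events estimate 1 - conversion_efficiency
  n_int <- sum(fr$true_class == "intermediate")
  n_sec <- sum(fr$true_class == "secondary")
  q <- 1 - p$conversion_efficiency
  se_q <- sqrt(q * (1 - q) / (n_int + n_sec))
  expect_lt(abs(n_int / (n_int + n_sec) - q), 3 * se_q)
})

test_that("contaminants never map to the reporter", {
  set.seed(13)
  p <- small_params()
  rep <- build_reporter(p)
  mir <- simulate_mirnas(200L, p, rep)
  expect_true(all(nchar(mir) >= 21 & nchar(mir) <= 23))
  hits <- vapply(mir[1:50], function(s)
    grepl(s, rep$sequence, fixed = TRUE) ||
      grepl(revcomp(s), rep$sequence, fixed = TRUE), logical(1))
  expect_false(any(hits))
})

test_that("zero depth yields an empty library with a warning", {
  set.seed(1)
  p <- small_params()
  rep <- build_reporter(p)
  expect_warning(fr <- simulate_biogenesis(rep, p, depth = 0L), "zero")
  expect_equal(nrow(fr), 0L)
  expect_warning(lib <- simulate_library(fr, p), "empty")
  expect_equal(nrow(lib), 0L)
})
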