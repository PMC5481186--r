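## Length distributions, normalisations, sense/antisense annotation,
## 5'-end sharing classification, PCC*100, nucleotide composition,
## feature comparison and signed consensus coverage.

#' Read length distribution
#'
#' @param x Integer vector of read lengths, or a data frame with a
#'   `length` column (e.g. from [align_reads()]), or a character vector of
#'   sequences.
#' @return A data frame `length`, `count`, `fraction`, with the modal
#'   length (ties broken towards the smaller length) in attribute
#'   `modal_length`.
#' @export
#' @examples
#' d <- length_distribution(c(26, 26, 27, 22))
#' attr(d, "modal_length")
length_distribution <- function(x) {
  lens <- if (is.data.frame(x)) x$length else if (is.character(x)) nchar(x) else x
  if (length(lens) == 0L) {
    out <- data.frame(length = integer(0), count = integer(0), fraction = numeric(0))
    attr(out, "modal_length") <- NA_integer_
    return(out)
  }
  tab <- table(lens)
  out <- data.frame(length = as.integer(names(tab)),
                    count = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab))
  attr(out, "modal_length") <- out$length[which.max(out$count)]  # smallest wins ties
  out
}

#' Modal length of a read set
#'
#' @inheritParams length_distribution
#' @return The most frequent length (smallest on ties), or `NA` when empty.
#' @export
modal_length <- function(x) attr(length_distribution(x), "modal_length")

#' Normalise read counts
#'
#' Two normalisations are supported: reads per million mapped reads
#' (`rpm`), and division by the count of reads of the normaliser length
#' (`per_normalizer`), the microRNA-anchored normalisation in which counts
#' are divided by the number of 23-nt reads in the library.
#'
#' @param counts Numeric vector of read counts.
#' @param mode `"rpm"` or `"per_normalizer"`.
#' @param total_mapped Total mapped reads (rpm denominator).
#' @param normalizer_count Count of reads of the normaliser length
#'   (default length 23 nt); must be positive for `per_normalizer`.
#' @return Normalised numeric vector.
#' @export
#' @examples
#' normalize_counts(5, "rpm", total_mapped = 2e6)       # 2.5
#' normalize_counts(8, "per_normalizer", normalizer_count = 4)  # 2
normalize_counts <- function(counts, mode = c("rpm", "per_normalizer"),
                             total_mapped = NULL, normalizer_count = NULL) {
  mode <- match.arg(mode)
  if (mode == "rpm") {
    if (is.null(total_mapped) || total_mapped <= 0)
      stopf("rpm normalisation needs a positive total_mapped")
    counts * 1e6 / total_mapped
  } else {
    if (is.null(normalizer_count) || normalizer_count <= 0)
      stopf("normaliser-length read count is zero; use mode = 'rpm' instead")
    counts / normalizer_count
  }
}

#' Annotate aligned reads by overlapping features
#'
#' Each read is assigned the highest-priority feature class covering at
#' least half of the read; reads overlapping nothing are `non_annotated`.
#' Orientation is `sense` when the read strand equals the feature strand
#' and `antisense` otherwise, distinguishing reads originating from
#' annotated transcripts from reads targeting them.
#'
#' @param alignments Data frame from [align_reads()].
#' @param annotations Data frame of intervals with columns `reference_id`,
#'   `start`, `end` (0-based half-open), `strand`, `class`, `priority`
#'   (smaller = higher priority).
#' @param min_overlap_frac Minimum fraction of the read covered by a
#'   feature.
#' @return A list with `reads` (the input plus `anno_class` and
#'   `orientation`) and `summary` (counts per class x orientation;
#'   `non_annotated` reads carry orientation `none`).
#' @export
annotate_reads <- function(alignments, annotations, min_overlap_frac = 0.5) {
  n <- nrow(alignments)
  cls <- rep("non_annotated", n)
  ori <- rep("none", n)
  if (n > 0L && nrow(annotations) > 0L) {
    rg <- GenomicRanges::GRanges(
      alignments$reference_id,
      IRanges::IRanges(alignments$start + 1L, alignments$end)
    )
    ag <- GenomicRanges::GRanges(
      annotations$reference_id,
      IRanges::IRanges(annotations$start + 1L, annotations$end)
    )
    ov <- GenomicRanges::findOverlaps(rg, ag, ignore.strand = TRUE)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      inter <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(rg)[qh], IRanges::ranges(ag)[sh]))
      keep <- inter >= min_overlap_frac * IRanges::width(rg)[qh]
      qh <- qh[keep]; sh <- sh[keep]
      if (length(qh)) {
        ord <- order(qh, annotations$priority[sh])
        first <- !duplicated(qh[ord])
        qi <- qh[ord][first]; si <- sh[ord][first]
        cls[qi] <- annotations$class[si]
        ori[qi] <- ifelse(alignments$strand[qi] == annotations$strand[si],
                          "sense", "antisense")
      }
    }
  }
  reads <- alignments
  reads$anno_class <- cls
  reads$orientation <- ori
  summary <- as.data.frame(table(class = cls, orientation = ori),
                           stringsAsFactors = FALSE)
  summary <- summary[summary$Freq > 0L, , drop = FALSE]
  names(summary)[3] <- "count"
  rownames(summary) <- NULL
  list(reads = reads, summary = summary)
}

#' Compare per-feature abundances between two libraries
#'
#' Keeps features whose rpm reaches `min_rpm` in at least one of the two
#' libraries (features missing from one library count as 0), reports the
#' per-feature ratio `libB / libA` of the supplied (possibly differently
#' normalised) abundances, and summarises with the median ratio across
#' kept features. Ratios with a zero denominator are reported as `Inf`
#' and flagged.
#'
#' @param lib_a,lib_b Named numeric vectors of per-feature abundances
#'   (any normalisation; the ratio is taken on this scale).
#' @param min_rpm Filter threshold applied to `rpm_a`/`rpm_b`.
#' @param rpm_a,rpm_b Named rpm vectors used only for the filter; default
#'   to `lib_a`/`lib_b` (i.e. the inputs are already rpm).
#' @return A list with `table` (feature, value_a, value_b, ratio,
#'   zero_denominator flag) and `median_ratio`.
#' @export
#' @examples
#' compare_features(c(g1 = 3, g2 = 5), c(g1 = 12, g2 = 5))
compare_features <- function(lib_a, lib_b, min_rpm = 10,
                             rpm_a = lib_a, rpm_b = lib_b) {
  feats <- union(names(lib_a), names(lib_b))
  va <- setNames(lib_a[feats], feats); va[is.na(va)] <- 0
  vb <- setNames(lib_b[feats], feats); vb[is.na(vb)] <- 0
  fa <- setNames(rpm_a[feats], feats); fa[is.na(fa)] <- 0
  fb <- setNames(rpm_b[feats], feats); fb[is.na(fb)] <- 0
  keep <- fa >= min_rpm | fb >= min_rpm
  va <- va[keep]; vb <- vb[keep]
  ratio <- ifelse(va == 0, ifelse(vb == 0, NA_real_, Inf), vb / va)
  tab <- data.frame(feature = names(va), value_a = unname(va),
                    value_b = unname(vb), ratio = unname(ratio),
                    zero_denominator = unname(va == 0))
  list(table = tab,
       median_ratio = if (nrow(tab)) median(tab$ratio, na.rm = TRUE) else NA_real_)
}

#' Classify 5'-end groups by their sharing across PIWI/helicase libraries
#'
#' Applies the abundance criteria, in order:
#'
#' 1. `MILI_specific`: at least `theta_rpm` in MILI and at least
#'    `theta_fold` times more abundant in MILI than in MIWI;
#' 2. `MIWI_specific`: the symmetric criterion;
#' 3. `MILI_and_MIWI`: at least `theta_rpm` in both, with less than
#'    `theta_fold`-fold difference between them;
#' 4. `MVH_specific`: at least `theta_rpm` in MVH and not in any of the
#'    above categories;
#' 5. `unclassified` otherwise.
#'
#' @param groups Data frame with columns `mili`, `miwi`, `mvh` holding rpm
#'   for each 5'-end group (additional columns are preserved).
#' @param theta_rpm Presence threshold in rpm.
#' @param theta_fold Fold-difference threshold.
#' @return `groups` with a `sharing_class` column appended.
#' @export
#' @examples
#' classify_sharing(data.frame(mili = 0.9, miwi = 0.2, mvh = 0))
classify_sharing <- function(groups, theta_rpm = 0.25, theta_fold = 3) {
  for (nm in c("mili", "miwi", "mvh")) {
    if (!nm %in% names(groups)) stopf("groups is missing the '%s' library column", nm)
  }
  mili <- groups$mili; miwi <- groups$miwi; mvh <- groups$mvh
  cls <- rep("unclassified", nrow(groups))
  mili_sp <- mili >= theta_rpm & mili >= theta_fold * miwi
  miwi_sp <- !mili_sp & miwi >= theta_rpm & miwi >= theta_fold * mili
  both <- !mili_sp & !miwi_sp & mili >= theta_rpm & miwi >= theta_rpm &
    pmax(mili, miwi) / pmin(mili, miwi) < theta_fold
  mvh_sp <- !mili_sp & !miwi_sp & !both & mvh >= theta_rpm
  cls[mvh_sp] <- "MVH_specific"
  cls[both] <- "MILI_and_MIWI"
  cls[miwi_sp] <- "MIWI_specific"
  cls[mili_sp] <- "MILI_specific"
  groups$sharing_class <- cls
  groups
}

#' Pearson correlation (x100) of shared 5'-end abundances
#'
#' Correlates the per-position abundances of two libraries over the 5'-end
#' positions where at least one library reaches the presence threshold,
#' and reports the Pearson correlation coefficient multiplied by 100.
#'
#' @param groups Data frame of 5'-end groups.
#' @param lib_a,lib_b Column names of the two abundance vectors (rpm).
#' @param presence_threshold Minimum rpm in either library for a position
#'   to be included.
#' @return PCC * 100 (in \[-100, 100\]), or `NA` with a warning when fewer
#'   than two positions qualify or a vector has zero variance.
#' @export
pcc100 <- function(groups, lib_a, lib_b, presence_threshold = 0.25) {
  a <- groups[[lib_a]]; b <- groups[[lib_b]]
  keep <- a >= presence_threshold | b >= presence_threshold
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) {
    warnf("fewer than 2 positions pass the presence threshold")
    return(NA_real_)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warnf("zero variance in an abundance vector; correlation undefined")
    return(NA_real_)
  }
  100 * cor(a, b)
}

#' Nucleotide composition at read positions 1 and 10
#'
#' Reports base fractions at the 5' (1st) and 10th read positions, the two
#' positions diagnostic of piRNA biogenesis (the 1U bias of primary/trail
#' piRNAs and the 10A bias of ping-pong partners).
#'
#' @param sequences Character vector of read sequences.
#' @return A list with `pos1` and `pos10` (named fractions over A/C/G/T),
#'   `u1` (fraction T at position 1, i.e. U in RNA space), `a10` (fraction
#'   A at position 10) and `n_short` (reads shorter than 10 nt excluded
#'   from the position-10 tally).
#' @export
nucleotide_bias <- function(sequences) {
  frac <- function(chars) {
    tab <- table(factor(chars, levels = DNA_BASES))
    setNames(as.numeric(tab) / max(1L, length(chars)), DNA_BASES)
  }
  p1 <- substr(sequences, 1L, 1L)
  long <- nchar(sequences) >= 10L
  p10 <- substr(sequences[long], 10L, 10L)
  pos1 <- frac(p1)
  pos10 <- frac(p10)
  list(pos1 = pos1, pos10 = pos10,
       u1 = unname(pos1["T"]), a10 = unname(pos10["A"]),
       n_short = sum(!long))
}

#' Signed per-position coverage on a consensus sequence
#'
#' Accumulates read coverage along a consensus, with sense alignments
#' contributing positive and antisense alignments negative values. The
#' `five_prime` mode counts only the 5'-end position of each read instead
#' of its full span.
#'
#' @param alignments Data frame from [align_reads()].
#' @param ref_length Consensus length in nt.
#' @param total_mapped Optional rpm denominator for the per-read weight.
#' @param mode `"span"` (full read footprint) or `"five_prime"` (5'-end
#'   position only).
#' @return Data frame with `position` (0-based) and signed `coverage`.
#' @export
coverage_consensus <- function(alignments, ref_length, total_mapped = NULL,
                               mode = c("span", "five_prime")) {
  mode <- match.arg(mode)
  w <- if (is.null(total_mapped)) 1 else 1e6 / total_mapped
  cov <- numeric(ref_length)
  if (nrow(alignments)) {
    sgn <- ifelse(alignments$strand == "+", w, -w)
    if (mode == "span") {
      for (i in seq_len(nrow(alignments))) {
        idx <- (alignments$start[i] + 1L):(alignments$end[i])
        cov[idx] <- cov[idx] + sgn[i]
      }
    } else {
      p5 <- ifelse(alignments$strand == "+", alignments$start,
                   alignments$end - 1L)
      for (i in seq_len(nrow(alignments))) {
        cov[p5[i] + 1L] <- cov[p5[i] + 1L] + sgn[i]
      }
    }
  }
  data.frame(position = seq_len(ref_length) - 1L, coverage = cov)
}
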