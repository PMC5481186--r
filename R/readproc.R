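## Read processing: demultiplexing, 3' adapter clipping, length filtering,
## and Hamming-distance alignment to small references.

# Vectorised adapter-trim lengths: for each sequence, the number of 3'
# bases to remove. Rule: if the full adapter occurs internally, truncate at
# its first occurrence; otherwise remove the longest suffix equal to a
# prefix of the adapter, requiring at least `min_overlap` matching bases.
.trim_lengths <- function(seqs, adapter, min_overlap) {
  n <- nchar(seqs)
  res <- integer(length(seqs))
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  hit <- pos > 0L
  res[hit] <- n[hit] - pos[hit] + 1L
  todo <- which(!hit)
  if (length(todo)) {
    kmax <- min(nchar(adapter) - 1L, max(n[todo]))
    k <- kmax
    while (k >= min_overlap && length(todo)) {
      ok <- n[todo] >= k &
        substr(seqs[todo], n[todo] - k + 1L, n[todo]) == substr(adapter, 1L, k)
      res[todo[ok]] <- k
      todo <- todo[!ok]
      k <- k - 1L
    }
  }
  res
}

#' Clip the 3' sequencing adapter from a read
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter (at least `min_overlap` bases); if the complete adapter occurs
#' internally, the read is truncated at its first occurrence. Reads
#' without any qualifying adapter overlap are returned unchanged.
#'
#' @param sequence Character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum adapter prefix length to trigger trimming.
#' @return Character vector of clipped sequences.
#' @export
#' @examples
#' trim_adapter("ACGTACGTAGATCGGAAGAG", "AGATCGGAAGAGCACACGTCT")
trim_adapter <- function(sequence, adapter, min_overlap = 3L) {
  if (nchar(adapter) < min_overlap)
    stopf("adapter must be at least min_overlap = %d nt", min_overlap)
  tl <- .trim_lengths(sequence, adapter, as.integer(min_overlap))
  substr(sequence, 1L, nchar(sequence) - tl)
}

#' Sort multiplexed reads into libraries by their 3' barcode
#'
#' Libraries are barcoded at the 3' end: each read is insert + barcode +
#' adapter (truncated at the maximum sequencing length). A read is
#' assigned to a library when trimming with that library's barcoded
#' adapter (`barcode` followed by `adapter`) removes the full barcode plus
#' at least `min_overlap` adapter bases. Assigned reads are returned with
#' barcode and adapter clipped; reads matching no barcode (including
#' maximum-length reads whose barcode was never sequenced) go to the
#' `undetermined` bin unchanged.
#'
#' @param reads Data frame with `read_id` and `sequence` columns.
#' @param barcode_map Named character vector: library tag -> barcode.
#' @param adapter 3' adapter sequence shared by all libraries.
#' @param min_overlap Minimum adapter overlap beyond the barcode.
#' @return A list with `reads` (the input plus `library_tag` and clipped
#'   `sequence`) and `counts` (reads per bin, including `undetermined`).
#' @export
demultiplex <- function(reads, barcode_map, adapter, min_overlap = 3L) {
  if (anyDuplicated(barcode_map))
    stopf("barcode collision: barcodes must be unique")
  if (length(unique(nchar(barcode_map))) > 1L)
    stopf("barcodes must have equal length")
  blen <- nchar(barcode_map[[1]])
  need <- blen + min_overlap

  n <- nrow(reads)
  best_tag <- rep("undetermined", n)
  best_len <- integer(n)
  for (tag in names(barcode_map)) {
    tl <- .trim_lengths(reads$sequence, paste0(barcode_map[[tag]], adapter),
                        min_overlap = need)
    better <- tl >= need & tl > best_len
    tie <- tl >= need & tl == best_len & best_tag != "undetermined"
    if (any(tie)) warnf("%d reads match multiple barcodes equally; keeping first", sum(tie))
    best_tag[better] <- tag
    best_len[better] <- tl[better]
  }
  out <- reads
  out$library_tag <- best_tag
  assigned <- best_tag != "undetermined"
  out$sequence[assigned] <- substr(out$sequence[assigned], 1L,
                                   nchar(out$sequence[assigned]) - best_len[assigned])
  counts <- table(factor(out$library_tag,
                         levels = c(names(barcode_map), "undetermined")))
  list(reads = out, counts = as.integer(counts) |>
         setNames(c(names(barcode_map), "undetermined")))
}

#' Keep reads of at least a minimum length
#'
#' @param reads Data frame with a `sequence` column, or a character vector.
#' @param min_len Minimum length in nt (default 15, the usual lower bound
#'   for confident small-RNA mapping).
#' @return The filtered reads; the number discarded is reported via
#'   `message()`.
#' @export
filter_min_length <- function(reads, min_len = 15L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  keep <- nchar(seqs) >= min_len
  if (any(!keep)) message(sum(!keep), " reads shorter than ", min_len, " nt discarded")
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}

# mismatch positions (1-based along the read, 5'->3') of `read` placed at
# `start0` (0-based) on `refchars`; for minus-strand placements the
# plus-strand comparison uses the reverse complement, so read position
# len - j + 1 corresponds to plus offset j.
.mismatch_positions <- function(readchars, refchars, start0, minus = FALSE) {
  len <- length(readchars)
  seg <- refchars[(start0 + 1L):(start0 + len)]
  if (minus) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")[readchars]
    comp[is.na(comp)] <- "N"
    mm_plus <- which(rev(comp) != seg)
    sort(len - mm_plus + 1L)
  } else {
    which(readchars != seg)
  }
}

#' Align a read to a reference by Hamming distance
#'
#' Scans every placement of the read on the requested strand(s) of the
#' reference and returns the best placement with at most `max_mm`
#' mismatches (an `N` in the read counts as a mismatch). Optionally a set
#' of read positions (1-based, 5'->3') may be declared mismatch-free: any
#' placement with a mismatch at a forbidden position is rejected. This
#' realises the seed-protected mapping rule used for targeting piRNAs
#' (3 mismatches allowed, none at read positions 2-10), while `max_mm = 0`
#' realises perfect-match-only mapping.
#'
#' Ties are broken deterministically: fewest mismatches, then smallest
#' start coordinate, then "+" before "-". For a minus-strand placement the
#' read's 5' nucleotide corresponds to reference coordinate `end - 1`.
#'
#' @param read Read sequence (single character string).
#' @param reference Reference sequence (character or `DNAString`).
#' @param max_mm Maximum number of mismatches.
#' @param forbidden_positions Optional integer vector of 1-based read
#'   positions where mismatches are not tolerated.
#' @param strands Strands to scan: `c("+", "-")`, `"+"` or `"-"`.
#' @return A one-row data frame with `strand`, `start`, `end` (0-based
#'   half-open), `n_mismatch`, `mismatch_positions` (comma-separated) and
#'   `length`; or `NULL` if the read has no valid placement.
#' @export
#' @examples
#' align_hamming("CCCCGGGG", "AAAACCCCGGGGTTTT")
align_hamming <- function(read, reference, max_mm = 0L,
                          forbidden_positions = NULL,
                          strands = c("+", "-")) {
  read <- toupper(read)
  subject <- if (is(reference, "DNAString")) reference else Biostrings::DNAString(reference)
  len <- nchar(read)
  if (len > length(subject)) return(NULL)
  refchars <- strsplit(as.character(subject), "", fixed = TRUE)[[1]]
  readchars <- strsplit(read, "", fixed = TRUE)[[1]]

  inside <- function(st) st[st >= 0L & st + len <= length(subject)]
  cand <- list()
  if ("+" %in% strands) {
    st <- inside(Biostrings::start(Biostrings::matchPattern(read, subject,
                                                            max.mismatch = max_mm, fixed = TRUE)) - 1L)
    for (s0 in st) {
      mm <- .mismatch_positions(readchars, refchars, s0, minus = FALSE)
      cand[[length(cand) + 1L]] <- list(strand = "+", start = s0, mm = mm)
    }
  }
  if ("-" %in% strands) {
    rc <- revcomp(read)
    st <- inside(Biostrings::start(Biostrings::matchPattern(rc, subject,
                                                            max.mismatch = max_mm, fixed = TRUE)) - 1L)
    for (s0 in st) {
      mm <- .mismatch_positions(readchars, refchars, s0, minus = TRUE)
      cand[[length(cand) + 1L]] <- list(strand = "-", start = s0, mm = mm)
    }
  }
  if (!length(cand)) return(NULL)

  valid <- Filter(function(p) {
    length(p$mm) <= max_mm &&
      (is.null(forbidden_positions) || !any(p$mm %in% forbidden_positions))
  }, cand)
  if (!length(valid)) return(NULL)

  nmm <- vapply(valid, function(p) length(p$mm), integer(1))
  sts <- vapply(valid, function(p) p$start, integer(1))
  strs <- vapply(valid, function(p) p$strand, character(1))
  ord <- order(nmm, sts, strs != "+")
  b <- valid[[ord[1L]]]
  data.frame(
    strand = b$strand, start = b$start, end = b$start + len,
    n_mismatch = length(b$mm),
    mismatch_positions = paste(b$mm, collapse = ","),
    length = len, stringsAsFactors = FALSE
  )
}

# exact-match placements for many sequences at once via PDict (grouped by
# width); returns the best placement per sequence under the same tie-break
# as align_hamming (smallest start, then "+" before "-")
.align_exact_many <- function(seqs, subject, strands) {
  L <- length(subject)
  rc_subject <- Biostrings::reverseComplement(subject)
  hits <- list()
  for (w in unique(nchar(seqs))) {
    sw <- seqs[nchar(seqs) == w]
    if (w > L) next
    dict <- Biostrings::PDict(Biostrings::DNAStringSet(sw))
    res <- data.frame(sequence = character(0), strand = character(0),
                      start = integer(0))
    if ("+" %in% strands) {
      m <- Biostrings::matchPDict(dict, subject)
      st <- Biostrings::startIndex(m)
      idx <- which(lengths(st) > 0L)
      if (length(idx))
        res <- rbind(res, data.frame(
          sequence = rep(sw[idx], lengths(st)[idx]),
          strand = "+", start = unlist(st[idx]) - 1L))
    }
    if ("-" %in% strands) {
      m <- Biostrings::matchPDict(dict, rc_subject)
      st <- Biostrings::startIndex(m)
      idx <- which(lengths(st) > 0L)
      if (length(idx)) {
        rc_start <- unlist(st[idx])
        res <- rbind(res, data.frame(
          sequence = rep(sw[idx], lengths(st)[idx]),
          strand = "-", start = L - (rc_start - 1L) - w))
      }
    }
    if (nrow(res)) {
      ord <- order(res$sequence, res$start, res$strand != "+")
      res <- res[ord, , drop = FALSE]
      hits[[as.character(w)]] <- res[!duplicated(res$sequence), , drop = FALSE]
    }
  }
  if (!length(hits)) {
    return(data.frame(sequence = character(0), strand = character(0),
                      start = integer(0)))
  }
  do.call(rbind, hits)
}

#' Align a table of reads to one reference
#'
#' Applies [align_hamming()] to the unique sequences in `reads` and joins
#' the placements back, so identical reads are aligned once. Perfect-match
#' alignment (`max_mm = 0`) uses a preprocessed dictionary
#' (`Biostrings::PDict`) over the unique sequences; placements and
#' tie-breaking are identical to [align_hamming()].
#'
#' @param reads Data frame with `read_id` and `sequence`.
#' @param reference Reference sequence (character or `DNAString`).
#' @param reference_id Name recorded in the `reference_id` column.
#' @inheritParams align_hamming
#' @return Data frame of aligned reads (unaligned reads are dropped) with
#'   columns `read_id`, `reference_id`, `strand`, `start`, `end`,
#'   `n_mismatch`, `mismatch_positions`, `length`.
#' @export
align_reads <- function(reads, reference, reference_id = "reference",
                        max_mm = 0L, forbidden_positions = NULL,
                        strands = c("+", "-")) {
  subject <- if (is(reference, "DNAString")) reference else Biostrings::DNAString(reference)
  uniq <- unique(reads$sequence)
  empty <- data.frame(read_id = character(0), reference_id = character(0),
                      strand = character(0), start = integer(0), end = integer(0),
                      n_mismatch = integer(0), mismatch_positions = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  clean <- grepl("^[ACGT]+$", uniq)
  if (max_mm == 0L && any(clean)) {
    tab <- .align_exact_many(uniq[clean], subject, strands)
    slow <- uniq[!clean]
  } else {
    tab <- data.frame(sequence = character(0), strand = character(0),
                      start = integer(0))
    slow <- uniq
  }
  tab$end <- tab$start + nchar(tab$sequence)
  tab$n_mismatch <- rep(0L, nrow(tab))
  tab$mismatch_positions <- rep("", nrow(tab))
  tab$length <- nchar(tab$sequence)
  if (length(slow)) {
    hits <- lapply(slow, align_hamming, reference = subject, max_mm = max_mm,
                   forbidden_positions = forbidden_positions, strands = strands)
    names(hits) <- slow
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits)) {
      tab2 <- do.call(rbind, hits)
      tab2$sequence <- names(hits)
      tab <- rbind(tab[, c("sequence", "strand", "start", "end", "n_mismatch",
                           "mismatch_positions", "length")],
                   tab2[, c("sequence", "strand", "start", "end", "n_mismatch",
                            "mismatch_positions", "length")])
    }
  }
  if (!nrow(tab)) return(empty)
  idx <- match(reads$sequence, tab$sequence)
  keep <- !is.na(idx)
  out <- tab[idx[keep], c("strand", "start", "end", "n_mismatch",
                          "mismatch_positions", "length")]
  out <- cbind(read_id = reads$read_id[keep], reference_id = reference_id,
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an alignment table as TSV
#'
#' @param alignments Data frame from [align_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  write.table(alignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
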