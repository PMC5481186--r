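#' Simulate slicer-triggered biogenesis products on a reporter
#'
#' Samples cleavage events at the reporter's guide binding sites and emits
#' the corresponding RNA fragments with ground-truth labels. For each
#' event at a site with cleavage coordinate `cc`:
#'
#' * With probability `conversion_efficiency` the downstream cleavage
#'   fragment is converted: a secondary piRNA starting at `cc` with length
#'   drawn from the 24-30-nt distribution, followed by `k` phased trail
#'   piRNAs (k ~ geometric, mean `trail_count_mean`), each starting exactly
#'   at the previous fragment's one-past-3' coordinate. The chain is
#'   confined to the downstream cleavage fragment it is processed from:
#'   it never extends past `cc + intermediate_length` (fragments reaching
#'   that boundary, or the precursor end, are shortened and flagged
#'   `truncated`).
#' * Otherwise the downstream fragment stays an unprocessed pre-piRNA
#'   intermediate of `intermediate_length` nt starting at `cc` (it will be
#'   sequenced to at most `max_read_length` nt).
#' * Independently, every event yields the upstream by-product: the
#'   protected fragment spanning `[cc - byproduct_length, cc)`, whose 3'
#'   end marks the cleavage site.
#'
#' A contaminant class of 21-23-nt microRNA-like reads (random sequences
#' that do not map to the reporter on either strand) is added so that
#' `mirna_fraction` of the library is contaminant.
#'
#' Trail 5' ends are biased towards uridine: when a trail will follow, the
#' preceding fragment's 3' end is chosen, with probability `u1_bias`, among
#' the candidate lengths that place the next 5' nucleotide on a T (when any
#' such length exists).
#'
#' @param reporter A [build_reporter()] result.
#' @param params A [sim_params()] object.
#' @param depth Total number of fragments (reads) to aim for; defaults to
#'   `params$depth`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#'
#' @return A data frame of fragments, one row per emitted read, with
#'   columns `read_id`, `true_class` (secondary, trail, byproduct16,
#'   intermediate, mirna), `site_id`, `start`, `end` (0-based half-open on
#'   the reporter, `NA` for contaminants), `sequence` (sense strand),
#'   `truncated` (logical; fragment ran past the precursor end) and
#'   `untruncated_length`.
#' @export
#' @examples
#' p <- sim_params(n_sites = 2, depth = 500)
#' rep <- build_reporter(p)
#' frags <- simulate_biogenesis(rep, p, seed = 1)
#' table(frags$true_class)
simulate_biogenesis <- function(reporter, params, depth = params$depth,
                                seed = NULL) {
  validate_sim_params(params)
  maybe_seed(seed)
  if (depth <= 0L) {
    warnf("depth is zero: no fragments simulated")
    return(data.frame(read_id = character(0), true_class = character(0),
                      site_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      truncated = logical(0), untruncated_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  seq_chr <- reporter$sequence
  L <- nchar(seq_chr)
  sites <- reporter$sites
  lens <- as.integer(names(params$secondary_length_probs))
  lprob <- params$secondary_length_probs / sum(params$secondary_length_probs)

  n_reporter_target <- round((1 - params$mirna_fraction) * depth)

  # choose a fragment length; when a trail follows, bias its 5' nt towards U
  pick_len <- function(start0, next_is_trail) {
    if (next_is_trail && runif(1) < params$u1_bias) {
      nxt <- substring(seq_chr, start0 + lens + 1L, start0 + lens + 1L)
      u_ok <- nxt == "T"
      if (any(u_ok)) {
        return(sample_vec(lens[u_ok], 1L, prob = lprob[u_ok]))
      }
    }
    sample_vec(lens, 1L, prob = lprob)
  }

  # events are drawn until the reporter-derived read count reaches its
  # target (chains are capped, so the yield per event is not closed-form)
  buf <- list()
  n_frags <- 0L
  while (n_frags < n_reporter_target) {
    s <- sites[sample.int(nrow(sites), 1L), ]
    cc <- s$cleavage_coord
    converted_e <- runif(1) < params$conversion_efficiency
    k_e <- rgeom(1, prob = 1 / (1 + params$trail_count_mean))
    e_cls <- character(0); e_st <- integer(0); e_en <- integer(0)
    e_tr <- logical(0); e_ul <- integer(0)

    # upstream by-product: 3' end at the cleavage site
    e_cls <- c(e_cls, "byproduct16")
    e_st <- c(e_st, cc - params$byproduct_length)
    e_en <- c(e_en, cc)
    e_tr <- c(e_tr, FALSE)
    e_ul <- c(e_ul, params$byproduct_length)

    if (converted_e) {
      k <- k_e
      pos <- cc
      # phasing consumes the protected downstream cleavage fragment, so
      # the chain cannot extend past its 3' end
      cap <- min(cc + params$intermediate_length, L)
      min_len <- min(lens)
      for (j in seq_len(k + 1L)) {               # j = 1 secondary, then trails
        len <- pick_len(pos, next_is_trail = j <= k)
        truncated <- pos + len > cap
        end <- min(pos + len, cap)
        e_cls <- c(e_cls, if (j == 1L) "secondary" else "trail")
        e_st <- c(e_st, pos); e_en <- c(e_en, end)
        e_tr <- c(e_tr, truncated); e_ul <- c(e_ul, len)
        pos <- end                                # phased: next 5' = previous one-past-3'
        if (cap - pos < min_len) break
      }
    } else {
      end <- min(cc + params$intermediate_length, L)
      e_cls <- c(e_cls, "intermediate")
      e_st <- c(e_st, cc); e_en <- c(e_en, end)
      e_tr <- c(e_tr, cc + params$intermediate_length > L)
      e_ul <- c(e_ul, params$intermediate_length)
    }
    buf[[length(buf) + 1L]] <- list(cls = e_cls,
                                    sid = rep(s$site_id, length(e_cls)),
                                    st = e_st, en = e_en, tr = e_tr, ul = e_ul)
    n_frags <- n_frags + length(e_cls)
  }

  cls <- unlist(lapply(buf, `[[`, "cls"), use.names = FALSE)
  sid <- unlist(lapply(buf, `[[`, "sid"), use.names = FALSE)
  st <- unlist(lapply(buf, `[[`, "st"), use.names = FALSE)
  en <- unlist(lapply(buf, `[[`, "en"), use.names = FALSE)
  trunc <- unlist(lapply(buf, `[[`, "tr"), use.names = FALSE)
  ulen <- unlist(lapply(buf, `[[`, "ul"), use.names = FALSE)
  if (is.null(cls)) {
    cls <- character(0); sid <- character(0); st <- integer(0)
    en <- integer(0); trunc <- logical(0); ulen <- integer(0)
  }
  seqs <- substring(seq_chr, st + 1L, en)

  # size the contaminant class off the realised reporter count so the
  # configured library mixture is honoured
  n_mirna <- if (params$mirna_fraction >= 1) as.integer(depth) else
    round(length(cls) * params$mirna_fraction / (1 - params$mirna_fraction))
  mirna_seqs <- simulate_mirnas(n_mirna, params, reporter)
  cls <- c(cls, rep("mirna", n_mirna))
  sid <- c(sid, rep(NA_character_, n_mirna))
  st <- c(st, rep(NA_integer_, n_mirna))
  en <- c(en, rep(NA_integer_, n_mirna))
  trunc <- c(trunc, rep(FALSE, n_mirna))
  ulen <- c(ulen, nchar(mirna_seqs))
  seqs <- c(seqs, mirna_seqs)

  n <- length(cls)
  out <- data.frame(
    read_id = sprintf("r%07d", seq_len(n)),
    true_class = cls, site_id = sid,
    start = st, end = en, sequence = seqs,
    truncated = trunc, untruncated_length = as.integer(ulen),
    stringsAsFactors = FALSE
  )
  # shuffle so class blocks are not ordered in the FASTQ
  out <- out[sample.int(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate contaminant microRNA-like sequences
#'
#' Random 21-23-nt sequences verified not to match the reporter exactly on
#' either strand (so they stay unmapped in downstream alignment, as real
#' miRNA contaminants would on an artificial reporter).
#'
#' @param n Number of sequences.
#' @param params A [sim_params()] object.
#' @param reporter Optional `reporter_spec` to exclude matches against.
#' @return Character vector of `n` DNA sequences.
#' @export
simulate_mirnas <- function(n, params, reporter = NULL) {
  if (n == 0L) return(character(0))
  lens <- as.integer(names(params$mirna_length_probs))
  lp <- params$mirna_length_probs / sum(params$mirna_length_probs)
  draw <- function(k) {
    ln <- sample_vec(lens, k, replace = TRUE, prob = lp)
    vapply(ln, random_dna, character(1))
  }
  out <- draw(n)
  if (!is.null(reporter)) {
    subject <- Biostrings::DNAString(reporter$sequence)
    for (pass in 1:5) {
      bad <- vapply(out, function(s) {
        Biostrings::countPattern(s, subject) > 0L ||
          Biostrings::countPattern(revcomp(s), subject) > 0L
      }, logical(1))
      if (!any(bad)) break
      out[bad] <- draw(sum(bad))
    }
  }
  out
}

#' Turn fragments into sequencing-ready FASTQ records
#'
#' Each record is the fragment's sense-strand sequence followed by the
#' library barcode and then the 3' adapter, truncated to
#' `max_read_length`. Inserts at least as long as the maximum sequencing
#' length therefore yield reads with no adapter (the pre-piRNA
#' intermediates appear as reads of exactly `max_read_length` nt).
#' Quality is a constant "I" (Phred+33, Q40); no sequencing-error model is
#' applied because downstream analysis keeps only perfect matches.
#'
#' @param fragments Data frame from [simulate_biogenesis()] (columns
#'   `read_id`, `sequence`).
#' @param params A [sim_params()] object.
#' @param library_tag Library whose barcode to use; must name an entry of
#'   `params$barcode_map`.
#' @return A data frame with columns `read_id`, `sequence`, `quality`,
#'   `library_tag`.
#' @export
simulate_library <- function(fragments, params, library_tag = names(params$barcode_map)[1]) {
  if (!library_tag %in% names(params$barcode_map))
    stopf("unknown library tag '%s'", library_tag)
  if (nrow(fragments) == 0L) {
    warnf("no fragments: writing an empty library")
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), library_tag = character(0),
                      stringsAsFactors = FALSE))
  }
  bc <- params$barcode_map[[library_tag]]
  full <- paste0(fragments$sequence, bc, params$adapter_seq)
  reads <- substr(full, 1L, params$max_read_length)
  data.frame(
    read_id = fragments$read_id,
    sequence = reads,
    quality = strrep("I", nchar(reads)),
    library_tag = library_tag,
    stringsAsFactors = FALSE
  )
}

#' Write FASTQ records
#'
#' Standard 4-line FASTQ, Phred+33.
#'
#' @param reads Data frame with `read_id`, `sequence`, `quality` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Read FASTQ records
#'
#' @param path FASTQ file path.
#' @return Data frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write a ground-truth table
#'
#' @param fragments Fragment data frame from [simulate_biogenesis()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(fragments, path) {
  truth <- fragments[, c("read_id", "true_class", "site_id", "untruncated_length")]
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
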