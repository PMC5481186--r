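#' Build an artificial piRNA precursor (reporter) with guide binding sites
#'
#' Constructs a precursor sequence in which the reverse complement of each
#' guide piRNA is embedded exactly once, so that every guide has one
#' perfectly complementary binding site. Sites are separated by random
#' spacers of at least `max_read_length` nucleotides, which keeps cleavage
#' fragments from neighbouring sites separable.
#'
#' Coordinates are 0-based, half-open. For each site, `q` is the precursor
#' coordinate paired with the guide's 5' (first) nucleotide; because the
#' guide anneals antisense, the binding site occupies
#' `[q - guide_length + 1, q + 1)` and `q` is the 3'-most (rightmost)
#' position of the embedded reverse complement. Slicing between the target
#' nucleotides paired to guide positions `cleavage_offset` and
#' `cleavage_offset + 1` puts the first nucleotide of the downstream
#' fragment at `cleavage_coord = q - cleavage_offset + 1` (`q - 9` under
#' defaults). The distance origin is `origin = q + 1`: distance 0 is the
#' position immediately downstream of the guide 5' end, and a read whose 5'
#' end is created by slicing sits at distance -10 (a 10-nt overlap with the
#' guide).
#'
#' @param params A [sim_params()] object.
#' @param guides Optional character vector of guide piRNA sequences (DNA
#'   alphabet, length `guide_length`, unique). If omitted, guides are drawn
#'   uniformly over A/C/G/T with a 5'-U (T) enforced.
#' @param name Reporter name used as the reference identifier.
#' @param max_tries Number of attempts to re-draw spacers if a guide's
#'   reverse complement happens to occur elsewhere in the precursor.
#'
#' @return An object of class `reporter_spec`: a list with `name`,
#'   `sequence` (character), and `sites`, a data frame with one row per
#'   binding site and columns `site_id`, `guide_seq`, `site_start`, `q`,
#'   `cleavage_coord`, `origin`.
#' @export
#' @examples
#' p <- sim_params(n_sites = 3)
#' rep <- build_reporter(p, name = "demo")
#' rep$sites
build_reporter <- function(params, guides = NULL, name = "reporter",
                           max_tries = 20L) {
  validate_sim_params(params)
  g <- params$guide_length
  n <- params$n_sites

  if (is.null(guides)) {
    guides <- replicate(n, paste0("T", random_dna(g - 1L)))
  }
  guides <- toupper(guides)
  if (length(guides) != n)
    stopf("expected %d guides, got %d", n, length(guides))
  if (any(nchar(guides) != g))
    stopf("all guides must have length guide_length = %d", g)
  if (anyDuplicated(guides))
    stopf("duplicate guide sequence supplied")
  if (!all(grepl("^[ACGT]+$", guides)))
    stopf("guides must be DNA strings over A/C/G/T")

  site_seqs <- revcomp(guides)
  flank_left <- max(params$spacer_length, params$byproduct_length + 5L)
  flank_right <- 2L * max(params$intermediate_length, params$max_read_length)

  for (try in seq_len(max_tries)) {
    spacers <- if (n > 1L) replicate(n - 1L, random_dna(params$spacer_length)) else character(0)
    pieces <- character(2L * n + 1L)
    pieces[1L] <- random_dna(flank_left)
    pieces[seq(2L, 2L * n, by = 2L)] <- site_seqs
    if (n > 1L) pieces[seq(3L, 2L * n - 1L, by = 2L)] <- spacers
    pieces[2L * n + 1L] <- random_dna(flank_right)
    sequence <- paste(pieces, collapse = "")

    subject <- Biostrings::DNAString(sequence)
    ok <- all(vapply(seq_len(n), function(i) {
      Biostrings::countPattern(site_seqs[i], subject) == 1L &&
        Biostrings::countPattern(guides[i], subject) == 0L
    }, logical(1)))
    if (ok) {
      site_start <- flank_left +
        cumsum(c(0L, rep(g + params$spacer_length, n - 1L)))  # 0-based
      q <- site_start + g - 1L
      sites <- data.frame(
        site_id = sprintf("site_%02d", seq_len(n)),
        guide_seq = guides,
        site_start = as.integer(site_start),
        q = as.integer(q),
        cleavage_coord = as.integer(q - params$cleavage_offset + 1L),
        origin = as.integer(q + 1L),
        stringsAsFactors = FALSE
      )
      out <- list(name = name, sequence = sequence, sites = sites,
                  params = params)
      class(out) <- "reporter_spec"
      validate_reporter(out)
      return(out)
    }
  }
  stopf("could not embed guides uniquely after %d tries", max_tries)
}

#' Validate a reporter specification
#'
#' Checks the geometric invariants of a `reporter_spec`: all sites inside
#' the precursor, non-overlapping, and each binding site equal to the
#' reverse complement of its guide.
#'
#' @param reporter A `reporter_spec` object.
#' @return `reporter`, invisibly.
#' @export
validate_reporter <- function(reporter) {
  stopifnot(inherits(reporter, "reporter_spec"))
  s <- reporter$sites
  g <- reporter$params$guide_length
  L <- nchar(reporter$sequence)
  if (any(s$site_start < 0L) || any(s$q + 1L > L))
    stopf("binding site outside precursor bounds")
  if (nrow(s) > 1L) {
    o <- order(s$site_start)
    if (any(s$site_start[o][-1L] < s$q[o][-nrow(s)] + 1L))
      stopf("binding sites overlap")
  }
  embedded <- substring(reporter$sequence, s$site_start + 1L, s$q + 1L)
  if (!all(revcomp(s$guide_seq) == embedded))
    stopf("binding site sequence does not match guide reverse complement")
  if (!all(s$cleavage_coord == s$q - reporter$params$cleavage_offset + 1L))
    stopf("cleavage_coord inconsistent with cleavage_offset")
  if (!all(s$origin == s$q + 1L))
    stopf("origin must be q + 1")
  invisible(reporter)
}

#' @export
print.reporter_spec <- function(x, ...) {
  cat(sprintf("Reporter '%s': %d nt, %d guide binding sites\n",
              x$name, nchar(x$sequence), nrow(x$sites)))
  print(head(x$sites))
  invisible(x)
}

#' Write the reporter FASTA and sites BED
#'
#' The BED file is 0-based half-open with strand "+" and the site id in the
#' name column; intervals span each guide binding site.
#'
#' @param reporter A `reporter_spec`.
#' @param fasta_path,bed_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the files written.
#' @export
write_reporter <- function(reporter, fasta_path = NULL, bed_path = NULL) {
  written <- character(0)
  if (!is.null(fasta_path)) {
    dna <- Biostrings::DNAStringSet(setNames(reporter$sequence, reporter$name))
    Biostrings::writeXStringSet(dna, filepath = fasta_path)
    written <- c(written, fasta_path)
  }
  if (!is.null(bed_path)) {
    s <- reporter$sites
    bed <- data.frame(chrom = reporter$name, start = s$site_start,
                      end = s$q + 1L, name = s$site_id, score = 0L,
                      strand = "+")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    written <- c(written, bed_path)
  }
  invisible(written)
}
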