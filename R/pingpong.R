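## Ping-pong and end-distance scoring between two position-weighted read
## sets. score(delta) = sum_i M(i) * N(i + delta), where M holds plus-strand
## end positions and N minus-strand end positions (in plus coordinates).
## delta = 0 means shared 5'-end nucleotide; delta = 9 means the 10-nt 5'
## overlap diagnostic of slicer-fed biogenesis.

#' Build a position-weight vector from aligned reads
#'
#' Collapses alignments of one strand into a weight per end coordinate.
#' Conventions (plus coordinates, 0-based half-open reads): the 5'
#' coordinate is `start` on "+" and `end - 1` on "-" (the coordinate of the
#' 5' nucleotide); the 3' coordinate is one-past-last along the read, i.e.
#' `end` on "+" and `start - 1` on "-".
#'
#' @param alignments Data frame from [align_reads()].
#' @param strand Which strand's reads to use: `"+"` or `"-"`.
#' @param end_type `"five_prime"` or `"three_prime"`.
#' @param total_mapped If non-`NULL`, weights are scaled to rpm with this
#'   denominator (the usual scale for the ping-pong score).
#' @param length_range Optional inclusive length filter `c(min, max)`.
#' @return A `position_weights` object: a list with `reference_id`,
#'   `strand`, `end_type` and `weights` (named numeric; names are
#'   positions).
#' @export
position_weights <- function(alignments, strand = c("+", "-"),
                             end_type = c("five_prime", "three_prime"),
                             total_mapped = NULL, length_range = NULL) {
  strand <- match.arg(strand)
  end_type <- match.arg(end_type)
  x <- alignments[alignments$strand == strand, , drop = FALSE]
  if (!is.null(length_range))
    x <- x[x$length >= length_range[1] & x$length <= length_range[2], , drop = FALSE]
  pos <- if (end_type == "five_prime") {
    if (strand == "+") x$start else x$end - 1L
  } else {
    if (strand == "+") x$end else x$start - 1L
  }
  w <- table(pos)
  weights <- setNames(as.numeric(w), names(w))
  if (!is.null(total_mapped)) weights <- weights * 1e6 / total_mapped
  structure(list(reference_id = if (nrow(x)) x$reference_id[1] else NA_character_,
                 strand = strand, end_type = end_type, weights = weights),
            class = "position_weights")
}

#' Position weights of the targeting guides implied by a reporter
#'
#' The guide piRNAs that target the reporter anneal antisense; their 5'
#' nucleotides pair with precursor coordinate `q`, so in plus coordinates
#' the targeting 5'-end weight vector has mass at each site's `q`.
#'
#' @param reporter A `reporter_spec`.
#' @param weights Per-site weights (recycled); default 1 per site.
#' @return A `position_weights` object on the minus strand.
#' @export
guide_position_weights <- function(reporter, weights = 1) {
  q <- reporter$sites$q
  w <- rep_len(weights, length(q))
  agg <- tapply(w, q, sum)
  structure(list(reference_id = reporter$name, strand = "-",
                 end_type = "five_prime",
                 weights = setNames(as.numeric(agg), names(agg))),
            class = "position_weights")
}

.score_sum <- function(m, n, deltas) {
  mi <- as.integer(names(m))
  np <- as.integer(names(n))
  vapply(deltas, function(d) {
    idx <- match(mi + d, np)
    ok <- !is.na(idx)
    sum(m[ok] * n[idx[ok]])
  }, numeric(1))
}

#' Ping-pong distance score between two position-weight sets
#'
#' Computes `score(delta) = sum_i M(i) * N(i + delta)` over a window of
#' 5'-end distances, plus the fraction normalisation
#' `score / sum(score)`. With M the plus-strand 5' ends of produced
#' piRNAs and N the minus-strand 5' ends of targeting piRNAs, a peak at
#' `delta = 9` (a 10-nt 5' overlap) is the ping-pong signature of
#' slicer-generated 5' ends.
#'
#' @param M,N `position_weights` objects (or bare named numeric vectors of
#'   position -> weight).
#' @param delta_range Inclusive integer window `c(min, max)`.
#' @return A `pingpong_profile` data frame with columns `delta`, `score`,
#'   `fraction`. When every score is zero the fractions are `NA` and a
#'   warning is raised.
#' @export
#' @examples
#' m <- structure(c(2), names = "10")
#' n <- structure(c(3), names = "19")
#' pingpong_score(m, n)  # score(9) = 6
pingpong_score <- function(M, N, delta_range = c(-20L, 30L)) {
  m <- if (inherits(M, "position_weights")) M$weights else M
  n <- if (inherits(N, "position_weights")) N$weights else N
  deltas <- seq(delta_range[1], delta_range[2])
  if (length(m) == 0L || length(n) == 0L) {
    warnf("empty position-weight set: ping-pong score is all zero")
    score <- numeric(length(deltas))
  } else {
    score <- .score_sum(m, n, deltas)
  }
  tot <- sum(score)
  frac <- if (tot > 0) score / tot else {
    if (length(m) && length(n)) warnf("all ping-pong scores are zero; fraction undefined")
    rep(NA_real_, length(score))
  }
  out <- data.frame(delta = deltas, score = score, fraction = frac)
  class(out) <- c("pingpong_profile", "data.frame")
  out
}

#' End-distance score between arbitrary end types
#'
#' The same summation as [pingpong_score()], but with the end types chosen
#' by the caller through [position_weights()]: comparing plus-strand 3'
#' ends with minus-strand 5' ends detects by-products (fragments whose 3'
#' end was created by the same cleavage that matches the targeting guide),
#' and comparing 5'-to-5' ends detects secondary piRNAs and intermediates.
#'
#' @param A,B `position_weights` objects; `A` plays the role of M
#'   (plus-strand ends), `B` of N (minus-strand ends).
#' @inheritParams pingpong_score
#' @return A `pingpong_profile` data frame.
#' @export
end_distance_score <- function(A, B, delta_range = c(-20L, 30L)) {
  pingpong_score(A, B, delta_range = delta_range)
}

#' Delta at which a ping-pong profile peaks
#'
#' @param profile A `pingpong_profile`.
#' @return The delta with maximal score, or `NA` if all scores are zero.
#' @export
pingpong_argmax <- function(profile) {
  if (all(profile$score == 0)) return(NA_integer_)
  profile$delta[which.max(profile$score)]
}

#' Ping-pong signature over the most-targeted transcripts
#'
#' Maps targeting reads antisense to each transcript with bounded
#' mismatches and a protected seed (no mismatches at read positions 2-10)
#' and produced reads sense with no mismatches; ranks transcripts by their
#' targeting-read count, keeps the `top_n` most targeted, and sums
#' `score(delta)` across the kept transcripts.
#'
#' @param transcripts Named character vector (or `DNAStringSet`) of
#'   transcript sequences.
#' @param targeting_reads,produced_reads Data frames with `read_id` and
#'   `sequence`.
#' @param top_n Number of most-targeted transcripts to keep (all are used,
#'   with a message, when fewer exist).
#' @param delta_range Inclusive delta window.
#' @param max_mm_targeting Mismatch allowance for targeting reads.
#' @param forbidden_positions Protected read positions for targeting reads.
#' @param total_targeting,total_produced Optional rpm denominators.
#' @return A list with `profile` (a `pingpong_profile` summed over kept
#'   transcripts) and `ranking` (data frame of transcript targeting
#'   counts, kept flag).
#' @export
genic_pingpong <- function(transcripts, targeting_reads, produced_reads,
                           top_n = 500L, delta_range = c(-20L, 30L),
                           max_mm_targeting = 3L,
                           forbidden_positions = 2:10,
                           total_targeting = NULL, total_produced = NULL) {
  if (is(transcripts, "DNAStringSet")) {
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  }
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("tx_%03d", seq_along(transcripts))

  tgt_aln <- lapply(names(transcripts), function(tx) {
    a <- align_reads(targeting_reads, transcripts[[tx]], reference_id = tx,
                     max_mm = max_mm_targeting,
                     forbidden_positions = forbidden_positions,
                     strands = "-")
    a
  })
  names(tgt_aln) <- names(transcripts)
  tgt_counts <- vapply(tgt_aln, nrow, integer(1))
  if (sum(tgt_counts) == 0L) {
    warnf("no targeting reads map to any transcript: empty profile")
    deltas <- seq(delta_range[1], delta_range[2])
    prof <- data.frame(delta = deltas, score = 0, fraction = NA_real_)
    class(prof) <- c("pingpong_profile", "data.frame")
    return(list(profile = prof,
                ranking = data.frame(transcript = names(transcripts),
                                     targeting_reads = tgt_counts, kept = FALSE)))
  }
  if (top_n > length(transcripts)) {
    message("fewer than top_n transcripts available; using all ",
            length(transcripts))
    top_n <- length(transcripts)
  }
  keep <- names(sort(tgt_counts, decreasing = TRUE))[seq_len(top_n)]
  keep <- keep[tgt_counts[keep] > 0L]

  deltas <- seq(delta_range[1], delta_range[2])
  score <- numeric(length(deltas))
  for (tx in keep) {
    prod_aln <- align_reads(produced_reads, transcripts[[tx]],
                            reference_id = tx, max_mm = 0L, strands = "+")
    if (nrow(prod_aln) == 0L) next
    M <- position_weights(prod_aln, "+", "five_prime",
                          total_mapped = total_produced)
    N <- position_weights(tgt_aln[[tx]], "-", "five_prime",
                          total_mapped = total_targeting)
    score <- score + .score_sum(M$weights, N$weights, deltas)
  }
  tot <- sum(score)
  prof <- data.frame(delta = deltas, score = score,
                     fraction = if (tot > 0) score / tot else NA_real_)
  class(prof) <- c("pingpong_profile", "data.frame")
  list(profile = prof,
       ranking = data.frame(transcript = names(transcripts),
                            targeting_reads = tgt_counts,
                            kept = names(transcripts) %in% keep))
}
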