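## End-distance profiles around guide target sites, product classification,
## and relative 16-mer/51-mer ratios.
##
## Distance convention (0-based, half-open): for a site with origin
## `origin = q + 1` (one past the precursor position paired to the guide's
## 5' nucleotide), a read [start, end) has
##   d5 = start - origin,   d3 = end - origin.
## Distance 0 is the position immediately downstream of the guide 5' end;
## d5 = -10 means the read 5' end was created by slicing (10-nt overlap
## with the guide), and the by-product's one-past-3' coordinate registers
## at d3 = -10 under the same convention.

#' Signed 5'/3'-end distances of a read from a target site
#'
#' @param start,end Read coordinates (0-based half-open) on the reporter.
#' @param origin The site's distance origin (`q + 1`).
#' @return A list with integer vectors `d5` and `d3`.
#' @export
#' @examples
#' end_distances(91, 117, 101)  # secondary piRNA: d5 = -10
end_distances <- function(start, end, origin) {
  list(d5 = as.integer(start - origin), d3 = as.integer(end - origin))
}

#' Assign aligned sense reads to their nearest target site
#'
#' Each read is assigned to the site minimising `|d5|`; a read exactly
#' equidistant between two sites goes to the upstream site (a logged,
#' deterministic tie-break).
#'
#' @param alignments Data frame from [align_reads()] (sense reads are
#'   selected with `strand == "+"`).
#' @param sites Site table from a `reporter_spec` (`reporter$sites`).
#' @return The sense-strand alignments with `site_id`, `d5`, `d3` columns
#'   appended.
#' @export
assign_sites <- function(alignments, sites) {
  aln <- alignments[alignments$strand == "+", , drop = FALSE]
  if (nrow(aln) == 0L) {
    aln$site_id <- character(0); aln$d5 <- integer(0); aln$d3 <- integer(0)
    return(aln)
  }
  origins <- sites$origin[order(sites$origin)]
  ids <- sites$site_id[order(sites$origin)]
  d <- abs(outer(aln$start, origins, "-"))
  idx <- max.col(-d, ties.method = "first")  # tie -> first = upstream site
  n_tied <- sum(rowSums(d == d[cbind(seq_len(nrow(d)), idx)]) > 1L)
  if (n_tied > 0L)
    message(n_tied, " reads equidistant between sites assigned upstream")
  aln$site_id <- ids[idx]
  org <- origins[idx]
  aln$d5 <- as.integer(aln$start - org)
  aln$d3 <- as.integer(aln$end - org)
  aln
}

#' End-distance profile aggregated over target sites
#'
#' Histograms of read 5'- and 3'-end distances from the nearest target
#' site, aggregated across all sites, optionally restricted to a read
#' length range (24-30 nt for piRNAs, exactly 16 nt for by-products,
#' exactly the maximum sequencing length for intermediates) and optionally
#' normalised to reads per million.
#'
#' @param assigned Alignments with `d5`/`d3` columns, from
#'   [assign_sites()].
#' @param length_range Length filter `c(min, max)` in nt, or `NULL` for no
#'   filter.
#' @param distance_range Distance window `c(min, max)` to tabulate.
#' @param total_mapped If non-`NULL`, counts are scaled to rpm with this
#'   denominator.
#' @return An `end_distance_profile` data frame with columns `distance`,
#'   `count_5p`, `count_3p`; the length filter and contributing sites are
#'   stored as attributes.
#' @export
profile_distances <- function(assigned, length_range = c(24L, 30L),
                              distance_range = c(-40L, 80L),
                              total_mapped = NULL) {
  x <- assigned
  if (!is.null(length_range))
    x <- x[x$length >= length_range[1] & x$length <= length_range[2], , drop = FALSE]
  dist <- seq(distance_range[1], distance_range[2])
  c5 <- tabulate(match(x$d5, dist), nbins = length(dist))
  c3 <- tabulate(match(x$d3, dist), nbins = length(dist))
  if (!is.null(total_mapped)) {
    c5 <- c5 * 1e6 / total_mapped
    c3 <- c3 * 1e6 / total_mapped
  }
  out <- data.frame(distance = dist, count_5p = c5, count_3p = c3)
  attr(out, "length_filter") <- length_range
  attr(out, "aggregated_over") <- unique(x$site_id)
  class(out) <- c("end_distance_profile", "data.frame")
  out
}

#' Distance at which a profile column peaks
#'
#' @param profile An `end_distance_profile`.
#' @param end Which end to inspect: `"5p"` or `"3p"`.
#' @return The distance with the maximal count (smallest on ties), or `NA`
#'   if the profile is empty.
#' @export
profile_argmax <- function(profile, end = c("5p", "3p")) {
  end <- match.arg(end)
  cnt <- if (end == "5p") profile$count_5p else profile$count_3p
  if (all(cnt == 0)) return(NA_integer_)
  profile$distance[which.max(cnt)]
}

#' Classify aligned sense reads into slicer-product classes
#'
#' Applies the cleavage-fragment geometry, in order of precedence:
#'
#' 1. `secondary_piRNA`: 5' end at the cleavage site (`d5 == -10` under
#'    defaults) and piRNA-sized (24-30 nt);
#' 2. `intermediate`: 5' end at the cleavage site and read of exactly the
#'    maximum sequencing length (the truncated pre-piRNA intermediate);
#' 3. `byproduct_16mer`: 3' end at the cleavage site (`d3 == -10`) and
#'    length equal to `guide_length - cleavage_offset`;
#' 4. `trail_piRNA`: piRNA-sized with 5' end downstream of the cleavage
#'    site within a configurable window;
#' 5. `other` otherwise.
#'
#' @param assigned Alignments with `d5`/`d3`, from [assign_sites()].
#' @param params A [sim_params()] object supplying `cleavage_offset`,
#'   `byproduct_length` and `max_read_length`.
#' @param pirna_range Inclusive piRNA length band in nt.
#' @param trail_window Half-open window `(lower, upper]` of `d5` values
#'   (relative to the site origin) accepted for trail piRNAs; the default
#'   `(-10, 60]` accepts anything downstream of the cleavage site within
#'   one spacer length.
#' @return The input with a `call` column appended.
#' @export
classify_products <- function(assigned, params, pirna_range = c(24L, 30L),
                              trail_window = c(-10L, 60L)) {
  cleave_d5 <- -(params$cleavage_offset)
  len <- assigned$length
  d5 <- assigned$d5
  d3 <- assigned$d3
  is_pirna_size <- len >= pirna_range[1] & len <= pirna_range[2]
  call <- rep("other", nrow(assigned))
  call[is_pirna_size & d5 > trail_window[1] & d5 <= trail_window[2]] <- "trail_piRNA"
  call[d3 == cleave_d5 & len == params$byproduct_length] <- "byproduct_16mer"
  call[d5 == cleave_d5 & len == params$max_read_length] <- "intermediate"
  call[d5 == cleave_d5 & is_pirna_size] <- "secondary_piRNA"
  assigned$call <- call
  assigned
}

#' Relative abundance of slicer products versus piRNAs
#'
#' The by-product and intermediate classes are expressed relative to the
#' piRNA level (secondary + trail calls) within the same library, the
#' comparison used to show that unprocessed slicer products accumulate
#' when conversion into piRNAs fails.
#'
#' @param calls Data frame with a `call` column from [classify_products()].
#' @param total_mapped Optional denominator to also report absolute rpm
#'   per class.
#' @return A list with `counts` (named vector per class), `byproduct_ratio`,
#'   `intermediate_ratio`, and (if `total_mapped` given) `rpm`. Ratios are
#'   `NA` with a warning when there are no piRNAs.
#' @export
relative_ratios <- function(calls, total_mapped = NULL) {
  lev <- c("secondary_piRNA", "trail_piRNA", "byproduct_16mer",
           "intermediate", "other")
  counts <- table(factor(calls$call, levels = lev))
  counts <- setNames(as.integer(counts), lev)
  pirna <- counts[["secondary_piRNA"]] + counts[["trail_piRNA"]]
  if (pirna == 0L) {
    warnf("no piRNA-class reads: relative ratios undefined")
    by_r <- NA_real_; in_r <- NA_real_
  } else {
    by_r <- counts[["byproduct_16mer"]] / pirna
    in_r <- counts[["intermediate"]] / pirna
  }
  out <- list(counts = counts, byproduct_ratio = by_r, intermediate_ratio = in_r)
  if (!is.null(total_mapped)) out$rpm <- counts * 1e6 / total_mapped
  out
}
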