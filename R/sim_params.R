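#' Simulation parameters for slicer-triggered piRNA biogenesis
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the reporter system used to dissect MILI-slicing-triggered biogenesis in
#' the neonatal mouse testis: a precursor carrying 35 perfectly
#' complementary binding sites for 26-nt guide piRNAs, cleavage 10 nt
#' downstream of each guide 5' end, secondary/trail piRNAs of 24-30 nt
#' (mode 26 nt), a 16-nt by-product (`guide_length - cleavage_offset`),
#' pre-piRNA intermediates sequenced to a 51-nt maximum, and a
#' contaminating 21-23-nt microRNA class peaking at 22 nt.
#'
#' @param n_sites Number of guide-piRNA binding sites on the precursor.
#' @param guide_length Guide piRNA length in nt.
#' @param cleavage_offset Slicing position: the target is cut between the
#'   nucleotides paired to guide positions `cleavage_offset` and
#'   `cleavage_offset + 1`, i.e. 10 nt downstream of the guide 5' end.
#' @param secondary_length_probs Named numeric vector of probabilities for
#'   secondary (and trail) piRNA lengths; names are lengths in nt. Must
#'   cover 24-30 nt with mode 26 to emulate MILI-bound piRNAs.
#' @param trail_count_mean Mean of the geometric distribution (support
#'   0, 1, 2, ...) for the number of phased trail piRNAs that follow one
#'   secondary piRNA.
#' @param max_read_length Maximum sequencing length in nt; longer inserts
#'   are truncated, so pre-piRNA intermediates appear as reads of exactly
#'   this length.
#' @param mirna_length_probs Named numeric vector of probabilities for
#'   contaminant microRNA lengths (21-23 nt, mode 22). The 23-nt class must
#'   have positive mass because 23-nt read counts serve as a
#'   normaliser downstream.
#' @param mirna_fraction Fraction of the library made of contaminant
#'   microRNA reads.
#' @param conversion_efficiency Probability that a cleavage event is
#'   converted into mature piRNAs (secondary + trails) rather than stalling
#'   as an unprocessed pre-piRNA intermediate. This is the genotype knob:
#'   high for wild-type-like processing, low for helicase-mutant-like
#'   processing.
#' @param u1_bias Probability that trail piRNA 5' ends are placed on a
#'   uridine (T in DNA space) when the local sequence allows it.
#' @param intermediate_length True length in nt of the unprocessed
#'   downstream cleavage fragment before sequencing truncation; must be at
#'   least `max_read_length`.
#' @param spacer_length Spacer in nt between consecutive binding sites on
#'   the precursor; must be at least `max_read_length` so that reads from
#'   neighbouring sites stay separable.
#' @param adapter_seq 3' sequencing adapter appended to every insert.
#' @param barcode_map Named character vector mapping library tags to the
#'   per-library barcode that sits between the insert and the adapter.
#' @param depth Number of reads per simulated library.
#'
#' @return An object of class `sim_params` (a validated list).
#' @export
#' @examples
#' p <- sim_params(n_sites = 4, depth = 1000)
#' p$byproduct_length  # guide_length - cleavage_offset = 16
sim_params <- function(n_sites = 35,
                       guide_length = 26,
                       cleavage_offset = 10,
                       secondary_length_probs = c(
                         "24" = 0.05, "25" = 0.12, "26" = 0.40, "27" = 0.20,
                         "28" = 0.12, "29" = 0.07, "30" = 0.04
                       ),
                       trail_count_mean = 2,
                       max_read_length = 51,
                       mirna_length_probs = c("21" = 0.25, "22" = 0.50, "23" = 0.25),
                       mirna_fraction = 0.2,
                       conversion_efficiency = 0.9,
                       u1_bias = 0.8,
                       intermediate_length = 80,
                       spacer_length = 80,
                       adapter_seq = "AGATCGGAAGAGCACACGTCT",
                       barcode_map = c(lib1 = "ATCACG", lib2 = "CGATGT", lib3 = "TTAGGC"),
                       depth = 50000) {
  p <- list(
    n_sites = as.integer(n_sites),
    guide_length = as.integer(guide_length),
    cleavage_offset = as.integer(cleavage_offset),
    secondary_length_probs = secondary_length_probs,
    trail_count_mean = trail_count_mean,
    byproduct_length = as.integer(guide_length) - as.integer(cleavage_offset),
    max_read_length = as.integer(max_read_length),
    mirna_length_probs = mirna_length_probs,
    mirna_fraction = mirna_fraction,
    conversion_efficiency = conversion_efficiency,
    u1_bias = u1_bias,
    intermediate_length = as.integer(intermediate_length),
    spacer_length = as.integer(spacer_length),
    adapter_seq = toupper(adapter_seq),
    barcode_map = barcode_map,
    depth = as.integer(depth)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

#' Validate simulation parameters
#'
#' @param p A `sim_params` object.
#' @return `p`, invisibly, after validation.
#' @export
validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_sites < 1L) stopf("n_sites must be >= 1")
  if (p$cleavage_offset >= p$guide_length)
    stopf("cleavage_offset must be smaller than guide_length")
  if (p$byproduct_length != p$guide_length - p$cleavage_offset)
    stopf("byproduct_length must equal guide_length - cleavage_offset")
  for (nm in c("mirna_fraction", "conversion_efficiency", "u1_bias")) {
    if (!is_probability(p[[nm]])) stopf("%s must be a probability in [0,1]", nm)
  }
  sl <- as.integer(names(p$secondary_length_probs))
  if (anyNA(sl) || any(sl < 24L) || any(sl > 30L))
    stopf("secondary piRNA lengths must lie within 24-30 nt")
  if (any(p$secondary_length_probs < 0) || sum(p$secondary_length_probs) <= 0)
    stopf("secondary_length_probs must be non-negative and sum > 0")
  ml <- as.integer(names(p$mirna_length_probs))
  if (anyNA(ml) || any(ml < 21L) || any(ml > 23L))
    stopf("miRNA lengths must lie within 21-23 nt")
  if (!("23" %in% names(p$mirna_length_probs)) || p$mirna_length_probs[["23"]] <= 0)
    stopf("mirna_length_probs must give positive mass to 23 nt (normaliser length)")
  if (p$intermediate_length < p$max_read_length)
    stopf("intermediate_length must be >= max_read_length")
  if (p$spacer_length < p$max_read_length)
    stopf("spacer_length must be >= max_read_length to keep sites separable")
  if (anyDuplicated(p$barcode_map))
    stopf("barcode_map contains duplicated barcodes")
  if (length(unique(nchar(p$barcode_map))) > 1L)
    stopf("all barcodes must have equal length")
  if (!grepl("^[ACGT]+$", p$adapter_seq))
    stopf("adapter_seq must be a DNA string over A/C/G/T")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (sim_params)\n")
  cat(sprintf("  %d binding sites for %d-nt guides, cleavage %d nt downstream of guide 5' end\n",
              x$n_sites, x$guide_length, x$cleavage_offset))
  cat(sprintf("  by-product %d nt; intermediates sequenced to %d nt\n",
              x$byproduct_length, x$max_read_length))
  cat(sprintf("  conversion efficiency %.2f; miRNA fraction %.2f; depth %d reads\n",
              x$conversion_efficiency, x$mirna_fraction, x$depth))
  invisible(x)
}
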