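# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# All placements of `read` on `ref` (and its reverse complement) by direct
# double-loop Hamming comparison; returns the best placement under the
# documented tie-break or NULL.
bf_align <- function(read, ref, max_mm = 0L, forbidden = NULL,
                     strands = c("+", "-")) {
  rc <- function(s) {
    m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(m[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- nchar(ref); n <- nchar(read)
  if (n > L) return(NULL)
  best <- NULL
  consider <- function(strand, start0, mm_read_pos) {
    if (length(mm_read_pos) > max_mm) return()
    if (!is.null(forbidden) && any(mm_read_pos %in% forbidden)) return()
    cand <- list(strand = strand, start = start0, mm = mm_read_pos)
    if (is.null(best)) { best <<- cand; return() }
    a <- c(length(cand$mm), cand$start, cand$strand != "+")
    b <- c(length(best$mm), best$start, best$strand != "+")
    for (i in 1:3) {
      if (a[i] < b[i]) { best <<- cand; return() }
      if (a[i] > b[i]) return()
    }
  }
  refc <- strsplit(ref, "")[[1]]
  for (strand in strands) {
    probe <- if (strand == "+") read else rc(read)
    pc <- strsplit(probe, "")[[1]]
    for (s0 in 0:(L - n)) {
      seg <- refc[(s0 + 1):(s0 + n)]
      mm_plus <- which(pc != seg | pc == "N")
      mm_read <- if (strand == "+") mm_plus else sort(n - mm_plus + 1L)
      consider(strand, s0, mm_read)
    }
  }
  if (is.null(best)) return(NULL)
  list(strand = best$strand, start = best$start, end = best$start + n,
       n_mismatch = length(best$mm), mm = best$mm)
}

# score(delta) by explicit double loop over all position pairs
bf_pingpong <- function(m, n, deltas) {
  mi <- as.integer(names(m)); np <- as.integer(names(n))
  out <- numeric(length(deltas))
  for (di in seq_along(deltas)) {
    for (i in seq_along(mi)) {
      for (j in seq_along(np)) {
        if (np[j] == mi[i] + deltas[di]) out[di] <- out[di] + m[i] * n[j]
      }
    }
  }
  out
}

# longest read suffix equal to an adapter prefix, by scanning every suffix
bf_trim <- function(read, adapter, min_overlap = 3L) {
  n <- nchar(read)
  pos <- regexpr(adapter, read, fixed = TRUE)
  if (pos > 0) return(substr(read, 1, pos - 1))
  for (k in seq(min(n, nchar(adapter) - 1L), 1L)) {
    if (k < min_overlap) break
    if (substr(read, n - k + 1L, n) == substr(adapter, 1L, k))
      return(substr(read, 1L, n - k))
  }
  read
}

# sharing criteria transcribed literally, one record at a time
bf_sharing <- function(mili, miwi, mvh, thr = 0.25, fold = 3) {
  if (mili >= thr && mili >= fold * miwi) return("MILI_specific")
  if (miwi >= thr && miwi >= fold * mili) return("MIWI_specific")
  if (mili >= thr && miwi >= thr &&
      max(mili, miwi) / min(mili, miwi) < fold) return("MILI_and_MIWI")
  if (mvh >= thr) return("MVH_specific")
  "unclassified"
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
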