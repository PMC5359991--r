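# Shared helpers: brute-force oracles for the index and the match records,
# and small fixture shortcuts. Oracles are deliberately independent of the
# package's own mapping/indexing code paths.

# Brute-force prefix-anchored k-mer scan: named list kmer -> 0-based
# ascending positions.
brute_force_index <- function(bases, k, prefix) {
  n <- nchar(bases)
  if (n < k) return(list())
  kmers <- substring(bases, 1:(n - k + 1), k:n)
  ok <- startsWith(kmers, prefix) & !grepl("[^ACGT]", kmers)
  if (!any(ok)) return(list())
  split((which(ok) - 1L), kmers[ok])
}

index_as_list <- function(index) {
  out <- stats::setNames(index$positions, index$kmers)
  out[order(names(out))]
}

# Character-by-character verification of every mapped segment of a match
# record against the reference: run positions must match, recorded
# mismatches must differ from the reference base, the tolerance rule must
# hold, and raw segments must copy the read verbatim.
verify_record <- function(rec, read, ref_bases, e) {
  if (rec$match_type == "RAW")
    return(identical(rec$raw_bases, read) && length(rec$segments) == 0)
  off <- 0L
  for (seg in rec$segments) {
    len <- seg$length
    piece <- substr(read, off + 1L, off + len)
    if (seg$kind == "RAW") {
      if (!identical(seg$raw_bases, piece)) return(FALSE)
    } else {
      runs <- seg$run_lengths
      mm <- seg$mismatch_bases
      if (length(runs) != nchar(mm) + 1L) return(FALSE)
      if (nchar(mm) > e * len) return(FALSE)
      oriented <- if (seg$palindrome) reverse_complement(piece) else piece
      rp <- seg$ref_pos
      pp <- 0L
      for (j in seq_along(runs)) {
        r <- runs[j]
        if (r > 0 &&
            substr(oriented, pp + 1L, pp + r) != substr(ref_bases, rp + 1L, rp + r))
          return(FALSE)
        pp <- pp + r; rp <- rp + r
        if (j <= nchar(mm)) {
          mb <- substr(mm, j, j)
          if (substr(oriented, pp + 1L, pp + 1L) != mb) return(FALSE)
          if (substr(ref_bases, rp + 1L, rp + 1L) == mb) return(FALSE)
          pp <- pp + 1L; rp <- rp + 1L
        }
      }
      if (pp != len) return(FALSE)
    }
    off <- off + len
  }
  off == nchar(read)
}

# TRUE for reads that contain at least one k-mer present in the index
# (computed independently of the mapper's seed search).
has_indexed_kmer <- function(reads, index) {
  k <- index$config$k
  kmset <- index$kmers
  vapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(FALSE)
    any(substring(r, 1:(n - k + 1), k:n) %in% kmset)
  }, logical(1), USE.NAMES = FALSE)
}

tmp_fastq <- function(bytes) {
  p <- tempfile(fileext = ".fastq")
  writeBin(bytes, p)
  p
}

tmp_fasta <- function(ref) {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", ref$name), ref$bases), p)
  p
}
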