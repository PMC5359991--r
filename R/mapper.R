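# The light-weight mapping model: a prefix-anchored k-mer index over the
# reference, ungapped seed-and-extend alignment with a mismatch-tolerance
# rate, reverse-complement ("palindrome") fallback, segment re-mapping of
# unmapped reads, and exact reconstruction from match records.
#
# Coordinates are 0-based, half-open, on the forward reference strand;
# palindrome records store the forward-strand interval plus a flag.

#' Mapping model configuration
#'
#' @param k K-mer length used by the index, in bases.
#' @param prefix Short nucleotide string; only k-mers starting with it are
#'   indexed (trades seed sensitivity for index size and speed).
#' @param L Minimum match length, in bases; shorter spans never count as
#'   mapped.
#' @param e Mismatch tolerance rate: a span of length n may carry at most
#'   `floor(e * n)` substitutions.
#' @param segment_len Piece length when an unmapped read is re-partitioned
#'   and each piece realigned independently.
#' @return An object of class `"mapper_config"`.
#' @export
mapper_config <- function(k = 12L, prefix = "CG", L = 16L, e = 0.05,
                          segment_len = 32L) {
  k <- as.integer(k); L <- as.integer(L); segment_len <- as.integer(segment_len)
  if (nchar(prefix) >= k) stop("prefix must be shorter than k")
  if (!grepl("^[ACGT]+$", prefix)) stop("prefix must be a non-empty string over {A,C,G,T}")
  if (L < k) stop("L must be >= k")
  if (e < 0 || e >= 0.5) stop("e must satisfy 0 <= e < 0.5")
  if (segment_len < L) stop("segment_len must be >= L")
  structure(list(k = k, prefix = prefix, L = L, e = e,
                 segment_len = segment_len),
            class = "mapper_config")
}

#' Build the prefix-anchored k-mer index
#'
#' Records the 0-based positions of every length-`k` reference substring
#' that begins with `config$prefix` and contains only `{A,C,G,T}`; positions
#' per k-mer are ascending.
#'
#' @param ref An `fq_reference` (see [reference()] / [read_fasta()]).
#' @param config A [mapper_config()].
#' @return An object of class `"reference_index"` with fields `kmers`,
#'   `positions` (parallel list of integer vectors), `config`, `junctions`
#'   and `ref_len`.
#' @export
build_index <- function(ref, config = mapper_config()) {
  stopifnot(inherits(ref, "fq_reference"), inherits(config, "mapper_config"))
  if (nchar(ref$bases) == 0) stop("reference bases must be non-empty")
  if (config$k > nchar(ref$bases))
    warning("k exceeds the reference length; index is empty")
  tbl <- .c_build_index(ref$bases, config$k, config$prefix)
  structure(list(kmers = tbl$kmers, positions = tbl$positions,
                 config = config, junctions = ref$junctions,
                 ref_len = nchar(ref$bases)),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index: %d k-mers (k=%d, prefix '%s'), %d positions>\n",
              length(x$kmers), x$config$k, x$config$prefix,
              sum(vapply(x$positions, length, 1L))))
  invisible(x)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. An involution:
#' applying it twice returns the input.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) .c_revcomp(seq)

#' Candidate seed anchors of a read
#'
#' All pairs `(read_offset, ref_pos)` (0-based) such that the read k-mer at
#' `read_offset` occurs in the index at `ref_pos`, ordered by read offset and
#' then reference position.
#'
#' @param read A single read string.
#' @param index A [build_index()] result.
#' @return A data frame with columns `read_offset` and `ref_pos` (possibly
#'   zero rows).
#' @export
find_seeds <- function(read, index) {
  stopifnot(inherits(index, "reference_index"))
  res <- .c_find_seeds(read, index[c("kmers", "positions")],
                       index$config$k, index$config$prefix)
  data.frame(read_offset = res$read_offset, ref_pos = res$ref_pos)
}

#' Extend a seed anchor across the full read
#'
#' Ungapped extension of the anchor in both directions over the whole read:
#' the read is aligned at reference offset `ref_pos - read_offset`. Fails
#' (returns `NULL`) if the alignment leaves the reference, crosses a FASTA
#' junction, is shorter than `L`, or carries more than `floor(e * n)`
#' mismatches.
#'
#' @param read A single read string.
#' @param ref An `fq_reference`.
#' @param anchor A list or vector with `read_offset` and `ref_pos` (0-based).
#' @param config A [mapper_config()].
#' @return A segment match (list with `ref_pos`, `palindrome`,
#'   `run_lengths`, `mismatch_bases`, `length`) or `NULL`.
#' @export
extend_seed <- function(read, ref, anchor, config = mapper_config()) {
  stopifnot(inherits(ref, "fq_reference"))
  a <- as.list(anchor)
  res <- .c_extend_seed(read, ref$bases, as.integer(a$read_offset),
                        as.integer(a$ref_pos), ref$junctions,
                        config$L, config$e)
  if (length(res) == 0) NULL else res[[1]]
}

#' Map reads to the reference
#'
#' For each read: (1) forward seeds are tried in order and the first anchor
#' whose extension satisfies `L` and `e` wins; (2) otherwise the reverse
#' complement undergoes the same procedure (palindrome flag set); (3)
#' otherwise the read is partitioned into `segment_len` pieces, each mapped
#' independently (forward then palindrome) with still-unmapped pieces kept
#' as literals; (4) otherwise the whole read is emitted raw. Reads
#' containing characters outside `{A,C,G,T}` go directly to raw, since the
#' mismatch alphabet is exactly `{A,C,G,T}`.
#'
#' @param reads Character vector of reads.
#' @param index A [build_index()] result.
#' @param ref The `fq_reference` the index was built from.
#' @return A list of match records; each has `match_type` (one of
#'   `"FULL_EXACT"`, `"FULL_SUB"`, `"SEGMENTED"`, `"RAW"`), `segments`,
#'   `raw_bases` and `read_len`.
#' @export
map_reads <- function(reads, index, ref) {
  stopifnot(inherits(index, "reference_index"), inherits(ref, "fq_reference"))
  cfg <- index$config
  .c_map_reads(reads, index[c("kmers", "positions")], ref$bases,
               index$junctions, cfg$k, cfg$prefix, cfg$L, cfg$e,
               cfg$segment_len)
}

#' @rdname map_reads
#' @param read A single read string.
#' @export
map_read <- function(read, index, ref) map_reads(read, index, ref)[[1]]

#' Reconstruct reads from match records
#'
#' Exact inverse of [map_reads()]: reference-strand bases are rebuilt from
#' the run lengths and mismatch bases (then reverse-complemented for
#' palindrome segments); raw segments are copied verbatim.
#'
#' @param records A list of match records.
#' @param ref The `fq_reference` used for mapping.
#' @return Character vector of reads.
#' @export
reconstruct_reads <- function(records, ref) {
  stopifnot(inherits(ref, "fq_reference"))
  .c_reconstruct_reads(records, ref$bases)
}

#' @rdname reconstruct_reads
#' @param record A single match record.
#' @export
reconstruct_read <- function(record, ref) reconstruct_reads(list(record), ref)[1]

#' Assemble a reference from the reads themselves
#'
#' Deterministic greedy pseudo-assembly used when no external reference is
#' available: reads are scanned in input order; each read is either skipped
#' (already contained in the growing contig), appended via its longest exact
#' suffix/prefix overlap of at least `overlap_min` bases, or opens a new
#' contig. Contigs are concatenated (junction offsets recorded) and
#' truncated at `target_len`. Assembly quality only affects the compression
#' ratio, never losslessness.
#'
#' @param reads Character vector of reads.
#' @param config A [mapper_config()]; at least one read must contain
#'   `config$prefix`.
#' @param target_len Maximum assembled reference length, in bases.
#' @param overlap_min Minimum exact overlap, in bases.
#' @param max_reads At most this many reads are considered.
#' @return An `fq_reference` named `"assembled"`.
#' @export
assemble_reference <- function(reads, config = mapper_config(),
                               target_len = 100000L, overlap_min = 16L,
                               max_reads = 2000L) {
  reads <- reads[grepl("^[ACGT]+$", reads)]
  if (!any(grepl(config$prefix, reads, fixed = TRUE)))
    stop(sprintf("no read contains the prefix '%s'; supply a reference with -r instead",
                 config$prefix))
  reads <- utils::head(reads, max_reads)
  contigs <- character()
  cur <- reads[1]
  for (r in reads[-1]) {
    if (nchar(cur) >= target_len) break
    if (grepl(r, cur, fixed = TRUE)) next
    o <- .c_max_overlap(cur, r, as.integer(overlap_min))
    if (o > 0) {
      cur <- paste0(cur, substring(r, o + 1L))
    } else {
      contigs <- c(contigs, cur)
      cur <- r
    }
  }
  contigs <- c(contigs, cur)
  bases <- paste0(contigs, collapse = "")
  junctions <- cumsum(nchar(contigs))
  junctions <- junctions[-length(junctions)]
  if (nchar(bases) > target_len) {
    bases <- substr(bases, 1L, target_len)
    junctions <- junctions[junctions < target_len]
  }
  reference(bases, name = "assembled", junctions = junctions)
}
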