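# End-to-end orchestration: block partitioning, the six intermediate
# streams, the archive format, and the compression/decompression drivers.
#
# Archive layout (all integers LEB128 varints unless noted):
#   magic "LWF2" | version u8 | record_count | block_count |
#   k | L | round(e*1e6) | segment_len | prefix_len | prefix bytes |
#   run_min | run_cap | order_general | order_bases | counter_cap | delta |
#   flags u8 (bit 0: assembled reference embedded) | reference checksum (8B)
#   [if embedded: name_len | name | framed coded reference | n_junctions |
#    junction offsets]
#   per block: n_records | 6 x (payload_len | payload)
#   trailer: FNV-1a of everything before it (8B)
#
# Stream order within a block: metadata, quality, positions, structure,
# mismatch bases, raw sequences. Blocks are self-contained (delta state
# resets at block boundaries), so they can be mapped and encoded
# concurrently and collected in block order; the archive bytes are a pure
# function of (input, reference, config), independent of thread count.

FQZ_MAGIC <- "LWF2"
FQZ_VERSION <- 1L

#' Compression configuration
#'
#' @param mapper A [mapper_config()].
#' @param run_min,run_cap Run-length-limited coding parameters for quality
#'   strings (see [rll_encode()]).
#' @param b Number of blocks the input is partitioned into; blocks are
#'   mapped independently (and possibly concurrently).
#' @param counter_cap,delta Entropy-model parameters (see [encode_stream()]).
#' @return An object of class `"fqzip_config"`.
#' @export
fqzip_config <- function(mapper = mapper_config(), run_min = 3L,
                         run_cap = 255L, b = 10L,
                         counter_cap = 1023L, delta = 1L) {
  stopifnot(inherits(mapper, "mapper_config"))
  b <- as.integer(b)
  if (b < 1) stop("b must be >= 1")
  if (run_min < 2 || run_cap > 255 || run_cap < run_min)
    stop("run-length parameters must satisfy 2 <= run_min <= run_cap <= 255")
  structure(list(mapper = mapper, run_min = as.integer(run_min),
                 run_cap = as.integer(run_cap), b = b,
                 counter_cap = as.integer(counter_cap),
                 delta = as.integer(delta)),
            class = "fqzip_config")
}

#' Partition records into contiguous blocks
#'
#' Blocks hold `ceiling(n / b)` records each (the last one possibly fewer);
#' concatenating them reproduces the input order.
#'
#' @param records A [fastq_records] object.
#' @param b Number of blocks requested.
#' @return A list of [fastq_records] blocks (fewer than `b` when `n < b`).
#' @export
partition_blocks <- function(records, b = 10L) {
  stopifnot(inherits(records, "fastq_records"), b >= 1)
  n <- length(records)
  if (n == 0) return(list())
  size <- ceiling(n / b)
  starts <- seq.int(1L, n, by = size)
  lapply(starts, function(s) records[s:min(s + size - 1L, n)])
}

wv <- function(...) .c_varint_encode(c(...))

frame_raw <- function(payload) c(wv(length(payload)), payload)

#' Encode one block into the six framed stream payloads
#'
#' Streams 1-4 and 6 (metadata deltas, quality planes, delta-coded segment
#' positions, match structure, raw sequences) are coded by [encode_stream()]
#' under the order-32 model; stream 5 (mismatch bases) by [encode_bases()]
#' under order 28.
#'
#' @param match_records List of match records from [map_reads()].
#' @param meta Metadata lines of the block.
#' @param plus Separator-line descriptor (`bare` flags and `literals`), as
#'   produced by [split_streams()].
#' @param quals Quality strings of the block.
#' @param config An [fqzip_config()].
#' @return Named list of six raw payloads (`meta`, `qual`, `positions`,
#'   `structure`, `mismatch`, `rawseq`).
#' @export
encode_bundle <- function(match_records, meta, plus, quals, config = fqzip_config()) {
  cc <- config$counter_cap; dd <- config$delta
  packed <- .c_pack_records(match_records)
  meta_payload <- c(.c_meta_pack(meta),
                    as.raw(as.integer(!plus$bare)),
                    .c_meta_pack(plus$literals))
  rll <- .c_rll_pack(quals, config$run_min, config$run_cap)
  qual_payload <- c(frame_raw(encode_stream(rll$symbols, ORDER_GENERAL, cc, dd)),
                    frame_raw(encode_stream(rll$control, ORDER_GENERAL, cc, dd)))
  # the structure stream carries four homogeneous planes (record/segment
  # tokens, lengths, mismatch counts, leading runs), each coded separately
  structure_payload <- c(
    frame_raw(encode_stream(packed$tokens, ORDER_GENERAL, cc, dd)),
    frame_raw(encode_stream(packed$lengths, ORDER_GENERAL, cc, dd)),
    frame_raw(encode_stream(packed$counts, ORDER_GENERAL, cc, dd)),
    frame_raw(encode_stream(packed$runs, ORDER_GENERAL, cc, dd)))
  list(meta = encode_stream(meta_payload, ORDER_GENERAL, cc, dd),
       qual = qual_payload,
       positions = encode_stream(packed$positions, ORDER_GENERAL, cc, dd),
       structure = structure_payload,
       mismatch = encode_bases(packed$mismatch, ORDER_BASES, cc, dd),
       rawseq = encode_stream(charToRaw(packed$rawseq), ORDER_GENERAL, cc, dd))
}

read_frame <- function(buf, pos) {
  r <- .c_varint_decode(buf, pos, 1L)
  len <- r$values[1]
  if (r$offset + len > length(buf)) stop("corrupted stream: framed payload truncated")
  list(payload = buf[seq_len(len) + r$offset], offset = r$offset + len)
}

#' Decode the six stream payloads of one block
#'
#' Exact inverse of [encode_bundle()].
#'
#' @param streams Named list of six raw payloads.
#' @param n_records Number of records in the block.
#' @param config The [fqzip_config()] used at encoding time.
#' @return List with `match_records`, `meta`, `plus` and `qual`.
#' @export
decode_bundle <- function(streams, n_records, config = fqzip_config()) {
  cc <- config$counter_cap; dd <- config$delta
  planes <- vector("list", 4)
  off <- 0
  for (i in 1:4) {
    fr <- read_frame(streams$structure, off)
    planes[[i]] <- decode_stream(fr$payload, ORDER_GENERAL, cc, dd)
    off <- fr$offset
  }
  if (off != length(streams$structure))
    stop("corrupted stream: trailing bytes in structure payload")
  positions_b <- decode_stream(streams$positions, ORDER_GENERAL, cc, dd)
  mismatch <- decode_bases(streams$mismatch, ORDER_BASES, cc, dd)
  rawseq <- rawToChar(decode_stream(streams$rawseq, ORDER_GENERAL, cc, dd))
  records <- .c_unpack_records(planes[[1]], planes[[2]], planes[[3]],
                               planes[[4]], positions_b, mismatch, rawseq,
                               n_records)
  meta_payload <- decode_stream(streams$meta, ORDER_GENERAL, cc, dd)
  mu <- .c_meta_unpack(meta_payload, n_records, 0)
  metas <- mu$lines
  off <- mu$offset
  if (off + n_records > length(meta_payload))
    stop("corrupted stream: separator flags truncated")
  flags <- meta_payload[seq_len(n_records) + off]
  bare <- flags == as.raw(0)
  lu <- .c_meta_unpack(meta_payload, sum(!bare), off + n_records)
  if (lu$offset != length(meta_payload))
    stop("corrupted stream: trailing bytes in metadata payload")
  f1 <- read_frame(streams$qual, 0)
  f2 <- read_frame(streams$qual, f1$offset)
  if (f2$offset != length(streams$qual))
    stop("corrupted stream: trailing bytes in quality payload")
  symbols <- decode_stream(f1$payload, ORDER_GENERAL, cc, dd)
  control <- decode_stream(f2$payload, ORDER_GENERAL, cc, dd)
  lens <- vapply(records, function(r) r$read_len, integer(1))
  quals <- .c_rll_unpack(symbols, control, lens, config$run_min, config$run_cap)
  list(match_records = records, meta = metas,
       plus = list(bare = bare, literals = lu$lines), qual = quals)
}

resolve_reference <- function(ref) {
  if (is.null(ref)) return(NULL)
  if (inherits(ref, "fq_reference")) return(ref)
  if (is.character(ref) || is.raw(ref)) return(read_fasta(ref))
  stop("reference must be an fq_reference, a FASTA path, or raw FASTA bytes")
}

compress_block <- function(block, index, ref, config) {
  mrec <- map_reads(block$seq, index, ref)
  streams <- split_streams(block)
  bundle <- encode_bundle(mrec, streams$meta, streams$plus, streams$qual, config)
  types <- vapply(mrec, function(r) r$match_type, character(1))
  bytes <- c(wv(length(block)), unlist(lapply(bundle, frame_raw), use.names = FALSE))
  list(bytes = bytes,
       sizes = vapply(bundle, length, numeric(1)),
       type_counts = c(FULL_EXACT = sum(types == "FULL_EXACT"),
                       FULL_SUB = sum(types == "FULL_SUB"),
                       SEGMENTED = sum(types == "SEGMENTED"),
                       RAW = sum(types == "RAW")))
}

#' Compress FASTQ data against a reference
#'
#' Splits the input into metadata/base/quality streams, partitions records
#' into `config$b` blocks, maps each block's reads to the reference, and
#' entropy-codes the six intermediate streams per block. The archive bytes
#' are a pure function of (input, reference, config): blocks may be mapped
#' concurrently but are always collected in block order.
#'
#' The external reference is not embedded; its 64-bit checksum is stored and
#' verified at decompression. With `assemble = TRUE` a reference is
#' pseudo-assembled from the reads ([assemble_reference()]) and embedded in
#' the archive, making it self-contained.
#'
#' @param input A [fastq_records] object, a FASTQ file path, or raw FASTQ
#'   bytes.
#' @param ref An `fq_reference`, a FASTA path, or `NULL` with
#'   `assemble = TRUE`.
#' @param config An [fqzip_config()].
#' @param threads Number of worker processes for block mapping (result bytes
#'   do not depend on it).
#' @param assemble Assemble (and embed) a reference from the reads instead
#'   of using an external one.
#' @return Raw vector of archive bytes, with a `"stats"` attribute (record
#'   counts, per-stream byte totals, match-type counts).
#' @export
fq_compress <- function(input, ref = NULL, config = fqzip_config(),
                        threads = 1L, assemble = FALSE) {
  records <- if (inherits(input, "fastq_records")) input else read_fastq(input)
  embedded <- NULL
  if (assemble) {
    ref <- assemble_reference(records$seq, config$mapper)
    embedded <- ref
  } else {
    ref <- resolve_reference(ref)
    if (is.null(ref)) stop("a reference is required unless assemble = TRUE")
  }
  if (nchar(ref$bases) == 0) stop("reference is empty")
  index <- build_index(ref, config$mapper)
  blocks <- partition_blocks(records, config$b)
  worker <- function(block) compress_block(block, index, ref, config)
  results <- if (threads > 1 && length(blocks) > 1 && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(blocks, worker, mc.cores = threads)
    errs <- vapply(out, inherits, logical(1), "try-error")
    if (any(errs)) stop(attr(out[[which(errs)[1]]], "condition"))
    out
  } else {
    lapply(blocks, worker)
  }
  header <- build_header(length(records), length(blocks), config, ref, embedded)
  body <- c(header, unlist(lapply(results, function(r) r$bytes), use.names = FALSE))
  archive <- c(body, fnv64(body))
  sizes <- Reduce(`+`, lapply(results, function(r) r$sizes),
                  c(meta = 0, qual = 0, positions = 0, structure = 0,
                    mismatch = 0, rawseq = 0))
  types <- Reduce(`+`, lapply(results, function(r) r$type_counts),
                  c(FULL_EXACT = 0, FULL_SUB = 0, SEGMENTED = 0, RAW = 0))
  attr(archive, "stats") <- list(record_count = length(records),
                                 block_count = length(blocks),
                                 input_bytes = length(fastq_serialize(records)),
                                 archive_bytes = length(archive),
                                 stream_bytes = sizes, match_types = types)
  archive
}

build_header <- function(n_records, n_blocks, config, ref, embedded) {
  m <- config$mapper
  flags <- as.raw(if (!is.null(embedded)) 1L else 0L)
  h <- c(charToRaw(FQZ_MAGIC), as.raw(FQZ_VERSION),
         wv(n_records, n_blocks, m$k, m$L, round(m$e * 1e6), m$segment_len,
            nchar(m$prefix)),
         charToRaw(m$prefix),
         wv(config$run_min, config$run_cap, ORDER_GENERAL, ORDER_BASES,
            config$counter_cap, config$delta),
         flags, ref$checksum)
  if (!is.null(embedded)) {
    nm <- charToRaw(embedded$name)
    body <- encode_stream(charToRaw(embedded$bases), ORDER_GENERAL,
                          config$counter_cap, config$delta)
    h <- c(h, wv(length(nm)), nm, frame_raw(body),
           wv(length(embedded$junctions)),
           if (length(embedded$junctions)) wv(embedded$junctions))
  }
  h
}

#' Decompress an archive back to FASTQ bytes
#'
#' Verifies the whole-archive trailer checksum and the reference checksum
#' before producing any output; reconstruction is byte-identical to the
#' original FASTQ, records in their original order.
#'
#' @param archive Raw vector of archive bytes (or a file path).
#' @param ref The same reference used at compression (an `fq_reference` or a
#'   FASTA path); ignored when the archive embeds an assembled reference.
#' @return Raw vector of FASTQ bytes.
#' @export
fq_decompress <- function(archive, ref = NULL) {
  if (is.character(archive)) archive <- read_source_raw(archive)
  stopifnot(is.raw(archive))
  n <- length(archive)
  if (n < 13) stop("corrupted archive: too short")
  body <- archive[seq_len(n - 8)]
  if (!identical(fnv64(body), archive[(n - 7):n]))
    stop("corrupted archive: trailer checksum mismatch")
  if (rawToChar(archive[1:4]) != FQZ_MAGIC)
    stop("corrupted archive: bad magic bytes")
  if (as.integer(archive[5]) != FQZ_VERSION)
    stop(sprintf("unsupported archive version %d", as.integer(archive[5])))
  pos <- 5
  r <- .c_varint_decode(archive, pos, 7L)
  n_records <- r$values[1]; n_blocks <- r$values[2]
  k <- r$values[3]; L <- r$values[4]; e <- r$values[5] / 1e6
  segment_len <- r$values[6]; plen <- r$values[7]
  pos <- r$offset
  prefix <- rawToChar(archive[seq_len(plen) + pos]); pos <- pos + plen
  r <- .c_varint_decode(archive, pos, 6L)
  run_min <- r$values[1]; run_cap <- r$values[2]
  counter_cap <- r$values[5]; delta <- r$values[6]
  pos <- r$offset
  flags <- as.integer(archive[pos + 1]); pos <- pos + 1
  want_checksum <- archive[seq_len(8) + pos]; pos <- pos + 8
  config <- fqzip_config(mapper_config(k, prefix, L, e, segment_len),
                         run_min, run_cap, max(n_blocks, 1),
                         counter_cap, delta)
  if (bitwAnd(flags, 1L) == 1L) {
    r <- .c_varint_decode(archive, pos, 1L)
    nm_len <- r$values[1]; pos <- r$offset
    nm <- rawToChar(archive[seq_len(nm_len) + pos]); pos <- pos + nm_len
    fr <- read_frame(archive, pos); pos <- fr$offset
    bases <- rawToChar(decode_stream(fr$payload, ORDER_GENERAL, counter_cap, delta))
    r <- .c_varint_decode(archive, pos, 1L)
    njx <- r$values[1]; pos <- r$offset
    jx <- integer()
    if (njx > 0) {
      r <- .c_varint_decode(archive, pos, as.integer(njx))
      jx <- as.integer(r$values); pos <- r$offset
    }
    ref <- reference(bases, nm, jx)
  } else {
    ref <- resolve_reference(ref)
    if (is.null(ref))
      stop("this archive needs the external reference it was compressed with")
  }
  if (!identical(ref$checksum, want_checksum))
    stop(sprintf("wrong reference: archive expects checksum %s but '%s' has %s",
                 paste(sprintf("%02x", as.integer(want_checksum)), collapse = ""),
                 ref$name,
                 paste(sprintf("%02x", as.integer(ref$checksum)), collapse = "")))
  meta <- vector("list", n_blocks); seqs <- vector("list", n_blocks)
  plus <- vector("list", n_blocks); qual <- vector("list", n_blocks)
  for (bi in seq_len(n_blocks)) {
    res <- tryCatch({
      r <- .c_varint_decode(archive, pos, 1L)
      nb <- as.integer(r$values[1]); pos <- r$offset
      streams <- vector("list", 6)
      for (si in 1:6) {
        fr <- read_frame(archive, pos)
        streams[[si]] <- fr$payload
        pos <- fr$offset
      }
      names(streams) <- c("meta", "qual", "positions", "structure",
                          "mismatch", "rawseq")
      dec <- decode_bundle(streams, nb, config)
      reads <- .c_reconstruct_reads(dec$match_records, ref$bases)
      bare <- dec$plus$bare
      pl <- rep("+", nb)
      pl[!bare] <- paste0("+", dec$plus$literals)
      list(meta = dec$meta, seqs = reads, plus = pl, qual = dec$qual)
    }, error = function(err) {
      stop(sprintf("corruption error in block %d: %s", bi, conditionMessage(err)),
           call. = FALSE)
    })
    meta[[bi]] <- res$meta; seqs[[bi]] <- res$seqs
    plus[[bi]] <- res$plus; qual[[bi]] <- res$qual
  }
  if (pos != n - 8) stop("corrupted archive: trailing bytes after last block")
  records <- fastq_records(unlist(meta, use.names = FALSE) %||% character(),
                           unlist(seqs, use.names = FALSE) %||% character(),
                           unlist(plus, use.names = FALSE) %||% character(),
                           unlist(qual, use.names = FALSE) %||% character())
  if (length(records) != n_records)
    stop("corrupted archive: record count disagrees with header")
  fastq_serialize(records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compress / decompress FASTQ files
#'
#' File-level wrappers around [fq_compress()] and [fq_decompress()]. Output
#' is written to a `.tmp` file first and renamed on success, so a failed run
#' never leaves a partial result under the target name.
#'
#' @param input Path of the FASTQ file to compress.
#' @param ref Path of the reference FASTA (or an `fq_reference`); optional
#'   when `assemble = TRUE` (compression) or when the archive embeds its
#'   reference (decompression).
#' @param out Output path (archive, or reconstructed FASTQ).
#' @inheritParams fq_compress
#' @return Compression statistics (invisibly) for `compress_fastq`; the
#'   number of bytes written (invisibly) for `decompress_fastq`.
#' @export
compress_fastq <- function(input, ref = NULL, out, config = fqzip_config(),
                           threads = 1L, assemble = FALSE) {
  archive <- fq_compress(input, ref, config, threads, assemble)
  tmp <- paste0(out, ".tmp")
  writeBin(as.raw(archive), tmp)
  file.rename(tmp, out)
  invisible(attr(archive, "stats"))
}

#' @rdname compress_fastq
#' @param archive Path of the archive to decompress.
#' @export
decompress_fastq <- function(archive, ref = NULL, out) {
  bytes <- fq_decompress(read_source_raw(archive), ref)
  tmp <- paste0(out, ".tmp")
  writeBin(bytes, tmp)
  file.rename(tmp, out)
  invisible(length(bytes))
}
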