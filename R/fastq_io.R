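# FASTQ / FASTA input and output, and the split into the three data streams
# (metadata, bases, quality scores). Parsing and serialization form a
# bijection on well-formed 4-line FASTQ so that the compressor's
# decompress(compress(x)) == x contract can hold byte for byte.

#' An ordered set of FASTQ records
#'
#' Column-oriented container for 4-line FASTQ records: the metadata line
#' (with its leading `"@"`), the bases, the separator line (with its leading
#' `"+"`, plus any annotation verbatim) and the quality string. Record order
#' is the file order and is never permuted by any operation in the package.
#'
#' @param meta,seq,plus,qual Character vectors of equal length.
#' @return An object of class `"fastq_records"`.
#' @export
fastq_records <- function(meta = character(), seq = character(),
                          plus = character(), qual = character()) {
  n <- length(meta)
  if (length(seq) != n || length(plus) != n || length(qual) != n)
    stop("corruption error: metadata, sequence, plus and quality streams have different record counts")
  if (n > 0) {
    bad <- which(!startsWith(meta, "@"))
    if (length(bad)) stop(sprintf("parse error at record %d: metadata line does not start with '@'", bad[1]))
    bad <- which(!startsWith(plus, "+"))
    if (length(bad)) stop(sprintf("parse error at record %d: separator line does not start with '+'", bad[1]))
    bad <- which(nchar(seq) != nchar(qual))
    if (length(bad)) stop(sprintf("parse error at record %d: sequence and quality lengths differ", bad[1]))
  }
  structure(list(meta = meta, seq = seq, plus = plus, qual = qual),
            class = "fastq_records")
}

#' @export
length.fastq_records <- function(x) length(x$meta)

#' @export
`[.fastq_records` <- function(x, i) {
  fastq_records(x$meta[i], x$seq[i], x$plus[i], x$qual[i])
}

#' @export
print.fastq_records <- function(x, ...) {
  cat(sprintf("<fastq_records: %d records>\n", length(x)))
  n <- min(length(x), 3L)
  for (i in seq_len(n))
    cat(sprintf("  %s  [%d bp]\n", x$meta[i], nchar(x$seq[i])))
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

read_source_raw <- function(source) {
  if (is.raw(source)) return(source)
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) stop(sprintf("input file not found: %s", source))
    return(readBin(source, "raw", n = file.size(source)))
  }
  stop("source must be a file path or a raw vector")
}

#' Read a 4-line FASTQ file
#'
#' Strict parser for the 4-line-per-record dialect: no wrapped sequence or
#' quality lines, `'\n'` line endings only (CRLF input is rejected rather
#' than silently normalized, since the byte-exact round trip would otherwise
#' be ambiguous). Serializing the result reproduces the input bytes exactly.
#'
#' @param source A file path or a raw vector of FASTQ bytes.
#' @return A [fastq_records] object, in file order.
#' @export
read_fastq <- function(source) {
  bytes <- read_source_raw(source)
  if (length(bytes) == 0) return(fastq_records())
  txt <- rawToChar(bytes)
  Encoding(txt) <- "bytes"
  if (grepl("\r", txt, fixed = TRUE, useBytes = TRUE))
    stop("parse error: input contains carriage returns; only '\\n' line endings are supported")
  if (bytes[length(bytes)] != charToRaw("\n"))
    stop("parse error: final line is not newline-terminated")
  lines <- strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  nl <- length(lines)
  if (nl %% 4 != 0)
    stop(sprintf("parse error at record %d: line count is not a multiple of 4", nl %/% 4 + 1))
  idx <- seq.int(1L, nl, by = 4L)
  fastq_records(meta = lines[idx], seq = lines[idx + 1L],
                plus = lines[idx + 2L], qual = lines[idx + 3L])
}

#' Serialize FASTQ records to bytes
#'
#' Exact inverse of [read_fastq()]: one `'\n'` per line, no trailing
#' alterations.
#'
#' @param records A [fastq_records] object.
#' @return A raw vector.
#' @export
fastq_serialize <- function(records) {
  stopifnot(inherits(records, "fastq_records"))
  if (length(records) == 0) return(raw(0))
  txt <- paste0(records$meta, "\n", records$seq, "\n",
                records$plus, "\n", records$qual, "\n", collapse = "")
  charToRaw(txt)
}

#' Write FASTQ records to a file
#'
#' @param records A [fastq_records] object.
#' @param path Output file path.
#' @return The number of bytes written, invisibly.
#' @export
write_fastq <- function(records, path) {
  bytes <- fastq_serialize(records)
  writeBin(bytes, path)
  invisible(length(bytes))
}

#' Reference sequence container
#'
#' @param bases A single string of (uppercase) nucleotide characters.
#' @param name Sequence name.
#' @param junctions Integer vector of 0-based offsets where concatenated
#'   FASTA records join; alignments never cross them.
#' @return An object of class `"fq_reference"` with fields `name`, `bases`,
#'   `junctions` and `checksum` (8-byte raw, FNV-1a of the bases).
#' @export
reference <- function(bases, name = "reference", junctions = integer()) {
  stopifnot(is.character(bases), length(bases) == 1)
  bases <- toupper(bases)
  structure(list(name = name, bases = bases,
                 junctions = as.integer(junctions),
                 checksum = fnv64(bases)),
            class = "fq_reference")
}

#' @export
print.fq_reference <- function(x, ...) {
  cat(sprintf("<fq_reference '%s': %d bases, checksum %s>\n",
              x$name, nchar(x$bases), paste(sprintf("%02x", as.integer(x$checksum)), collapse = "")))
  invisible(x)
}

#' Read a FASTA reference
#'
#' Multi-record FASTA files are concatenated in order; the junction offsets
#' between records are recorded so the mapper never aligns a read across
#' them. Bases are uppercased and line wrapping is removed.
#'
#' @param source A file path or a raw vector of FASTA bytes.
#' @return An `fq_reference` object.
#' @export
read_fasta <- function(source) {
  path <- if (is.raw(source)) {
    tmp <- tempfile(fileext = ".fa")
    writeBin(source, tmp)
    on.exit(unlink(tmp))
    tmp
  } else source
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop("reference FASTA not found or not a file path / raw vector")
  if (file.size(path) == 0) stop("format error: empty FASTA input")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("format error: not a FASTA file (%s)", conditionMessage(e))))
  if (length(set) == 0) stop("format error: FASTA input contains no records")
  widths <- Biostrings::width(set)
  bases <- paste0(toupper(as.character(set)), collapse = "")
  junctions <- if (length(set) > 1) cumsum(widths)[-length(widths)] else integer()
  reference(bases, name = names(set)[1], junctions = junctions)
}

#' Split records into the three data streams
#'
#' Splits an ordered record set into parallel metadata, nucleotide and
#' quality streams plus a compact descriptor of the separator lines: a
#' per-record flag for a bare `"+"`, and the annotation text (after the
#' `"+"`) stored verbatim for annotated lines.
#'
#' @param records A [fastq_records] object.
#' @return A list with elements `meta`, `seq`, `qual` and `plus` (itself a
#'   list with logical `bare` and character `literals`).
#' @export
split_streams <- function(records) {
  stopifnot(inherits(records, "fastq_records"))
  bare <- records$plus == "+"
  list(meta = records$meta, seq = records$seq, qual = records$qual,
       plus = list(bare = bare, literals = substring(records$plus[!bare], 2L)))
}

#' Merge the three data streams back into records
#'
#' Exact inverse of [split_streams()].
#'
#' @param streams A list as returned by [split_streams()].
#' @return A [fastq_records] object.
#' @export
merge_streams <- function(streams) {
  n <- length(streams$meta)
  if (length(streams$seq) != n || length(streams$qual) != n ||
      length(streams$plus$bare) != n)
    stop("corruption error: stream record counts disagree")
  if (sum(!streams$plus$bare) != length(streams$plus$literals))
    stop("corruption error: separator-line literals do not match flags")
  plus <- rep("+", n)
  plus[!streams$plus$bare] <- paste0("+", streams$plus$literals)
  fastq_records(streams$meta, streams$seq, plus, streams$qual)
}
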