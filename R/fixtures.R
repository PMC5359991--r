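# Deterministic synthetic-data generator: references and FASTQ files with
# controlled structure (substitution rate, reverse-complement fraction,
# junk reads, N injection, quality/metadata dialects) plus per-read ground
# truth, so the mapper and the end-to-end round trip are testable without
# any download.

QUALITY_ALPHABET <- strsplit(rawToChar(as.raw(33:73)), "")[[1]] # Phred+33, Q0-40

#' Specification of a synthetic FASTQ fixture
#'
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param ref_len Reference length in bases.
#' @param n_reads Number of reads.
#' @param read_len A single integer for fixed-length reads, or `c(min, max)`
#'   for variable-length reads (as produced by long-read platforms).
#' @param sub_rate Per-base substitution probability applied to
#'   reference-derived reads.
#' @param revcomp_frac Fraction of reference-derived reads emitted as
#'   reverse complements.
#' @param junk_frac Fraction of reads generated independently of the
#'   reference.
#' @param n_frac Fraction of reads receiving at least one `'N'`.
#' @param plus_frac Fraction of records whose separator line carries the
#'   metadata annotation (`"+..."`) instead of a bare `"+"`.
#' @param quality_model `"CONSTANT"`, `"RUNNY"` (geometric run lengths,
#'   Illumina/PacBio-like plateaus) or `"UNIFORM"`.
#' @param meta_style `"SRA"`, `"ILLUMINA"` or `"PACBIO"` header dialect.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, ref_len = 50000L, n_reads = 1000L,
                         read_len = 100L, sub_rate = 0.01,
                         revcomp_frac = 0, junk_frac = 0, n_frac = 0,
                         plus_frac = 0,
                         quality_model = c("RUNNY", "CONSTANT", "UNIFORM"),
                         meta_style = c("SRA", "ILLUMINA", "PACBIO")) {
  quality_model <- match.arg(quality_model)
  meta_style <- match.arg(meta_style)
  fr <- c(sub_rate, revcomp_frac, junk_frac, n_frac, plus_frac)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (!length(read_len) %in% 1:2 || any(read_len < 1))
    stop("read_len must be a positive length or a (min, max) pair")
  if (length(read_len) == 2 && read_len[1] > read_len[2])
    stop("read_len min must not exceed max")
  structure(list(seed = as.integer(seed), ref_len = as.integer(ref_len),
                 n_reads = as.integer(n_reads),
                 read_len = as.integer(read_len), sub_rate = sub_rate,
                 revcomp_frac = revcomp_frac, junk_frac = junk_frac,
                 n_frac = n_frac, plus_frac = plus_frac,
                 quality_model = quality_model, meta_style = meta_style),
            class = "fixture_spec")
}

random_bases <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference
#'
#' I.i.d. uniform ACGT bases, deterministic under the fixture spec's seed. Every
#' 1 kb window is guaranteed at least one occurrence of `prefix` (injected
#' if absent) so that prefix-anchored indexing is always exercised.
#'
#' @param spec A [fixture_spec()].
#' @param prefix The mapper prefix to guarantee (see [mapper_config()]).
#' @return An `fq_reference` named `"synthetic"`.
#' @export
gen_reference <- function(spec, prefix = "CG") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$ref_len < 1) stop("ref_len must be positive")
  with_seed(spec$seed, {
    bases <- random_bases(spec$ref_len)
    win <- 1000L
    plen <- nchar(prefix)
    if (spec$ref_len >= plen) {
      for (pass in 1:5) {
        occ <- gregexpr(prefix, bases, fixed = TRUE)[[1]]
        occ <- occ[occ > 0]
        starts <- seq.int(1L, spec$ref_len, by = win)
        missing <- starts[vapply(starts, function(s) {
          !any(occ >= s & occ <= min(s + win - 1L, spec$ref_len))
        }, logical(1))]
        missing <- missing[missing + plen - 1L <= spec$ref_len]
        if (length(missing) == 0) break
        for (s in missing) {
          hi <- min(s + win - 1L, spec$ref_len) - plen + 1L
          at <- if (hi > s) s + sample.int(hi - s + 1L, 1L) - 1L else s
          substr(bases, at, at + plen - 1L) <- prefix
        }
      }
    }
    reference(bases, name = "synthetic")
  })
}

gen_quals <- function(model, lens) {
  n <- length(lens)
  switch(model,
    CONSTANT = strrep("I", lens),
    UNIFORM = vapply(lens, function(l) {
      paste0(sample(QUALITY_ALPHABET, l, replace = TRUE), collapse = "")
    }, character(1)),
    RUNNY = vapply(lens, function(l) {
      k <- max(2L, ceiling(l / 4))
      rl <- stats::rgeom(k, 1 / 8) + 1L
      while (sum(rl) < l) rl <- c(rl, stats::rgeom(k, 1 / 8) + 1L)
      sym <- sample(QUALITY_ALPHABET, length(rl), replace = TRUE)
      q <- paste0(strrep(sym, rl), collapse = "")
      substr(q, 1L, l)
    }, character(1)))
}

gen_metas <- function(style, n, lens) {
  switch(style,
    SRA = sprintf("@SRR042213.%d length=%d", seq_len(n), lens),
    ILLUMINA = sprintf("@SIM:1:FCX:1:%d:%d:%d 1:N:0:ATCACG",
                       1000L + (seq_len(n) - 1L) %/% 500L,
                       sample.int(25000L, n, replace = TRUE),
                       sample.int(25000L, n, replace = TRUE)),
    PACBIO = sprintf("@m54006_160504_020529/%d/0_%d", seq_len(n), lens))
}

mutate_read <- function(seq, sub_rate) {
  if (sub_rate <= 0) return(list(seq = seq, n_sub = 0L))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < sub_rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  list(seq = paste0(ch, collapse = ""), n_sub = length(hit))
}

#' Generate a synthetic FASTQ file with ground truth
#'
#' Each read is drawn from a uniform reference start, mutated by i.i.d.
#' substitutions at `sub_rate`, reverse-complemented with probability
#' `revcomp_frac`, or replaced outright by reference-free "junk" with
#' probability `junk_frac`; `n_frac` of reads receive 1-3 `'N'` characters.
#' Qualities and metadata follow the fixture spec's dialects. Ground truth (true
#' 0-based origin, strand, substitution count) is returned per read for
#' oracle tests of the mapper.
#'
#' @param spec A [fixture_spec()].
#' @param ref An `fq_reference`, normally from [gen_reference()].
#' @return A list with `records` ([fastq_records]), `truth` (data frame) and
#'   `fastq` (raw bytes, i.e. `fastq_serialize(records)`).
#' @export
gen_fastq <- function(spec, ref) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(ref, "fq_reference"))
  with_seed(spec$seed + 1L, {
    n <- spec$n_reads
    L <- nchar(ref$bases)
    lens <- if (length(spec$read_len) == 1) rep(spec$read_len, n) else
      spec$read_len[1] + floor(stats::runif(n) * (spec$read_len[2] - spec$read_len[1] + 1))
    if (any(lens > L)) stop("read length exceeds reference length")
    junk <- stats::runif(n) < spec$junk_frac
    strand <- ifelse(!junk & stats::runif(n) < spec$revcomp_frac, "-", "+")
    starts <- ifelse(junk, NA_integer_,
                     1L + as.integer(floor(stats::runif(n) * (L - lens + 1))))
    seqs <- character(n)
    n_sub <- integer(n)
    for (i in seq_len(n)) {
      if (junk[i]) {
        seqs[i] <- random_bases(lens[i])
      } else {
        m <- mutate_read(substr(ref$bases, starts[i], starts[i] + lens[i] - 1L),
                         spec$sub_rate)
        n_sub[i] <- m$n_sub
        seqs[i] <- if (strand[i] == "-") reverse_complement(m$seq) else m$seq
      }
    }
    with_n <- stats::runif(n) < spec$n_frac
    n_injected <- integer(n)
    for (i in which(with_n)) {
      m <- sample.int(3L, 1L)
      at <- sample.int(lens[i], min(m, lens[i]))
      for (a in at) substr(seqs[i], a, a) <- "N"
      n_injected[i] <- length(at)
    }
    quals <- gen_quals(spec$quality_model, lens)
    metas <- gen_metas(spec$meta_style, n, lens)
    plus <- rep("+", n)
    ann <- stats::runif(n) < spec$plus_frac
    plus[ann] <- paste0("+", substring(metas[ann], 2L))
    records <- fastq_records(metas, seqs, plus, quals)
    truth <- data.frame(read = seq_len(n), length = lens,
                        origin = starts - 1L, strand = strand,
                        n_sub = n_sub, junk = junk,
                        n_injected = n_injected,
                        stringsAsFactors = FALSE)
    truth$strand[junk] <- NA_character_
    list(records = records, truth = truth, fastq = fastq_serialize(records))
  })
}

#' Write a fixture to disk
#'
#' Writes `<stem>.fasta`, `<stem>.fastq` and the ground-truth sidecar
#' `<stem>.truth.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param stem Output path stem.
#' @param prefix Mapper prefix guaranteed in the reference.
#' @return Invisibly, a list with the three file paths.
#' @export
write_fixture <- function(spec, stem, prefix = "CG") {
  ref <- gen_reference(spec, prefix)
  fx <- gen_fastq(spec, ref)
  fa <- paste0(stem, ".fasta")
  fq <- paste0(stem, ".fastq")
  tsv <- paste0(stem, ".truth.tsv")
  writeLines(c(paste0(">", ref$name), ref$bases), fa)
  writeBin(fx$fastq, fq)
  utils::write.table(fx$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fa, fastq = fq, truth = tsv))
}
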