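small_cfg <- function(k = 3L, prefix = "CG", L = 3L, e = 0, segment_len = 3L) {
  # bypasses mapper_config() floors for tiny hand-traced cases
  structure(list(k = k, prefix = prefix, L = L, e = e,
                 segment_len = segment_len), class = "mapper_config")
}

test_that("build_index records exactly the prefix-anchored k-mer positions", {
  ref <- reference("CGACGA")
  idx <- build_index(ref, small_cfg())
  expect_equal(index_as_list(idx), list(CGA = c(0L, 3L)))

  idx <- build_index(reference("AAAATTTT"), small_cfg())
  expect_length(idx$kmers, 0)

  idx <- build_index(reference("CGNCG"), small_cfg(k = 2L, prefix = "C", L = 2L,
                                                   segment_len = 2L))
  expect_equal(index_as_list(idx)[["CG"]], c(0L, 3L))

  expect_warning(build_index(reference("ACG"), mapper_config(k = 12L)),
                 "exceeds")
})

test_that("build_index agrees with a brute-force scan on random references", {
  set.seed(402)
  for (rep in 1:20) {
    n <- sample(50:3000, 1)
    ch <- sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    bases <- paste0(ch, collapse = "")
    for (k in c(4L, 8L)) {
      for (prefix in c("CG", "AT")) {
        idx <- build_index(reference(bases),
                           small_cfg(k = k, prefix = prefix, L = k,
                                     segment_len = k))
        expect_identical(index_as_list(idx),
                         brute_force_index(bases, k, prefix))
      }
    }
  }
})

test_that("reverse_complement is the Watson-Crick involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAA"), "TTTT")
  expect_equal(reverse_complement("GATTACA"), "TGTAATC")
  expect_equal(reverse_complement("ANCT"), "AGNT")
  expect_error(reverse_complement("ACGX"), "outside")
  set.seed(7)
  seqs <- vapply(1:50, function(i) {
    paste0(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1), TRUE),
           collapse = "")
  }, character(1))
  expect_equal(reverse_complement(reverse_complement(seqs)), seqs)
})

test_that("find_seeds returns all anchors ordered by read offset then position", {
  ref <- reference("CGACGA")
  idx <- build_index(ref, small_cfg())
  seeds <- find_seeds("CGACGA", idx)
  expect_equal(seeds$read_offset, c(0L, 0L, 3L, 3L))
  expect_equal(seeds$ref_pos, c(0L, 3L, 0L, 3L))
  expect_equal(nrow(find_seeds("TTTT", idx)), 0)
  expect_equal(nrow(find_seeds("CG", idx)), 0) # shorter than k
})

test_that("extend_seed aligns the whole read ungapped under the tolerance rule", {
  set.seed(12)
  bases <- paste0(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  ref <- reference(bases)
  cfg <- mapper_config(k = 12L, prefix = "CG", L = 16L, e = 0.1,
                       segment_len = 32L)

  read <- substr(bases, 11, 30) # ref offset 10, length 20
  seg <- extend_seed(read, ref, list(read_offset = 0L, ref_pos = 10L), cfg)
  expect_equal(seg$ref_pos, 10L)
  expect_equal(seg$run_lengths, 20L)
  expect_equal(seg$mismatch_bases, "")

  sub1 <- read
  old <- substr(sub1, 6, 6) # 0-based offset 5
  substr(sub1, 6, 6) <- setdiff(c("A", "C", "G", "T"), old)[1]
  seg <- extend_seed(sub1, ref, list(read_offset = 0L, ref_pos = 10L), cfg)
  expect_equal(seg$run_lengths, c(5L, 14L))
  expect_equal(nchar(seg$mismatch_bases), 1L)

  sub5 <- read
  for (i in c(2, 6, 10, 14, 18)) {
    old <- substr(sub5, i, i)
    substr(sub5, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_null(extend_seed(sub5, ref, list(read_offset = 0L, ref_pos = 10L), cfg))

  # out of bounds and span shorter than L both fail
  expect_null(extend_seed(read, ref, list(read_offset = 5L, ref_pos = 2L), cfg))
  expect_null(extend_seed("CGACG", ref, list(read_offset = 0L, ref_pos = 10L), cfg))
})

test_that("map_read applies forward, palindrome, segmented and raw fallbacks in order", {
  spec <- fixture_spec(seed = 21, ref_len = 20000)
  ref <- gen_reference(spec)
  idx <- build_index(ref, mapper_config())

  exact <- substr(ref$bases, 501, 600)
  rec <- map_read(exact, idx, ref)
  expect_equal(rec$match_type, "FULL_EXACT")
  expect_length(rec$segments, 1)
  expect_false(rec$segments[[1]]$palindrome)
  expect_equal(rec$segments[[1]]$run_lengths, 100L)
  expect_equal(reconstruct_read(rec, ref), exact)

  pal <- reverse_complement(exact)
  rec <- map_read(pal, idx, ref)
  expect_equal(rec$match_type, "FULL_EXACT")
  expect_true(rec$segments[[1]]$palindrome)
  expect_equal(reconstruct_read(rec, ref), pal)

  rec <- map_read("NNNN", idx, ref)
  expect_equal(rec$match_type, "RAW")
  expect_equal(rec$raw_bases, "NNNN")
  expect_length(rec$segments, 0)

  # half reference-derived, half junk: the matching half is recovered as
  # mapped segments and the junk half kept raw
  with_seed(77, {
    starts <- which(vapply(seq_len(10000), function(s) {
      w1 <- substr(ref$bases, s, s + 31)
      w2 <- substr(ref$bases, s + 32, s + 63)
      grepl("CG", substr(w1, 1, 21), fixed = TRUE) &&
        grepl("CG", substr(w2, 1, 21), fixed = TRUE)
    }, logical(1)))
    s <- starts[1]
    junk <- paste0(sample(c("A", "C", "G", "T"), 64, TRUE), collapse = "")
    read <- paste0(substr(ref$bases, s, s + 63), junk)
  })
  rec <- map_read(read, idx, ref)
  expect_equal(rec$match_type, "SEGMENTED")
  kinds <- vapply(rec$segments, function(sg) sg$kind, character(1))
  expect_true(any(kinds == "MAP"))
  expect_true(any(kinds == "RAW"))
  expect_equal(reconstruct_read(rec, ref), read)
})

test_that("mapping is deterministic and reconstruct inverts it at several divergences", {
  for (sub in c(0, 0.05, 0.15)) {
    spec <- fixture_spec(seed = 30 + round(100 * sub), ref_len = 30000,
                         n_reads = 400, read_len = 100, sub_rate = sub,
                         revcomp_frac = 0.4, junk_frac = 0.1, n_frac = 0.05)
    ref <- gen_reference(spec)
    fx <- gen_fastq(spec, ref)
    idx <- build_index(ref, mapper_config())
    recs <- map_reads(fx$records$seq, idx, ref)
    expect_identical(reconstruct_reads(recs, ref), fx$records$seq)
    recs2 <- map_reads(fx$records$seq, idx, ref)
    expect_identical(recs, recs2)
  }
})

test_that("alignments never cross FASTA junctions", {
  p <- tempfile(fileext = ".fa")
  set.seed(55)
  left <- paste0(paste0(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""),
                 "CGAAAA")
  right <- "GGTGTTTTGGGGTTTT"
  writeLines(c(">a", left, ">b", right), p)
  ref <- read_fasta(p)
  unlink(p)
  expect_equal(ref$junctions, 16L)
  cfg <- small_cfg(k = 4L, prefix = "CG", L = 8L, e = 0, segment_len = 8L)
  idx <- build_index(ref, cfg)
  # a read copied straight across the junction cannot be mapped there
  read <- substr(ref$bases, 11, 26)
  rec <- map_read(read, idx, ref)
  for (seg in rec$segments) {
    if (seg$kind != "MAP") next
    expect_true(seg$ref_pos + seg$length <= 16 || seg$ref_pos >= 16)
  }
  expect_equal(reconstruct_read(rec, ref), read)
})

test_that("assemble_reference greedily merges overlapping reads", {
  r <- assemble_reference(rep("CGAAATGGC", 5), mapper_config())
  expect_equal(r$bases, "CGAAATGGC")

  r <- assemble_reference(c("CGAAAT", "AATTTG"), mapper_config(),
                          overlap_min = 3L)
  expect_equal(r$bases, "CGAAATTTG")

  expect_error(assemble_reference(c("AAAA", "TTTT"), mapper_config()),
               "prefix")

  # assembled reference supports round-trip compression
  spec <- fixture_spec(seed = 61, ref_len = 4000, n_reads = 150,
                       read_len = 90, sub_rate = 0)
  fx <- gen_fastq(spec, gen_reference(spec))
  arc <- fq_compress(fx$records, assemble = TRUE)
  expect_identical(fq_decompress(as.raw(arc)), fx$fastq)
})
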