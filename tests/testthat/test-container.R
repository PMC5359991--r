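test_that("partition_blocks yields contiguous ceiling-sized blocks", {
  spec <- fixture_spec(seed = 2, ref_len = 1000, n_reads = 10, read_len = 30)
  fx <- gen_fastq(spec, gen_reference(spec))

  blocks <- partition_blocks(fx$records, 10L)
  expect_length(blocks, 10)
  expect_true(all(vapply(blocks, length, 1L) == 1L))

  blocks <- partition_blocks(fx$records[1:7], 3L)
  expect_equal(vapply(blocks, length, 1L), c(3L, 3L, 1L))
  expect_identical(do.call(c, lapply(blocks, function(b) b$meta)),
                   fx$records$meta[1:7])

  expect_length(partition_blocks(fastq_records(), 10L), 0)
})

test_that("encode_bundle/decode_bundle invert each other, including all-RAW blocks", {
  spec <- fixture_spec(seed = 42, ref_len = 10000, n_reads = 80,
                       read_len = c(40, 120), sub_rate = 0.02,
                       revcomp_frac = 0.3, junk_frac = 0.1, plus_frac = 0.3)
  ref <- gen_reference(spec)
  fx <- gen_fastq(spec, ref)
  idx <- build_index(ref, mapper_config())
  cfg <- fqzip_config()
  mrec <- map_reads(fx$records$seq, idx, ref)
  st <- split_streams(fx$records)
  bundle <- encode_bundle(mrec, st$meta, st$plus, st$qual, cfg)
  expect_named(bundle, c("meta", "qual", "positions", "structure",
                         "mismatch", "rawseq"))
  dec <- decode_bundle(bundle, length(fx$records), cfg)
  expect_identical(dec$match_records, mrec)
  expect_identical(dec$meta, st$meta)
  expect_identical(dec$qual, st$qual)
  expect_identical(dec$plus$bare, st$plus$bare)
  expect_identical(dec$plus$literals, st$plus$literals)

  # junk-only input: every read is RAW, so positions and mismatch streams
  # carry no content (framing byte only)
  spec2 <- fixture_spec(seed = 43, ref_len = 5000, n_reads = 30,
                        read_len = 50, junk_frac = 1)
  fx2 <- gen_fastq(spec2, ref)
  mrec2 <- map_reads(fx2$records$seq, idx, ref)
  expect_true(all(vapply(mrec2, function(r) r$match_type, "") == "RAW"))
  st2 <- split_streams(fx2$records)
  bundle2 <- encode_bundle(mrec2, st2$meta, st2$plus, st2$qual, cfg)
  expect_equal(length(bundle2$positions), 1L)
  expect_equal(length(bundle2$mismatch), 1L)
  dec2 <- decode_bundle(bundle2, 30L, cfg)
  expect_identical(dec2$match_records, mrec2)
})

test_that("identical reads give a near-constant delta-coded position stream", {
  spec <- fixture_spec(seed = 44, ref_len = 20000)
  ref <- gen_reference(spec)
  idx <- build_index(ref, mapper_config())
  read <- substr(ref$bases, 1001, 1100)
  n <- 2000L
  mrec <- map_reads(rep(read, n), idx, ref)
  expect_true(all(vapply(mrec, function(r) r$match_type, "") == "FULL_EXACT"))
  cfg <- fqzip_config()
  bundle <- encode_bundle(mrec, sprintf("@r%d", 1:n),
                          list(bare = rep(TRUE, n), literals = character()),
                          rep(strrep("I", 100), n), cfg)
  expect_lt(length(bundle$positions), 0.01 * (4 * n))
})

test_that("compression round-trips byte-exactly across input shapes", {
  cases <- list(
    list(seed = 50, read_len = 75L, sub = 0.01, rc = 0.5, junk = 0, nf = 0.05,
         plus = 0.5, qm = "RUNNY"),
    list(seed = 51, read_len = c(40L, 300L), sub = 0.05, rc = 0, junk = 0.2,
         nf = 0, plus = 0, qm = "UNIFORM"),
    list(seed = 52, read_len = 30L, sub = 0, rc = 0, junk = 0, nf = 0,
         plus = 0, qm = "CONSTANT"))
  for (cs in cases) {
    spec <- fixture_spec(seed = cs$seed, ref_len = 8000, n_reads = 120,
                         read_len = cs$read_len, sub_rate = cs$sub,
                         revcomp_frac = cs$rc, junk_frac = cs$junk,
                         n_frac = cs$nf, plus_frac = cs$plus,
                         quality_model = cs$qm)
    ref <- gen_reference(spec)
    fx <- gen_fastq(spec, ref)
    arc <- fq_compress(fx$records, ref, fqzip_config(b = 4L))
    expect_identical(fq_decompress(as.raw(arc), ref), fx$fastq)
  }

  # empty file and single record
  ref <- gen_reference(fixture_spec(seed = 53, ref_len = 2000))
  arc <- fq_compress(fastq_records(), ref)
  expect_identical(fq_decompress(as.raw(arc), ref), raw(0))
  one <- read_fastq(charToRaw("@solo\nACGTNACGT\n+solo\n!!!!!!!!!\n"))
  arc <- fq_compress(one, ref)
  expect_identical(fq_decompress(as.raw(arc), ref), fastq_serialize(one))
})

test_that("damaged archives are rejected before any output", {
  spec <- fixture_spec(seed = 54, ref_len = 5000, n_reads = 60, read_len = 60)
  ref <- gen_reference(spec)
  fx <- gen_fastq(spec, ref)
  arc <- as.raw(fq_compress(fx$records, ref))

  expect_error(fq_decompress(arc[1:(length(arc) - 10)], ref), "corrupt")
  bad <- arc
  bad[length(bad) %/% 2] <- xor(bad[length(bad) %/% 2], as.raw(1))
  expect_error(fq_decompress(bad, ref), "corrupt")
  bad <- arc
  bad[5] <- as.raw(99) # version byte is checksummed too
  expect_error(fq_decompress(bad, ref), "corrupt|version")
  expect_error(fq_decompress(as.raw(1:5), ref), "corrupt")
})

test_that("per-block corruption reports the block index", {
  spec <- fixture_spec(seed = 55, ref_len = 5000, n_reads = 40, read_len = 60)
  ref <- gen_reference(spec)
  fx <- gen_fastq(spec, ref)
  arc <- as.raw(fq_compress(fx$records, ref, fqzip_config(b = 4L)))
  # corrupt a byte well inside the block payloads and re-seal the trailer
  body <- arc[1:(length(arc) - 8)]
  at <- length(body) - 200L
  body[at] <- xor(body[at], as.raw(0x40))
  resealed <- c(body, fnv64(body))
  expect_error(fq_decompress(resealed, ref), "block [0-9]+")
})

test_that("archive bytes are a pure function of input, independent of threads", {
  spec <- fixture_spec(seed = 56, ref_len = 10000, n_reads = 300,
                       read_len = 80, sub_rate = 0.02, revcomp_frac = 0.2)
  ref <- gen_reference(spec)
  fx <- gen_fastq(spec, ref)
  a1 <- as.raw(fq_compress(fx$records, ref, threads = 1L))
  a2 <- as.raw(fq_compress(fx$records, ref, threads = 4L))
  expect_identical(a1, a2)
})

test_that("the CLI compresses, verifies and decompresses files", {
  spec <- fixture_spec(seed = 57, ref_len = 6000, n_reads = 100, read_len = 70,
                       sub_rate = 0.01, plus_frac = 0.2)
  ref <- gen_reference(spec)
  fx <- gen_fastq(spec, ref)
  fq <- tmp_fastq(fx$fastq)
  fa <- tmp_fasta(ref)
  arc <- tempfile(fileext = ".lwf2")
  out <- tempfile(fileext = ".fastq")
  on.exit(unlink(c(fq, fa, arc, out)))

  code <- suppressMessages(
    fqzip_cli(c("compress", "-i", fq, "-r", fa, "-o", arc, "-b", "3",
                "--verify")))
  expect_equal(code, 0L)
  expect_true(file.exists(arc))
  expect_false(file.exists(paste0(arc, ".tmp")))

  code <- suppressMessages(
    fqzip_cli(c("decompress", "-i", arc, "-r", fa, "-o", out)))
  expect_equal(code, 0L)
  expect_identical(readBin(out, "raw", file.size(out)), fx$fastq)

  expect_equal(suppressMessages(
    fqzip_cli(c("verify", "-i", fq, "-r", fa))), 0L)

  # assembled-reference mode is self-contained
  arc2 <- tempfile(fileext = ".lwf2")
  out2 <- tempfile(fileext = ".fastq")
  on.exit(unlink(c(arc2, out2)), add = TRUE)
  expect_equal(suppressMessages(
    fqzip_cli(c("compress", "-i", fq, "-o", arc2, "-a"))), 0L)
  expect_equal(suppressMessages(
    fqzip_cli(c("decompress", "-i", arc2, "-o", out2))), 0L)
  expect_identical(readBin(out2, "raw", file.size(out2)), fx$fastq)

  expect_equal(suppressMessages(
    fqzip_cli(c("compress", "-i", "no-such-file.fq", "-r", fa, "-o", arc))),
    2L)
  expect_equal(suppressMessages(
    fqzip_cli(c("compress", "-i", fq, "-r", fa, "-o", arc,
                "--backend", "zpaq"))), 1L)
  expect_equal(suppressMessages(fqzip_cli(character())), 2L)
})
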