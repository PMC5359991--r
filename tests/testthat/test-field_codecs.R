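random_header <- function(style, i) {
  switch(style,
    sra = sprintf("@SRR%06d.%d length=%d", 42, i, sample(30:150, 1)),
    illumina = sprintf("@HWI-ST%d:%d:FC:%d:%d:%d:%d 1:N:0:%s",
                       sample(100:999, 1), sample(1:8, 1), sample(1:2, 1),
                       sample(1:100, 1), sample(1:25000, 1),
                       sample(1:25000, 1),
                       paste0(sample(c("A", "C", "G", "T"), 6, TRUE),
                              collapse = "")),
    pacbio = sprintf("@m%d_%06d/%d/0_%d", sample(50000:59999, 1),
                     sample(1:999999, 1), i, sample(500:8000, 1)))
}

test_that("meta_encode stores shared-prefix deltas and meta_decode inverts them", {
  enc <- meta_encode(c("@r1", "@r1"))
  expect_equal(enc$lcp, c(0L, 3L))
  expect_equal(enc$suffix, c("@r1", ""))

  enc <- meta_encode(c("@SRR001.1 len=100", "@SRR001.2 len=100"))
  expect_equal(enc$lcp[2], 8L)
  expect_equal(enc$suffix[2], "2 len=100")

  expect_equal(meta_encode("@only"), data.frame(lcp = 0L, suffix = "@only"))
  expect_equal(meta_decode(data.frame(lcp = 0L, suffix = "@a")), "@a")

  # m identical lines give m-1 empty suffixes
  enc <- meta_encode(rep("@same header", 20))
  expect_equal(sum(enc$suffix == ""), 19L)

  expect_error(meta_decode(data.frame(lcp = 5L, suffix = "x")), "corruption")
})

test_that("metadata delta coding round-trips across header dialects", {
  set.seed(83)
  for (style in c("sra", "illumina", "pacbio")) {
    lines <- vapply(1:200, function(i) random_header(style, i), character(1))
    expect_identical(meta_decode(meta_encode(lines)), lines)
  }
  # arbitrary printable strings, including empties
  lines <- vapply(1:200, function(i) {
    paste0(sample(strsplit(rawToChar(as.raw(32:126)), "")[[1]],
                  sample(0:40, 1), TRUE), collapse = "")
  }, character(1))
  expect_identical(meta_decode(meta_encode(lines)), lines)
})

test_that("rll_encode tokenizes runs with the cap-splitting rule", {
  tok <- rll_encode("IIIII", run_min = 2L, run_cap = 255L)
  expect_equal(tok$kind, "RUN")
  expect_equal(tok$symbol, "I")
  expect_equal(tok$count, 5L)

  tok <- rll_encode("AB")
  expect_equal(tok$kind, c("LITERAL", "LITERAL"))
  expect_equal(tok$symbol, c("A", "B"))

  tok <- rll_encode(strrep("#", 300), run_cap = 255L)
  expect_equal(tok$kind, c("RUN", "RUN"))
  expect_equal(tok$count, c(255L, 45L))

  # a sub-run_min remainder falls back to literals
  tok <- rll_encode(strrep("#", 257), run_min = 3L, run_cap = 255L)
  expect_equal(tok$kind, c("RUN", "LITERAL", "LITERAL"))

  # constant string of length n costs ceiling(n / run_cap) tokens
  tok <- rll_encode(strrep("Q", 1020), run_cap = 255L)
  expect_equal(nrow(tok), 4L)

  expect_equal(nrow(rll_encode("")), 0L)
})

test_that("rll_decode inverts rll_encode and rejects out-of-range runs", {
  expect_equal(rll_decode(rll_encode("")), "")
  expect_error(rll_decode(data.frame(kind = "RUN", symbol = "I", count = 1L)),
               "corruption")
  expect_error(rll_decode(data.frame(kind = "RUN", symbol = "I", count = 999L)),
               "corruption")

  set.seed(84)
  alphabet <- strsplit(rawToChar(as.raw(33:73)), "")[[1]]
  for (i in 1:150) {
    # mix of short random stretches and long runs (PacBio-like plateaus)
    parts <- vapply(1:sample(1:8, 1), function(j) {
      if (runif(1) < 0.5)
        paste0(sample(alphabet, sample(1:30, 1), TRUE), collapse = "")
      else strrep(sample(alphabet, 1), sample(c(2:10, 250:300), 1))
    }, character(1))
    q <- paste0(parts, collapse = "")
    expect_identical(rll_decode(rll_encode(q)), q)
    expect_lte(nrow(rll_encode(q)), nchar(q))
  }
})

test_that("the batch quality planes agree with the per-string token codec", {
  set.seed(85)
  quals <- vapply(1:60, function(i) {
    paste0(strrep(sample(LETTERS, sample(1:6, 1), TRUE),
                  sample(1:300, sample(1:6, 1), TRUE)), collapse = "")
  }, character(1))
  planes <- fqzip:::.c_rll_pack(quals, 3L, 255L)
  # the control plane is 0 for literals and the run length otherwise
  toks <- do.call(rbind, lapply(quals, rll_encode))
  expect_equal(length(planes$control), nrow(toks))
  expect_equal(as.integer(planes$control),
               ifelse(toks$kind == "RUN", toks$count, 0L))
  expect_equal(rawToChar(planes$symbols), paste0(toks$symbol, collapse = ""))
  back <- fqzip:::.c_rll_unpack(planes$symbols, planes$control,
                                nchar(quals), 3L, 255L)
  expect_identical(back, quals)
})
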