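test_that("the bit predictor follows the smoothed counter rule", {
  p <- bit_predictor(order_bits = 1L, counter_cap = 255L, delta = 1L)
  expect_equal(predictor_prob(p), 0.5)

  # revisit context 0 after observing a single 1 bit there: (1+1)/(1+2)
  predictor_update(p, 1) # context 0 -> counts (0,1), register now 1
  predictor_update(p, 0) # context 1 -> counts (1,0), register now 0
  st <- predictor_state(p)
  expect_equal(st$context, 0)
  expect_equal(c(st$n0, st$n1), c(0, 1))
  expect_equal(predictor_prob(p), 2 / 3)

  # heavy one-sided evidence drives the probability near 0 despite capping
  p <- bit_predictor(order_bits = 1L, counter_cap = 255L, delta = 1L)
  for (i in 1:1000) predictor_update(p, 0)
  expect_lt(predictor_prob(p), 0.01)
  st <- predictor_state(p)
  expect_lte(st$n0, 255)

  # the context register shifts the coded bits in (1,0,1 -> ...101)
  p <- bit_predictor(order_bits = 8L)
  for (b in c(1, 0, 1)) predictor_update(p, b)
  expect_equal(predictor_state(p)$context, 5)
})

test_that("stream coding is a bijection for arbitrary payloads", {
  expect_equal(length(encode_stream(raw(0))), 1L)
  expect_identical(decode_stream(encode_stream(raw(0))), raw(0))

  set.seed(101)
  for (i in 1:120) {
    n <- sample(0:3000, 1)
    x <- as.raw(sample(0:255, n, TRUE))
    ord <- sample(c(1L, 8L, 16L, 32L), 1)
    expect_identical(decode_stream(encode_stream(x, ord), ord), x)
  }
})

test_that("corrupted or truncated streams are detected", {
  x <- as.raw(sample(0:255, 500, TRUE))
  coded <- encode_stream(x)
  expect_error(decode_stream(coded[1:(length(coded) - 3)]), "corrupt|trunc")
  flipped <- coded
  flipped[10] <- xor(flipped[10], as.raw(0xFF))
  expect_error(decode_stream(flipped), "corrupt|trunc|checksum")
  # decoding under a different model order is not required to succeed,
  # but must never silently return wrong bytes
  res <- tryCatch(decode_stream(coded, order_bits = 8L), error = function(e) NULL)
  if (!is.null(res)) expect_false(identical(res, x))
})

test_that("the adaptive model approaches strongly skewed and fair sources", {
  zeros <- integer(1e4)
  coded <- encode_bits(zeros, order_bits = 1L)
  expect_lt(length(coded), 100)
  expect_identical(decode_bits(coded, order_bits = 1L), zeros)

  set.seed(102)
  fair <- as.integer(runif(1e6) < 0.5)
  coded <- encode_bits(fair, order_bits = 1L)
  expect_lt(abs(length(coded) - 125000), 1250)
})

test_that("order-32 context modelling exploits periodic byte patterns", {
  pattern <- rep(as.raw(c(0x12, 0x34, 0xAB, 0xCD)), 4096) # 16 KiB
  coded <- encode_stream(pattern, 32L)
  expect_lt(length(coded), 0.02 * length(pattern))
  expect_identical(decode_stream(coded, 32L), pattern)
})

test_that("base coding packs 2 bits per base under an order-28 model", {
  expect_equal(length(encode_bases("")), 1L)
  expect_identical(decode_bases(encode_bases("")), "")
  expect_error(encode_bases("ACGN"), "outside")

  b <- paste(rep("ACGT", 4096), collapse = "")
  coded <- encode_bases(b)
  expect_lt(length(coded), 0.05 * (nchar(b) / 4)) # vs 2-bit-packed size
  expect_identical(decode_bases(coded), b)

  set.seed(103)
  for (i in 1:40) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(0:800, 1), TRUE),
                collapse = "")
    expect_identical(decode_bases(encode_bases(s)), s)
  }
})

test_that("the order-0 baseline coder round-trips and ignores cross-byte context", {
  set.seed(104)
  x <- as.raw(sample(0:255, 2000, TRUE))
  expect_identical(decode_order0(encode_order0(x)), x)
  # a 4-byte period is invisible to an order-0 model: stays near 8 bits/byte
  pattern <- rep(as.raw(c(0x12, 0x34, 0xAB, 0xCD)), 4096)
  expect_gt(length(encode_order0(pattern)), 0.24 * length(pattern))
})
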