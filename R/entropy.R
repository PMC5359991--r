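# Entropy-coding back end: an adaptive bitwise context model driving a
# binary arithmetic coder. General byte streams use an order-32 bit context
# (the previous 4 bytes); the 2-bit-packed mismatch-base stream uses order
# 28. Per-context counters (n0, n1) give p1 = (n1+delta)/(n0+n1+2*delta);
# an unseen context predicts 1/2. When a counter passes counter_cap both
# are halved (rounding up), keeping the model adaptive while the estimate
# converges towards the source statistics. The coding path is integer-only,
# so output bytes are identical across platforms.

ORDER_GENERAL <- 32L
ORDER_BASES <- 28L
DEFAULT_CAP <- 1023L
DEFAULT_DELTA <- 1L

as_payload <- function(x) {
  if (is.character(x)) charToRaw(paste0(x, collapse = "")) else {
    stopifnot(is.raw(x)); x
  }
}

#' Entropy-code a byte stream
#'
#' Frames the payload as `[varint length][arithmetic-coded body][8-byte
#' FNV-1a checksum of the payload]`; an empty payload is the single varint
#' byte. Deterministic: identical input gives identical bytes.
#'
#' @param payload A raw vector (or a character scalar, taken as its bytes).
#' @param order_bits Context length in bits (1-32); 32 for general streams.
#' @param counter_cap Per-context counter cap before both counts are halved.
#' @param delta Additive (Laplace) smoothing constant, a positive integer.
#' @return Raw vector of compressed bytes.
#' @export
encode_stream <- function(payload, order_bits = ORDER_GENERAL,
                          counter_cap = DEFAULT_CAP, delta = DEFAULT_DELTA) {
  .c_encode_stream(as_payload(payload), order_bits, counter_cap, delta)
}

#' @rdname encode_stream
#' @param coded Raw vector produced by [encode_stream()] with the same model
#'   parameters.
#' @export
decode_stream <- function(coded, order_bits = ORDER_GENERAL,
                          counter_cap = DEFAULT_CAP, delta = DEFAULT_DELTA) {
  .c_decode_stream(coded, order_bits, counter_cap, delta)
}

#' Entropy-code a nucleotide string
#'
#' Packs bases 2 bits each (A=00, C=01, G=10, T=11) and codes them bitwise
#' under an order-28 context model; characters outside `{A,C,G,T}` are an
#' error (the mapper routes such reads to the raw stream instead).
#'
#' @param bases A string over `{A,C,G,T}`.
#' @inheritParams encode_stream
#' @return Raw vector of compressed bytes.
#' @export
encode_bases <- function(bases, order_bits = ORDER_BASES,
                         counter_cap = DEFAULT_CAP, delta = DEFAULT_DELTA) {
  .c_encode_bases(bases, order_bits, counter_cap, delta)
}

#' @rdname encode_bases
#' @param coded Raw vector produced by [encode_bases()].
#' @export
decode_bases <- function(coded, order_bits = ORDER_BASES,
                         counter_cap = DEFAULT_CAP, delta = DEFAULT_DELTA) {
  .c_decode_bases(coded, order_bits, counter_cap, delta)
}

#' Entropy-code a raw bit vector
#'
#' Codes individual bits under the adaptive model; mainly useful for
#' studying the coder against entropy bounds on synthetic bit sources.
#'
#' @param bits Integer vector of 0/1 values.
#' @inheritParams encode_stream
#' @return Raw vector of compressed bytes.
#' @export
encode_bits <- function(bits, order_bits = 1L, counter_cap = DEFAULT_CAP,
                        delta = DEFAULT_DELTA) {
  .c_encode_bits(as.integer(bits), order_bits, counter_cap, delta)
}

#' @rdname encode_bits
#' @param coded Raw vector produced by [encode_bits()].
#' @export
decode_bits <- function(coded, order_bits = 1L, counter_cap = DEFAULT_CAP,
                        delta = DEFAULT_DELTA) {
  .c_decode_bits(coded, order_bits, counter_cap, delta)
}

#' Byte-wise order-0 baseline coder
#'
#' Adaptive order-0 model (context = the bits of the current byte seen so
#' far, reset each byte) with the same arithmetic coder; a generic baseline
#' with no cross-byte context, useful as a yardstick for the reference-based
#' path.
#'
#' @inheritParams encode_stream
#' @return Raw vector of compressed bytes.
#' @export
encode_order0 <- function(payload, counter_cap = DEFAULT_CAP,
                          delta = DEFAULT_DELTA) {
  .c_encode_order0(as_payload(payload), counter_cap, delta)
}

#' @rdname encode_order0
#' @param coded Raw vector produced by [encode_order0()].
#' @export
decode_order0 <- function(coded, counter_cap = DEFAULT_CAP,
                          delta = DEFAULT_DELTA) {
  .c_decode_order0(coded, counter_cap, delta)
}

#' Adaptive bit predictor handle
#'
#' A stateful per-context bit-probability model, exposed for inspection and
#' testing; [encode_stream()] and friends run the same model internally, in
#' lockstep between encoder and decoder.
#'
#' @inheritParams encode_stream
#' @return An object of class `"bit_predictor"`.
#' @export
bit_predictor <- function(order_bits = ORDER_GENERAL, counter_cap = DEFAULT_CAP,
                          delta = DEFAULT_DELTA) {
  structure(list(ptr = .c_bp_new(order_bits, counter_cap, delta),
                 order_bits = order_bits, counter_cap = counter_cap,
                 delta = delta),
            class = "bit_predictor")
}

#' @rdname bit_predictor
#' @param predictor A `bit_predictor`.
#' @return `predictor_prob()`: the probability of a 1 bit in the current
#'   context (1/2 for an unseen context); does not change state.
#' @export
predictor_prob <- function(predictor) .c_bp_predict(predictor$ptr)

#' @rdname bit_predictor
#' @param bit 0 or 1.
#' @export
predictor_update <- function(predictor, bit) {
  .c_bp_update(predictor$ptr, as.integer(bit))
  invisible(predictor)
}

#' @rdname bit_predictor
#' @return `predictor_state()`: list with the current context's counts `n0`,
#'   `n1` and the rolling `context` register value.
#' @export
predictor_state <- function(predictor) .c_bp_state(predictor$ptr)
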