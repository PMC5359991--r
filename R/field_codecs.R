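# Reversible pre-transforms for the non-nucleotide streams: incremental
# (shared-prefix delta) coding of metadata lines and run-length-limited
# coding of quality strings. Both are exact bijections; the entropy coder
# does the actual size reduction downstream.

#' Incremental (delta) encoding of metadata lines
#'
#' Each line is stored as the length of its longest common prefix with the
#' previous line plus the remaining suffix; the first line is delta'd
#' against the empty string.
#'
#' @param lines Character vector of metadata lines.
#' @return A data frame with integer column `lcp` and character column
#'   `suffix`, one row per line.
#' @export
meta_encode <- function(lines) {
  lcp <- .c_lcp_lengths(as.character(lines))
  data.frame(lcp = lcp, suffix = substring(lines, lcp + 1L),
             stringsAsFactors = FALSE)
}

#' Decode incrementally encoded metadata lines
#'
#' Exact inverse of [meta_encode()].
#'
#' @param deltas A data frame as returned by [meta_encode()].
#' @return Character vector of lines.
#' @export
meta_decode <- function(deltas) {
  n <- nrow(deltas)
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    lcp <- deltas$lcp[i]
    if (lcp > nchar(prev))
      stop(sprintf("corruption error: metadata delta %d has prefix length %d > previous line length %d",
                   i, lcp, nchar(prev)))
    out[i] <- paste0(substr(prev, 1L, lcp), deltas$suffix[i])
    prev <- out[i]
  }
  out
}

#' Run-length-limited encoding of a quality string
#'
#' Maximal left-to-right munch: repeats of length at least `run_min` become
#' RUN tokens, capped at `run_cap` (longer runs split; a sub-`run_min`
#' remainder falls back to literals); everything else is a LITERAL token.
#'
#' @param qual A single quality string.
#' @param run_min Minimum repeat length coded as a run (at least 2).
#' @param run_cap Maximum run length per token (at most 255).
#' @return A data frame with columns `kind` (`"LITERAL"` or `"RUN"`),
#'   `symbol` (single character) and `count` (`NA` for literals).
#' @export
rll_encode <- function(qual, run_min = 3L, run_cap = 255L) {
  stopifnot(run_min >= 2, run_cap <= 255, run_cap >= run_min)
  kind <- character(); symbol <- character(); count <- integer()
  if (nchar(qual) > 0) {
    r <- rle(strsplit(qual, "", fixed = TRUE)[[1]])
    for (i in seq_along(r$lengths)) {
      rem <- r$lengths[i]
      while (rem > 0) {
        chunk <- min(rem, run_cap)
        if (chunk >= run_min) {
          kind <- c(kind, "RUN"); symbol <- c(symbol, r$values[i])
          count <- c(count, chunk)
          rem <- rem - chunk
        } else {
          kind <- c(kind, rep("LITERAL", rem))
          symbol <- c(symbol, rep(r$values[i], rem))
          count <- c(count, rep(NA_integer_, rem))
          rem <- 0
        }
      }
    }
  }
  data.frame(kind = kind, symbol = symbol, count = count,
             stringsAsFactors = FALSE)
}

#' Decode a run-length-limited token stream
#'
#' Exact inverse of [rll_encode()].
#'
#' @param tokens A data frame as returned by [rll_encode()].
#' @param run_min,run_cap Must match the encoding parameters; RUN counts
#'   outside `[run_min, run_cap]` raise a corruption error.
#' @return The decoded quality string.
#' @export
rll_decode <- function(tokens, run_min = 3L, run_cap = 255L) {
  if (nrow(tokens) == 0) return("")
  run <- tokens$kind == "RUN"
  bad <- run & (is.na(tokens$count) | tokens$count < run_min | tokens$count > run_cap)
  if (any(bad))
    stop(sprintf("corruption error: RUN token %d has count outside [%d, %d]",
                 which(bad)[1], run_min, run_cap))
  reps <- ifelse(run, tokens$count, 1L)
  paste0(strrep(tokens$symbol, reps), collapse = "")
}
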