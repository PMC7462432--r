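# Classed conditions so callers can distinguish failure modes programmatically.
adhStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("adh_", class), "adh_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

adhWarn <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(paste0("adh_", class), "adh_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a child seed from a run seed
#'
#' Deterministically maps a run seed plus a sequence of integer tags (e.g.
#' repetition index, node index, threshold index) to a new seed, so that
#' every stochastic operation in a run receives an explicit, reproducible
#' seed and no two operations share one. A Lehmer-style multiplicative
#' congruential step keeps all values inside the 32-bit signed range.
#'
#' @param seed Integer run seed.
#' @param ... Integer tags identifying the operation.
#' @return A single integer in `[1, 2^31 - 43]`.
#' @export
#' @examples
#' deriveSeed(1, 3, 7)
deriveSeed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483587
  for (x in c(tags, 0)) {
    s <- (s * 48271 + as.double(x) + 1) %% 2147483587
  }
  as.integer(s) + 1L
}

# Sniff the field separator of a delimited text file from its first line.
sniffSep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) adhStop("emptyFile", "file '%s' is empty", path)
  if (grepl("\t", line)) "\t" else ","
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
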