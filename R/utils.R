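#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x)))
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## split a UTF-8 string into single characters
chars <- function(x) strsplit(x, "", fixed = FALSE)[[1]]

## 0-based half-open slice of a string by character offsets
substr0 <- function(text, start, end) substr(text, start + 1L, end)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

## round half up to integer (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
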