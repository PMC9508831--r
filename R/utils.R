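#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  cpp_revcomp(as.character(x))
}

## Phred+33 helpers ---------------------------------------------------------

phred_to_string <- function(phred) {
  vapply(phred, function(p) rawToChar(as.raw(pmin(p, 93L) + 33L)), character(1))
}

string_to_phred <- function(qstr) {
  lapply(qstr, function(s) as.integer(charToRaw(s)) - 33L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## shared parameter validation
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("%s must be a single value in [0, 1]", name)
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stopf("%s must be a single number >= %d", name, min)
  as.integer(x)
}
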