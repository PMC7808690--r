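# Small sequence helpers shared across modules. All sequences are uppercase
# A/C/G/T/N character strings; N never matches a motif symbol.

#' Complement of a DNA string (vectorised)
#' @param x character vector of DNA strings (A/C/G/T/N)
#' @return complemented strings, same orientation
#' @keywords internal
comp_chr <- function(x) chartr("ACGTN", "TGCAN", x)

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  out <- vapply(strsplit(comp_chr(x), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
  out[is.na(x)] <- NA_character_
  out
}

# IUPAC nucleotide codes -> the set of concrete bases they stand for.
# N deliberately matches only A/C/G/T: an N base in the sequence matches
# nothing (unknown bases are never counted as motif matches).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Test bases against an IUPAC symbol
#' @param bases character vector of single bases (may include "N")
#' @param code single IUPAC symbol
#' @return logical vector; N bases never match
#' @keywords internal
iupac_match <- function(bases, code) {
  set <- IUPAC_SETS[[toupper(code)]]
  if (is.null(set)) stop("unknown IUPAC symbol: ", code)
  bases %in% set
}

#' IUPAC symbol for the complement of an IUPAC symbol
#' @keywords internal
iupac_comp <- function(code) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(code))
}

# stopifnot-style check with a custom message
check_that <- function(ok, ...) if (!isTRUE(ok)) stop(..., call. = FALSE)

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  neq <- which(av != bv | av == "N")
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# longest common suffix length of two strings
lcs_len <- function(a, b) {
  ra <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  rb <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
  lcp_len(ra, rb)
}
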