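#' Round half away from zero
#'
#' Fixed-precision rounding in the "half-up" convention used by the package's
#' report tables (base [round()] rounds half to even, which does not reproduce
#' printed Mean+/-SD cells such as 66.39 from a mean of 66.385).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(66.385, 2)  # 66.39; round() would give 66.38
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, IUPAC allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## sample a random sequence at given base frequencies
random_seq <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  freqs <- freqs / sum(freqs)
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## split a sequence into an integer vector (utf8 codes) for fast comparisons
seq_ints <- function(s) utf8ToInt(toupper(s))

## format "min~max" collapsing equal bounds, mirroring the tilde notation of
## multi-genome gene tables
range_tilde <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  lo <- min(x); hi <- max(x)
  if (lo == hi) format(lo) else paste0(format(lo), "~", format(hi))
}

stopifnot_scalar_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string", call. = FALSE)
}
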