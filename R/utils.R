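#' Round half away from zero
#'
#' Fixed-precision rounding where exact halves round up (away from zero),
#' the convention used throughout the package's report tables. Base R's
#' `round()` rounds halves to even, which does not reproduce tabulated
#' percentages such as 36.1 or 50.63 from their raw ratios.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percent with fixed decimals, half-up
pct <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# reverse complement of a plain character nucleotide string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# translate a CDS (with terminal stop codon) into its protein, dropping the
# terminal stop; internal stops raise an error unless allow_internal_stop.
translate_cds <- function(nt, code = "11", allow_internal_stop = FALSE) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode(code),
    if.fuzzy.codon = "solve"
  ))
  aa <- sub("\\*$", "", aa)
  if (!allow_internal_stop && grepl("\\*", aa)) {
    abort("internal stop codon in CDS translation")
  }
  aa
}
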