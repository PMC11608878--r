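# IUPAC nucleotide ambiguity machinery shared across modules.

.IUPAC_TWO <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
.IUPAC_THREE <- c(B = "CGT", D = "AGT", H = "ACT", V = "ACG")
.IUPAC_ALL <- c("A", "C", "G", "T", "N", "-",
                names(.IUPAC_TWO), names(.IUPAC_THREE))
.BASES <- c("A", "C", "G", "T")

#' Two-base IUPAC code for an unordered base pair
#'
#' Returns the single-letter ambiguity code for a pair of (possibly equal)
#' bases; equal bases return the base itself.
#'
#' @param a,b single bases in `A`, `C`, `G`, `T`.
#' @return A single character.
#' @examples
#' iupac_code("A", "C")  # "M"
#' @export
iupac_code <- function(a, b) {
  stopifnot(a %in% .BASES, b %in% .BASES)
  if (a == b) return(a)
  key <- paste(sort(c(a, b)), collapse = "")
  names(.IUPAC_TWO)[match(key, .IUPAC_TWO)]
}

#' Expand a two-base IUPAC code into its two bases
#'
#' Plain bases expand to two copies of themselves; three/four-base codes are
#' an error (they must be masked to `N` first).
#'
#' @param code single character.
#' @return Character vector of length 2 (sorted).
#' @export
iupac_expand <- function(code) {
  if (code %in% .BASES) return(c(code, code))
  hit <- .IUPAC_TWO[match(code, names(.IUPAC_TWO))]
  if (is.na(hit)) {
    stop("cannot expand '", code,
         "': not a base or two-base IUPAC code (mask triple codes first)")
  }
  strsplit(unname(hit), "")[[1]]
}

.is_het_code <- function(chars) chars %in% names(.IUPAC_TWO)

.seq_to_chars <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) strsplit(seq, "")[[1]] else seq
}

.chars_to_seq <- function(chars) paste(chars, collapse = "")
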