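#' The 20 standard amino-acid one-letter codes
#'
#' Alphabet used throughout for epitopes, flanks, spacers and scoring-model
#' rows. Order is alphabetical and fixed; parameter tables are validated
#' against it.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Split a peptide into its residue characters.
aa_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# TRUE when every character of every element is a standard residue code.
is_valid_peptide <- function(x) {
  vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) length(ch) > 0L && all(ch %in% AA_ALPHABET),
    logical(1)
  )
}

assert_peptide <- function(x, what = "peptide") {
  bad <- !is_valid_peptide(x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-standard residue characters: %s",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}
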