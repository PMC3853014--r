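#' Read an HLA genotypic-frequency table
#'
#' Two-column TSV with header `allele<TAB>frequency`. Frequencies are
#' genotypic frequencies (fraction of individuals carrying the allele) and
#' must lie in \[0, 1\]. Duplicate alleles are an error. An empty table is
#' valid: every lookup then returns 0 with a warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `allele`, `frequency`.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("frequency table not found: %s", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    allele = readr::col_character(),
    frequency = readr::col_double()
  ), comment = "#", progress = FALSE)
  validate_frequency_table(tbl)
}

validate_frequency_table <- function(tbl) {
  if (!all(c("allele", "frequency") %in% names(tbl))) {
    abort("frequency table must have columns 'allele' and 'frequency'")
  }
  if (anyDuplicated(tbl$allele)) {
    abort(sprintf(
      "duplicate allele(s) in frequency table: %s",
      paste(unique(tbl$allele[duplicated(tbl$allele)]), collapse = ", ")
    ))
  }
  bad <- !is.finite(tbl$frequency) | tbl$frequency < 0 | tbl$frequency > 1
  if (any(bad)) {
    abort(sprintf(
      "frequency out of [0, 1] for allele(s): %s",
      paste(tbl$allele[bad], collapse = ", ")
    ))
  }
  as_tibble(tbl[, c("allele", "frequency")])
}

#' Build a frequency table in memory
#'
#' @param alleles Character vector of HLA allele names.
#' @param frequencies Genotypic frequencies in \[0, 1\].
#' @return Frequency tibble (`allele`, `frequency`).
#' @export
frequency_table <- function(alleles = character(0), frequencies = numeric(0)) {
  validate_frequency_table(tibble(allele = alleles, frequency = frequencies))
}

# Frequency lookup; unknown alleles are 0 with a one-shot warning (dbMHC-style
# tables are incomplete, so missingness is expected, not fatal).
lookup_frequency <- function(freqs, alleles) {
  if (length(alleles) == 0L) return(numeric(0))
  idx <- match(alleles, freqs$allele)
  if (anyNA(idx)) {
    warn(sprintf(
      "allele(s) absent from frequency table, using frequency 0: %s",
      paste(unique(alleles[is.na(idx)]), collapse = ", ")
    ))
  }
  out <- freqs$frequency[idx]
  out[is.na(out)] <- 0
  out
}
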