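#' Read a CTL epitope list
#'
#' Plain-text format: one peptide per line, optionally followed by a tab and
#' a comma-separated list of restricting HLA alleles. `#` starts a comment.
#' Duplicate peptide sequences are collapsed into a single epitope whose
#' allele annotations are merged (a warning reports the collapse). Ids are
#' auto-assigned `e1...eN` in input order.
#'
#' @param path Path to the epitope file.
#' @param config A [design_config()]; epitope lengths are validated against
#'   `config$epitope_lengths`.
#' @return A tibble with columns `id`, `sequence`, and list-column
#'   `alleles`.
#' @examples
#' f <- tempfile()
#' writeLines(c("SLYNTVATL\tHLA-A*02:01", "ILKEPVHGV"), f)
#' read_epitopes(f)
#' @export
read_epitopes <- function(path, config = design_config()) {
  if (!file.exists(path)) abort(sprintf("epitope file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  lines <- trimws(raw[keep])
  if (length(lines) == 0L) abort("no epitopes: file contains no peptide lines")

  parts <- strsplit(lines, "\t", fixed = TRUE)
  seqs <- toupper(vapply(parts, `[[`, character(1), 1L))
  alleles <- map(parts, function(p) {
    if (length(p) < 2L) character(0)
    else unique(trimws(strsplit(p[[2]], ",", fixed = TRUE)[[1]]))
  })

  bad <- !is_valid_peptide(seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "line %d: '%s' is not a valid peptide (non-standard residue character)",
      lineno[i], seqs[i]
    ))
  }
  len <- nchar(seqs)
  out_of_bounds <- len < config$epitope_lengths[1] | len > config$epitope_lengths[2]
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1]
    abort(sprintf(
      "line %d: epitope '%s' has length %d, outside configured bounds [%d, %d]",
      lineno[i], seqs[i], len[i],
      config$epitope_lengths[1], config$epitope_lengths[2]
    ))
  }

  if (anyDuplicated(seqs)) {
    dup <- unique(seqs[duplicated(seqs)])
    warn(sprintf(
      "collapsed %d duplicate epitope sequence(s): %s",
      length(dup), paste(dup, collapse = ", ")
    ))
    first <- !duplicated(seqs)
    merged <- lapply(seqs[first], function(s) {
      unique(unlist(alleles[seqs == s], use.names = FALSE))
    })
    seqs <- seqs[first]
    alleles <- merged
  }

  tibble(
    id = paste0("e", seq_along(seqs)),
    sequence = seqs,
    alleles = alleles
  )
}

#' Build an epitope table from sequences in memory
#'
#' Programmatic counterpart of [read_epitopes()].
#'
#' @param sequences Character vector of peptides.
#' @param alleles Optional list of restricting-allele character vectors,
#'   one per peptide.
#' @param ids Optional ids; defaults to `e1...eN`.
#' @return Epitope tibble (`id`, `sequence`, `alleles`).
#' @export
epitope_table <- function(sequences, alleles = NULL, ids = NULL) {
  sequences <- toupper(sequences)
  assert_peptide(sequences, "epitope sequence")
  if (is.null(ids)) ids <- paste0("e", seq_along(sequences))
  if (anyDuplicated(ids)) abort("epitope ids must be unique")
  if (is.null(alleles)) alleles <- rep(list(character(0)), length(sequences))
  tibble(id = ids, sequence = sequences, alleles = alleles)
}
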