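#' TAP-binding scoring matrix
#'
#' Additive model of peptide affinity for the TAP transporter in which the
#' first three N-terminal residues (roles N1, N2, N3) and the C-terminal
#' residue (role C) are the contributing positions. Higher score means
#' better TAP binding; the parameter file must declare this orientation in
#' its header to avoid sign drift between sources.
#'
#' @param scores Numeric 20 x 4 matrix, rownames the 20 residues
#'   ([AA_ALPHABET]), colnames `N1`, `N2`, `N3`, `C`.
#' @return Object of class `"tap_matrix"`.
#' @export
tap_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (!setequal(rownames(scores), AA_ALPHABET)) {
    abort("TAP matrix must have one row per standard residue")
  }
  if (!identical(colnames(scores), c("N1", "N2", "N3", "C"))) {
    abort("TAP matrix columns must be N1, N2, N3, C (in that order)")
  }
  if (!all(is.finite(scores))) abort("TAP matrix contains non-finite scores")
  structure(
    list(scores = scores[AA_ALPHABET, , drop = FALSE]),
    class = "tap_matrix"
  )
}

#' Read a TAP matrix file
#'
#' TSV with rows = the 20 residues and columns `residue`, `N1`, `N2`, `N3`,
#' `C`. The header comment `#orientation: higher=better` is required.
#'
#' @param path Path to the file.
#' @return A `tap_matrix`.
#' @export
read_tap_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("TAP matrix file not found: %s", path))
  hdr <- readLines(path, n = 5L, warn = FALSE)
  if (!any(grepl("^#\\s*orientation:\\s*higher=better", hdr))) {
    abort("TAP matrix file must declare '#orientation: higher=better'")
  }
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    residue = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(tbl[, c("N1", "N2", "N3", "C")])
  rownames(m) <- tbl$residue
  tap_matrix(m)
}

#' Write a TAP matrix file
#'
#' @param matrix A `tap_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tap_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "tap_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#orientation: higher=better", con)
  writeLines(paste(c("residue", colnames(matrix$scores)), collapse = "\t"), con)
  for (r in rownames(matrix$scores)) {
    writeLines(
      paste(c(r, sprintf("%.6f", matrix$scores[r, ])), collapse = "\t"),
      con
    )
  }
  invisible(path)
}

#' Score peptides for TAP binding
#'
#' Additive score over the four contributing positions:
#' `N1[p1] + N2[p2] + N3[p3] + C[p_last]`. Positions beyond N1-N3 and C
#' contribute zero.
#'
#' @param peptide Character vector of peptides, each of length >= 4.
#' @param matrix A `tap_matrix`.
#' @return Numeric vector of scores (higher = better TAP binding).
#' @export
score_tap <- function(peptide, matrix) {
  stopifnot(inherits(matrix, "tap_matrix"))
  assert_peptide(peptide, "peptide")
  if (any(nchar(peptide) < 4L)) {
    abort("TAP scoring requires peptides of length >= 4")
  }
  m <- matrix$scores
  idx <- function(ch) {
    i <- match(ch, AA_ALPHABET)
    if (anyNA(i)) abort("residue absent from TAP matrix")
    i
  }
  m[idx(substr(peptide, 1L, 1L)), "N1"] +
    m[idx(substr(peptide, 2L, 2L)), "N2"] +
    m[idx(substr(peptide, 3L, 3L)), "N3"] +
    m[idx(substr(peptide, nchar(peptide), nchar(peptide))), "C"]
}

# All flank candidates of length 0..max_flank, shortest first then
# lexicographic (20 + 400 + 8000 strings at max_flank = 3).
flank_candidates <- function(max_flank = 3L) {
  out <- ""
  for (k in seq_len(max_flank)) {
    grid <- expand.grid(
      rep(list(AA_ALPHABET), k),
      stringsAsFactors = FALSE
    )
    out <- c(out, sort(do.call(paste0, grid)))
  }
  out
}

#' Select an N-terminal flank optimizing TAP transport
#'
#' Epitopes already scoring at or above `tap_threshold` are left unflanked.
#' Otherwise every flank of length 1 to `max_flank` is searched exhaustively
#' and the shortest flank reaching the threshold is returned (ties within
#' that length: highest score, then lexicographic). If no flank reaches the
#' threshold, the candidate (including the empty flank) with the maximal
#' score wins, ties broken by shorter flank then lexicographic order — so
#' the flanked score never falls below the unflanked score.
#'
#' @param sequence A single epitope sequence.
#' @param matrix A `tap_matrix`.
#' @param config A [design_config()]; uses `tap_threshold` and `max_flank`.
#' @return One-row tibble: `flank`, `full_sequence`, `tap_before`,
#'   `tap_after`.
#' @export
select_flank <- function(sequence, matrix, config = design_config(tap_threshold = 0)) {
  stopifnot(length(sequence) == 1L)
  thr <- config$tap_threshold
  if (is.null(thr)) {
    abort("select_flank needs a numeric tap_threshold (see flank_epitopes for self-calibration)")
  }
  before <- score_tap(sequence, matrix)
  if (config$max_flank == 0L || before >= thr) {
    return(tibble(
      flank = "", full_sequence = sequence,
      tap_before = before, tap_after = before
    ))
  }
  cand <- flank_candidates(config$max_flank)
  scores <- score_tap(paste0(cand, sequence), matrix)
  reach <- scores >= thr
  if (any(reach)) {
    lens <- nchar(cand)
    kmin <- min(lens[reach])
    pool <- which(reach & lens == kmin)
    pool <- pool[scores[pool] == max(scores[pool])]
    pick <- pool[order(cand[pool])][1]     # lexicographic tie-break
  } else {
    pool <- which(scores == max(scores))
    pick <- pool[order(nchar(cand[pool]), cand[pool])][1]
  }
  tibble(
    flank = cand[pick],
    full_sequence = paste0(cand[pick], sequence),
    tap_before = before,
    tap_after = scores[pick]
  )
}

#' Calibrate a TAP threshold from reference sequences
#'
#' Median TAP score of all 9-mers of the given sequences (epitope-length
#' windows of a reference antigen, or an epitope set itself). Used when no
#' explicit threshold is configured.
#'
#' @param sequences Character vector of peptides or antigen sequences.
#' @param matrix A `tap_matrix`.
#' @param window Window length for long sequences (default 9).
#' @return Numeric scalar threshold.
#' @export
calibrate_tap_threshold <- function(sequences, matrix, window = 9L) {
  peps <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n <= window) return(s)
    substring(s, seq_len(n - window + 1L), seq_len(n - window + 1L) + window - 1L)
  }), use.names = FALSE)
  median(score_tap(peps, matrix))
}

#' Flank every epitope in a table
#'
#' Applies [select_flank()] to each row. When `config$tap_threshold` is
#' `NULL` the threshold self-calibrates to the median TAP score of the
#' input epitopes (logged), so roughly the weaker-binding half of the set
#' receives flanks.
#'
#' @param epitopes Epitope tibble (`id`, `sequence`, ...).
#' @param matrix A `tap_matrix`.
#' @param config A [design_config()].
#' @return The epitope tibble with added columns `flank`, `full_sequence`,
#'   `tap_before`, `tap_after`.
#' @export
flank_epitopes <- function(epitopes, matrix, config = design_config()) {
  if (is.null(config$tap_threshold)) {
    config$tap_threshold <- calibrate_tap_threshold(epitopes$sequence, matrix)
    inform(sprintf(
      "tap_threshold self-calibrated to %.4f (median TAP score of %d epitopes)",
      config$tap_threshold, nrow(epitopes)
    ))
  }
  res <- bind_rows(lapply(epitopes$sequence, select_flank, matrix = matrix, config = config))
  dplyr::bind_cols(epitopes, res)
}
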