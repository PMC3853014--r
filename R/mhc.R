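#' Per-allele MHC position-specific scoring matrix
#'
#' Reference peptide-MHC binding predictor behind the pluggable predictor
#' interface: predicted pIC50 (= -log10 IC50, IC50 in molar) is the matrix
#' intercept plus one weight per peptide position. One matrix per
#' (allele, peptide length); class I and class II matrices share the
#' format, distinguished by the `class` marker.
#'
#' @param allele HLA allele name.
#' @param length Supported peptide length.
#' @param weights Numeric 20 x `length` matrix, rownames [AA_ALPHABET].
#' @param intercept Scalar added to every prediction.
#' @param mhc_class `"I"` or `"II"`.
#' @return Object of class `"mhc_pssm"`.
#' @export
mhc_pssm <- function(allele, length, weights, intercept = 0, mhc_class = "I") {
  weights <- as.matrix(weights)
  if (!setequal(rownames(weights), AA_ALPHABET)) {
    abort("PSSM must have one row per standard residue")
  }
  if (ncol(weights) != length) {
    abort(sprintf("PSSM for length %d must have %d columns", length, length))
  }
  stopifnot(is.finite(intercept), mhc_class %in% c("I", "II"))
  weights <- weights[AA_ALPHABET, , drop = FALSE]
  colnames(weights) <- paste0("P", seq_len(ncol(weights)))
  structure(
    list(
      allele = allele, length = as.integer(length),
      weights = weights,
      intercept = intercept, mhc_class = mhc_class
    ),
    class = "mhc_pssm"
  )
}

#' Read an MHC PSSM file
#'
#' Header comments `#allele:`, `#length:`, `#intercept:`, `#class:`; body is
#' TSV with a `residue` column and one column per position `P1..PL`.
#'
#' @param path Path to the file.
#' @return An `mhc_pssm`.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) abort(sprintf("PSSM file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (length(hit) == 0L) abort(sprintf("PSSM file missing '#%s:' header", key))
    trimws(sub(sprintf("^#\\s*%s:", key), "", hit[1]))
  }
  len <- as.integer(grab("length"))
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    residue = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  w <- as.matrix(tbl[, paste0("P", seq_len(len))])
  rownames(w) <- tbl$residue
  mhc_pssm(grab("allele"), len, w, as.numeric(grab("intercept")), grab("class"))
}

#' Write an MHC PSSM file
#'
#' @param pssm An `mhc_pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "mhc_pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#allele: %s", pssm$allele),
    sprintf("#length: %d", pssm$length),
    sprintf("#intercept: %.6f", pssm$intercept),
    sprintf("#class: %s", pssm$mhc_class)
  ), con)
  writeLines(
    paste(c("residue", paste0("P", seq_len(pssm$length))), collapse = "\t"),
    con
  )
  for (r in rownames(pssm$weights)) {
    writeLines(
      paste(c(r, sprintf("%.6f", pssm$weights[r, ])), collapse = "\t"),
      con
    )
  }
  invisible(path)
}

#' Read a directory of PSSM files into a panel
#'
#' @param dir Directory containing `*.tsv` PSSM files.
#' @param mhc_class Optional filter, `"I"` or `"II"`.
#' @return List of `mhc_pssm` objects.
#' @export
read_pssm_panel <- function(dir, mhc_class = NULL) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  panel <- lapply(files, read_pssm)
  if (!is.null(mhc_class)) {
    panel <- keep(panel, function(p) p$mhc_class == mhc_class)
  }
  panel
}

#' Predict pIC50 for peptides under a PSSM
#'
#' `intercept + sum over positions of weights[(i, peptide_i)]`.
#'
#' @param peptide Character vector of peptides, all of `pssm$length`.
#' @param pssm An `mhc_pssm`.
#' @return Numeric vector of predicted pIC50 values.
#' @export
predict_pic50 <- function(peptide, pssm) {
  stopifnot(inherits(pssm, "mhc_pssm"))
  if (any(nchar(peptide) != pssm$length)) {
    abort(sprintf(
      "peptide length mismatch: PSSM for %s supports length %d",
      pssm$allele, pssm$length
    ))
  }
  vapply(peptide, function(p) {
    ch <- aa_chars(p)
    i <- match(ch, AA_ALPHABET)
    if (anyNA(i)) abort(sprintf("non-standard residue in peptide '%s'", p))
    pssm$intercept + sum(pssm$weights[cbind(i, seq_along(ch))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Map predicted pIC50 to the 4-level binding rank
#'
#' Rank 0: non-binder (pIC50 < 6.3). Rank 1: moderate affinity
#' (6.3 <= pIC50 < 7.3). Rank 2: high affinity (7.3 <= pIC50 < 8.3).
#' Rank 3: highest affinity (pIC50 >= 8.3). Lower bounds are closed.
#'
#' @param pic50 Numeric vector of predicted pIC50 values.
#' @return Integer vector of ranks in 0..3.
#' @examples
#' binding_rank(c(5.0, 6.3, 7.8, 9.1)) # 0 1 2 3
#' @export
binding_rank <- function(pic50) {
  stopifnot(all(is.finite(pic50)))
  as.integer(cut(pic50, breaks = c(-Inf, 6.3, 7.3, 8.3, Inf), right = FALSE)) - 1L
}

#' Scan a junction for non-target epitopes
#'
#' Enumerates, for each configured scan length L, every L-mer window of
#' `pep1_full + ss + pep2_full` that is not fully contained within either
#' flanked peptide alone — i.e. peptides that exist only because of the
#' artificial juxtaposition. Each window is scored against every panel
#' matrix of matching length; windows whose sequence equals a target
#' epitope are excluded, and only windows with binding rank >= 1 are
#' returned.
#'
#' @param pep1_full,pep2_full Flanked-epitope sequences.
#' @param ss Spacer between them (may be empty).
#' @param panel List of class-I `mhc_pssm` objects.
#' @param targets Character vector of target epitope sequences to exclude.
#' @param config A [design_config()]; uses `junction_lengths`.
#' @return Tibble of hits: `peptide`, `start` (1-based in the junction
#'   context), `length`, `allele`, `pic50`, `rank`.
#' @export
scan_junction <- function(pep1_full, ss, pep2_full, panel,
                          targets = character(0),
                          config = design_config()) {
  ctx <- paste0(pep1_full, ss, pep2_full)
  n <- nchar(ctx)
  n1 <- nchar(pep1_full)
  p2_start <- n1 + nchar(ss) + 1L
  if (length(panel) == 0L) {
    warn("empty MHC panel: junction scan returns no hits")
    return(empty_hits())
  }
  out <- list()
  for (L in config$junction_lengths) {
    if (L > n) next
    starts <- seq_len(n - L + 1L)
    ends <- starts + L - 1L
    straddling <- !(ends <= n1) & !(starts >= p2_start)
    starts <- starts[straddling]
    if (length(starts) == 0L) next
    windows <- substring(ctx, starts, starts + L - 1L)
    keep_w <- !(windows %in% targets)
    starts <- starts[keep_w]
    windows <- windows[keep_w]
    if (length(windows) == 0L) next
    for (pssm in panel) {
      if (pssm$length != L) next
      pic <- predict_pic50(windows, pssm)
      rk <- binding_rank(pic)
      hit <- rk >= 1L
      if (!any(hit)) next
      out[[length(out) + 1L]] <- tibble(
        peptide = windows[hit], start = starts[hit], length = L,
        allele = pssm$allele, pic50 = pic[hit], rank = rk[hit]
      )
    }
  }
  if (length(out) == 0L) empty_hits() else bind_rows(out)
}

empty_hits <- function() {
  tibble(
    peptide = character(0), start = integer(0), length = integer(0),
    allele = character(0), pic50 = numeric(0), rank = integer(0)
  )
}

#' Summarize junctional hits for the ranking function
#'
#' Per allele the best (maximal) rank among its hits; `n_eps` counts
#' distinct (peptide, allele) pairs; `n_hla` counts alleles with at least
#' one hit; `weighted_sum` is the frequency-weighted sum of per-allele best
#' ranks; `mean_rank` is the mean per-allele best rank (0 when there are no
#' hits).
#'
#' @param hits Hit tibble from [scan_junction()].
#' @param freqs Frequency tibble ([read_frequency_table()]).
#' @return List: `per_allele` (named integer vector), `n_eps`, `n_hla`,
#'   `mean_rank`, `weighted_sum`.
#' @export
summarize_junction <- function(hits, freqs) {
  if (nrow(hits) == 0L) {
    return(list(
      per_allele = setNames(integer(0), character(0)),
      n_eps = 0L, n_hla = 0L, mean_rank = 0, weighted_sum = 0
    ))
  }
  stopifnot(all(hits$rank >= 1L))
  best <- hits |>
    group_by(.data$allele) |>
    summarise(best_rank = max(.data$rank), .groups = "drop")
  per_allele <- setNames(as.integer(best$best_rank), best$allele)
  list(
    per_allele = per_allele,
    n_eps = nrow(distinct(hits, .data$peptide, .data$allele)),
    n_hla = length(per_allele),
    mean_rank = mean(per_allele),
    weighted_sum = sum(per_allele * lookup_frequency(freqs, names(per_allele)))
  )
}
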