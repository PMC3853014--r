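#' Run configuration for polyepitope design
#'
#' Collects every tunable threshold of the design pipeline in one validated
#' object. Defaults reflect the standard operating point: epitope lengths
#' 8-11, up to 3 N-terminal flanking residues, junction scans at the dominant
#' class-I ligand lengths 9 and 10, cleavage admissibility at rank 7 on the
#' 1-11 efficiency scale, and disallowed-pair edge weight 5000.
#'
#' @param tap_threshold TAP score (in the loaded matrix's units) at or above
#'   which an epitope is considered an efficient TAP binder and receives no
#'   flank. `NULL` (default) self-calibrates at run time to the median TAP
#'   score of the input epitope set (logged).
#' @param max_flank Maximum N-terminal flank length searched (default 3).
#' @param epitope_lengths Accepted epitope lengths, inclusive bounds
#'   (default 8-11).
#' @param junction_lengths Peptide lengths scanned for junctional epitopes
#'   (default `c(9, 10)`).
#' @param cleavage_allow_threshold Junction admissibility cutoff: a candidate
#'   spacer is admissible when `min(rank_pr, rank_impr)` is at or below this
#'   rank (default 7).
#' @param disallowed_weight Weight assigned to graph edges for which no
#'   candidate spacer is admissible. Fixed at 5000 by convention.
#' @param hitfree_mean_term How the `0.05 * (4 - mean rank)` term of the
#'   ranking function is evaluated when a junction has no predicted epitopes:
#'   `"zero"` (default) takes it as 0 so a hit-free junction is never
#'   penalized; `"verbatim"` evaluates it as `0.05 * 4 = 0.2`.
#' @param ga_pop_size,ga_generations,ga_cx_prob,ga_mut_prob,ga_tournament,ga_elitism
#'   Genetic-algorithm parameters (permutation encoding): population size,
#'   number of generations, order-crossover probability, per-gene swap
#'   mutation probability, tournament size, elite count.
#' @param redundancy Coverage redundancy r (each requested HLA allele must be
#'   bound by at least r selected epitopes).
#'
#' @return A list of class `"design_config"`.
#' @examples
#' cfg <- design_config(tap_threshold = 1.0)
#' cfg$disallowed_weight
#' @export
design_config <- function(tap_threshold = NULL,
                          max_flank = 3L,
                          epitope_lengths = c(8L, 11L),
                          junction_lengths = c(9L, 10L),
                          cleavage_allow_threshold = 7L,
                          disallowed_weight = 5000,
                          hitfree_mean_term = c("zero", "verbatim"),
                          ga_pop_size = 80L,
                          ga_generations = 500L,
                          ga_cx_prob = 0.9,
                          ga_mut_prob = 0.02,
                          ga_tournament = 2L,
                          ga_elitism = 1L,
                          redundancy = 1L) {
  hitfree_mean_term <- match.arg(hitfree_mean_term)
  stopifnot(
    is.null(tap_threshold) || (is.numeric(tap_threshold) && is.finite(tap_threshold)),
    max_flank >= 0L, max_flank <= 3L,
    length(epitope_lengths) == 2L, epitope_lengths[1] >= 1L,
    epitope_lengths[1] <= epitope_lengths[2],
    length(junction_lengths) >= 1L, all(junction_lengths >= 1L),
    cleavage_allow_threshold >= 1L, cleavage_allow_threshold <= 11L,
    disallowed_weight > 0,
    ga_pop_size >= 1L, ga_generations >= 0L,
    ga_cx_prob >= 0, ga_cx_prob <= 1,
    ga_mut_prob >= 0, ga_mut_prob <= 1,
    ga_tournament >= 1L, ga_elitism >= 0L,
    redundancy >= 1L
  )
  structure(
    list(
      tap_threshold = tap_threshold,
      max_flank = as.integer(max_flank),
      epitope_lengths = as.integer(epitope_lengths),
      junction_lengths = as.integer(junction_lengths),
      cleavage_allow_threshold = as.integer(cleavage_allow_threshold),
      disallowed_weight = disallowed_weight,
      hitfree_mean_term = hitfree_mean_term,
      ga_pop_size = as.integer(ga_pop_size),
      ga_generations = as.integer(ga_generations),
      ga_cx_prob = ga_cx_prob,
      ga_mut_prob = ga_mut_prob,
      ga_tournament = as.integer(ga_tournament),
      ga_elitism = as.integer(ga_elitism),
      redundancy = as.integer(redundancy)
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf(
      "  %-26s %s\n", nm,
      if (is.null(v)) "(self-calibrating)" else paste(v, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Recognized keys are the arguments of [design_config()]; list-valued keys
#' take comma-separated values.
#'
#' @param path Path to the configuration file.
#' @return A `design_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) abort(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (anyNA(num)) val else num
  }
  do.call(design_config, args)
}
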