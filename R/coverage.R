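#' Select a minimal epitope set covering an HLA repertoire
#'
#' Greedy set-multicover: repeatedly picks the epitope covering the most
#' requested alleles that are not yet covered `r` times, breaking ties by
#' the summed genotypic frequency of the newly covered alleles (descending)
#' and then by epitope id. Stops when every requested allele is covered at
#' least `r` times or no remaining epitope adds coverage; infeasible
#' repertoires yield `complete = FALSE`, never an error.
#'
#' @param binding Tibble with columns `epitope`, `allele`: one row per
#'   (epitope, allele) binding pair (annotated restriction or predicted at
#'   a rank cutoff).
#' @param repertoire Character vector of requested HLA alleles.
#' @param r Redundancy: required number of selected epitopes per allele
#'   (default 1).
#' @param freqs Optional frequency tibble used for tie-breaking.
#' @return Object of class `"coverage_solution"`: list with `selected`
#'   (epitope ids in pick order), `per_allele_cover` (named integer
#'   vector over the repertoire), `redundancy`, `complete`.
#' @export
select_minimal_set <- function(binding, repertoire, r = 1L,
                               freqs = frequency_table()) {
  stopifnot(r >= 1L, all(c("epitope", "allele") %in% names(binding)))
  repertoire <- unique(repertoire)
  binding <- distinct(binding, .data$epitope, .data$allele) |>
    filter(.data$allele %in% repertoire)
  cover <- setNames(rep(0L, length(repertoire)), repertoire)
  freq_of <- suppressWarnings(
    setNames(lookup_frequency(freqs, repertoire), repertoire)
  )
  remaining <- sort(unique(binding$epitope))
  selected <- character(0)
  repeat {
    if (all(cover >= r) || length(remaining) == 0L) break
    need <- names(cover)[cover < r]
    gain <- vapply(remaining, function(e) {
      sum(binding$allele[binding$epitope == e] %in% need)
    }, integer(1))
    if (max(gain) == 0L) break
    pool <- remaining[gain == max(gain)]
    if (length(pool) > 1L) {
      fsum <- vapply(pool, function(e) {
        covered <- intersect(binding$allele[binding$epitope == e], need)
        sum(freq_of[covered])
      }, numeric(1))
      pool <- pool[fsum == max(fsum)]
    }
    pick <- sort(pool)[1L]
    hit <- binding$allele[binding$epitope == pick]   # true counts, uncapped
    cover[hit] <- cover[hit] + 1L
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(
    list(
      selected = selected,
      per_allele_cover = cover,
      redundancy = as.integer(r),
      complete = length(cover) > 0L && all(cover >= r)
    ),
    class = "coverage_solution"
  )
}

#' @export
print.coverage_solution <- function(x, ...) {
  cat(sprintf(
    "<coverage_solution> %d epitope(s) selected, redundancy %d, %s\n",
    length(x$selected), x$redundancy,
    if (x$complete) "complete" else "INCOMPLETE"
  ))
  invisible(x)
}

#' Tidy a coverage solution
#'
#' @param x A `coverage_solution`.
#' @param ... Unused.
#' @return Tibble: `allele`, `cover`, `satisfied`.
#' @method tidy coverage_solution
#' @export
tidy.coverage_solution <- function(x, ...) {
  tibble(
    allele = names(x$per_allele_cover),
    cover = as.integer(x$per_allele_cover),
    satisfied = x$per_allele_cover >= x$redundancy
  )
}

#' @rdname tidy.coverage_solution
#' @method glance coverage_solution
#' @export
glance.coverage_solution <- function(x, ...) {
  tibble(
    n_selected = length(x$selected),
    n_alleles = length(x$per_allele_cover),
    redundancy = x$redundancy,
    complete = x$complete
  )
}

#' Coverage bar chart
#'
#' @param object A `coverage_solution`.
#' @param ... Unused.
#' @return A ggplot: per-allele cover counts against the redundancy target.
#' @method autoplot coverage_solution
#' @export
autoplot.coverage_solution <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$allele, y = .data$cover,
                               fill = .data$satisfied)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$redundancy, linetype = 2) +
    ggplot2::labs(x = NULL, y = "selected epitopes covering allele",
                  title = "HLA repertoire coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Read an epitope-allele binding map
#'
#' TSV with columns `epitope`, `allele`.
#'
#' @param path Path to the file.
#' @return Tibble (`epitope`, `allele`).
#' @export
read_binding_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("binding map not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    epitope = readr::col_character(), allele = readr::col_character()
  ), comment = "#", progress = FALSE)
}

#' Predict a binding map from a PSSM panel
#'
#' An epitope is taken to bind an allele when its predicted pIC50 under the
#' allele's matrix of matching length reaches the given binding rank.
#'
#' @param epitopes Epitope tibble.
#' @param panel List of class-I `mhc_pssm`s.
#' @param min_rank Minimum [binding_rank()] counted as binding (default 1).
#' @return Tibble (`epitope`, `allele`).
#' @export
predicted_binding_map <- function(epitopes, panel, min_rank = 1L) {
  rows <- list()
  for (pssm in panel) {
    ok <- nchar(epitopes$sequence) == pssm$length
    if (!any(ok)) next
    pic <- predict_pic50(epitopes$sequence[ok], pssm)
    hit <- binding_rank(pic) >= min_rank
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- tibble(
        epitope = epitopes$id[ok][hit], allele = pssm$allele
      )
    }
  }
  if (length(rows) == 0L) {
    tibble(epitope = character(0), allele = character(0))
  } else {
    distinct(bind_rows(rows), .data$epitope, .data$allele)
  }
}
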