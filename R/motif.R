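#' Parse a spacer motif in bracket notation
#'
#' A motif is a concatenation of single residues and bracketed residue
#' groups, e.g. `"ADLVKV"` or the degenerate `"[ARSP][DLIT][LGA][VKA]"`.
#' Each position is a non-empty set of allowed residues; at most six
#' positions are permitted (spacers hold up to six residues).
#'
#' @param raw Motif string.
#' @return An object of class `"spacer_motif"`: list with `positions` (list
#'   of character vectors) and `raw` (normalized bracket notation).
#' @examples
#' parse_motif("ADLVKV")
#' parse_motif("[KR][KR]")
#' @export
parse_motif <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(trimws(raw))
  if (!nzchar(s)) abort("empty motif")
  positions <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) abort(sprintf("unbalanced bracket in motif '%s'", raw))
      grp <- substr(s, i + 1L, i + j - 2L)
      if (!nzchar(grp)) abort(sprintf("empty residue group in motif '%s'", raw))
      res <- unique(aa_chars(grp))
      if (!all(res %in% AA_ALPHABET)) {
        abort(sprintf("illegal residue in motif group '[%s]'", grp))
      }
      positions[[length(positions) + 1L]] <- res
      i <- i + j
    } else if (ch == "]") {
      abort(sprintf("unbalanced bracket in motif '%s'", raw))
    } else {
      if (!ch %in% AA_ALPHABET) {
        abort(sprintf("illegal residue '%s' in motif '%s'", ch, raw))
      }
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    }
  }
  if (length(positions) > 6L) {
    abort(sprintf(
      "motif '%s' has %d positions; spacers may hold at most 6 residues",
      raw, length(positions)
    ))
  }
  structure(
    list(positions = positions, raw = motif_string(positions)),
    class = "spacer_motif"
  )
}

# Normalized bracket notation: singletons bare, groups bracketed.
motif_string <- function(positions) {
  paste(vapply(positions, function(p) {
    if (length(p) == 1L) p else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.spacer_motif <- function(x, ...) {
  cat(sprintf(
    "<spacer_motif> %s (%d positions%s)\n", x$raw, length(x$positions),
    if (is_degenerate_motif(x)) ", degenerate" else ""
  ))
  invisible(x)
}

#' Is a motif degenerate (any position with more than one residue)?
#'
#' @param motif A `spacer_motif`.
#' @return Logical scalar.
#' @export
is_degenerate_motif <- function(motif) {
  any(lengths(motif$positions) > 1L)
}

#' Enumerate candidate spacers from a motif
#'
#' Candidates are the direct junction (empty spacer) plus, for every prefix
#' length k of the motif, every sequence in the Cartesian product of the
#' first k residue sets. `"ADLVKV"` therefore yields the direct junction and
#' the six prefixes A, AD, ADL, ADLV, ADLVK, ADLVKV. Order is deterministic:
#' shorter candidates first, lexicographic within a length.
#'
#' @param motif A `spacer_motif` (or a raw motif string, parsed on the fly).
#' @return Character vector of candidate spacers, starting with `""`.
#' @examples
#' enumerate_spacers("ADLVKV")
#' length(enumerate_spacers("[ARSP][DLIT][LGA][VKA]")) # 213
#' @export
enumerate_spacers <- function(motif) {
  if (is.character(motif)) motif <- parse_motif(motif)
  stopifnot(inherits(motif, "spacer_motif"))
  out <- ""
  for (k in seq_along(motif$positions)) {
    grid <- expand.grid(
      rev(motif$positions[seq_len(k)]),
      stringsAsFactors = FALSE
    )
    cand <- do.call(paste0, rev(grid))
    out <- c(out, sort(unique(cand)))
  }
  unique(out)
}
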