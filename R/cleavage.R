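#' Proteasomal / immunoproteasomal cleavage rank model
#'
#' Cleavage efficiency at a scissile bond is ranked on an 11-level scale:
#' rank 1 is the most efficient cleavage site, rank 11 the least efficient.
#' The rank is read from a pattern table over a fixed context window around
#' the bond (default 4 residues upstream — P4..P1 — and 2 downstream —
#' P1'..P2'). Each pattern constrains a subset of window slots with residue
#' sets in bracket notation (`.` = unconstrained); the most specific
#' matching pattern wins (ties by table order) and unmatched contexts fall
#' back to the table's declared default rank.
#'
#' @param kind `"proteasome"` or `"immunoproteasome"`.
#' @param patterns Tibble with columns `pattern` (character) and `rank`
#'   (integer 1-11); may have zero rows.
#' @param default_rank Rank for contexts matched by no pattern.
#' @param window_up,window_down Residues upstream/downstream of the bond in
#'   the context window (defaults 4 and 2).
#' @return Object of class `"cleavage_model"`.
#' @export
cleavage_model <- function(kind = c("proteasome", "immunoproteasome"),
                           patterns = tibble(pattern = character(0), rank = integer(0)),
                           default_rank = 9L,
                           window_up = 4L, window_down = 2L) {
  kind <- match.arg(kind)
  stopifnot(
    default_rank >= 1L, default_rank <= 11L,
    window_up >= 1L, window_down >= 1L,
    all(c("pattern", "rank") %in% names(patterns))
  )
  if (nrow(patterns) > 0L && (any(patterns$rank < 1L) || any(patterns$rank > 11L))) {
    abort("cleavage ranks must lie in 1..11")
  }
  nslots <- window_up + window_down
  slots <- lapply(patterns$pattern, parse_context_pattern, nslots = nslots)
  structure(
    list(
      kind = kind,
      window_up = as.integer(window_up),
      window_down = as.integer(window_down),
      default_rank = as.integer(default_rank),
      patterns = tibble(
        pattern = patterns$pattern,
        rank = as.integer(patterns$rank),
        slots = slots,
        specificity = vapply(slots, function(s) sum(!vapply(s, is.null, logical(1))), integer(1))
      )
    ),
    class = "cleavage_model"
  )
}

# One token per slot: '.' (or 'x') wildcard, a residue, or a bracket group.
parse_context_pattern <- function(pattern, nslots) {
  s <- toupper(trimws(pattern))
  slots <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c(".", "X")) {
      slots[[length(slots) + 1L]] <- NULL_SLOT
      i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) abort(sprintf("unbalanced bracket in cleavage pattern '%s'", pattern))
      grp <- aa_chars(substr(s, i + 1L, i + j - 2L))
      if (length(grp) == 0L || !all(grp %in% AA_ALPHABET)) {
        abort(sprintf("bad residue group in cleavage pattern '%s'", pattern))
      }
      slots[[length(slots) + 1L]] <- unique(grp)
      i <- i + j
    } else if (ch %in% AA_ALPHABET) {
      slots[[length(slots) + 1L]] <- ch
      i <- i + 1L
    } else {
      abort(sprintf("illegal character '%s' in cleavage pattern '%s'", ch, pattern))
    }
  }
  if (length(slots) != nslots) {
    abort(sprintf(
      "cleavage pattern '%s' has %d slots; window requires %d",
      pattern, length(slots), nslots
    ))
  }
  # represent wildcards as NULL entries
  lapply(slots, function(x) if (identical(x, NULL_SLOT)) NULL else x)
}

NULL_SLOT <- structure("__wild__", class = "wild_slot")

#' Read a cleavage rank table
#'
#' Header comments declare `#kind:`, `#window: <up> <down>` and
#' `#default_rank:`; body lines are `pattern<TAB>rank`.
#'
#' @param path Path to the table file.
#' @return A `cleavage_model`.
#' @export
read_cleavage_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("cleavage table not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (length(hit) == 0L) abort(sprintf("cleavage table missing '#%s:' header", key))
    trimws(sub(sprintf("^#\\s*%s:", key), "", hit[1]))
  }
  kind <- grab("kind")
  win <- as.integer(strsplit(grab("window"), "\\s+")[[1]])
  if (length(win) != 2L || anyNA(win)) abort("bad '#window:' header (expect '<up> <down>')")
  default_rank <- as.integer(grab("default_rank"))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) abort("cleavage table body lines must be 'pattern<TAB>rank'")
    patterns <- tibble(
      pattern = vapply(parts, `[[`, character(1), 1L),
      rank = as.integer(vapply(parts, `[[`, character(1), 2L))
    )
  } else {
    patterns <- tibble(pattern = character(0), rank = integer(0))
  }
  cleavage_model(kind, patterns, default_rank, win[1], win[2])
}

#' Write a cleavage rank table
#'
#' @param model A `cleavage_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleavage_table <- function(model, path) {
  stopifnot(inherits(model, "cleavage_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#kind: %s", model$kind),
    sprintf("#window: %d %d", model$window_up, model$window_down),
    sprintf("#default_rank: %d", model$default_rank)
  ), con)
  if (nrow(model$patterns) > 0L) {
    writeLines(sprintf("%s\t%d", model$patterns$pattern, model$patterns$rank), con)
  }
  invisible(path)
}

#' Rank a cleavage site
#'
#' Ranks the scissile bond C-terminal to residue `position` of `sequence`.
#' The context window spans `window_up` residues ending at `position` and
#' `window_down` residues after it; slots falling outside the sequence match
#' only unconstrained pattern slots.
#'
#' @param sequence Amino-acid string.
#' @param position 1-based index of the residue after which cleavage occurs;
#'   must leave at least one residue on each side of the bond.
#' @param model A `cleavage_model`.
#' @return Integer rank in 1..11.
#' @export
rank_cleavage <- function(sequence, position, model) {
  stopifnot(inherits(model, "cleavage_model"))
  n <- nchar(sequence)
  if (position < 1L || position >= n) {
    abort(sprintf(
      "cleavage position %d is at or beyond the sequence terminus (length %d)",
      position, n
    ))
  }
  pos <- (position - model$window_up + 1L):(position + model$window_down)
  ctx <- ifelse(pos >= 1L & pos <= n, substring(sequence, pos, pos), NA_character_)
  best_rank <- model$default_rank
  best_spec <- -1L
  pats <- model$patterns
  for (i in seq_len(nrow(pats))) {
    slots <- pats$slots[[i]]
    ok <- TRUE
    for (k in seq_along(slots)) {
      if (is.null(slots[[k]])) next
      if (is.na(ctx[k]) || !(ctx[k] %in% slots[[k]])) { ok <- FALSE; break }
    }
    if (ok && pats$specificity[i] > best_spec) {   # ties: first in file order
      best_spec <- pats$specificity[i]
      best_rank <- pats$rank[i]
    }
  }
  best_rank
}

#' Rank cleavage at an epitope's C-terminus within a junction
#'
#' Ranks the bond after the last residue of `pep1` in the concatenation
#' `pep1 + ss + pep2_context`, separately for the proteasome and the
#' immunoproteasome.
#'
#' @param pep1 First (flanked) peptide.
#' @param ss Spacer string (possibly empty for a direct junction).
#' @param pep2_context Downstream sequence (the second flanked peptide or
#'   its first residues).
#' @param model_pr,model_impr Proteasomal and immunoproteasomal
#'   `cleavage_model`s.
#' @return One-row tibble: `position`, `rank_pr`, `rank_impr`.
#' @export
rank_epitope_cterm <- function(pep1, ss, pep2_context, model_pr, model_impr) {
  if (!nzchar(pep1)) abort("pep1 must be non-empty")
  full <- paste0(pep1, ss, pep2_context)
  pos <- nchar(pep1)
  tibble(
    position = pos,
    rank_pr = rank_cleavage(full, pos, model_pr),
    rank_impr = rank_cleavage(full, pos, model_impr)
  )
}
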