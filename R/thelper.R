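#' Scan an antigen for T-helper epitope cores
#'
#' Slides a 9-residue window over the antigen and records, for every
#' class-II matrix in the panel, each window scoring at or above the
#' allele's threshold.
#'
#' @param antigen Antigen amino-acid sequence.
#' @param class2_panel List of class-II `mhc_pssm`s (9-mer core matrices).
#' @param threshold Scalar score threshold, or a named vector with one
#'   threshold per allele.
#' @return Tibble of hits: `allele`, `start` (1-based), `peptide`, `score`.
#' @export
scan_th_cores <- function(antigen, class2_panel, threshold) {
  assert_peptide(antigen, "antigen")
  n <- nchar(antigen)
  if (n < 9L) {
    return(tibble(allele = character(0), start = integer(0),
                  peptide = character(0), score = numeric(0)))
  }
  starts <- seq_len(n - 8L)
  windows <- substring(antigen, starts, starts + 8L)
  out <- list()
  for (pssm in class2_panel) {
    if (pssm$length != 9L) {
      abort(sprintf("class-II matrix for %s is not a 9-mer core matrix", pssm$allele))
    }
    thr <- if (length(threshold) > 1L || !is.null(names(threshold))) {
      if (!pssm$allele %in% names(threshold)) {
        abort(sprintf("no threshold for allele %s", pssm$allele))
      }
      threshold[[pssm$allele]]
    } else threshold
    sc <- predict_pic50(windows, pssm)
    hit <- sc >= thr
    if (any(hit)) {
      out[[length(out) + 1L]] <- tibble(
        allele = pssm$allele, start = starts[hit],
        peptide = windows[hit], score = sc[hit]
      )
    }
  }
  if (length(out) == 0L) {
    tibble(allele = character(0), start = integer(0),
           peptide = character(0), score = numeric(0))
  } else {
    bind_rows(out)
  }
}

#' Select T-helper-rich antigen fragments
#'
#' Evaluates every window of length 20-40 over the antigen, counting the
#' distinct 9-mer epitope cores fully contained in it (`n_epitopes`) and
#' the class-II alleles they cover (`n_alleles`). Windows are ranked by
#' allele breadth, then hit count, then shorter length, then earlier start,
#' and accepted greedily so that accepted cores never overlap. Each
#' accepted core is extended by five residues on both sides (clamped at the
#' antigen termini) — flanking residues contribute to CD4+ T-cell receptor
#' engagement.
#'
#' @param antigen Antigen sequence (length >= 20; shorter input yields an
#'   empty result with a warning).
#' @param hits Hit tibble from [scan_th_cores()].
#' @param count Maximum number of fragments to return (default all).
#' @param antigen_id Label recorded in the result.
#' @return Tibble of fragments: `antigen_id`, `core_start`, `core_end`,
#'   `ext_start`, `ext_end`, `n_epitopes`, `n_alleles`, `sequence` (the
#'   extended fragment).
#' @export
select_fragments <- function(antigen, hits, count = Inf, antigen_id = "antigen") {
  n <- nchar(antigen)
  empty <- tibble(
    antigen_id = character(0), core_start = integer(0), core_end = integer(0),
    ext_start = integer(0), ext_end = integer(0),
    n_epitopes = integer(0), n_alleles = integer(0), sequence = character(0)
  )
  if (n < 20L) {
    warn(sprintf("antigen shorter than 20 residues (%d): no fragments", n))
    return(empty)
  }
  if (nrow(hits) == 0L) return(empty)
  cores <- distinct(hits, .data$start)
  windows <- list()
  for (L in 20:40) {
    if (L > n) break
    s <- seq_len(n - L + 1L)
    windows[[length(windows) + 1L]] <- tibble(start = s, end = s + L - 1L, len = L)
  }
  win <- bind_rows(windows)
  counts <- pmap(win, function(start, end, len) {
    inside <- hits$start >= start & (hits$start + 8L) <= end
    tibble(
      n_epitopes = length(unique(hits$start[inside])),
      n_alleles = length(unique(hits$allele[inside]))
    )
  })
  win <- dplyr::bind_cols(win, bind_rows(counts))
  win <- win |>
    filter(.data$n_epitopes > 0L) |>
    arrange(desc(.data$n_alleles), desc(.data$n_epitopes), .data$len, .data$start)
  accepted <- empty
  for (k in seq_len(nrow(win))) {
    if (nrow(accepted) >= count) break
    w <- win[k, ]
    overlaps <- nrow(accepted) > 0L &&
      any(w$start <= accepted$core_end & w$end >= accepted$core_start)
    if (overlaps) next
    es <- max(1L, w$start - 5L)
    ee <- min(n, w$end + 5L)
    accepted <- bind_rows(accepted, tibble(
      antigen_id = antigen_id,
      core_start = w$start, core_end = w$end,
      ext_start = es, ext_end = ee,
      n_epitopes = w$n_epitopes, n_alleles = w$n_alleles,
      sequence = substr(antigen, es, ee)
    ))
  }
  arrange(accepted, .data$core_start)
}

#' Join T-helper fragments through a cathepsin-cleavable motif
#'
#' Joins the extended fragments, in input order, choosing for every
#' adjacent pair the minimal-weight candidate from the (default)
#' `[KR][KR]` motif — di-basic spacers forming cleavage sites for several
#' lysosomal cathepsins — using the same junction ranking machinery as the
#' CTL module (class-I junctional scan included). Fragment order is not
#' optimized.
#'
#' @param fragments Fragment tibble from [select_fragments()] (>= 1 row).
#' @param motif Joining motif (default `"[KR][KR]"`).
#' @param model_pr,model_impr `cleavage_model`s.
#' @param panel List of class-I `mhc_pssm`s for the junctional scan.
#' @param freqs Frequency tibble.
#' @param config A [design_config()].
#' @return List of class `"th_design"`: `sequence`, `junctions` tibble,
#'   `fragments`.
#' @export
join_fragments <- function(fragments, motif = "[KR][KR]",
                           model_pr, model_impr, panel, freqs,
                           config = design_config()) {
  if (nrow(fragments) == 0L) abort("no fragments to join")
  if (is.character(motif)) motif <- parse_motif(motif)
  seqs <- fragments$sequence
  ids <- sprintf("%s:%d-%d", fragments$antigen_id,
                 fragments$ext_start, fragments$ext_end)
  junctions <- list()
  assembled <- seqs[1L]
  if (nrow(fragments) > 1L) {
    for (k in seq_len(nrow(fragments) - 1L)) {
      ev <- evaluate_junction_candidates(
        seqs[k], seqs[k + 1L], motif, model_pr, model_impr,
        panel, freqs, targets = character(0), config = config
      )
      ord <- order(ev$w, nchar(ev$ss), ev$ss)
      pick <- ev[ord[1L], ]
      junctions[[k]] <- tibble(
        from = ids[k], to = ids[k + 1L], ss = pick$ss,
        rank_pr = pick$rank_pr, rank_impr = pick$rank_impr,
        n_eps = pick$n_eps, n_hla = pick$n_hla, w = pick$w
      )
      assembled <- paste0(assembled, pick$ss, seqs[k + 1L])
    }
  }
  structure(
    list(
      sequence = assembled,
      junctions = if (length(junctions)) bind_rows(junctions) else tibble(),
      fragments = fragments
    ),
    class = "th_design"
  )
}

#' @export
print.th_design <- function(x, ...) {
  cat(sprintf(
    "<th_design> %d fragment(s), assembled length %d\n",
    nrow(x$fragments), nchar(x$sequence)
  ))
  invisible(x)
}

#' @rdname join_fragments
#' @param x A `th_design`.
#' @param ... Unused.
#' @method tidy th_design
#' @export
tidy.th_design <- function(x, ...) as_tibble(x$junctions)
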