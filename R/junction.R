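#' Junction ranking function W
#'
#' Weight of a candidate spacer `ss` between an ordered epitope pair:
#'
#' `W = sum_HLA(best_rank_HLA * freq_HLA) + len(ss)
#'    + 0.5 * min(rank_pr, rank_impr) + 0.05 * (4 - mean_rank_HLA)
#'    + 0.05 * N_eps + 0.05 * N_HLA + 0.25 * rank_pr + 0.25 * rank_impr`
#'
#' Lower is better: the optimal spacer minimizes W. Cleavage ranks use the
#' 1-11 efficiency scale (1 most efficient), so efficient liberation of the
#' first epitope's C-terminus lowers W; every junctional binder raises the
#' frequency-weighted and count terms; the `len(ss)` term prefers the
#' shortest spacer when all else is equal. When the junction has no
#' predicted epitopes the `(4 - mean_rank)` term is taken as 0 under the
#' default `hitfree_mean_term = "zero"` policy (see [design_config()]), so
#' a hit-free junction is never penalized.
#'
#' @param summary Junction summary from [summarize_junction()].
#' @param ss Spacer string.
#' @param rank_pr,rank_impr Proteasomal and immunoproteasomal cleavage
#'   ranks (1-11) at the first epitope's C-terminus.
#' @param config A [design_config()]; uses `hitfree_mean_term`.
#' @return Numeric weight W (dimensionless, >= 0 in practice).
#' @examples
#' s <- list(per_allele = integer(0), n_eps = 0L, n_hla = 0L,
#'           mean_rank = 0, weighted_sum = 0)
#' ranking_weight(s, "AD", 1, 3) # 3.5
#' @export
ranking_weight <- function(summary, ss, rank_pr, rank_impr,
                           config = design_config()) {
  stopifnot(
    rank_pr >= 1, rank_pr <= 11,
    rank_impr >= 1, rank_impr <= 11
  )
  mean_term <- if (summary$n_eps == 0L && config$hitfree_mean_term == "zero") {
    0
  } else {
    0.05 * (4 - summary$mean_rank)
  }
  summary$weighted_sum + nchar(ss) +
    0.5 * min(rank_pr, rank_impr) +
    mean_term +
    0.05 * summary$n_eps + 0.05 * summary$n_hla +
    0.25 * rank_pr + 0.25 * rank_impr
}

#' Evaluate every candidate spacer for one ordered epitope pair
#'
#' Workhorse behind [best_junction()]: one row per candidate from
#' [enumerate_spacers()], carrying its cleavage ranks, junctional summary,
#' weight W and admissibility. A candidate is admissible when
#' `min(rank_pr, rank_impr) <= config$cleavage_allow_threshold`, i.e. at
#' least one proteasome form cleaves the first epitope's C-terminus
#' efficiently enough.
#'
#' @param pep1_full,pep2_full Flanked-epitope sequences.
#' @param motif A `spacer_motif` (or motif string).
#' @param model_pr,model_impr `cleavage_model`s.
#' @param panel List of class-I `mhc_pssm`s.
#' @param freqs Frequency tibble.
#' @param targets Target epitope sequences excluded from the junctional scan.
#' @param config A [design_config()].
#' @return Tibble: `ss`, `rank_pr`, `rank_impr`, `n_eps`, `n_hla`,
#'   `mean_rank`, `weighted_sum`, `w`, `admissible`.
#' @export
evaluate_junction_candidates <- function(pep1_full, pep2_full, motif,
                                         model_pr, model_impr, panel, freqs,
                                         targets = character(0),
                                         config = design_config()) {
  if (is.character(motif)) motif <- parse_motif(motif)
  cands <- enumerate_spacers(motif)
  rows <- lapply(cands, function(ss) {
    cr <- rank_epitope_cterm(pep1_full, ss, pep2_full, model_pr, model_impr)
    hits <- scan_junction(pep1_full, ss, pep2_full, panel, targets, config)
    sm <- summarize_junction(hits, freqs)
    tibble(
      ss = ss,
      rank_pr = cr$rank_pr, rank_impr = cr$rank_impr,
      n_eps = sm$n_eps, n_hla = sm$n_hla,
      mean_rank = sm$mean_rank, weighted_sum = sm$weighted_sum,
      w = ranking_weight(sm, ss, cr$rank_pr, cr$rank_impr, config),
      admissible = min(cr$rank_pr, cr$rank_impr) <= config$cleavage_allow_threshold
    )
  })
  bind_rows(rows)
}

#' Select the optimal spacer for an ordered epitope pair
#'
#' Evaluates every candidate spacer and returns the admissible candidate of
#' minimal weight W, ties broken by shorter spacer then lexicographic
#' order. When no candidate is admissible the junction is DISALLOWED
#' (`status = "disallowed"`); the returned row then reports the overall
#' minimum-W candidate for diagnostics, and the design graph assigns the
#' pair the fixed disallowed edge weight.
#'
#' @inheritParams evaluate_junction_candidates
#' @param pep1_id,pep2_id Ids recorded in the result.
#' @return One-row tibble: `pep1`, `pep2`, `ss`, `rank_pr`, `rank_impr`,
#'   `n_eps`, `n_hla`, `mean_rank`, `weighted_sum`, `w`, `status`.
#' @export
best_junction <- function(pep1_full, pep2_full, motif,
                          model_pr, model_impr, panel, freqs,
                          targets = character(0),
                          config = design_config(),
                          pep1_id = "pep1", pep2_id = "pep2") {
  ev <- evaluate_junction_candidates(
    pep1_full, pep2_full, motif, model_pr, model_impr,
    panel, freqs, targets, config
  )
  pool <- if (any(ev$admissible)) ev[ev$admissible, ] else ev
  ord <- order(pool$w, nchar(pool$ss), pool$ss)
  pick <- pool[ord[1], ]
  if (pick$w > 10) {
    inform(sprintf(
      "junction %s->%s: best weight %.3f exceeds the usual regime (<= 10)",
      pep1_id, pep2_id, pick$w
    ))
  }
  tibble(
    pep1 = pep1_id, pep2 = pep2_id, ss = pick$ss,
    rank_pr = pick$rank_pr, rank_impr = pick$rank_impr,
    n_eps = pick$n_eps, n_hla = pick$n_hla,
    mean_rank = pick$mean_rank, weighted_sum = pick$weighted_sum,
    w = pick$w,
    status = if (any(ev$admissible)) "allowed" else "disallowed"
  )
}
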