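#' End-to-end polyepitope design
#'
#' Runs the full CTL-module pipeline: TAP flank selection for every epitope,
#' construction of the complete weighted junction digraph, minimum-weight
#' Hamiltonian-path search, and rendering of the final construct. The
#' greedy solver is reserved for nondegenerate spacer motifs; requesting it
#' with a degenerate motif downgrades to the genetic algorithm with a
#' warning.
#'
#' @param epitopes Epitope tibble ([read_epitopes()] / [epitope_table()]).
#' @param motif Spacer motif (string or `spacer_motif`).
#' @param tap A `tap_matrix`.
#' @param model_pr,model_impr `cleavage_model`s.
#' @param panel List of class-I `mhc_pssm`s.
#' @param freqs Frequency tibble.
#' @param config A [design_config()].
#' @param solver `"ga"`, `"greedy"` or `"exhaustive"`.
#' @param seed Integer seed for the GA solver.
#' @return A `polyepitope_design`; the flanked epitope table and graph are
#'   attached as attributes `"flanked"` and `"graph"`.
#' @export
design_polyepitope <- function(epitopes, motif, tap, model_pr, model_impr,
                               panel, freqs,
                               config = design_config(),
                               solver = c("ga", "greedy", "exhaustive"),
                               seed = 1L) {
  solver <- match.arg(solver)
  if (is.character(motif)) motif <- parse_motif(motif)
  if (solver == "greedy" && is_degenerate_motif(motif)) {
    warn("greedy solver is restricted to nondegenerate spacer motifs; using the genetic algorithm instead")
    solver <- "ga"
  }
  inform(sprintf("flanking %d epitopes", nrow(epitopes)))
  flanked <- flank_epitopes(epitopes, tap, config)
  graph <- build_graph(flanked, motif, model_pr, model_impr, panel, freqs, config)
  design <- switch(solver,
    ga = solve_ga(graph, seed = seed),
    greedy = solve_greedy(graph),
    exhaustive = solve_exhaustive(graph)
  )
  attr(design, "flanked") <- flanked
  attr(design, "graph") <- graph
  design
}
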