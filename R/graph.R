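#' Build the complete weighted design digraph
#'
#' Nodes are flanked epitopes; every ordered pair (i, j), i != j, carries
#' the optimal spacer and weight from [best_junction()]. Pairs for which no
#' candidate spacer is admissible become disallowed edges with the fixed
#' weight `config$disallowed_weight` (5000 by convention), turning the
#' incomplete graph of allowed matchings into a complete one so that path
#' solvers always have a feasible tour.
#'
#' @param flanked Flanked epitope tibble from [flank_epitopes()] (columns
#'   `id`, `sequence`, `full_sequence`, ...), at least 2 rows.
#' @param motif A `spacer_motif` or motif string.
#' @param model_pr,model_impr `cleavage_model`s.
#' @param panel List of class-I `mhc_pssm`s.
#' @param freqs Frequency tibble.
#' @param config A [design_config()].
#' @return Object of class `"design_graph"`: list with `nodes` (the input
#'   tibble), `edges` (tibble `from`, `to`, `ss`, `weight`, `status` plus
#'   junction diagnostics) and `config`.
#' @export
build_graph <- function(flanked, motif, model_pr, model_impr, panel, freqs,
                        config = design_config()) {
  if (nrow(flanked) < 2L) abort("design graph needs at least 2 epitopes")
  if (anyDuplicated(flanked$id)) abort("epitope ids must be unique")
  if (is.character(motif)) motif <- parse_motif(motif)
  targets <- flanked$sequence
  pairs <- expand.grid(
    i = seq_len(nrow(flanked)), j = seq_len(nrow(flanked))
  )
  pairs <- pairs[pairs$i != pairs$j, ]
  pairs <- pairs[order(pairs$i, pairs$j), ]
  edges <- bind_rows(pmap(pairs, function(i, j) {
    best_junction(
      flanked$full_sequence[i], flanked$full_sequence[j], motif,
      model_pr, model_impr, panel, freqs, targets, config,
      pep1_id = flanked$id[i], pep2_id = flanked$id[j]
    )
  }))
  edges <- edges |>
    dplyr::rename(from = "pep1", to = "pep2") |>
    mutate(
      weight = ifelse(.data$status == "allowed", .data$w, config$disallowed_weight),
      ss = ifelse(.data$status == "allowed", .data$ss, NA_character_)
    )
  inform(sprintf(
    "design graph: %d nodes, %d edges (%d allowed, %d disallowed)",
    nrow(flanked), nrow(edges),
    sum(edges$status == "allowed"), sum(edges$status == "disallowed")
  ))
  structure(
    list(nodes = flanked, edges = edges, config = config, motif = motif),
    class = "design_graph"
  )
}

#' Assemble a design graph from precomputed edges
#'
#' Mainly for testing and for solver benchmarks on synthetic weight
#' matrices: wraps a node table and an edge table into a `design_graph`
#' without re-running junction evaluation.
#'
#' @param nodes Tibble with at least `id`, `full_sequence`.
#' @param edges Tibble with `from`, `to`, `ss`, `weight`, `status`.
#' @param config A [design_config()].
#' @return A `design_graph`.
#' @export
design_graph <- function(nodes, edges, config = design_config()) {
  need <- c("from", "to", "ss", "weight", "status")
  if (!all(need %in% names(edges))) {
    abort(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  }
  n <- nrow(nodes)
  if (nrow(edges) != n * (n - 1L)) {
    abort("design graph must be complete: one edge per ordered pair")
  }
  if (any(edges$from == edges$to)) abort("self-edges are not allowed")
  structure(
    list(nodes = nodes, edges = edges, config = config, motif = NULL),
    class = "design_graph"
  )
}

# n x n weight matrix (Inf-free; diagonal NA), rows/cols in node order.
edge_weight_matrix <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  W <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  W[cbind(
    match(graph$edges$from, ids),
    match(graph$edges$to, ids)
  )] <- graph$edges$weight
  W
}

#' @export
print.design_graph <- function(x, ...) {
  cat(sprintf(
    "<design_graph> %d nodes, %d edges (%d disallowed)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$status == "disallowed")
  ))
  invisible(x)
}

#' @rdname build_graph
#' @param x A `design_graph`.
#' @param ... Unused.
#' @method tidy design_graph
#' @export
tidy.design_graph <- function(x, ...) as_tibble(x$edges)

#' @rdname build_graph
#' @method glance design_graph
#' @export
glance.design_graph <- function(x, ...) {
  allowed <- x$edges$weight[x$edges$status == "allowed"]
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_disallowed = sum(x$edges$status == "disallowed"),
    min_weight = if (length(allowed)) min(allowed) else NA_real_,
    median_weight = if (length(allowed)) median(allowed) else NA_real_,
    max_weight = if (length(allowed)) max(allowed) else NA_real_
  )
}

#' Heatmap of pairwise junction weights
#'
#' @param object A `design_graph`.
#' @param ... Unused.
#' @return A ggplot: tile map of edge weights (disallowed edges hatched out
#'   as `NA`), ordered epitope pairs on the axes.
#' @method autoplot design_graph
#' @export
autoplot.design_graph <- function(object, ...) {
  ed <- object$edges
  ed$w_plot <- ifelse(ed$status == "allowed", ed$weight, NA_real_)
  ggplot2::ggplot(ed, ggplot2::aes(x = .data$to, y = .data$from)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$w_plot), colour = "grey80") +
    ggplot2::scale_fill_viridis_c(name = "junction W", na.value = "grey30") +
    ggplot2::scale_y_discrete(limits = rev(object$nodes$id)) +
    ggplot2::scale_x_discrete(limits = object$nodes$id) +
    ggplot2::labs(
      x = "second epitope", y = "first epitope",
      title = "Pairwise junction weights (grey = disallowed)"
    ) +
    ggplot2::theme_minimal()
}
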