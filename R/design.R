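#' Render a polyepitope design along an epitope ordering
#'
#' Concatenates the flanked peptides and the chosen spacers along the given
#' path. A path forced through a disallowed edge joins the pair directly
#' (no admissible spacer exists) and flags the design.
#'
#' @param graph A `design_graph`.
#' @param order Character vector: a permutation of all node ids.
#' @param solver Label recorded in the result.
#' @return Object of class `"polyepitope_design"`: list with `order`,
#'   `junctions` (edge rows along the path), `total_weight`, `sequence`,
#'   `contains_disallowed`, `solver`.
#' @export
render_polyepitope <- function(graph, order, solver = "manual") {
  ids <- graph$nodes$id
  if (!setequal(order, ids) || length(order) != length(ids)) {
    abort("order must be a permutation of all node ids")
  }
  if (length(order) == 1L) {
    return(structure(
      list(
        order = order, junctions = graph$edges[0, ],
        total_weight = 0,
        sequence = graph$nodes$full_sequence[match(order, ids)],
        contains_disallowed = FALSE, solver = solver
      ),
      class = "polyepitope_design"
    ))
  }
  steps <- tibble(from = order[-length(order)], to = order[-1L])
  jx <- dplyr::inner_join(steps, graph$edges, by = c("from", "to"))
  if (nrow(jx) != nrow(steps)) abort("graph is missing edges along the path")
  pieces <- character(2L * length(order) - 1L)
  pieces[seq(1L, by = 2L, length.out = length(order))] <-
    graph$nodes$full_sequence[match(order, ids)]
  spacers <- ifelse(is.na(jx$ss), "", jx$ss)
  pieces[seq(2L, by = 2L, length.out = nrow(jx))] <- spacers
  structure(
    list(
      order = order,
      junctions = jx,
      total_weight = sum(jx$weight),
      sequence = paste(pieces, collapse = ""),
      contains_disallowed = any(jx$status == "disallowed"),
      solver = solver
    ),
    class = "polyepitope_design"
  )
}

#' @export
print.polyepitope_design <- function(x, ...) {
  cat(sprintf(
    "<polyepitope_design> %d epitopes, total weight %.3f (%s solver)%s\n",
    length(x$order), x$total_weight, x$solver,
    if (x$contains_disallowed) " [contains disallowed junction]" else ""
  ))
  cat("  order:   ", paste(x$order, collapse = " -> "), "\n")
  cat("  sequence:", x$sequence, "\n")
  invisible(x)
}

#' Tidy a polyepitope design
#'
#' One row per junction along the path, in path order.
#'
#' @param x A `polyepitope_design`.
#' @param ... Unused.
#' @return Tibble of junctions.
#' @method tidy polyepitope_design
#' @export
tidy.polyepitope_design <- function(x, ...) as_tibble(x$junctions)

#' One-row design summary
#'
#' @param x A `polyepitope_design`.
#' @param ... Unused.
#' @return Tibble: epitope count, total weight, sequence length,
#'   disallowed flag, solver.
#' @method glance polyepitope_design
#' @export
glance.polyepitope_design <- function(x, ...) {
  tibble(
    n_epitopes = length(x$order),
    total_weight = x$total_weight,
    sequence_length = nchar(x$sequence),
    contains_disallowed = x$contains_disallowed,
    solver = x$solver
  )
}

#' Junction-weight profile of a design
#'
#' @param object A `polyepitope_design`.
#' @param ... Unused.
#' @return A ggplot: bar chart of W per junction along the construct.
#' @method autoplot polyepitope_design
#' @export
autoplot.polyepitope_design <- function(object, ...) {
  jx <- as_tibble(object$junctions)
  jx$junction <- factor(
    paste(jx$from, jx$to, sep = " → "),
    levels = paste(jx$from, jx$to, sep = " → ")
  )
  ggplot2::ggplot(jx, ggplot2::aes(x = .data$junction, y = .data$weight,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(allowed = "#2c7fb8", disallowed = "#de2d26")) +
    ggplot2::labs(
      x = NULL, y = "junction weight W",
      title = "Junction weights along the polyepitope"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write design outputs
#'
#' Emits the designed polyepitope as a single-record FASTA, the junction
#' report as TSV (columns `pep1`, `pep2`, `spacer`, `rank_pr`, `rank_impr`,
#' `n_eps`, `n_hla`, `weighted_sum`, `w`, `status`) and a machine-readable
#' run summary as key-value lines.
#'
#' @param design A `polyepitope_design`.
#' @param out_prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>_junctions.tsv`, `<prefix>_summary.txt`.
#' @param run_name FASTA record id.
#' @param config Optional [design_config()] echoed into the summary.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_design <- function(design, out_prefix, run_name = "polyepitope",
                         config = NULL) {
  stopifnot(inherits(design, "polyepitope_design"))
  fa <- paste0(out_prefix, ".fasta")
  aa <- Biostrings::AAStringSet(setNames(design$sequence, run_name))
  Biostrings::writeXStringSet(aa, fa)

  tsv <- paste0(out_prefix, "_junctions.tsv")
  jx <- as_tibble(design$junctions) |>
    mutate(spacer = ifelse(is.na(.data$ss), "-", .data$ss)) |>
    select("from", "to", "spacer", "rank_pr", "rank_impr",
           "n_eps", "n_hla", "weighted_sum", "w", "status", "weight")
  readr::write_tsv(jx, tsv, progress = FALSE)

  smry <- paste0(out_prefix, "_summary.txt")
  lines <- c(
    sprintf("run_name=%s", run_name),
    sprintf("solver=%s", design$solver),
    sprintf("order=%s", paste(design$order, collapse = ",")),
    sprintf("total_weight=%.6f", design$total_weight),
    sprintf("sequence=%s", design$sequence),
    sprintf("sequence_length=%d", nchar(design$sequence)),
    sprintf("contains_disallowed=%s", tolower(design$contains_disallowed))
  )
  if (!is.null(config)) {
    lines <- c(lines, sprintf(
      "config.%s=%s",
      names(config),
      vapply(config, function(v) {
        if (is.null(v)) "self-calibrated" else paste(v, collapse = ",")
      }, character(1))
    ))
  }
  writeLines(lines, smry)
  invisible(c(fasta = fa, junctions = tsv, summary = smry))
}
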