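# All permutations of 1..n in lexicographic order, one per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  dimnames(out) <- NULL
  out
}

path_weight <- function(W, perm) {
  if (length(perm) < 2L) return(0)
  sum(W[cbind(perm[-length(perm)], perm[-1L])])
}

#' Exhaustive minimum-weight Hamiltonian path
#'
#' Scans all n! epitope orderings and returns the globally minimal-weight
#' open path. Guarded at n <= 8 (40320 orderings); larger instances should
#' use [solve_ga()].
#'
#' @param graph A `design_graph`.
#' @return A `polyepitope_design` (see [render_polyepitope()]); ties are
#'   broken lexicographically on the id sequence.
#' @export
solve_exhaustive <- function(graph) {
  n <- nrow(graph$nodes)
  if (n > 8L) {
    abort(sprintf(
      "exhaustive search refused for %d nodes (> 8); use solve_ga()", n
    ))
  }
  if (n == 1L) return(render_polyepitope(graph, graph$nodes$id, solver = "exhaustive"))
  W <- edge_weight_matrix(graph)
  # enumerate in lexicographic id order so the first minimum is the tie-break
  ord_ids <- order(graph$nodes$id)
  perms <- all_permutations(n)
  weights <- vapply(
    seq_len(nrow(perms)),
    function(k) path_weight(W, ord_ids[perms[k, ]]),
    numeric(1)
  )
  best <- perms[which.min(weights), ]
  render_polyepitope(graph, graph$nodes$id[ord_ids[best]], solver = "exhaustive")
}

#' Greedy nearest-neighbour Hamiltonian path
#'
#' From each possible start node, repeatedly follows the cheapest outgoing
#' edge to an unvisited node (ties: first node in table order); returns the
#' best of the n resulting paths. Deterministic. In the original workflow
#' this heuristic is reserved for nondegenerate spacer motifs.
#'
#' @param graph A `design_graph`.
#' @return A `polyepitope_design`.
#' @export
solve_greedy <- function(graph) {
  n <- nrow(graph$nodes)
  W <- edge_weight_matrix(graph)
  best_perm <- NULL
  best_w <- Inf
  for (start in seq_len(n)) {
    perm <- integer(n)
    perm[1L] <- start
    visited <- rep(FALSE, n)
    visited[start] <- TRUE
    for (k in seq_len(n - 1L)) {
      w <- W[perm[k], ]
      w[visited] <- Inf
      nxt <- which.min(w)          # first index on ties
      perm[k + 1L] <- nxt
      visited[nxt] <- TRUE
    }
    pw <- path_weight(W, perm)
    if (pw < best_w) {
      best_w <- pw
      best_perm <- perm
    }
  }
  render_polyepitope(graph, graph$nodes$id[best_perm], solver = "greedy")
}

# Order crossover (OX): child keeps parent1[i:j]; remaining genes appear in
# parent2's cyclic order starting after j.
ox_crossover <- function(p1, p2) {
  n <- length(p1)
  cut <- sort(sample.int(n, 2L))
  i <- cut[1L]; j <- cut[2L]
  child <- integer(n)
  child[i:j] <- p1[i:j]
  fill <- setdiff(p2[c(seq_len(n) + j - 1L) %% n + 1L], p1[i:j])
  slots <- setdiff(seq_len(n), i:j)
  slots <- slots[order((slots - j - 1L) %% n)]  # positions after j, wrapping
  child[slots] <- fill
  child
}

#' Genetic-algorithm Hamiltonian-path solver
#'
#' Permutation-encoded GA minimizing open-path weight: tournament
#' selection, order crossover (OX), per-gene swap mutation, elitism. With a
#' fixed seed the result is bit-identical across runs. Parameters come from
#' the graph's [design_config()] unless overridden.
#'
#' @param graph A `design_graph` with >= 2 nodes.
#' @param seed Integer random seed (required: design runs must be
#'   reproducible).
#' @param params Optional named list overriding `ga_*` config entries
#'   (`pop_size`, `generations`, `cx_prob`, `mut_prob`, `tournament`,
#'   `elitism`).
#' @return A `polyepitope_design` from the best individual of the final
#'   generation.
#' @export
solve_ga <- function(graph, seed, params = list()) {
  n <- nrow(graph$nodes)
  if (n < 2L) abort("GA solver needs at least 2 nodes")
  cfg <- graph$config
  p <- list(
    pop_size = cfg$ga_pop_size, generations = cfg$ga_generations,
    cx_prob = cfg$ga_cx_prob, mut_prob = cfg$ga_mut_prob,
    tournament = cfg$ga_tournament, elitism = cfg$ga_elitism
  )
  bad <- setdiff(names(params), names(p))
  if (length(bad)) abort(sprintf("unknown GA parameter(s): %s", paste(bad, collapse = ", ")))
  p[names(params)] <- params
  if (p$pop_size < 1L || p$generations < 0L || p$tournament < 1L ||
      p$cx_prob < 0 || p$cx_prob > 1 || p$mut_prob < 0 || p$mut_prob > 1 ||
      p$elitism < 0L || p$elitism > p$pop_size) {
    abort("invalid GA parameters")
  }
  if (missing(seed) || is.null(seed)) abort("solve_ga requires an explicit seed")
  W <- edge_weight_matrix(graph)

  best <- withr::with_seed(as.integer(seed), {
    pop <- replicate(p$pop_size, sample.int(n), simplify = FALSE)
    fit <- vapply(pop, function(x) path_weight(W, x), numeric(1))
    gen <- 0L
    while (gen < p$generations) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(min(p$elitism, p$pop_size))]]
      newpop <- elite
      while (length(newpop) < p$pop_size) {
        pick <- function() {
          cand <- sample.int(p$pop_size, p$tournament, replace = TRUE)
          pop[[cand[which.min(fit[cand])]]]
        }
        pa <- pick(); pb <- pick()
        child <- if (runif(1) < p$cx_prob && n >= 2L) ox_crossover(pa, pb) else pa
        mut <- which(runif(n) < p$mut_prob)
        for (g in mut) {
          h <- sample.int(n, 1L)
          tmp <- child[g]; child[g] <- child[h]; child[h] <- tmp
        }
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, function(x) path_weight(W, x), numeric(1))
      gen <- gen + 1L
    }
    pop[[which.min(fit)]]
  })
  render_polyepitope(graph, graph$nodes$id[best], solver = "ga")
}
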