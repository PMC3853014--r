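hand_graph <- function() {
  # w(A->B)=1, w(B->C)=2, w(A->C)=5, w(B->A)=4, w(C->A)=6, w(C->B)=3
  nodes <- tibble::tibble(
    id = c("A", "B", "C"),
    sequence = c("SLYNTVATL", "ILKEPVHGV", "KIRLRPGGK")
  )
  nodes$full_sequence <- nodes$sequence
  edges <- tibble::tibble(
    from  = c("A", "B", "A", "B", "C", "C"),
    to    = c("B", "C", "C", "A", "A", "B"),
    ss    = "AD",
    weight = c(1, 2, 5, 4, 6, 3),
    status = "allowed"
  )
  design_graph(nodes, edges)
}

test_that("exhaustive solver finds the hand-enumerated optimum", {
  d <- solve_exhaustive(hand_graph())
  expect_equal(d$order, c("A", "B", "C"))
  expect_equal(d$total_weight, 3)
  expect_false(d$contains_disallowed)
})

test_that("exhaustive solver handles a single node and refuses n > 8", {
  nodes <- tibble::tibble(id = "A", sequence = "SLYNTVATL",
                          full_sequence = "SLYNTVATL")
  g1 <- design_graph(nodes, tibble::tibble(
    from = character(0), to = character(0), ss = character(0),
    weight = numeric(0), status = character(0)
  ))
  d1 <- solve_exhaustive(g1)
  expect_equal(d1$order, "A")
  expect_equal(d1$total_weight, 0)

  g9 <- random_edge_graph(9, seed = 1)
  expect_error(solve_exhaustive(g9), "use solve_ga")
})

test_that("exhaustive solver matches an independently coded permutation scan", {
  for (s in 1:5) {
    g <- random_edge_graph(6, seed = 100 + s)
    d <- solve_exhaustive(g)
    o <- oracle_min_path(g)
    expect_equal(d$total_weight, o$w, tolerance = 1e-9)
    expect_identical(d$order, o$order)
  }
})

test_that("greedy follows cheapest edges, never beats the optimum", {
  d <- solve_greedy(hand_graph())
  expect_equal(d$order, c("A", "B", "C"))
  expect_equal(d$total_weight, 3)

  for (s in 1:10) {
    g <- random_edge_graph(6, seed = 300 + s)
    expect_gte(solve_greedy(g)$total_weight,
               solve_exhaustive(g)$total_weight - 1e-9)
  }

  # degenerate tie case: all weights equal
  g <- hand_graph()
  g$edges$weight <- 2
  expect_equal(solve_greedy(g)$total_weight, 4)  # (n-1) * w
})

test_that("greedy can be trapped by an adversarial instance", {
  # from every start the locally cheapest edge leads into an expensive tail
  nodes <- tibble::tibble(id = c("A", "B", "C", "D"))
  nodes$sequence <- nodes$full_sequence <- "SLYNTVATL"
  pairs <- expand.grid(from = nodes$id, to = nodes$id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  w <- c("A B" = 1, "B C" = 10, "C D" = 10, "A C" = 2, "C B" = 1.5,
         "B D" = 10, "A D" = 9, "B A" = 9, "C A" = 9, "D A" = 9,
         "D B" = 9, "D C" = 9)
  edges <- tibble::tibble(
    from = pairs$from, to = pairs$to, ss = "A",
    weight = unname(w[paste(pairs$from, pairs$to)]), status = "allowed"
  )
  g <- design_graph(nodes, edges)
  expect_gte(solve_greedy(g)$total_weight,
             solve_exhaustive(g)$total_weight)
})

test_that("GA is deterministic under a fixed seed and needs one", {
  g <- random_edge_graph(6, seed = 7)
  a <- solve_ga(g, seed = 11)
  b <- solve_ga(g, seed = 11)
  expect_identical(a$order, b$order)
  expect_equal(a$total_weight, b$total_weight)
  expect_error(solve_ga(g), "seed")
  expect_error(solve_ga(g, seed = 1, params = list(bogus = 2)), "unknown GA")
})

test_that("a degenerate GA returns the seeded random permutation", {
  g <- random_edge_graph(5, seed = 3)
  d <- solve_ga(g, seed = 5, params = list(pop_size = 1, generations = 0))
  perm <- withr::with_seed(5L, sample.int(5))
  expect_identical(d$order, g$nodes$id[perm])
  W <- polyepi:::edge_weight_matrix(g)
  expect_equal(d$total_weight, polyepi:::path_weight(W, perm))
})

test_that("GA with default parameters reaches the exhaustive optimum", {
  hits <- 0L
  for (s in 1:5) {
    g <- random_edge_graph(sample(5:7, 1), seed = 500 + s)
    opt <- solve_exhaustive(g)$total_weight
    got <- solve_ga(g, seed = 600 + s)$total_weight
    expect_gte(got, opt - 1e-9)
    if (abs(got - opt) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("rendering concatenates peptides and spacers and keeps the books", {
  g <- hand_graph()
  d <- render_polyepitope(g, c("A", "B", "C"))
  # three 9-mers and two 2-residue spacers
  expect_equal(nchar(d$sequence), 3 * 9 + 2 * 2)
  expect_equal(d$sequence,
               paste0("SLYNTVATL", "AD", "ILKEPVHGV", "AD", "KIRLRPGGK"))
  expect_equal(d$total_weight, sum(d$junctions$weight))
  expect_error(render_polyepitope(g, c("A", "B")), "permutation")
  expect_error(render_polyepitope(g, c("A", "B", "B")), "permutation")

  # disallowed edge on the path: direct join, flagged, weight >= 5000
  g$edges$status[g$edges$from == "A" & g$edges$to == "B"] <- "disallowed"
  g$edges$weight[g$edges$from == "A" & g$edges$to == "B"] <- 5000
  g$edges$ss[g$edges$from == "A" & g$edges$to == "B"] <- NA
  d2 <- render_polyepitope(g, c("A", "B", "C"))
  expect_true(d2$contains_disallowed)
  expect_gte(d2$total_weight, 5000)
  expect_equal(nchar(d2$sequence), 3 * 9 + 2)
})

test_that("every solver returns a valid permutation", {
  g <- random_edge_graph(6, seed = 77, p_disallowed = 0.2)
  for (d in list(solve_exhaustive(g), solve_greedy(g), solve_ga(g, seed = 2))) {
    expect_setequal(d$order, g$nodes$id)
    expect_length(d$order, 6L)
    expect_equal(d$total_weight, sum(d$junctions$weight))
  }
})

test_that("graph construction from fixtures produces a complete digraph", {
  fx <- build_fixtures(fixture_spec(seed = 9, n_epitopes = 3, n_alleles = 2))
  cfg <- design_config(tap_threshold = -100)  # no flanks, keep it fast
  fl <- flank_epitopes(fx$epitopes, fx$tap, cfg)
  g <- quiet(build_graph(fl, fx$motif, fx$cleavage_pr, fx$cleavage_impr,
                         fx$panel, fx$freqs, cfg))
  expect_equal(nrow(g$edges), 3 * 2)
  expect_true(all(g$edges$weight[g$edges$status == "allowed"] < 5000))
  expect_false(any(g$edges$from == g$edges$to))

  # per-edge oracle: every edge equals an independent best_junction recompute
  for (k in seq_len(nrow(g$edges))) {
    e <- g$edges[k, ]
    i <- match(e$from, fl$id); j <- match(e$to, fl$id)
    o <- quiet(oracle_best_junction(
      fl$full_sequence[i], fl$full_sequence[j], fx$motif,
      fx$cleavage_pr, fx$cleavage_impr, fx$panel, fx$freqs,
      targets = fl$sequence, cfg = cfg
    ))
    expect_equal(e$w, o$w, tolerance = 1e-9)
    expect_identical(e$ss, o$ss)
  }
})
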