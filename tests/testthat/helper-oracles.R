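# Independent oracles and random-fixture builders. These deliberately avoid
# the code paths they check: permutation scans are recursive rather than
# table-generated, and the junction oracle re-enumerates candidates and
# re-derives W from raw components.

# Complete random design graph over synthetic edge weights.
random_edge_graph <- function(n, seed, p_disallowed = 0, cfg = design_config()) {
  withr::with_seed(seed, {
    ids <- paste0("e", seq_len(n))
    nodes <- tibble::tibble(
      id = ids,
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(AA_ALPHABET, 9, replace = TRUE), collapse = "")
      }, character(1))
    )
    nodes$full_sequence <- nodes$sequence
    pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    dis <- stats::runif(nrow(pairs)) < p_disallowed
    edges <- tibble::tibble(
      from = pairs$from, to = pairs$to,
      ss = ifelse(dis, NA_character_, "A"),
      weight = ifelse(dis, cfg$disallowed_weight, round(stats::runif(nrow(pairs), 1, 9), 3)),
      status = ifelse(dis, "disallowed", "allowed")
    )
    design_graph(nodes, edges, cfg)
  })
}

# Recursive exhaustive minimum-weight open path; ids visited in sorted order
# with strict improvement, so the first lexicographic optimum wins ties.
# Also counts how many orderings attain the optimum.
oracle_min_path <- function(graph) {
  ids <- sort(graph$nodes$id)
  wt <- stats::setNames(
    graph$edges$weight,
    paste(graph$edges$from, graph$edges$to)
  )
  best <- list(w = Inf, order = NULL, n_optimal = 0L)
  recurse <- function(prefix, remaining, acc) {
    if (length(remaining) == 0L) {
      if (acc < best$w - 1e-9) {
        best <<- list(w = acc, order = prefix, n_optimal = 1L)
      } else if (abs(acc - best$w) <= 1e-9) {
        best$n_optimal <<- best$n_optimal + 1L
      }
      return(invisible())
    }
    for (x in remaining) {
      step <- if (length(prefix)) wt[[paste(prefix[length(prefix)], x)]] else 0
      recurse(c(prefix, x), setdiff(remaining, x), acc + step)
    }
  }
  recurse(character(0), ids, 0)
  best
}

# Random cleavage model with a handful of random degenerate patterns.
random_cleavage_model <- function(kind, seed) {
  withr::with_seed(seed, {
    npat <- sample(2:5, 1)
    pats <- vapply(seq_len(npat), function(i) {
      paste(vapply(1:6, function(j) {
        if (stats::runif(1) < 0.55) "." else {
          paste0("[", paste(sample(AA_ALPHABET, sample(1:5, 1)), collapse = ""), "]")
        }
      }, character(1)), collapse = "")
    }, character(1))
    cleavage_model(
      kind,
      tibble::tibble(pattern = pats, rank = sample(1:11, npat, replace = TRUE)),
      default_rank = sample(1:11, 1)
    )
  })
}

random_peptide <- function(len = 9L) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Independent exhaustive junction scan: own candidate expansion, own W
# arithmetic from raw summary components.
oracle_best_junction <- function(p1, p2, motif, mpr, mimpr, panel, freqs,
                                 targets, cfg) {
  cands <- ""
  for (k in seq_along(motif$positions)) {
    grid <- do.call(
      expand.grid,
      c(motif$positions[seq_len(k)], list(stringsAsFactors = FALSE))
    )
    cands <- c(cands, apply(as.matrix(grid), 1, paste, collapse = ""))
  }
  cands <- unique(cands)
  evs <- lapply(cands, function(ss) {
    cr <- rank_epitope_cterm(p1, ss, p2, mpr, mimpr)
    hits <- scan_junction(p1, ss, p2, panel, targets, cfg)
    if (nrow(hits) > 0L) {
      bestr <- tapply(hits$rank, hits$allele, max)
      fr <- freqs$frequency[match(names(bestr), freqs$allele)]
      fr[is.na(fr)] <- 0
      wsum <- sum(bestr * fr)
      neps <- nrow(unique(hits[, c("peptide", "allele")]))
      nhla <- length(bestr)
      meanterm <- 0.05 * (4 - mean(bestr))
    } else {
      wsum <- 0; neps <- 0L; nhla <- 0L; meanterm <- 0
    }
    w <- wsum + nchar(ss) + 0.5 * min(cr$rank_pr, cr$rank_impr) + meanterm +
      0.05 * neps + 0.05 * nhla + 0.25 * cr$rank_pr + 0.25 * cr$rank_impr
    list(ss = ss, w = w,
         adm = min(cr$rank_pr, cr$rank_impr) <= cfg$cleavage_allow_threshold)
  })
  adm <- Filter(function(e) e$adm, evs)
  pool <- if (length(adm) > 0L) adm else evs
  ws <- vapply(pool, `[[`, numeric(1), "w")
  sss <- vapply(pool, `[[`, character(1), "ss")
  ord <- order(ws, nchar(sss), sss)
  list(ss = sss[ord[1]], w = ws[ord[1]], allowed = length(adm) > 0L)
}

# Small all-zero TAP matrix / PSSM builders for targeted fixtures.
zero_tap <- function() {
  tap_matrix(matrix(0, 20, 4,
                    dimnames = list(AA_ALPHABET, c("N1", "N2", "N3", "C"))))
}

const_pssm <- function(allele, length = 9L, intercept = 0, set = NULL) {
  w <- matrix(0, 20, length, dimnames = list(AA_ALPHABET, NULL))
  if (!is.null(set)) for (s in set) w[s$residue, s$position] <- s$value
  mhc_pssm(allele, length, w, intercept)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
quiet_msgs <- function(expr) suppressMessages(expr)
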