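test_that("core scan finds exactly the planted window", {
  # matrix that scores 9 only for a window starting with 'W' at P1
  p <- const_pssm("DR1", 9, intercept = 0,
                  set = list(list(residue = "W", position = 1, value = 9)))
  antigen <- paste0(strrep("A", 10), "WLLLLLLLL", strrep("A", 10))
  hits <- scan_th_cores(antigen, list(p), threshold = 9)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 11L)  # brute-force window position
  expect_equal(hits$peptide, "WLLLLLLLL")

  # all-zero matrices with a positive threshold: no hits
  expect_equal(nrow(scan_th_cores(antigen, list(const_pssm("DR2", 9)), 1)), 0L)

  # hit set invariant under panel reordering
  p2 <- const_pssm("DR2", 9, intercept = 0,
                   set = list(list(residue = "A", position = 1, value = 5)))
  h1 <- scan_th_cores(antigen, list(p, p2), threshold = c(DR1 = 9, DR2 = 5))
  h2 <- scan_th_cores(antigen, list(p2, p), threshold = c(DR1 = 9, DR2 = 5))
  expect_setequal(paste(h1$allele, h1$start), paste(h2$allele, h2$start))
})

test_that("fragment selection covers a hit cluster with a floor-20 core", {
  # 3 overlapping 9-mer hits at starts 21, 23, 25: cluster spans 21..33
  p <- const_pssm("DR1", 9, intercept = 0,
                  set = list(list(residue = "W", position = 1, value = 9)))
  antigen <- paste0(
    strrep("A", 20), "W", "A", "W", "A", "W", strrep("L", 8), strrep("A", 20)
  )
  hits <- scan_th_cores(antigen, list(p), threshold = 9)
  expect_equal(hits$start, c(21L, 23L, 25L))
  frags <- select_fragments(antigen, hits, antigen_id = "ag1")

  # exhaustive window-evaluation oracle: best = max alleles, max hits,
  # shortest, then leftmost
  best <- NULL
  n <- nchar(antigen)
  for (L in 20:40) for (s in seq_len(n - L + 1)) {
    inside <- hits$start >= s & hits$start + 8 <= s + L - 1
    cand <- list(s = s, e = s + L - 1, L = L,
                 ne = length(unique(hits$start[inside])),
                 na = length(unique(hits$allele[inside])))
    if (cand$ne == 0) next
    if (is.null(best) ||
        cand$na > best$na ||
        (cand$na == best$na && cand$ne > best$ne) ||
        (cand$na == best$na && cand$ne == best$ne && cand$L < best$L) ||
        (cand$na == best$na && cand$ne == best$ne && cand$L == best$L &&
         cand$s < best$s)) best <- cand
  }
  expect_equal(nrow(frags), 1L)
  expect_equal(frags$core_start, best$s)
  expect_equal(frags$core_end, best$e)
  expect_equal(frags$core_end - frags$core_start + 1L, 20L)  # padded to floor
  expect_equal(frags$n_epitopes, 3L)
  # extension is exactly 5 per side away from the termini
  expect_equal(frags$ext_start, frags$core_start - 5L)
  expect_equal(frags$ext_end, frags$core_end + 5L)
  expect_equal(frags$sequence,
               substr(antigen, frags$ext_start, frags$ext_end))
})

test_that("extensions clamp at antigen termini and short antigens warn", {
  p <- const_pssm("DR1", 9, intercept = 0,
                  set = list(list(residue = "W", position = 1, value = 9)))
  antigen <- paste0("W", strrep("L", 8), strrep("A", 16))  # length 25, hit at 1
  hits <- scan_th_cores(antigen, list(p), threshold = 9)
  frags <- select_fragments(antigen, hits)
  expect_equal(frags$ext_start, 1L)   # clamped
  expect_lte(frags$ext_end, 25L)

  expect_warning(f0 <- select_fragments(strrep("A", 15), hits), "shorter than 20")
  expect_equal(nrow(f0), 0L)
  expect_equal(nrow(select_fragments(antigen, hits[0, ])), 0L)  # no hits
})

test_that("accepted fragment cores never overlap and selection is deterministic", {
  p <- const_pssm("DR1", 9, intercept = 0,
                  set = list(list(residue = "W", position = 1, value = 9)))
  antigen <- paste0(
    strrep("A", 5), "W", strrep("L", 8),
    strrep("A", 40), "W", strrep("L", 8), strrep("A", 10)
  )
  hits <- scan_th_cores(antigen, list(p), threshold = 9)
  f1 <- select_fragments(antigen, hits)
  f2 <- select_fragments(antigen, hits)
  expect_identical(f1, f2)
  expect_gte(nrow(f1), 2L)
  if (nrow(f1) >= 2L) {
    ord <- order(f1$core_start)
    expect_true(all(f1$core_start[ord][-1] > f1$core_end[ord][-nrow(f1)]))
  }
  expect_true(all(f1$core_end - f1$core_start + 1 >= 20))
  expect_true(all(f1$core_end - f1$core_start + 1 <= 40))
})

test_that("fragments are joined through the di-basic motif by minimal W", {
  fx <- build_fixtures(fixture_spec(seed = 21, n_alleles = 2, n_epitopes = 2))
  frags <- tibble::tibble(
    antigen_id = "ag1",
    core_start = c(6L, 46L), core_end = c(25L, 65L),
    ext_start = c(1L, 41L), ext_end = c(30L, 70L),
    n_epitopes = c(2L, 1L), n_alleles = c(1L, 1L),
    sequence = c(strrep("ALSVTN", 5), strrep("ILKEPW", 5))
  )
  th <- quiet(join_fragments(frags, "[KR][KR]", fx$cleavage_pr,
                             fx$cleavage_impr, fx$panel, fx$freqs))
  expect_equal(nrow(th$junctions), 1L)
  expect_true(th$junctions$ss %in% c("", "K", "R", "KK", "KR", "RK", "RR"))
  expect_equal(
    th$sequence,
    paste0(frags$sequence[1], th$junctions$ss, frags$sequence[2])
  )

  # chosen spacer equals an independent minimal-W re-evaluation
  o <- quiet(oracle_best_junction(
    frags$sequence[1], frags$sequence[2], parse_motif("[KR][KR]"),
    fx$cleavage_pr, fx$cleavage_impr, fx$panel, fx$freqs,
    targets = character(0), cfg = design_config()
  ))
  # th joins take the global minimum-W candidate (no admissibility gate)
  expect_equal(th$junctions$w, o$w, tolerance = 1e-9)

  # single fragment: identity
  th1 <- join_fragments(frags[1, ], "[KR][KR]", fx$cleavage_pr,
                        fx$cleavage_impr, fx$panel, fx$freqs)
  expect_equal(th1$sequence, frags$sequence[1])
  expect_equal(nrow(th1$junctions), 0L)
})
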