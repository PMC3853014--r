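test_that("pIC50 prediction is intercept plus per-position lookups", {
  expect_equal(predict_pic50("SLYNTVATL", const_pssm("A1", intercept = 6.0)), 6.0)

  p <- const_pssm("A1", intercept = 6.0,
                  set = list(list(residue = "S", position = 1, value = 0.5)))
  expect_equal(predict_pic50("SLYNTVATL", p), 6.5)
  expect_equal(predict_pic50("TLYNTVATL", p), 6.0)

  # random 9-mer against an independent 9-lookup summation oracle
  pr <- random_pssm("A2", 9, seed = 19, intercept = 5.5, sd = 0.8)
  withr::with_seed(4, {
    for (i in 1:10) {
      pep <- random_peptide(9)
      ch <- strsplit(pep, "")[[1]]
      expected <- pr$intercept +
        sum(vapply(1:9, function(k) pr$weights[ch[k], k], numeric(1)))
      expect_equal(predict_pic50(pep, pr), expected)
    }
  })
  expect_error(predict_pic50("SLYNTVAT", pr), "length mismatch")
})

test_that("binding rank uses closed lower bounds at 6.3, 7.3 and 8.3", {
  expect_equal(binding_rank(5.0), 0L)
  expect_equal(binding_rank(6.3), 1L)
  expect_equal(binding_rank(7.3), 2L)
  expect_equal(binding_rank(7.8), 2L)
  expect_equal(binding_rank(8.3), 3L)
  expect_equal(binding_rank(6.2999), 0L)
  # monotone non-decreasing
  x <- sort(stats::runif(200, 4, 10))
  expect_true(all(diff(binding_rank(x)) >= 0))
})

test_that("junction scan enumerates exactly the straddling windows", {
  hot <- const_pssm("A1", 9, intercept = 9)  # every 9-mer is a rank-3 binder
  cfg <- design_config(junction_lengths = 9L)
  # 9 + 2 + 9 = 20 residues: 12 nine-mer windows minus one inside each peptide
  h <- scan_junction("SLYNTVATL", "AD", "ILKEPVHGV", list(hot), config = cfg)
  expect_equal(nrow(h), 10L)
  expect_true(all(h$start >= 2 & h$start <= 11))
  # empty spacer, identical 9-mers: 8 straddling windows
  h2 <- scan_junction("AAAAAAAAA", "", "AAAAAAAAA", list(hot), config = cfg)
  expect_equal(nrow(h2), 8L)
})

test_that("windows equal to a target epitope are excluded from the scan", {
  hot <- const_pssm("A1", 9, intercept = 9)
  cfg <- design_config(junction_lengths = 9L)
  h <- scan_junction("AAAAAAAAA", "", "AAAAAAAAA", list(hot),
                     targets = "AAAAAAAAA", config = cfg)
  expect_equal(nrow(h), 0L)  # every straddling window equals the target
})

test_that("scan respects matrix lengths and warns on an empty panel", {
  hot9 <- const_pssm("A1", 9, intercept = 9)
  hot10 <- const_pssm("B1", 10, intercept = 9)
  cfg <- design_config(junction_lengths = c(9L, 10L))
  h <- scan_junction("SLYNTVATL", "AD", "ILKEPVHGV", list(hot9, hot10),
                     config = cfg)
  expect_setequal(unique(h$length[h$allele == "A1"]), 9L)
  expect_setequal(unique(h$length[h$allele == "B1"]), 10L)
  expect_warning(h0 <- scan_junction("SLYNTVATL", "AD", "ILKEPVHGV", list(),
                                     config = cfg), "empty MHC panel")
  expect_equal(nrow(h0), 0L)
})

test_that("scan output is local to the junction neighbourhood", {
  panel <- list(random_pssm("A1", 9, seed = 8, intercept = 6.5, sd = 0.5))
  cfg <- design_config(junction_lengths = 9L)
  withr::with_seed(15, {
    for (i in 1:10) {
      p1 <- random_peptide(12)
      p2 <- random_peptide(9)
      h <- scan_junction(p1, "A", p2, list(panel[[1]]), config = cfg)
      # perturbing p1 more than 8 positions before the junction cannot matter
      p1b <- p1
      substr(p1b, 1, 1) <- sample(setdiff(AA_ALPHABET, substr(p1, 1, 1)), 1)
      hb <- scan_junction(p1b, "A", p2, list(panel[[1]]), config = cfg)
      expect_equal(h$peptide, hb$peptide)
      expect_equal(h$pic50, hb$pic50)
    }
  })
})

test_that("junction summary computes best ranks, counts and weighted sum", {
  freqs <- frequency_table(c("A1", "B1"), c(0.1, 0.3))
  empty <- summarize_junction(polyepi:::empty_hits(), freqs)
  expect_equal(empty$n_eps, 0L)
  expect_equal(empty$n_hla, 0L)
  expect_equal(empty$mean_rank, 0)
  expect_equal(empty$weighted_sum, 0)

  one <- tibble::tibble(peptide = "X", start = 1L, length = 9L,
                        allele = "A1", pic50 = 7.5, rank = 2L)
  s1 <- summarize_junction(one, freqs)
  expect_equal(s1$n_eps, 1L); expect_equal(s1$n_hla, 1L)
  expect_equal(s1$mean_rank, 2); expect_equal(s1$weighted_sum, 0.2)

  two <- tibble::tibble(peptide = c("X", "Y"), start = c(1L, 2L),
                        length = 9L, allele = "A1",
                        pic50 = c(6.5, 8.5), rank = c(1L, 3L))
  s2 <- summarize_junction(two, freqs)
  expect_equal(unname(s2$per_allele["A1"]), 3L)  # best = max
  expect_equal(s2$n_eps, 2L); expect_equal(s2$n_hla, 1L)

  # bound: sum of best_rank * freq <= 3 * sum freq
  expect_lte(s2$weighted_sum, 3 * sum(freqs$frequency))
})

test_that("PSSM files round-trip", {
  p <- random_pssm("HLA-A*02:01", 10, seed = 44, intercept = 5.2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pssm(p, f)
  p2 <- read_pssm(f)
  expect_equal(p2$allele, p$allele)
  expect_equal(p2$length, p$length)
  expect_equal(p2$intercept, p$intercept, tolerance = 1e-6)
  expect_equal(p2$weights, p$weights, tolerance = 1e-6)
})
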