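#' Specification for a synthetic fixture set
#'
#' Describes a fully synthetic, clearly labelled parameter-file set with
#' planted structure: one designated "good" spacer residue whose appearance
#' immediately after a scissile bond gives cleavage rank 1 in both
#' proteasome tables, against a high (inefficient) default rank. Epitopes
#' are generated so that none begins with the good residue, so the planted
#' optimal spacer for every ordered pair is the single good residue — the
#' construction itself is the oracle. Same seed, same fixture, byte for
#' byte.
#'
#' @param seed Integer seed.
#' @param n_alleles Number of HLA class-I alleles (and frequency rows).
#' @param n_epitopes Number of 9-mer epitopes.
#' @param good_residue Spacer residue planted as the efficient cleavage
#'   signal (default `"G"`).
#' @param default_rank Default (inefficient) cleavage rank (default 9).
#' @return List of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_alleles = 3L, n_epitopes = 6L,
                         good_residue = "G", default_rank = 9L) {
  stopifnot(
    n_alleles >= 1L, n_epitopes >= 2L,
    good_residue %in% AA_ALPHABET,
    default_rank > 7L, default_rank <= 11L
  )
  structure(
    list(
      seed = as.integer(seed), n_alleles = as.integer(n_alleles),
      n_epitopes = as.integer(n_epitopes),
      good_residue = good_residue, default_rank = as.integer(default_rank)
    ),
    class = "fixture_spec"
  )
}

#' Random TAP matrix (synthetic)
#'
#' @param seed Integer seed.
#' @param sd Spread of the normal score draws.
#' @return A `tap_matrix`.
#' @export
random_tap_matrix <- function(seed = 1L, sd = 1) {
  withr::with_seed(as.integer(seed), {
    m <- matrix(round(rnorm(80, sd = sd), 4), 20, 4,
                dimnames = list(AA_ALPHABET, c("N1", "N2", "N3", "C")))
    tap_matrix(m)
  })
}

#' Random MHC PSSM (synthetic)
#'
#' @param allele Allele label.
#' @param length Peptide length.
#' @param seed Integer seed.
#' @param intercept Intercept (default 5, so random 9-mers sit below the
#'   6.3 binder threshold unless weights push them up).
#' @param sd Spread of the weight draws.
#' @param mhc_class `"I"` or `"II"`.
#' @return An `mhc_pssm`.
#' @export
random_pssm <- function(allele, length = 9L, seed = 1L, intercept = 5,
                        sd = 0.3, mhc_class = "I") {
  withr::with_seed(as.integer(seed), {
    w <- matrix(round(rnorm(20 * length, sd = sd), 4), 20, length,
                dimnames = list(AA_ALPHABET, NULL))
    mhc_pssm(allele, length, w, intercept, mhc_class)
  })
}

# Planted cleavage model: P1' = good residue -> rank 1, everything else the
# default. Window P4-P2': pattern "....[G]." constrains slot 5 only.
planted_cleavage_model <- function(kind, good_residue, default_rank,
                                   good_rank = 1L) {
  cleavage_model(
    kind = kind,
    patterns = tibble(
      pattern = sprintf("....[%s].", good_residue),
      rank = as.integer(good_rank)
    ),
    default_rank = default_rank
  )
}

# Random 9-mer epitopes avoiding a first residue (so direct junctions never
# trip the planted cleavage signal by accident).
random_epitopes <- function(n, avoid_first = "G", length = 9L) {
  seqs <- vapply(seq_len(n), function(i) {
    first <- sample(setdiff(AA_ALPHABET, avoid_first), 1L)
    paste0(first, paste(sample(AA_ALPHABET, length - 1L, replace = TRUE),
                        collapse = ""))
  }, character(1))
  # regenerate collisions deterministically
  while (anyDuplicated(seqs)) {
    k <- which(duplicated(seqs))[1L]
    seqs[k] <- paste0(
      sample(setdiff(AA_ALPHABET, avoid_first), 1L),
      paste(sample(AA_ALPHABET, length - 1L, replace = TRUE), collapse = "")
    )
  }
  seqs
}

#' Build a synthetic fixture set in memory
#'
#' Deterministic in `spec$seed`. See [fixture_spec()] for the planted
#' structure.
#'
#' @param spec A `fixture_spec`.
#' @return List: `tap`, `cleavage_pr`, `cleavage_impr`, `panel` (class I),
#'   `class2_panel`, `freqs`, `epitopes`, `motif`, `manifest`.
#' @export
build_fixtures <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- spec$good_residue
  withr::with_seed(spec$seed, {
    alleles <- sprintf("HLA-X*%02d:01", seq_len(spec$n_alleles))
    freqs <- frequency_table(alleles, round(runif(spec$n_alleles, 0.01, 0.4), 4))
    epitopes <- epitope_table(
      random_epitopes(spec$n_epitopes, avoid_first = g),
      alleles = lapply(seq_len(spec$n_epitopes),
                       function(i) sample(alleles, 1L))
    )
    pssm_seeds <- sample.int(1e6, 2L * spec$n_alleles + spec$n_alleles)
    tap_seed <- sample.int(1e6, 1L)
  })
  tap <- random_tap_matrix(tap_seed)
  panel <- c(
    lapply(seq_len(spec$n_alleles), function(i) {
      random_pssm(alleles[i], 9L, pssm_seeds[i], intercept = 5, mhc_class = "I")
    }),
    lapply(seq_len(spec$n_alleles), function(i) {
      random_pssm(alleles[i], 10L, pssm_seeds[spec$n_alleles + i],
                  intercept = 5, mhc_class = "I")
    })
  )
  class2_panel <- lapply(seq_len(spec$n_alleles), function(i) {
    random_pssm(paste0("DRB1*", sprintf("%02d:01", i)), 9L,
                pssm_seeds[2L * spec$n_alleles + i],
                intercept = 6, sd = 0.6, mhc_class = "II")
  })
  list(
    tap = tap,
    cleavage_pr = planted_cleavage_model("proteasome", g, spec$default_rank),
    cleavage_impr = planted_cleavage_model("immunoproteasome", g, spec$default_rank),
    panel = panel,
    class2_panel = class2_panel,
    freqs = freqs,
    epitopes = epitopes,
    motif = parse_motif(paste0(g, "DLVKV")),
    manifest = list(
      synthetic = TRUE,
      seed = spec$seed,
      n_alleles = spec$n_alleles,
      n_epitopes = spec$n_epitopes,
      good_residue = g,
      default_rank = spec$default_rank,
      planted_best_spacer = g,
      motif = paste0(g, "DLVKV")
    )
  )
}

#' Write a synthetic fixture set to disk
#'
#' Emits syntactically valid parameter files — TAP matrix, proteasomal and
#' immunoproteasomal cleavage tables, class-I and class-II PSSMs, HLA
#' frequency table, epitope list — plus `manifest.json` recording the seed
#' and the planted optimum. All files are plain text and clearly labelled
#' synthetic; identical seeds produce byte-identical files.
#'
#' @param spec A `fixture_spec`.
#' @param outdir Output directory (created if missing).
#' @return Character vector of paths written, invisibly; the built fixture
#'   list is attached as attribute `"fixtures"`.
#' @export
make_fixtures <- function(spec = fixture_spec(), outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create fixture directory: %s", outdir))
  }
  fx <- build_fixtures(spec)
  paths <- character(0)
  p <- function(...) file.path(outdir, ...)

  write_tap_matrix(fx$tap, p("tap_matrix.tsv"))
  write_cleavage_table(fx$cleavage_pr, p("cleavage_pr.tsv"))
  write_cleavage_table(fx$cleavage_impr, p("cleavage_impr.tsv"))
  dir.create(p("mhc"), showWarnings = FALSE)
  for (pssm in c(fx$panel, fx$class2_panel)) {
    f <- p("mhc", sprintf("%s_L%d.tsv",
                          gsub("[^A-Za-z0-9]", "_", pssm$allele), pssm$length))
    write_pssm(pssm, f)
    paths <- c(paths, f)
  }
  readr::write_tsv(fx$freqs, p("freqs.tsv"), progress = FALSE)
  writeLines(
    c("# synthetic epitope fixture",
      sprintf("%s\t%s", fx$epitopes$sequence,
              vapply(fx$epitopes$alleles, paste, character(1), collapse = ","))),
    p("epitopes.txt")
  )
  jsonlite::write_json(fx$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths <- c(
    p(c("tap_matrix.tsv", "cleavage_pr.tsv", "cleavage_impr.tsv",
        "freqs.tsv", "epitopes.txt", "manifest.json")),
    paths
  )
  structure(invisible(paths), fixtures = fx)
}
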