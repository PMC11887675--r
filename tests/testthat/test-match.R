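toy_proteome <- function() {
  data.frame(accession = c("P1", "P2", "P3"),
             description = "",
             sequence = c("NAYSAFKKW", "GGNLLSTYW", "AANVVFSSTW"),
             stringsAsFactors = FALSE)
}

toy_settings <- function(...) {
  search_settings(glycan_panel = default_glycan_panel(),
                  min_len = 2L, max_len = 60L, ...)
}

test_that("the candidate index enforces attachment constraints", {
  prot <- data.frame(accession = "P1", description = "",
                     sequence = "NAYSAF", stringsAsFactors = FALSE)
  n_only <- search_settings(
    glycan_panel = list(parse_composition("H5N4F1S1",
                                          attachment = "N_linked")),
    min_len = 2L)
  idx <- build_index(prot, n_only)
  expect_true(all(grepl("N", idx$sequence)))
  expect_true(all(idx$attachment == "N_linked"))
  expect_error(search_settings(glycan_panel = list()), "non-empty")
  expect_error(build_index(prot[0, ], n_only), "empty")
})

test_that("candidate count equals the brute-force triple loop", {
  settings <- toy_settings()
  idx <- build_index(toy_proteome(), settings)
  # independent enumeration: peptides x compatible glycans x Mox states
  expected <- 0L
  for (i in seq_len(nrow(toy_proteome()))) {
    peps <- oracle_digest(toy_proteome()$sequence[i], 2, 2, 60)
    for (pp in peps) {
      n_met <- sum(strsplit(pp, "")[[1]] == "M")
      for (g in settings$glycan_panel) {
        ok <- if (g$attachment == "N_linked") grepl("N", pp)
              else grepl("[ST]", pp)
        if (ok) expected <- expected + (n_met + 1L)
      }
    }
  }
  expect_equal(nrow(idx), expected)
  expect_false(is.unsorted(idx$theoretical_mass))
})

test_that("precursor matching finds constructed spectra at 0 ppm", {
  settings <- toy_settings()
  idx <- build_index(toy_proteome(), settings)
  row <- idx[17, ]
  s <- ms2_spectrum("exact", mz_from_mass(row$theoretical_mass, 2), 2)
  m <- match_precursor(s, idx, settings)
  expect_true(row$sequence %in% m$sequence)
  expect_true(any(abs(m$mass_error_ppm) < 1e-6))
  # 20 ppm off: nothing at tol 10
  s_off <- ms2_spectrum("off",
                        mz_from_mass(row$theoretical_mass *
                                       (1 + 20e-6), 2), 2)
  hits <- match_precursor(s_off, idx, settings)
  expect_false(row$sequence %in%
                 hits$sequence[abs(hits$mass_error_ppm) <= 10])
})

test_that("binary-search matching equals the linear-scan oracle", {
  set.seed(55)
  prot <- generate_proteome(10, c(60, 120), seed = 55)
  settings <- toy_settings()
  idx <- build_index(prot, settings)
  expect_gte(nrow(idx), 500)
  for (i in 1:40) {
    target <- idx$theoretical_mass[sample(nrow(idx), 1)] *
      (1 + runif(1, -15e-6, 15e-6))
    s <- ms2_spectrum(paste0("q", i), mz_from_mass(target, 2), 2)
    got <- match_precursor(s, idx, settings)
    linear <- which(abs(ppm_error(target, idx$theoretical_mass)) <=
                      settings$tolerances$precursor_ppm)
    expect_setequal(
      paste(got$sequence, got$glycan, got$n_oxidized_met),
      paste(idx$sequence[linear], idx$glycan[linear],
            idx$n_oxidized_met[linear]))
  }
})

test_that("widening the precursor tolerance never loses matches", {
  prot <- generate_proteome(5, c(60, 120), seed = 77)
  narrow <- toy_settings()
  wide <- toy_settings(tolerances = tolerance_settings(precursor_ppm = 30))
  idx <- build_index(prot, narrow)
  set.seed(78)
  for (i in 1:10) {
    target <- idx$theoretical_mass[sample(nrow(idx), 1)] *
      (1 + runif(1, -12e-6, 12e-6))
    s <- ms2_spectrum("w", mz_from_mass(target, 2), 2)
    m_narrow <- match_precursor(s, idx, narrow)
    m_wide <- match_precursor(s, idx, wide)
    expect_true(all(paste(m_narrow$sequence, m_narrow$glycan) %in%
                      paste(m_wide$sequence, m_wide$glycan)))
  }
})

test_that("backbone scoring counts matched b/y ions, intensity-free", {
  tol <- tolerance_settings()
  ions <- backbone_ions("PEPTIDE")
  expect_length(ions, 12)
  s <- ms2_spectrum("full", 500, 2, ions, rep(1, length(ions)))
  expect_equal(score_backbone(s, "PEPTIDE", tol), 12L)
  expect_equal(score_backbone(ms2_spectrum("e", 500, 2), "PEPTIDE", tol),
               0L)
  s_scaled <- ms2_spectrum("sc", 500, 2, ions, rep(1e-4, length(ions)))
  expect_equal(score_backbone(s_scaled, "PEPTIDE", tol), 12L)
})

test_that("confidence tiers split on the inclusive ion threshold", {
  settings <- search_settings(high_confidence_ions = 6L)
  expect_equal(assign_confidence(10L, 0, settings), "high")
  expect_equal(assign_confidence(0L, 0, settings), "low")
  expect_equal(assign_confidence(6L, 0, settings), "high")
  expect_equal(assign_confidence(5L, 0, settings), "low")
  expect_equal(assign_confidence(10L, 50, settings), "low")
})

test_that("search output ordering is deterministic per spectrum", {
  prot <- toy_proteome()
  settings <- toy_settings()
  idx <- build_index(prot, settings)
  row <- idx[5, ]
  s <- synthetic_full_spectrum <- ms2_spectrum(
    "s", mz_from_mass(row$theoretical_mass, 2), 2,
    c(backbone_ions(row$sequence), 204.0867, 292.1027, 366.1395),
    rep(0.5, length(backbone_ions(row$sequence)) + 3))
  m <- search_spectra(list(s), idx, settings)
  if (nrow(m) > 1) {
    expect_true(!is.unsorted(abs(m$mass_error_ppm)))
  }
  expect_true(all(m$oxonium_pass))
})
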