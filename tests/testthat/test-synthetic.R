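test_that("proteome generation is reproducible and satisfies constraints", {
  p1 <- generate_proteome(50, c(80, 200), seed = 123)
  p2 <- generate_proteome(50, c(80, 200), seed = 123)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 50)
  expect_true(all(nchar(p1$sequence) >= 80 & nchar(p1$sequence) <= 200))
  for (s in p1$sequence) {
    expect_gte(length(glycopull:::chymotryptic_sites(s)), 1)
    expect_true(grepl("N", s) && grepl("[ST]", s))
  }
  expect_error(generate_proteome(5, c(2, 3), seed = 1), "too small")
})

test_that("generated residue usage is approximately uniform", {
  p <- generate_proteome(80, c(120, 160), seed = 9)
  chars <- strsplit(paste(p$sequence, collapse = ""), "")[[1]]
  expect_gte(length(chars), 1e4)
  counts <- table(factor(chars, levels = names(amino_acid_masses())))
  # I and L are distinct letters here, so all 20 cells are expected equal
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("noise-free planted spectra pass, decoys fail, by construction", {
  proteome <- generate_proteome(20, seed = 31)
  sim <- plant_and_synthesize(proteome, n_true = 8, n_decoy = 4,
                              n_contaminants = 2, seed = 32)
  truth <- sim$ground_truth
  all_spectra <- unlist(sim$spectra_by_run, recursive = FALSE)
  names(all_spectra) <- vapply(all_spectra, function(s) s$spectrum_id,
                               character(1))
  tol <- tolerance_settings()
  for (sid in truth$planted$spectrum_id)
    expect_true(passes_sle_oxonium_filter(all_spectra[[sid]], tol))
  settings <- search_settings()
  idx <- build_index(proteome, settings)
  for (j in seq_len(nrow(truth$decoys))) {
    s <- all_spectra[[truth$decoys$spectrum_id[j]]]
    hits <- match_precursor(s, idx, settings)
    if (truth$decoys$flavor[j] == "offmass") {
      expect_equal(nrow(hits), 0)
    } else {
      expect_false(passes_sle_oxonium_filter(s, tol))
    }
  }
  expect_error(plant_and_synthesize(generate_proteome(2, seed = 1),
                                    n_true = 500, n_decoy = 0,
                                    n_contaminants = 0, seed = 2),
               "exceeds")
})

test_that("the noise-free pipeline recovers exactly the planted truth", {
  proteome <- generate_proteome(20, seed = 41)
  sim <- plant_and_synthesize(proteome, n_true = 10, n_decoy = 4,
                              n_contaminants = 2, n_both = 2, seed = 42)
  manifest <- default_synthetic_manifest()
  settings <- search_settings()
  idx <- build_index(proteome, settings)
  matches <- do.call(rbind, lapply(manifest$run_id, function(run) {
    m <- search_spectra(sim$spectra_by_run[[run]], idx, settings)
    if (nrow(m)) m$run_id <- run else m$run_id <- character(0)
    m
  }))
  final <- finalize_list(differential_filter(
    aggregate_evidence(matches, manifest), manifest))
  perf <- evaluate_recovery(final, sim$ground_truth)
  expect_equal(perf$precision, 1)
  expect_equal(perf$recall, 1)
  expect_equal(perf$n_contaminants_in_final, 0)
  # linkage partition equals the planted design bookkeeping
  expect_equal(linkage_partition(final), sim$ground_truth$linkage_design)
})

test_that("recall stays high under sub-tolerance precursor jitter", {
  recalls <- vapply(1:6, function(seed) {
    proteome <- generate_proteome(20, seed = 100 + seed)
    sim <- plant_and_synthesize(proteome, n_true = 8, n_decoy = 2,
                                n_contaminants = 1,
                                noise = list(jitter_ppm = 5,
                                             n_noise_peaks = 15),
                                seed = 200 + seed)
    manifest <- default_synthetic_manifest()
    settings <- search_settings()
    idx <- build_index(proteome, settings)
    matches <- do.call(rbind, lapply(manifest$run_id, function(run) {
      m <- search_spectra(sim$spectra_by_run[[run]], idx, settings)
      if (nrow(m)) m$run_id <- run else m$run_id <- character(0)
      m
    }))
    final <- finalize_list(differential_filter(
      aggregate_evidence(matches, manifest), manifest))
    evaluate_recovery(final, sim$ground_truth)$recall
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})

test_that("annotation generation plants a strictly dominant target", {
  accs <- sprintf("ACC%02d", 1:15)
  ann <- generate_annotations(accs, "ACC07", seed = 77)
  expect_identical(ann, generate_annotations(accs, "ACC07", seed = 77))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  loaded <- load_annotations(path) # passes validation
  r <- rank_proteins(loaded)
  expect_equal(r$accession[1], "ACC07")
  expect_equal(r$rank[1], 1L)
  expect_gt(r$total[1], max(r$total[-1]))
  expect_error(generate_annotations(accs, "NOT_THERE", seed = 1),
               "not among")
})

test_that("fixture bundles are complete and seed-stamped", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(dir, seed = 7, n_true = 6, n_decoy = 2,
                       n_contaminants = 1)
  for (p in c(b$fasta, b$manifest, b$glycan_panel, b$annotations,
              b$ground_truth))
    expect_true(file.exists(p))
  for (run in b$manifest_df$run_id)
    expect_true(file.exists(file.path(dir, paste0(run, ".mgf"))))
  expect_match(readLines(b$glycan_panel, n = 1), "seed 7")
  gt <- jsonlite::read_json(b$ground_truth)
  expect_equal(gt$seed, 8) # derived stream seed is recorded
})
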