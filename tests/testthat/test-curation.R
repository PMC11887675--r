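toy_manifest <- function() {
  run_manifest(c("pd1", "pd2", "igg", "noca"),
               c("eselectin_pulldown", "eselectin_pulldown",
                 "igg_control", "no_calcium_control"))
}

toy_match <- function(spectrum_id, accession, run_id,
                      attachment = "N_linked", confidence = "high",
                      oxonium = TRUE) {
  data.frame(spectrum_id = spectrum_id, accession = accession,
             start = 0L, end = 5L, sequence = "NAYST",
             missed_cleavages = 0L, n_oxidized_met = 0L,
             glycan = "H5N4F1S1", attachment = attachment,
             theoretical_mass = 1000, observed_mass = 1000,
             mass_error_ppm = 0, backbone_ion_count = 8L,
             oxonium_pass = oxonium, confidence = confidence,
             run_id = run_id, stringsAsFactors = FALSE)
}

test_that("manifests validate labels and require a pulldown run", {
  expect_error(run_manifest("r1", "bad_label"), "unknown run label")
  expect_error(run_manifest(c("r1", "r1"),
                            c("eselectin_pulldown", "igg_control")),
               "duplicate")
  expect_error(run_manifest("r1", "igg_control"), "at least one")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_run_manifest(toy_manifest(), path)
  expect_equal(read_run_manifest(path), toy_manifest())
})

test_that("evidence aggregation groups matches per accession", {
  matches <- rbind(toy_match("s1", "A", "pd1"),
                   toy_match("s2", "A", "pd2", attachment = "O_linked",
                             confidence = "low"),
                   toy_match("s3", "A", "pd1"))
  ev <- aggregate_evidence(matches, toy_manifest())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_runs, 2)
  expect_equal(ev$n_matches, 3)
  expect_true(ev$n_linked_evidence && ev$o_linked_evidence)
  expect_equal(ev$best_confidence, "high")
  expect_equal(nrow(aggregate_evidence(toy_match("s", "A", "pd1")[0, ],
                                       toy_manifest())), 0)
  orphan <- toy_match("s9", "A", "mystery_run")
  expect_error(aggregate_evidence(orphan, toy_manifest()),
               "mystery_run")
})

test_that("differential filter keeps pulldown-exclusive proteins only", {
  ev <- rbind(make_evidence("A", "pd1", TRUE, FALSE),
              make_evidence("B", "pd1,igg", TRUE, FALSE),
              make_evidence("C", "igg", TRUE, FALSE),
              make_evidence("D", "pd1,pd2", FALSE, TRUE),
              make_evidence("E", "pd2,noca", FALSE, TRUE))
  kept <- differential_filter(ev, toy_manifest())
  expect_setequal(kept$accession, c("A", "D"))
})

test_that("differential filter equals a set-comprehension oracle", {
  set.seed(88)
  manifest <- toy_manifest()
  accs <- sprintf("PR%02d", 1:20)
  ev <- do.call(rbind, lapply(accs, function(a) {
    runs <- sample(manifest$run_id, sample(1:4, 1))
    make_evidence(a, paste(sort(runs), collapse = ","),
                  TRUE, FALSE)
  }))
  kept <- differential_filter(ev, manifest)
  labels_of <- function(runs) {
    manifest$label[match(strsplit(runs, ",")[[1]], manifest$run_id)]
  }
  oracle <- accs[vapply(ev$runs_observed, function(r) {
    l <- labels_of(r)
    "eselectin_pulldown" %in% l &&
      !any(c("igg_control", "no_calcium_control") %in% l)
  }, logical(1))]
  expect_setequal(kept$accession, oracle)
  # and the result never contains a control-run protein
  in_control <- accs[vapply(ev$runs_observed, function(r) {
    any(labels_of(r) != "eselectin_pulldown")
  }, logical(1))]
  expect_length(intersect(kept$accession, in_control), 0)
})

test_that("the final list applies the confidence/validation rule", {
  ev <- rbind(
    make_evidence("HI", "pd1", TRUE, FALSE, "high", FALSE),
    make_evidence("LOVAL", "pd1", TRUE, FALSE, "low", TRUE),
    make_evidence("LONLY", "pd1", TRUE, FALSE, "low", FALSE))
  final <- finalize_list(ev)
  expect_setequal(final$accession, c("HI", "LOVAL"))
  # each curation stage only removes
  manifest <- toy_manifest()
  kept <- differential_filter(ev, manifest)
  expect_true(all(finalize_list(kept)$accession %in% kept$accession))
  expect_true(all(kept$accession %in% ev$accession))
})

test_that("linkage partition counts obey inclusion-exclusion", {
  ev <- rbind(make_evidence("A", "pd1", FALSE, TRUE),
              make_evidence("B", "pd1", TRUE, FALSE),
              make_evidence("C", "pd1", TRUE, TRUE))
  p <- linkage_partition(ev)
  expect_equal(p, list(o_total = 2L, n_total = 2L, both = 1L,
                       union = 3L))
  empty <- linkage_partition(ev[0, ])
  expect_equal(empty$union, 0L)
  # property: identity holds on random flag tables
  set.seed(99)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    flags_n <- sample(c(TRUE, FALSE), n, replace = TRUE)
    flags_o <- ifelse(flags_n, sample(c(TRUE, FALSE), n, replace = TRUE),
                      TRUE)
    ev_i <- make_evidence(sprintf("X%03d", seq_len(n)), "pd1",
                          flags_n, flags_o)
    p_i <- linkage_partition(ev_i)
    expect_equal(p_i$o_total + p_i$n_total - p_i$both, p_i$union)
    expect_equal(p_i$union, n)
  }
  # rows with no linkage evidence at all cannot be partitioned
  expect_error(linkage_partition(make_evidence("Z", "pd1", FALSE, FALSE)),
               "linkage flag")
})

test_that("final list writer emits the TSV and the Venn JSON", {
  ev <- rbind(make_evidence("A", "pd1", FALSE, TRUE),
              make_evidence("B", "pd1", TRUE, TRUE))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_final_list(ev, tsv, js)
  expect_equal(utils::read.delim(tsv)$accession, c("A", "B"))
  venn <- jsonlite::read_json(js)
  expect_equal(venn$o_total, 2)
  expect_equal(venn$union, 2)
})
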