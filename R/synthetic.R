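#' Default synthetic run manifest
#'
#' Two E-selectin pulldown runs plus the two negative controls used in the
#' affinity workflow: an IgG1 isotype-control IP and a pulldown with
#' calcium withheld.
#'
#' @return A [run_manifest()].
#' @export
default_synthetic_manifest <- function() {
  run_manifest(c("pulldown_1", "pulldown_2", "igg_1", "noca_1"),
               c("eselectin_pulldown", "eselectin_pulldown",
                 "igg_control", "no_calcium_control"))
}

#' Generate a random proteome with plantable glycosites
#'
#' Uniform sequences over the 20 amino-acid letters, resampled until each
#' record carries at least one internal chymotryptic cleavage site, one
#' Asn (so an N-glycopeptide can be planted) and one Ser or Thr (for an
#' O-glycopeptide). Reproducible for a given seed.
#'
#' @param n_proteins Number of records (>= 1).
#' @param length_range Length bounds, default c(80, 200).
#' @param seed Integer seed.
#' @return data.frame as from [read_proteome()], accessions SYNP0001...
#' @export
generate_proteome <- function(n_proteins, length_range = c(80L, 200L),
                              seed = 1L) {
  stopifnot(n_proteins >= 1L, length(length_range) == 2L)
  if (length_range[1L] < 5L)
    stop("length_range too small to satisfy the site constraints")
  aa <- names(amino_acid_masses())
  set.seed(seed)
  seqs <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    repeat {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      s <- paste(sample(aa, len, replace = TRUE), collapse = "")
      if (length(chymotryptic_sites(s)) >= 1L &&
          grepl("N", s, fixed = TRUE) && grepl("[ST]", s)) {
        seqs[i] <- s
        break
      }
    }
  }
  data.frame(accession = sprintf("SYNP%04d", seq_len(n_proteins)),
             description = sprintf("synthetic protein %d (seed %d)",
                                   seq_len(n_proteins), seed),
             sequence = seqs, stringsAsFactors = FALSE)
}

# Candidates whose precursor mass is isolated from every other accession's
# candidates (anywhere in the full index, oxidized variants included) by at
# least `guard` ppm; planting only these keeps the ground-truth protein
# labels unambiguous under the search tolerance.
unambiguous_candidates <- function(cand, index, guard_ppm) {
  m_all <- index$theoretical_mass
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    m <- cand$theoretical_mass[i]
    near <- which(m_all >= m * (1 - guard_ppm / 1e6) &
                    m_all <= m * (1 + guard_ppm / 1e6))
    all(index$accession[near] == cand$accession[i])
  }, logical(1))
  cand[ok, , drop = FALSE]
}

runif_between <- function(n, lo, hi) lo + (hi - lo) * stats::runif(n)

# Assemble one synthetic MS2 spectrum for a candidate glycopeptide.
# include_oxonium selects which of the three diagnostic classes to emit;
# max_backbone_ions caps the planted b/y series (sparse-backbone decoys).
synth_spectrum <- function(spectrum_id, sequence, neutral_mass, charge = 2L,
                           include_oxonium = c("hexnac", "neuac",
                                               "hexnac_hex"),
                           max_backbone_ions = Inf,
                           jitter_ppm = 0, n_noise_peaks = 0L) {
  ions <- backbone_ions(sequence)
  oxref <- c(hexnac = 204.0867, neuac = 292.1027, hexnac_hex = 366.1395)
  excluded <- oxref[setdiff(names(oxref), include_oxonium)]
  if (length(excluded)) {
    # keep planted fragments away from withheld diagnostic windows so a
    # decoy cannot accidentally validate itself
    near <- vapply(ions, function(x) any(abs(x - excluded) < 0.05),
                   logical(1))
    ions <- ions[!near]
  }
  if (is.finite(max_backbone_ions))
    ions <- ions[seq_len(min(length(ions), max_backbone_ions))]
  mzv <- ions
  intv <- runif_between(length(ions), 0.1, 0.5)
  keep <- oxref[include_oxonium]
  mzv <- c(mzv, keep)
  intv <- c(intv, runif_between(length(keep), 0.2, 0.8))
  jitter <- if (jitter_ppm > 0) runif_between(1, -jitter_ppm, jitter_ppm)
            else 0
  pre_mz <- mz_from_mass(neutral_mass, charge) * (1 + jitter / 1e6)
  # base peak anchors the relative-intensity floor
  mzv <- c(mzv, pre_mz)
  intv <- c(intv, 1.0)
  if (n_noise_peaks > 0L) {
    mzv <- c(mzv, runif_between(n_noise_peaks, 300, 2000))
    intv <- c(intv, runif_between(n_noise_peaks, 0.001, 0.05))
  }
  ms2_spectrum(spectrum_id, pre_mz, charge, mzv, intv)
}

#' Plant glycopeptide spectra and synthesize an MGF bundle
#'
#' Builds the candidate index for the proteome, restricts to candidates
#' whose precursor mass is unambiguous across accessions, and plants three
#' kinds of spectra: true glycopeptides (exact precursor, full b/y series,
#' all three oxonium classes) in pulldown runs; decoys that either sit far
#' outside the precursor tolerance or lack the sialic acid oxonium class
#' while carrying too sparse a backbone for high confidence; and
#' contaminant proteins whose spectra appear only in control runs. Noise
#' adds bounded precursor jitter and low-intensity random peaks.
#'
#' @param proteome data.frame from [generate_proteome()].
#' @param glycan_panel Panel list, default [default_glycan_panel()].
#' @param n_true Number of true glycopeptide spectra.
#' @param n_decoy Number of decoy spectra.
#' @param n_contaminants Number of contaminant proteins (control runs).
#' @param n_both Minimum number of true proteins planted with both an
#'   N- and an O-glycopeptide.
#' @param manifest A [run_manifest()].
#' @param noise List with jitter_ppm (precursor jitter bound, ppm) and
#'   n_noise_peaks per spectrum.
#' @param seed Integer seed.
#' @param settings [search_settings()] the downstream search will use.
#' @return List: `spectra_by_run` (named list of spectrum lists) and
#'   `ground_truth` (planted table, decoy table, contaminant accessions,
#'   expected linkage design, seed).
#' @export
plant_and_synthesize <- function(proteome,
                                 glycan_panel = default_glycan_panel(),
                                 n_true = 10L, n_decoy = 4L,
                                 n_contaminants = 2L, n_both = 1L,
                                 manifest = default_synthetic_manifest(),
                                 noise = list(jitter_ppm = 0,
                                              n_noise_peaks = 0L),
                                 seed = 1L,
                                 settings = search_settings(
                                   glycan_panel = glycan_panel)) {
  stopifnot(n_true >= 0L, n_decoy >= 0L, n_contaminants >= 0L,
            inherits(manifest, "run_manifest"))
  set.seed(seed)
  index <- build_index(proteome, settings)
  # plant only unmodified-Met candidates with enough backbone for a
  # confident series, isolated by 3x the precursor tolerance
  cand <- index[index$n_oxidized_met == 0L &
                  nchar(index$sequence) >= 5L, , drop = FALSE]
  cand <- unambiguous_candidates(cand, index,
                                 3 * settings$tolerances$precursor_ppm)
  by_acc <- split(cand, cand$accession)
  has_n <- vapply(by_acc, function(g) any(g$attachment == "N_linked"),
                  logical(1))
  has_o <- vapply(by_acc, function(g) any(g$attachment == "O_linked"),
                  logical(1))
  both_capable <- names(by_acc)[has_n & has_o]

  pulldown_runs <- manifest$run_id[manifest$label == "eselectin_pulldown"]
  control_runs <- manifest$run_id[manifest$label != "eselectin_pulldown"]

  pick_one <- function(acc, attach) {
    g <- by_acc[[acc]]
    g <- g[g$attachment == attach, , drop = FALSE]
    g[sample.int(nrow(g), 1L), , drop = FALSE]
  }

  # schedule the true plants: (accession, attachment) pairs
  plan <- list()
  used <- character(0)
  n_both_eff <- min(n_both, length(both_capable), n_true %/% 2L)
  for (acc in utils::head(both_capable, n_both_eff)) {
    plan <- c(plan, list(c(acc, "N_linked")), list(c(acc, "O_linked")))
    used <- c(used, acc)
  }
  remaining <- setdiff(names(by_acc), used)
  attach_cycle <- c("N_linked", "O_linked")
  k <- 0L
  while (length(plan) < n_true && length(remaining)) {
    acc <- remaining[1L]
    att <- attach_cycle[k %% 2L + 1L]
    if (!((att == "N_linked" && has_n[[acc]]) ||
          (att == "O_linked" && has_o[[acc]])))
      att <- if (has_n[[acc]]) "N_linked" else "O_linked"
    plan <- c(plan, list(c(acc, att)))
    used <- c(used, acc)
    remaining <- remaining[-1L]
    k <- k + 1L
  }
  if (length(plan) < n_true)
    stop("n_true = ", n_true, " exceeds the ", length(plan),
         " plantable unambiguous glycopeptides in this proteome")

  spectra_by_run <- stats::setNames(
    vector("list", nrow(manifest)), manifest$run_id)
  planted <- list()
  for (i in seq_len(n_true)) {
    acc <- plan[[i]][1L]; att <- plan[[i]][2L]
    row <- pick_one(acc, att)
    run <- pulldown_runs[(i - 1L) %% length(pulldown_runs) + 1L]
    sid <- sprintf("%s_true_%03d", run, i)
    sp <- synth_spectrum(sid, row$sequence, row$theoretical_mass,
                         jitter_ppm = noise$jitter_ppm,
                         n_noise_peaks = noise$n_noise_peaks)
    spectra_by_run[[run]] <- c(spectra_by_run[[run]], list(sp))
    planted[[i]] <- data.frame(spectrum_id = sid, run_id = run,
                               accession = acc, sequence = row$sequence,
                               glycan = row$glycan, attachment = att,
                               stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, c(planted, list(NULL)))

  # decoy proteins: accessions never planted as true targets
  decoy_pool_acc <- setdiff(names(by_acc), unique(planted$accession))
  decoys <- list()
  for (j in seq_len(n_decoy)) {
    flavor <- if (j %% 2L == 1L) "offmass" else "no_oxonium"
    run <- pulldown_runs[(j - 1L) %% length(pulldown_runs) + 1L]
    sid <- sprintf("%s_decoy_%03d", run, j)
    if (length(decoy_pool_acc)) {
      acc <- decoy_pool_acc[(j - 1L) %% length(decoy_pool_acc) + 1L]
      g <- by_acc[[acc]]
      row <- g[sample.int(nrow(g), 1L), , drop = FALSE]
    } else {
      row <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
    }
    if (flavor == "offmass") {
      # shift the precursor well outside tolerance, to a mass that is also
      # isolated from every other candidate
      tol <- settings$tolerances$precursor_ppm
      off_mass <- NA_real_
      for (mult in c(5, -5, 7, -7, 9, -9, 13, -13)) {
        trial <- row$theoretical_mass * (1 + mult * tol / 1e6)
        rel <- abs(ppm_error(trial, index$theoretical_mass))
        if (min(rel) > tol) { off_mass <- trial; break }
      }
      if (is.na(off_mass))
        stop("could not place an off-mass decoy away from all candidates")
      sp <- synth_spectrum(sid, row$sequence, off_mass,
                           jitter_ppm = 0,
                           n_noise_peaks = noise$n_noise_peaks)
    } else {
      # matches the precursor but lacks the sialic acid class and carries
      # too sparse a backbone for high confidence
      sp <- synth_spectrum(sid, row$sequence, row$theoretical_mass,
                           include_oxonium = c("hexnac", "hexnac_hex"),
                           max_backbone_ions =
                             max(0L, settings$high_confidence_ions - 2L),
                           jitter_ppm = noise$jitter_ppm,
                           n_noise_peaks = noise$n_noise_peaks)
    }
    spectra_by_run[[run]] <- c(spectra_by_run[[run]], list(sp))
    decoys[[j]] <- data.frame(spectrum_id = sid, run_id = run,
                              flavor = flavor, accession = row$accession,
                              stringsAsFactors = FALSE)
  }
  decoys <- do.call(rbind, c(decoys, list(NULL)))

  # contaminants: true-looking spectra confined to control runs
  contam_pool <- setdiff(decoy_pool_acc,
                         if (!is.null(decoys)) decoys$accession else
                           character(0))
  if (n_contaminants > length(contam_pool))
    stop("n_contaminants = ", n_contaminants, " exceeds the ",
         length(contam_pool), " available non-planted accessions")
  contaminant_acc <- utils::head(contam_pool, n_contaminants)
  if (length(contaminant_acc) && !length(control_runs))
    stop("manifest has no control run to host contaminants")
  for (j in seq_along(contaminant_acc)) {
    acc <- contaminant_acc[j]
    g <- by_acc[[acc]]
    row <- g[sample.int(nrow(g), 1L), , drop = FALSE]
    run <- control_runs[(j - 1L) %% length(control_runs) + 1L]
    sid <- sprintf("%s_contam_%03d", run, j)
    sp <- synth_spectrum(sid, row$sequence, row$theoretical_mass,
                         jitter_ppm = noise$jitter_ppm,
                         n_noise_peaks = noise$n_noise_peaks)
    spectra_by_run[[run]] <- c(spectra_by_run[[run]], list(sp))
  }

  # expected linkage partition of the recovered final list
  if (!is.null(planted)) {
    acc_n <- unique(planted$accession[planted$attachment == "N_linked"])
    acc_o <- unique(planted$accession[planted$attachment == "O_linked"])
    design <- list(o_total = length(acc_o), n_total = length(acc_n),
                   both = length(intersect(acc_n, acc_o)),
                   union = length(union(acc_n, acc_o)))
  } else {
    design <- list(o_total = 0L, n_total = 0L, both = 0L, union = 0L)
  }

  list(spectra_by_run = spectra_by_run,
       ground_truth = list(planted = planted, decoys = decoys,
                           contaminant_accessions = contaminant_acc,
                           linkage_design = design, seed = seed))
}

#' Generate a synthetic annotation table with a planted dominant target
#'
#' The planted top accession receives the strongest reward fields (cancer
#' association 3, ten unfavorable-prognosis cancers, membrane localized)
#' and zero healthy expression in every organ; all other accessions draw
#' weaker rewards (cancer 0..2, prognosis 0..3) and random organ levels,
#' so the planted target's total strictly dominates under any
#' non-negative weighting with positive reward weights.
#'
#' @param accessions Character vector of accessions to annotate.
#' @param planted_top The accession to make dominant (must be in
#'   `accessions`).
#' @param seed Integer seed.
#' @return Annotation data.frame (see [load_annotations()]).
#' @export
generate_annotations <- function(accessions, planted_top, seed = 1L) {
  if (!planted_top %in% accessions)
    stop("planted_top ", sQuote(planted_top), " is not among accessions")
  if (anyDuplicated(accessions)) stop("accessions must be unique")
  set.seed(seed)
  n <- length(accessions)
  organs <- organ_vocabulary()
  levels <- names(EXPRESSION_LEVELS)
  ann <- data.frame(accession = accessions,
                    cancer_association = sample(0:2, n, replace = TRUE),
                    n_unfavorable_prognosis = sample(0:3, n, replace = TRUE),
                    membrane_localized = sample(c(TRUE, FALSE), n,
                                                replace = TRUE),
                    stringsAsFactors = FALSE)
  for (org in organs)
    ann[[org]] <- sample(levels, n, replace = TRUE)
  top <- ann$accession == planted_top
  ann$cancer_association[top] <- 3L
  ann$n_unfavorable_prognosis[top] <- 10L
  ann$membrane_localized[top] <- TRUE
  for (org in organs) ann[[org]][top] <- "not_detected"
  ann
}

#' Score a recovered final list against planted ground truth
#'
#' Protein-level precision and recall of the curated final list relative
#' to the planted accessions, plus the number of contaminant (control-run)
#' proteins that leaked into the final list.
#'
#' @param final Final-list evidence table from [finalize_list()] or
#'   [run_pipeline()].
#' @param ground_truth The `ground_truth` element of
#'   [plant_and_synthesize()].
#' @return List: precision, recall, n_contaminants_in_final, n_final,
#'   n_planted.
#' @export
evaluate_recovery <- function(final, ground_truth) {
  truth_acc <- unique(ground_truth$planted$accession)
  found <- unique(final$accession)
  tp <- length(intersect(found, truth_acc))
  list(precision = if (length(found)) tp / length(found) else NA_real_,
       recall = if (length(truth_acc)) tp / length(truth_acc) else
         NA_real_,
       n_contaminants_in_final =
         length(intersect(found, ground_truth$contaminant_accessions)),
       n_final = length(found), n_planted = length(truth_acc))
}

#' Write a complete synthetic fixture bundle
#'
#' One call emits everything the pipeline consumes: FASTA proteome, one
#' MGF per run (named `<run_id>.mgf`), the run-manifest TSV, the glycan
#' panel text file, the annotation TSV with a planted dominant target,
#' and a JSON ground-truth record (seed included in every header).
#'
#' @param dir Output directory (created if needed).
#' @param n_proteins Proteome size.
#' @param seed Integer seed driving every random draw.
#' @param ... Passed to [plant_and_synthesize()].
#' @return List with file paths and the ground truth.
#' @export
simulate_bundle <- function(dir, n_proteins = 20L, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteome <- generate_proteome(n_proteins, seed = seed)
  manifest <- default_synthetic_manifest()
  sim <- plant_and_synthesize(proteome, manifest = manifest,
                              seed = seed + 1L, ...)
  paths <- list(
    fasta = file.path(dir, "proteome.fasta"),
    manifest = file.path(dir, "manifest.tsv"),
    glycan_panel = file.path(dir, "glycan_panel.txt"),
    annotations = file.path(dir, "annotations.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    mgf_dir = dir)
  write_proteome(proteome, paths$fasta)
  write_run_manifest(manifest, paths$manifest)
  panel_lines <- vapply(default_glycan_panel(), function(g) {
    paste(format_composition(g, "short"),
          if (g$attachment == "N_linked") "N" else "O")
  }, character(1))
  writeLines(c(sprintf("# synthetic glycan panel (seed %d)", seed),
               panel_lines), paths$glycan_panel)
  for (run in manifest$run_id) {
    write_mgf(sim$spectra_by_run[[run]],
              file.path(dir, paste0(run, ".mgf")),
              header = sprintf("synthetic run %s (seed %d)", run, seed))
  }
  planted_acc <- unique(sim$ground_truth$planted$accession)
  planted_top <- planted_acc[1L]
  ann <- generate_annotations(proteome$accession, planted_top,
                              seed = seed + 2L)
  write_annotations(ann, paths$annotations)
  gt <- sim$ground_truth
  gt$planted_top <- planted_top
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  c(paths, list(truth = gt, proteome = proteome, manifest_df = manifest))
}
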