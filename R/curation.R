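RUN_LABELS <- c("eselectin_pulldown", "igg_control", "no_calcium_control")

#' Run manifest
#'
#' Maps each MS run to its role: the E-selectin pulldown itself, the IgG1
#' isotype-control IP, or the pulldown with calcium withheld (E-selectin
#' binding is Ca2+-dependent, so the no-Ca2+ run is a binding-specificity
#' control). At least one pulldown run is required.
#'
#' @param run_id Character vector of run identifiers.
#' @param label Character vector over
#'   {eselectin_pulldown, igg_control, no_calcium_control}.
#' @return data.frame of class `run_manifest`.
#' @export
run_manifest <- function(run_id, label) {
  stopifnot(length(run_id) == length(label))
  if (anyDuplicated(run_id)) stop("duplicate run_id in manifest")
  bad <- setdiff(label, RUN_LABELS)
  if (length(bad))
    stop("unknown run label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(RUN_LABELS, collapse = ", "))
  if (!any(label == "eselectin_pulldown"))
    stop("manifest must contain at least one eselectin_pulldown run")
  out <- data.frame(run_id = as.character(run_id),
                    label = as.character(label), stringsAsFactors = FALSE)
  class(out) <- c("run_manifest", "data.frame")
  out
}

#' Read / write a run manifest TSV (columns run_id, label)
#'
#' @param path TSV path.
#' @return A [run_manifest()].
#' @export
read_run_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("run_id", "label") %in% names(df)))
    stop("manifest must have columns run_id and label")
  run_manifest(df$run_id, df$label)
}

#' @rdname read_run_manifest
#' @param manifest A [run_manifest()].
#' @export
write_run_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate glycopeptide matches into per-protein evidence
#'
#' Groups the match table by accession, records which runs the protein was
#' observed in, derives the N-/O-linkage evidence flags from the matched
#' glycans' attachment classes, the best confidence tier, and whether any
#' match passed the oxonium validation filter.
#'
#' @param matches Match table from [search_spectra()] with an added
#'   `run_id` column mapping each spectrum to its run.
#' @param manifest A [run_manifest()]; every run_id in `matches` must
#'   appear in it.
#' @return data.frame: accession, runs_observed (comma-joined, sorted),
#'   n_runs, n_matches, n_linked_evidence, o_linked_evidence,
#'   best_confidence, any_oxonium_pass; ordered by accession.
#' @export
aggregate_evidence <- function(matches, manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (!nrow(matches)) {
    out <- data.frame(accession = character(0), runs_observed = character(0),
                      n_runs = integer(0), n_matches = integer(0),
                      n_linked_evidence = logical(0),
                      o_linked_evidence = logical(0),
                      best_confidence = character(0),
                      any_oxonium_pass = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (!"run_id" %in% names(matches))
    stop("match table needs a run_id column")
  orphan <- setdiff(unique(matches$run_id), manifest$run_id)
  if (length(orphan)) {
    sp <- unique(matches$spectrum_id[matches$run_id %in% orphan])
    stop("spectra from run(s) absent from the manifest: ",
         paste(orphan, collapse = ", "), " (e.g. spectrum ", sp[1L], ")")
  }
  by_acc <- split(matches, matches$accession)
  rows <- lapply(by_acc, function(g) {
    runs <- sort(unique(g$run_id))
    data.frame(accession = g$accession[1L],
               runs_observed = paste(runs, collapse = ","),
               n_runs = length(runs), n_matches = nrow(g),
               n_linked_evidence = any(g$attachment == "N_linked"),
               o_linked_evidence = any(g$attachment == "O_linked"),
               best_confidence = if (any(g$confidence == "high")) "high"
                                 else "low",
               any_oxonium_pass = any(g$oxonium_pass),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[order(names(rows))])
  rownames(out) <- NULL
  out
}

evidence_run_labels <- function(evidence, manifest) {
  lapply(strsplit(evidence$runs_observed, ",", fixed = TRUE), function(r) {
    manifest$label[match(r, manifest$run_id)]
  })
}

#' Keep proteins exclusive to the E-selectin pulldowns
#'
#' Retains exactly the proteins observed in at least one pulldown run and
#' in no control run (IgG or no-Ca2+). A protein seen only in controls is
#' silently dropped as a contaminant.
#'
#' @param evidence Evidence table from [aggregate_evidence()].
#' @param manifest A [run_manifest()].
#' @return Filtered evidence table.
#' @export
differential_filter <- function(evidence, manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (!nrow(evidence)) return(evidence)
  labels <- evidence_run_labels(evidence, manifest)
  keep <- vapply(labels, function(l) {
    any(l == "eselectin_pulldown") &&
      !any(l %in% c("igg_control", "no_calcium_control"))
  }, logical(1))
  out <- evidence[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the confidence / validation rule
#'
#' After differential filtering, keeps proteins identified with high
#' confidence, or with low confidence but carrying at least one
#' oxonium-validated glycopeptide match.
#'
#' @param evidence Differentially filtered evidence table.
#' @return Final-list evidence table.
#' @export
finalize_list <- function(evidence) {
  if (!nrow(evidence)) return(evidence)
  keep <- evidence$best_confidence == "high" |
    (evidence$best_confidence == "low" & evidence$any_oxonium_pass)
  out <- evidence[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition the final list by glycan linkage type
#'
#' Counts proteins with O-linked evidence, with N-linked evidence, with
#' both, and the union. The identity `o_total + n_total - both == union ==
#' number of distinct accessions` holds by construction and is asserted.
#'
#' @param evidence Final-list evidence table.
#' @return List with o_total, n_total, both, union.
#' @export
linkage_partition <- function(evidence) {
  o_total <- sum(evidence$o_linked_evidence)
  n_total <- sum(evidence$n_linked_evidence)
  both <- sum(evidence$o_linked_evidence & evidence$n_linked_evidence)
  union <- length(unique(evidence$accession))
  # every final-list protein has at least one linkage flag, so
  # inclusion-exclusion must close exactly
  if (nrow(evidence) &&
      any(!evidence$o_linked_evidence & !evidence$n_linked_evidence))
    stop("evidence rows without any linkage flag cannot be partitioned")
  stopifnot(o_total + n_total - both == union)
  list(o_total = o_total, n_total = n_total, both = both, union = union)
}

#' Write the final list TSV and the linkage-partition JSON summary
#'
#' @param evidence Final-list evidence table.
#' @param tsv_path,json_path Output paths.
#' @export
write_final_list <- function(evidence, tsv_path, json_path = NULL) {
  utils::write.table(evidence, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(linkage_partition(evidence), json_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsv_path)
}
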