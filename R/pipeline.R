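#' Default pipeline configuration
#'
#' Flat key/value configuration (YAML-compatible) for the full
#' digest-search-curate-partition-score pipeline. Paths: `fasta`,
#' `mgf_dir` (one `<run_id>.mgf` per manifest run), `manifest`,
#' `glycan_panel` (optional; the built-in panel if NULL), `annotations`
#' (optional; scoring skipped if NULL), `out_dir`. Search keys mirror
#' [search_settings()], score keys mirror [score_weights()].
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(fasta = NULL, mgf_dir = NULL, manifest = NULL,
       glycan_panel = NULL, annotations = NULL, out_dir = "glycopull_out",
       enzyme = "chymotrypsin_high_specificity",
       max_missed = 2L, precursor_ppm = 10, product_da = 0.02,
       allow_oxidized_met = TRUE, min_len = 5L, max_len = 60L,
       high_confidence_ions = 6L,
       w_cancer = 1, w_prognosis = 1, w_membrane = 1, w_healthy = 1,
       vital_organs = default_vital_organs(),
       seed = 1L, log_level = "info")
}

#' Read a pipeline configuration file
#'
#' YAML (flat keys as in [default_pipeline_config()]); unknown keys are an
#' error, missing keys take defaults. Relative paths are resolved against
#' the config file's directory.
#'
#' @param path YAML config path.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  base <- dirname(normalizePath(path))
  for (key in c("fasta", "mgf_dir", "manifest", "glycan_panel",
                "annotations", "out_dir")) {
    p <- out[[key]]
    if (is.null(p)) next
    if (length(p) != 1L || is.na(p))
      stop("config key ", sQuote(key),
           " must be a single path (quote values like '.' in YAML)")
    p <- as.character(p)
    out[[key]] <- if (grepl("^/", p)) p else file.path(base, p)
  }
  out
}

validate_pipeline_config <- function(config) {
  defaults <- default_pipeline_config()
  config <- utils::modifyList(defaults, config)
  for (key in c("fasta", "mgf_dir", "manifest"))
    if (is.null(config[[key]]))
      stop("config is missing required path ", sQuote(key))
  for (key in c("fasta", "mgf_dir", "manifest", "glycan_panel",
                "annotations")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config path ", sQuote(key), " does not exist: ", sQuote(p))
  }
  config
}

config_settings <- function(config) {
  panel <- if (is.null(config$glycan_panel)) default_glycan_panel()
           else read_glycan_panel(config$glycan_panel)
  search_settings(enzyme = config$enzyme,
                  max_missed = config$max_missed,
                  tolerances = tolerance_settings(config$precursor_ppm,
                                                  config$product_da),
                  glycan_panel = panel,
                  allow_oxidized_met = config$allow_oxidized_met,
                  min_len = config$min_len, max_len = config$max_len,
                  high_confidence_ions = config$high_confidence_ions)
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full curation pipeline
#'
#' Orchestrates digest, glycopeptide search, oxonium validation,
#' differential curation against the control runs, linkage partitioning
#' and (when annotations are supplied) Target Score ranking of the final
#' list. All outputs are written atomically into `out_dir`:
#' `matches.tsv`, `final_list.tsv`, `venn.json`, `targets.tsv` (if
#' scored) and `run_log.txt`. Identical config and inputs give
#' byte-identical TSV/JSON outputs.
#'
#' @param config Config list (see [default_pipeline_config()]) or a path
#'   to a YAML config file.
#' @return Invisible list: matches, evidence, final, partition, ranked
#'   (NULL if no annotations), output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  settings <- config_settings(config)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage ", sQuote(name), " failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  proteome <- stage("read_fasta", read_proteome(config$fasta))
  manifest <- stage("read_manifest", read_run_manifest(config$manifest))
  mgf_paths <- file.path(config$mgf_dir, paste0(manifest$run_id, ".mgf"))
  missing <- !file.exists(mgf_paths)
  if (any(missing))
    stop("pipeline stage 'read_spectra' failed: missing MGF for run(s): ",
         paste(manifest$run_id[missing], collapse = ", "))

  index <- stage("build_index", build_index(proteome, settings))
  matches <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    spectra <- stage("read_spectra", read_mgf(mgf_paths[i]))
    m <- stage("search", search_spectra(spectra, index, settings))
    if (nrow(m)) m$run_id <- manifest$run_id[i]
    else m$run_id <- character(0)
    m
  }))

  evidence <- stage("aggregate", aggregate_evidence(matches, manifest))
  kept <- stage("differential_filter",
                differential_filter(evidence, manifest))
  final <- stage("finalize", finalize_list(kept))
  partition <- stage("linkage_partition", linkage_partition(final))

  ranked <- NULL
  if (!is.null(config$annotations)) {
    ann <- stage("load_annotations", load_annotations(config$annotations))
    ann <- ann[ann$accession %in% final$accession, , drop = FALSE]
    if (nrow(ann)) {
      weights <- score_weights(config$w_cancer, config$w_prognosis,
                               config$w_membrane, config$w_healthy)
      ranked <- stage("target_score",
                      rank_proteins(ann, weights, config$vital_organs))
    }
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(matches = file.path(config$out_dir, "matches.tsv"),
                final_list = file.path(config$out_dir, "final_list.tsv"),
                venn = file.path(config$out_dir, "venn.json"),
                targets = file.path(config$out_dir, "targets.tsv"),
                log = file.path(config$out_dir, "run_log.txt"))
  write_atomic(function(p) write_match_table(matches, p), paths$matches)
  write_atomic(function(p) utils::write.table(final, p, sep = "\t",
                                              quote = FALSE,
                                              row.names = FALSE),
               paths$final_list)
  write_atomic(function(p) jsonlite::write_json(partition, p,
                                                auto_unbox = TRUE,
                                                pretty = TRUE),
               paths$venn)
  if (!is.null(ranked))
    write_atomic(function(p) utils::write.table(ranked, p, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE),
                 paths$targets)

  cfg_for_hash <- config[order(names(config))]
  log_lines <- c(
    sprintf("glycopull %s",
            as.character(utils::packageVersion("glycopull"))),
    sprintf("config_hash: %s",
            digest_config(cfg_for_hash)),
    sprintf("seed: %d", config$seed),
    sprintf("runs: %s", paste(manifest$run_id, collapse = ", ")),
    sprintf("spectra_matched: %d", length(unique(matches$spectrum_id))),
    sprintf("proteins_with_evidence: %d", nrow(evidence)),
    sprintf("final_list: %d", nrow(final)),
    sprintf("venn o/n/both/union: %d/%d/%d/%d", partition$o_total,
            partition$n_total, partition$both, partition$union))
  write_atomic(function(p) writeLines(log_lines, p), paths$log)

  invisible(list(matches = matches, evidence = evidence, final = final,
                 partition = partition, ranked = ranked, paths = paths))
}

# stable fingerprint of the serialized config, dependency-free
digest_config <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
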