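#' Controlled vocabulary of healthy-organ expression columns
#'
#' Organ names accepted in annotation tables, with a default subset of
#' penalty-relevant ("vital") organs used by the Target Score healthy
#' expression penalty.
#'
#' @return Character vector of organ names.
#' @export
organ_vocabulary <- function() {
  c("brain", "heart", "lung", "liver", "kidney", "pancreas", "colon",
    "stomach", "spleen", "skin", "muscle", "testis")
}

#' @rdname organ_vocabulary
#' @export
default_vital_organs <- function() {
  c("brain", "heart", "lung", "liver", "kidney", "pancreas", "colon")
}

EXPRESSION_LEVELS <- c(not_detected = 0L, low = 1L, medium = 2L, high = 3L)

#' Target Score weights
#'
#' Non-negative weights on the four additive components: cancer
#' association, unfavorable-prognosis count, membrane localization, and
#' the healthy-tissue expression penalty. Defaults are all 1, i.e. plain
#' ordinal sums; indicator-style or normalized scorings are expressible by
#' re-weighting.
#'
#' @param w_cancer,w_prognosis,w_membrane,w_healthy Non-negative reals.
#' @return Object of class `score_weights`.
#' @export
score_weights <- function(w_cancer = 1, w_prognosis = 1, w_membrane = 1,
                          w_healthy = 1) {
  w <- c(w_cancer, w_prognosis, w_membrane, w_healthy)
  if (any(!is.finite(w)) || any(w < 0))
    stop("score weights must be non-negative finite numbers")
  structure(list(w_cancer = w_cancer, w_prognosis = w_prognosis,
                 w_membrane = w_membrane, w_healthy = w_healthy),
            class = "score_weights")
}

validate_annotations <- function(ann, where = "annotation table") {
  req <- c("accession", "cancer_association", "n_unfavorable_prognosis",
           "membrane_localized")
  missing <- setdiff(req, names(ann))
  if (length(missing))
    stop(where, " is missing column(s): ", paste(missing, collapse = ", "))
  organ_cols <- setdiff(names(ann), req)
  unknown <- setdiff(organ_cols, organ_vocabulary())
  if (length(unknown))
    stop(where, " has unknown organ column(s): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(ann$accession))
    stop(where, " has duplicate accessions")
  bad <- which(!ann$cancer_association %in% 0:3)
  if (length(bad))
    stop(where, " row ", bad[1L],
         ": cancer_association must be an ordinal 0..3")
  bad <- which(ann$n_unfavorable_prognosis < 0 |
                 ann$n_unfavorable_prognosis !=
                 round(ann$n_unfavorable_prognosis))
  if (length(bad))
    stop(where, " row ", bad[1L],
         ": n_unfavorable_prognosis must be a non-negative integer")
  for (org in organ_cols) {
    bad <- which(!ann[[org]] %in% names(EXPRESSION_LEVELS))
    if (length(bad))
      stop(where, " row ", bad[1L], ", column ", sQuote(org),
           ": unknown expression level ", sQuote(ann[[org]][bad[1L]]),
           " (allowed: ", paste(names(EXPRESSION_LEVELS), collapse = ", "),
           ")")
  }
  organ_cols
}

#' Score one annotation record
#'
#' Additive Target Score: reward cancer association (ordinal 0..3, HPA
#' evidence strength), the number of cancers with an unfavorable prognostic
#' association, and membrane localization (targetability); penalize summed
#' healthy expression levels (not_detected 0 .. high 3) over the vital
#' organs. total = w_c*cancer + w_p*prognosis + w_m*membrane -
#' w_h*sum(levels).
#'
#' @param annotation One-row data.frame (or list) with the columns of
#'   [load_annotations()].
#' @param weights A [score_weights()].
#' @param vital_organs Organs entering the penalty; each must be a column
#'   of the annotation.
#' @return One-row data.frame: accession, cancer_term, prognosis_term,
#'   membrane_term, healthy_penalty, total.
#' @export
score_protein <- function(annotation, weights = score_weights(),
                          vital_organs = default_vital_organs()) {
  missing <- setdiff(vital_organs, names(annotation))
  if (length(missing))
    stop("vital organ(s) absent from annotation: ",
         paste(missing, collapse = ", "))
  levels <- vapply(vital_organs, function(org) {
    lv <- annotation[[org]]
    if (!lv %in% names(EXPRESSION_LEVELS))
      stop("unknown expression level ", sQuote(lv), " for organ ", org)
    EXPRESSION_LEVELS[[lv]]
  }, integer(1))
  cancer_term <- weights$w_cancer * annotation$cancer_association
  prognosis_term <- weights$w_prognosis * annotation$n_unfavorable_prognosis
  membrane_term <- weights$w_membrane *
    as.numeric(isTRUE(as.logical(annotation$membrane_localized)))
  healthy_penalty <- weights$w_healthy * sum(levels)
  data.frame(accession = annotation$accession,
             cancer_term = cancer_term, prognosis_term = prognosis_term,
             membrane_term = membrane_term,
             healthy_penalty = healthy_penalty,
             total = cancer_term + prognosis_term + membrane_term -
               healthy_penalty,
             stringsAsFactors = FALSE)
}

#' Rank annotated proteins by Target Score
#'
#' Scores every record and sorts by total descending; ties break toward
#' the lower healthy penalty, then lexicographically by accession. Ranks
#' 1..n are assigned in that order.
#'
#' @param annotations Annotation data.frame from [load_annotations()].
#' @inheritParams score_protein
#' @return data.frame of [score_protein()] rows plus `rank`, ordered by
#'   rank.
#' @export
rank_proteins <- function(annotations, weights = score_weights(),
                          vital_organs = default_vital_organs()) {
  if (!nrow(annotations)) stop("no annotations to rank")
  validate_annotations(annotations)
  scored <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    score_protein(annotations[i, , drop = FALSE], weights, vital_organs)
  }))
  o <- order(-scored$total, scored$healthy_penalty, scored$accession)
  scored <- scored[o, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored
}

#' Load / write an annotation TSV
#'
#' Header: accession, cancer_association (0..3), n_unfavorable_prognosis
#' (count), membrane_localized (TRUE/FALSE), then one column per organ
#' from [organ_vocabulary()] holding a level in {not_detected, low,
#' medium, high}. Validation errors name the offending row and column.
#'
#' @param path TSV path.
#' @return Validated annotation data.frame.
#' @export
load_annotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  ann$cancer_association <- suppressWarnings(
    as.integer(ann$cancer_association))
  ann$n_unfavorable_prognosis <- suppressWarnings(
    as.integer(ann$n_unfavorable_prognosis))
  ann$membrane_localized <- as.logical(ann$membrane_localized)
  validate_annotations(ann, where = paste0("annotation file ", sQuote(path)))
  ann
}

#' @rdname load_annotations
#' @param annotations Annotation data.frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write ranked Target Score results (TSV + JSON)
#'
#' @param ranked Result of [rank_proteins()].
#' @param tsv_path,json_path Output paths (JSON optional).
#' @export
write_target_scores <- function(ranked, tsv_path, json_path = NULL) {
  utils::write.table(ranked, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(ranked, json_path, dataframe = "rows",
                         pretty = TRUE, digits = NA)
  invisible(tsv_path)
}
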