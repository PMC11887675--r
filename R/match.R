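#' Search settings
#'
#' Bundles the digestion and matching parameters: enzyme rule, maximum
#' missed cleavages (default 2), precursor/product tolerances (default
#' 10 ppm / 0.02 Da), the glycan panel, whether oxidized Met variants are
#' generated, the peptide length window, and the matched-backbone-ion
#' count at or above which a match is called high confidence.
#'
#' @param enzyme Enzyme rule id; only "chymotrypsin_high_specificity" is
#'   built in (extra cleavage residues may be supplied).
#' @param max_missed Maximum missed cleavages.
#' @param tolerances A [tolerance_settings()].
#' @param glycan_panel Non-empty list of [glycan_composition()] objects.
#' @param allow_oxidized_met Generate Met-oxidation variants (default TRUE).
#' @param min_len,max_len Peptide length window.
#' @param high_confidence_ions Backbone b/y ion count threshold (default 6).
#' @param extra_cleavage_residues e.g. c("M", "H") for low-specificity
#'   chymotrypsin.
#' @return Object of class `search_settings`.
#' @export
search_settings <- function(enzyme = "chymotrypsin_high_specificity",
                            max_missed = 2L,
                            tolerances = tolerance_settings(),
                            glycan_panel = default_glycan_panel(),
                            allow_oxidized_met = TRUE,
                            min_len = 5L, max_len = 60L,
                            high_confidence_ions = 6L,
                            extra_cleavage_residues = character(0)) {
  if (!length(glycan_panel)) stop("glycan panel must be non-empty")
  stopifnot(inherits(tolerances, "tolerance_settings"),
            max_missed >= 0L, high_confidence_ions >= 0L)
  structure(list(enzyme = enzyme, max_missed = as.integer(max_missed),
                 tolerances = tolerances, glycan_panel = glycan_panel,
                 allow_oxidized_met = isTRUE(allow_oxidized_met),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 high_confidence_ions = as.integer(high_confidence_ions),
                 extra_cleavage_residues = extra_cleavage_residues),
            class = "search_settings")
}

# TRUE if the peptide carries the residue the glycan attaches to.
attachment_ok <- function(sequence, attachment) {
  has_n <- grepl("N", sequence, fixed = TRUE)
  has_st <- grepl("[ST]", sequence)
  switch(attachment,
         N_linked = has_n,
         O_linked = has_st,
         unspecified = has_n | has_st)
}

#' Build the glycopeptide candidate index
#'
#' Digests every protein, crosses each peptide with each panel glycan whose
#' attachment residue the peptide carries and with each Met-oxidation state
#' (0..#M if enabled), computes theoretical neutral masses, and returns the
#' candidates sorted ascending by mass for binary-search precursor lookup.
#'
#' @param proteome data.frame from [read_proteome()].
#' @param settings A [search_settings()].
#' @return data.frame of class `glycopeptide_index`: accession, start, end,
#'   sequence, missed_cleavages, n_oxidized_met, glycan (short form),
#'   attachment, theoretical_mass; sorted by theoretical_mass.
#' @export
build_index <- function(proteome, settings = search_settings()) {
  if (is.null(proteome) || nrow(proteome) == 0L)
    stop("proteome is empty")
  peptides <- digest_proteome(proteome, max_missed = settings$max_missed,
                              min_len = settings$min_len,
                              max_len = settings$max_len,
                              extra_residues =
                                settings$extra_cleavage_residues)
  if (is.null(peptides) || nrow(peptides) == 0L)
    stop("digestion produced no peptides inside the length window")
  rows <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    seqi <- peptides$sequence[i]
    n_met <- nchar(gsub("[^M]", "", seqi))
    ox_states <- if (settings$allow_oxidized_met) 0:n_met else 0L
    glycans <- Filter(function(g) attachment_ok(seqi, g$attachment),
                      settings$glycan_panel)
    if (!length(glycans)) next
    base_mass <- peptide_monoisotopic_mass(seqi)
    combos <- expand.grid(g = seq_along(glycans), ox = ox_states)
    rows[[i]] <- data.frame(
      accession = peptides$accession[i],
      start = peptides$start[i], end = peptides$end[i],
      sequence = seqi,
      missed_cleavages = peptides$missed_cleavages[i],
      n_oxidized_met = combos$ox,
      glycan = vapply(glycans[combos$g], format_composition, character(1)),
      attachment = vapply(glycans[combos$g], function(g) g$attachment,
                          character(1)),
      theoretical_mass = base_mass + combos$ox * MOD_MET_OXIDATION +
        vapply(glycans[combos$g], composition_delta_mass, numeric(1)),
      stringsAsFactors = FALSE)
  }
  idx <- do.call(rbind, rows)
  if (is.null(idx) || nrow(idx) == 0L)
    stop("no glycopeptide candidates: no peptide carries an attachment residue")
  idx <- idx[order(idx$theoretical_mass, idx$accession, idx$start,
                   idx$glycan), , drop = FALSE]
  rownames(idx) <- NULL
  class(idx) <- c("glycopeptide_index", "data.frame")
  idx
}

empty_match_table <- function() {
  data.frame(spectrum_id = character(0), accession = character(0),
             start = integer(0), end = integer(0), sequence = character(0),
             missed_cleavages = integer(0), n_oxidized_met = integer(0),
             glycan = character(0), attachment = character(0),
             theoretical_mass = numeric(0), observed_mass = numeric(0),
             mass_error_ppm = numeric(0), backbone_ion_count = integer(0),
             oxonium_pass = logical(0), confidence = character(0),
             stringsAsFactors = FALSE)
}

#' Match a spectrum's precursor against the index
#'
#' Computes the spectrum's neutral mass from PEPMASS and CHARGE and returns
#' every candidate within the precursor ppm tolerance, located by binary
#' search over the mass-sorted index. Matches carry the signed ppm error;
#' backbone scoring and confidence are filled by [score_matches()].
#'
#' @param s An [ms2_spectrum()].
#' @param index A [build_index()] result.
#' @param settings The [search_settings()] the index was built with.
#' @return Match table rows (possibly zero).
#' @export
match_precursor <- function(s, index, settings = search_settings()) {
  obs <- spectrum_neutral_mass(s)
  tol <- settings$tolerances$precursor_ppm
  half <- obs * tol / 1e6
  masses <- index$theoretical_mass
  # widen the bracket by a hair so exact-boundary candidates survive to the
  # exact |ppm| <= tol filter below
  lo <- findInterval(obs - half - 1e-9, masses) + 1L
  hi <- findInterval(obs + half + 1e-9, masses)
  if (hi < lo) return(empty_match_table())
  cand <- index[lo:hi, , drop = FALSE]
  err <- ppm_error(obs, cand$theoretical_mass)
  keep <- abs(err) <= tol
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_match_table())
  out <- data.frame(spectrum_id = s$spectrum_id, cand,
                    observed_mass = obs,
                    mass_error_ppm = err[keep],
                    backbone_ion_count = NA_integer_,
                    oxonium_pass = NA, confidence = NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count matched backbone b/y ions
#'
#' Enumerates the singly protonated b- and y-ion series of the peptide
#' backbone (the glycan treated as fully lost on fragmentation, Met
#' oxidations retained on their residues are ignored at this level since
#' sites are not localized) and counts series members with an observed
#' peak within the product-ion tolerance. Intensity plays no role.
#'
#' @param s An [ms2_spectrum()].
#' @param sequence Peptide sequence.
#' @param tol A [tolerance_settings()].
#' @return Integer count of matched b/y ions.
#' @export
score_backbone <- function(s, sequence, tol = tolerance_settings()) {
  ions <- backbone_ions(sequence)
  if (!length(s$mz)) return(0L)
  sum(vapply(ions, function(ion) any(abs(s$mz - ion) <= tol$product_da),
             logical(1)))
}

#' Theoretical singly charged b/y fragment m/z of a peptide backbone
#'
#' @param sequence Peptide sequence (Cys carbamidomethylated).
#' @return Numeric vector of 2*(n-1) fragment m/z values.
#' @export
backbone_ions <- function(sequence) {
  tab <- amino_acid_masses()
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  res <- tab[chars] + ifelse(chars == "C", MOD_CARBAMIDOMETHYL, 0)
  n <- length(res)
  if (n < 2L) return(numeric(0))
  b <- cumsum(res[-n]) + MASS_PROTON
  y <- rev(cumsum(rev(res[-1L]))) + MASS_WATER + MASS_PROTON
  c(b, y)
}

#' Assign a confidence tier to scored matches
#'
#' High confidence requires at least `high_confidence_ions` matched
#' backbone ions (inclusive) and a precursor error inside tolerance;
#' everything else is low confidence. Low-confidence identifications can
#' still reach the final list when validated by the oxonium filter (see
#' [finalize_list()]).
#'
#' @param backbone_ion_count Matched-ion counts.
#' @param mass_error_ppm Signed precursor errors.
#' @param settings A [search_settings()].
#' @return Character vector "high"/"low".
#' @export
assign_confidence <- function(backbone_ion_count, mass_error_ppm,
                              settings = search_settings()) {
  ifelse(backbone_ion_count >= settings$high_confidence_ions &
           abs(mass_error_ppm) <= settings$tolerances$precursor_ppm,
         "high", "low")
}

#' Search a set of spectra against a proteome index
#'
#' Runs [match_precursor()] per spectrum, fills backbone scores, the
#' oxonium validation flag and the confidence tier, and orders matches
#' deterministically: |ppm| ascending, then backbone count descending,
#' then accession, per spectrum.
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param index A [build_index()] result.
#' @param settings A [search_settings()].
#' @return Match table (one row per spectrum-candidate pair).
#' @export
search_spectra <- function(spectra, index, settings = search_settings()) {
  per <- lapply(spectra, function(s) {
    m <- match_precursor(s, index, settings)
    if (!nrow(m)) return(m)
    m$backbone_ion_count <- vapply(m$sequence, function(sq) {
      score_backbone(s, sq, settings$tolerances)
    }, integer(1), USE.NAMES = FALSE)
    m$oxonium_pass <- passes_sle_oxonium_filter(s, settings$tolerances)
    m$confidence <- assign_confidence(m$backbone_ion_count,
                                      m$mass_error_ppm, settings)
    m <- m[order(abs(m$mass_error_ppm), -m$backbone_ion_count,
                 m$accession), , drop = FALSE]
    m
  })
  out <- do.call(rbind, c(per, list(empty_match_table())))
  rownames(out) <- NULL
  out
}

#' Write a match table as TSV
#'
#' Stable column order as documented in the README.
#'
#' @param matches Match table from [search_spectra()].
#' @param path Output path.
#' @export
write_match_table <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
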