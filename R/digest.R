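#' Amino-acid monoisotopic residue masses
#'
#' Standard monoisotopic residue masses (Da) for the 20 amino acids, plus
#' the constants used throughout: water 18.010565 Da, proton 1.007276 Da,
#' carbamidomethyl +57.021464 Da (fixed on Cys), Met oxidation
#' +15.994915 Da (variable).
#'
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
amino_acid_masses <- function() {
  c(G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)
}

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MOD_CARBAMIDOMETHYL <- 57.021464
MOD_MET_OXIDATION <- 15.994915

#' Read protein records from FASTA
#'
#' Standard FASTA via Biostrings; the accession is the first
#' whitespace-delimited token of the header. Sequences must use the 20
#' standard uppercase letters.
#'
#' @param path FASTA file path.
#' @return data.frame with columns accession, description, sequence.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no sequences in ", sQuote(path))
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- sub("^\\S+\\s*", "", headers)
  sequence <- toupper(as.character(aa))
  bad <- grepl(sprintf("[^%s]", paste(names(amino_acid_masses()),
                                      collapse = "")), sequence)
  if (any(bad))
    stop("non-standard amino-acid letters in record(s): ",
         paste(accession[bad], collapse = ", "))
  if (anyDuplicated(accession))
    stop("duplicate accessions in ", sQuote(path))
  data.frame(accession = accession, description = description,
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteome data.frame as from [read_proteome()].
#' @param path Output path.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- ifelse(nzchar(proteome$description),
                      paste(proteome$accession, proteome$description),
                      proteome$accession)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

# 0-based positions after which chymotrypsin cleaves (high specificity:
# C-terminal to F/W/Y/L, not before Pro). Returns cut points excluding the
# sequence ends.
chymotryptic_sites <- function(sequence, residues = c("F", "W", "Y", "L")) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% residues & chars[-1L] != "P")
  idx
}

#' Chymotryptic in-silico digestion
#'
#' Cleaves C-terminal to F, W, Y and L except before proline (the
#' high-specificity chymotrypsin rule; M and H cleavage can be enabled via
#' `extra_residues`), and enumerates every peptide with at most
#' `max_missed` internal missed-cleavage sites inside the length window.
#' Coordinates are 0-based half-open on the parent sequence.
#'
#' @param sequence Protein sequence string (or one row of a proteome
#'   data.frame via `accession`).
#' @param accession Parent accession carried into the output.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_len,max_len Peptide length window (default 5..60).
#' @param extra_residues Additional cleavage residues, e.g. c("M","H").
#' @return data.frame with columns accession, start, end, sequence,
#'   missed_cleavages, ordered by start then end.
#' @export
chymotryptic_digest <- function(sequence, accession = NA_character_,
                                max_missed = 2L, min_len = 5L,
                                max_len = 60L, extra_residues = character(0)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("cannot digest an empty sequence")
  stopifnot(max_missed >= 0L, min_len >= 1L, max_len >= min_len)
  sites <- chymotryptic_sites(sequence,
                              residues = c("F", "W", "Y", "L",
                                           extra_residues))
  cuts <- c(0L, sites, nchar(sequence))
  k <- length(cuts)
  out <- vector("list", k - 1L)
  for (i in seq_len(k - 1L)) {
    jmax <- min(i + max_missed + 1L, k)
    js <- seq.int(i + 1L, jmax)
    starts <- rep.int(cuts[i], length(js))
    ends <- cuts[js]
    out[[i]] <- data.frame(start = starts, end = ends,
                           missed_cleavages = js - i - 1L)
  }
  pep <- do.call(rbind, out)
  len <- pep$end - pep$start
  pep <- pep[len >= min_len & len <= max_len, , drop = FALSE]
  pep <- pep[order(pep$start, pep$end), , drop = FALSE]
  data.frame(accession = rep.int(accession, nrow(pep)),
             start = pep$start, end = pep$end,
             sequence = substring(sequence, pep$start + 1L, pep$end),
             missed_cleavages = pep$missed_cleavages,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Digest a whole proteome
#'
#' @param proteome data.frame from [read_proteome()].
#' @param ... Passed to [chymotryptic_digest()].
#' @return Row-bound peptide data.frame.
#' @export
digest_proteome <- function(proteome, ...) {
  do.call(rbind, lapply(seq_len(nrow(proteome)), function(i) {
    chymotryptic_digest(proteome$sequence[i],
                        accession = proteome$accession[i], ...)
  }))
}

#' Peptide monoisotopic mass
#'
#' Residue masses + water, with carbamidomethyl applied as a fixed
#' modification on every Cys and `n_oxidized_met` variable Met oxidations.
#'
#' @param sequence Peptide sequence.
#' @param n_oxidized_met Number of oxidized methionines (<= count of M).
#' @param fixed_cys Apply the +57.021464 Da carbamidomethyl on Cys
#'   (default TRUE; FALSE gives the unmodified backbone mass).
#' @return Neutral monoisotopic mass in Da (vectorized over `sequence`).
#' @export
peptide_monoisotopic_mass <- function(sequence, n_oxidized_met = 0L,
                                      fixed_cys = TRUE) {
  tab <- amino_acid_masses()
  n_met <- nchar(gsub("[^M]", "", sequence))
  if (any(n_oxidized_met > n_met))
    stop("n_oxidized_met exceeds the number of methionines")
  vapply(seq_along(sequence), function(i) {
    chars <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    m <- tab[chars]
    if (anyNA(m))
      stop("unknown residue in peptide ", sQuote(sequence[i]))
    n_cys <- sum(chars == "C")
    sum(m) + MASS_WATER +
      (if (fixed_cys) n_cys * MOD_CARBAMIDOMETHYL else 0) +
      rep_len(n_oxidized_met, length(sequence))[i] * MOD_MET_OXIDATION
  }, numeric(1))
}

#' Glycopeptide monoisotopic mass
#'
#' Peptide mass plus the glycan composition delta. The attachment class is
#' enforced: N-linked glycans require an Asn in the peptide, O-linked
#' require a Ser or Thr, unspecified requires any of the three.
#'
#' @param sequence Peptide sequence.
#' @param comp A [glycan_composition()].
#' @param n_oxidized_met Oxidized Met count on the peptide.
#' @return Neutral mass in Da.
#' @export
glycopeptide_mass <- function(sequence, comp, n_oxidized_met = 0L) {
  if (total_residues(comp) > 0L) {
    has_n <- grepl("N", sequence, fixed = TRUE)
    has_st <- grepl("[ST]", sequence)
    ok <- switch(comp$attachment,
                 N_linked = has_n,
                 O_linked = has_st,
                 unspecified = has_n | has_st)
    if (!ok)
      stop("peptide ", sQuote(sequence), " lacks the attachment residue: ",
           switch(comp$attachment,
                  N_linked = "asparagine",
                  O_linked = "serine and threonine",
                  unspecified = "asparagine, serine or threonine"),
           " required")
  }
  peptide_monoisotopic_mass(sequence, n_oxidized_met) +
    composition_delta_mass(comp)
}

#' Convert neutral mass to m/z and back
#'
#' `m/z = (M + z * 1.007276) / z` for protonated positive ions.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z (or neutral mass for the inverse).
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  if (any(charge < 1L) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  (neutral_mass + charge * MASS_PROTON) / charge
}

#' @rdname mz_from_mass
#' @param mz Observed m/z.
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(charge < 1L) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  mz * charge - charge * MASS_PROTON
}
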