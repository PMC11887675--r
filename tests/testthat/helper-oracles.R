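# Independent oracles built from first principles (elemental compositions
# and brute-force enumeration), deliberately sharing no code with the
# package internals.

ATOM <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
          O = 15.9949146221, S = 31.97207069)

formula_mass <- function(nC = 0, nH = 0, nN = 0, nO = 0, nS = 0) {
  nC * ATOM[["C"]] + nH * ATOM[["H"]] + nN * ATOM[["N"]] +
    nO * ATOM[["O"]] + nS * ATOM[["S"]]
}

# residue (water-loss) masses from elemental formulas
oracle_aa_mass <- local({
  f <- list(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
  vapply(f, function(x) formula_mass(x[1], x[2], x[3], x[4], x[5]),
         numeric(1))
})

oracle_glycan_residue <- c(
  Hex = formula_mass(6, 10, 0, 5),      # C6H10O5
  HexNAc = formula_mass(8, 13, 1, 5),   # C8H13NO5
  dHex = formula_mass(6, 10, 0, 4),     # C6H10O4
  NeuAc = formula_mass(11, 17, 1, 8))   # C11H17NO8

oracle_water <- formula_mass(0, 2, 0, 1)
oracle_proton <- 1.007276467

oracle_peptide_mass <- function(sequence, n_ox = 0, cam = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  m <- sum(oracle_aa_mass[chars]) + oracle_water
  if (cam) m <- m + sum(chars == "C") * formula_mass(2, 3, 1, 1) # +C2H3NO
  m + n_ox * ATOM[["O"]]
}

oracle_glycan_mass <- function(hex, hexnac, dhex, neuac) {
  hex * oracle_glycan_residue[["Hex"]] +
    hexnac * oracle_glycan_residue[["HexNAc"]] +
    dhex * oracle_glycan_residue[["dHex"]] +
    neuac * oracle_glycan_residue[["NeuAc"]]
}

# brute-force chymotryptic digestion: enumerate every window between cut
# points and count internal sites directly
oracle_digest <- function(sequence, max_missed, min_len, max_len) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  sites <- integer(0)
  for (i in seq_len(max(0, n - 1))) {
    if (chars[i] %in% c("F", "W", "Y", "L") && chars[i + 1] != "P")
      sites <- c(sites, i)
  }
  cuts <- c(0, sites, n)
  out <- character(0)
  for (a in seq_along(cuts)) {
    for (b in seq_along(cuts)) {
      if (b <= a) next
      internal <- sum(sites > cuts[a] & sites < cuts[b])
      len <- cuts[b] - cuts[a]
      if (internal <= max_missed && len >= min_len && len <= max_len)
        out <- c(out, substr(sequence, cuts[a] + 1, cuts[b]))
    }
  }
  sort(out)
}

random_aa_sequence <- function(len) {
  paste(sample(names(oracle_aa_mass), len, replace = TRUE), collapse = "")
}

random_composition <- function() {
  glycan_composition(hex = sample(0:6, 1), hexnac = sample(0:6, 1),
                     dhex = sample(0:4, 1), neuac = sample(0:4, 1),
                     attachment = sample(c("N_linked", "O_linked",
                                           "unspecified"), 1))
}

# evidence-table builder for curation tests
make_evidence <- function(accession, runs, n_flag, o_flag,
                          confidence = "high", oxonium = TRUE) {
  data.frame(accession = accession,
             runs_observed = runs, n_runs = lengths(strsplit(runs, ",")),
             n_matches = 1L, n_linked_evidence = n_flag,
             o_linked_evidence = o_flag, best_confidence = confidence,
             any_oxonium_pass = oxonium, stringsAsFactors = FALSE)
}
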