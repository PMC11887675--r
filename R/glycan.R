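#' Monosaccharide residue mass table
#'
#' Monoisotopic residue masses (Da) of the four monosaccharide building
#' blocks used in composition shorthand: Hex (hexose, e.g. Gal/Man),
#' HexNAc (N-acetylhexosamine, e.g. GlcNAc/GalNAc), dHex (deoxyhexose,
#' i.e. fucose) and NeuAc (N-acetylneuraminic / sialic acid). These are the
#' residue (water-loss) masses, so a glycan delta mass on a peptide is the
#' plain sum over counts.
#'
#' @return Named numeric vector with entries Hex, HexNAc, dHex, NeuAc.
#' @export
monosaccharide_table <- function() {
  c(Hex = 162.052824, HexNAc = 203.079373, dHex = 146.057909,
    NeuAc = 291.095417)
}

.GLYCAN_SYMBOLS <- c("Hex", "HexNAc", "dHex", "NeuAc")
.SHORT_LETTERS <- c(H = "Hex", N = "HexNAc", F = "dHex", S = "NeuAc")
.ATTACHMENTS <- c("N_linked", "O_linked", "unspecified")

#' Construct a glycan composition
#'
#' A glycan composition is a multiset of monosaccharide residues -- counts
#' only, no topology -- together with an attachment class recording whether
#' it is searched as an N-glycan (on Asn), an O-glycan (on Ser/Thr) or
#' either.
#'
#' @param hex,hexnac,dhex,neuac Non-negative integer residue counts.
#' @param attachment One of "N_linked", "O_linked", "unspecified".
#' @return Object of class `glycan_composition`.
#' @export
glycan_composition <- function(hex = 0L, hexnac = 0L, dhex = 0L, neuac = 0L,
                               attachment = "unspecified") {
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("glycan composition counts must be non-negative integers")
  attachment <- match.arg(attachment, .ATTACHMENTS)
  structure(list(hex = as.integer(hex), hexnac = as.integer(hexnac),
                 dhex = as.integer(dhex), neuac = as.integer(neuac),
                 attachment = attachment),
            class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(sprintf("<glycan %s, %s>\n", format_composition(x, "short"),
              x$attachment))
  invisible(x)
}

total_residues <- function(comp) comp$hex + comp$hexnac + comp$dhex + comp$neuac

#' Parse a glycan composition string
#'
#' Two dialects are auto-detected: the compact letter form `H5N4F1S1`
#' (H = Hex, N = HexNAc, F = dHex/fucose, S = NeuAc/sialic acid) and the
#' long form `Hex(2)HexNAc(2)NeuAc(1)dHex(1)`. Symbols absent from the
#' string have count zero. An all-zero composition is rejected, since a
#' composition used as a modification must carry at least one residue.
#'
#' @param text Composition string in either dialect.
#' @param attachment Attachment class to stamp on the result.
#' @return A [glycan_composition()].
#' @export
parse_composition <- function(text, attachment = "unspecified") {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty composition string")
  counts <- c(Hex = 0L, HexNAc = 0L, dHex = 0L, NeuAc = 0L)
  if (grepl("\\(", text, fixed = FALSE)) {
    # long dialect: Name(count) tokens
    tokens <- regmatches(text, gregexpr("[A-Za-z]+\\(\\d+\\)", text))[[1]]
    residue <- paste(tokens, collapse = "")
    if (!identical(gsub("\\s", "", text), residue))
      stop("cannot parse composition string: ", sQuote(text))
    for (tok in tokens) {
      name <- sub("\\(.*$", "", tok)
      n <- as.integer(sub("^.*\\((\\d+)\\)$", "\\1", tok))
      if (!name %in% names(counts))
        stop("unknown monosaccharide symbol ", sQuote(name), " in ",
             sQuote(text))
      counts[name] <- counts[name] + n
    }
  } else {
    tokens <- regmatches(text, gregexpr("[A-Za-z]\\d+", text))[[1]]
    if (!identical(gsub("\\s", "", text), paste(tokens, collapse = "")))
      stop("cannot parse composition string: ", sQuote(text))
    for (tok in tokens) {
      letter <- substr(tok, 1L, 1L)
      if (!letter %in% names(.SHORT_LETTERS))
        stop("unknown monosaccharide symbol ", sQuote(letter), " in ",
             sQuote(text))
      counts[.SHORT_LETTERS[[letter]]] <-
        counts[.SHORT_LETTERS[[letter]]] + as.integer(substring(tok, 2L))
    }
  }
  if (sum(counts) == 0L)
    stop("composition ", sQuote(text), " has zero total residues")
  glycan_composition(hex = counts[["Hex"]], hexnac = counts[["HexNAc"]],
                     dhex = counts[["dHex"]], neuac = counts[["NeuAc"]],
                     attachment = attachment)
}

#' Format a glycan composition
#'
#' Inverse of [parse_composition()]: `short` gives `H5N4F1S1` style (zero
#' counts omitted), `long` gives `Hex(5)HexNAc(4)dHex(1)NeuAc(1)`.
#'
#' @param comp A [glycan_composition()].
#' @param dialect "short" or "long".
#' @return Composition string.
#' @export
format_composition <- function(comp, dialect = c("short", "long")) {
  dialect <- match.arg(dialect)
  counts <- c(comp$hex, comp$hexnac, comp$dhex, comp$neuac)
  if (dialect == "short") {
    letters <- c("H", "N", "F", "S")
    keep <- counts > 0L
    paste0(letters[keep], counts[keep], collapse = "")
  } else {
    keep <- counts > 0L
    paste0(.GLYCAN_SYMBOLS[keep], "(", counts[keep], ")", collapse = "")
  }
}

#' Monoisotopic delta mass of a glycan composition
#'
#' Sum of residue masses over counts: the mass added to a peptide when the
#' glycan is attached (residue masses already account for the glycosidic
#' water loss). The empty composition is allowed here and returns 0,
#' preserving additivity.
#'
#' @param comp A [glycan_composition()].
#' @param table Residue-mass table, default [monosaccharide_table()].
#' @return Delta mass in Da.
#' @export
composition_delta_mass <- function(comp, table = monosaccharide_table()) {
  needed <- .GLYCAN_SYMBOLS
  if (!all(needed %in% names(table)))
    stop("residue mass table is missing: ",
         paste(setdiff(needed, names(table)), collapse = ", "))
  comp$hex * table[["Hex"]] + comp$hexnac * table[["HexNAc"]] +
    comp$dhex * table[["dHex"]] + comp$neuac * table[["NeuAc"]]
}

#' Composition-level sialyl Lewis compatibility
#'
#' A sialylated Lewis (sLeA/sLeX) terminus requires NeuAc, Gal (a Hex),
#' fucose (dHex) and GlcNAc (a HexNAc). At composition level only a
#' necessary condition is decidable: at least one of each of the four
#' residues. Topology (whether they actually form the epitope) cannot be
#' inferred from counts, and the reason string says so.
#'
#' @param comp A [glycan_composition()].
#' @return List with `compatible` (logical) and `reason` (string naming the
#'   first failing residue, or stating the necessary condition holds).
#' @export
is_sle_compatible <- function(comp) {
  checks <- c(Hex = comp$hex >= 1L, HexNAc = comp$hexnac >= 1L,
              dHex = comp$dhex >= 1L, NeuAc = comp$neuac >= 1L)
  if (all(checks)) {
    list(compatible = TRUE,
         reason = paste("contains Hex, HexNAc, dHex and NeuAc; necessary",
                        "(not sufficient: topology unknown from composition)",
                        "condition for a sialylated Lewis terminus holds"))
  } else {
    missing <- names(checks)[!checks][1L]
    list(compatible = FALSE,
         reason = sprintf("no %s residue: sialylated Lewis termini require %s",
                          missing, missing))
  }
}

#' Classify an N-glycan composition
#'
#' Deterministic class from counts alone, using a documented heuristic rule
#' table (composition cannot prove topology): paucimannose has HexNAc <= 2
#' and Hex <= 3; oligomannose has exactly the chitobiose HexNAc2 core with
#' Hex >= 4 and no fucose or sialic acid; complex has HexNAc >= 4; hybrid
#' has HexNAc == 3 and Hex >= 4; everything else is "other".
#'
#' @param comp A [glycan_composition()] with attachment N_linked or
#'   unspecified.
#' @return One of "oligomannose", "complex", "hybrid", "paucimannose",
#'   "other".
#' @export
n_glycan_class <- function(comp) {
  if (comp$attachment == "O_linked")
    stop("n_glycan_class applies to N-linked or unspecified compositions")
  if (comp$hexnac <= 2L && comp$hex <= 3L) return("paucimannose")
  if (comp$hexnac == 2L && comp$hex >= 4L && comp$dhex == 0L &&
      comp$neuac == 0L) return("oligomannose")
  if (comp$hexnac >= 4L) return("complex")
  if (comp$hexnac == 3L && comp$hex >= 4L) return("hybrid")
  "other"
}

#' Read a glycan panel file
#'
#' Plain text, one composition per line in either dialect; `#` starts a
#' comment; an optional second whitespace-delimited token `N` or `O` (or
#' `N_linked` / `O_linked`) sets the attachment class, default unspecified.
#'
#' @param path File path.
#' @return List of [glycan_composition()] objects.
#' @export
read_glycan_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("glycan panel file ", sQuote(path), " is empty")
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\\s+")[[1]]
    att <- "unspecified"
    if (length(parts) >= 2L) {
      att <- switch(toupper(parts[2L]),
                    "N" = , "N_LINKED" = "N_linked",
                    "O" = , "O_LINKED" = "O_linked",
                    stop("unknown attachment tag ", sQuote(parts[2L]),
                         " in panel line ", sQuote(ln)))
    }
    parse_composition(parts[1L], attachment = att)
  })
}

#' The default search panel of sialyl-Lewis-compatible glycans
#'
#' Two complex N-glycan compositions (searched on Asn) and three O-glycan
#' compositions (searched on Ser/Thr), all carrying at least one Hex,
#' HexNAc, dHex and NeuAc and therefore composition-compatible with
#' sialylated Lewis termini.
#'
#' @return List of [glycan_composition()] objects.
#' @export
default_glycan_panel <- function() {
  c(lapply(c("H5N4F1S1", "H5N4F1S2"),
           parse_composition, attachment = "N_linked"),
    lapply(c("Hex(2)HexNAc(2)NeuAc(1)dHex(1)",
             "Hex(2)HexNAc(2)NeuAc(2)dHex(1)",
             "Hex(3)HexNAc(3)NeuAc(2)dHex(2)"),
           parse_composition, attachment = "O_linked"))
}
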