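#' Construct an MS2 spectrum
#'
#' Precursor (m/z, charge) plus a centroided peak list. Peaks are stored
#' sorted ascending by m/z; intensities must be non-negative.
#'
#' @param spectrum_id Identifier (MGF TITLE).
#' @param precursor_mz Precursor m/z (> 0).
#' @param precursor_charge Positive integer charge.
#' @param mz,intensity Parallel numeric peak vectors.
#' @param retention_time Optional retention time in seconds.
#' @return Object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(spectrum_id, precursor_mz, precursor_charge,
                         mz = numeric(0), intensity = numeric(0),
                         retention_time = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (!is.finite(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be positive")
  if (precursor_charge < 1L || precursor_charge != round(precursor_charge))
    stop("precursor_charge must be a positive integer")
  if (length(intensity) && any(intensity < 0))
    stop("intensities must be non-negative")
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 retention_time = retention_time,
                 mz = mz[o], intensity = intensity[o]),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2 %s: %.4f m/z, %d+, %d peaks>\n", x$spectrum_id,
              x$precursor_mz, x$precursor_charge, length(x$mz)))
  invisible(x)
}

#' Neutral precursor mass of a spectrum
#'
#' @param s An [ms2_spectrum()].
#' @return Neutral monoisotopic mass in Da.
#' @export
spectrum_neutral_mass <- function(s) {
  mass_from_mz(s$precursor_mz, s$precursor_charge)
}

#' Tolerance settings
#'
#' @param precursor_ppm Precursor tolerance in parts per million
#'   (default 10).
#' @param product_da Product-ion tolerance in Da (default 0.02).
#' @return Object of class `tolerance_settings`.
#' @export
tolerance_settings <- function(precursor_ppm = 10, product_da = 0.02) {
  if (precursor_ppm <= 0 || product_da <= 0)
    stop("tolerances must be positive")
  structure(list(precursor_ppm = precursor_ppm, product_da = product_da),
            class = "tolerance_settings")
}

#' Read an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with PEPMASS, CHARGE ("2+" style or
#' bare integer), TITLE and optional RTINSECONDS. Peak lists are sorted on
#' read. A spectrum lacking CHARGE is assumed to be doubly charged, with a
#' warning.
#'
#' @param path MGF file path.
#' @return List of [ms2_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) ||
      (length(begins) && any(ends < begins)))
    stop("malformed MGF ", sQuote(path), ": block ", length(ends) + 1L,
         " lacks END IONS")
  spectra <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_kv <- grepl("^[A-Z][A-Z0-9]*=", block)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    get <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pepmass <- get("PEPMASS")
    if (is.na(pepmass))
      stop("MGF block ", b, " in ", sQuote(path), " is missing PEPMASS")
    precursor_mz <- as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1])
    charge_raw <- get("CHARGE")
    if (is.na(charge_raw)) {
      warning("MGF block ", b, " has no CHARGE; assuming 2+")
      charge <- 2L
    } else {
      charge <- as.integer(sub("\\+$", "", trimws(charge_raw)))
    }
    title <- get("TITLE")
    if (is.na(title)) title <- sprintf("spectrum_%04d", b)
    rt <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    peak_lines <- block[!is_kv]
    if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"),
                                   function(x) as.numeric(x[1:2])))
      if (anyNA(mat))
        stop("unparseable peak line in MGF block ", b, " of ", sQuote(path))
      mzv <- mat[, 1]; intv <- mat[, 2]
    } else {
      mzv <- numeric(0); intv <- numeric(0)
    }
    spectra[[b]] <- ms2_spectrum(title, precursor_mz, charge, mzv, intv,
                                 retention_time = rt)
  }
  spectra
}

#' Write spectra to MGF
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param path Output path.
#' @param header Optional comment lines written at the top (prefixed '#').
#' @export
write_mgf <- function(spectra, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    if (!is.null(s$retention_time) && !is.na(s$retention_time))
      writeLines(sprintf("RTINSECONDS=%.3f", s$retention_time), con)
    if (length(s$mz))
      writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Signed relative mass error in ppm
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed,theoretical Masses in Da (theoretical > 0).
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' @rdname ppm_error
#' @param tol_ppm Tolerance in ppm.
#' @return `ppm_match`: TRUE iff |error| <= tol_ppm.
#' @export
ppm_match <- function(observed, theoretical, tol_ppm) {
  abs(ppm_error(observed, theoretical)) <= tol_ppm
}

#' Diagnostic oxonium-ion reference m/z values
#'
#' Singly protonated glycan fragment ions grouped into the three classes
#' whose joint presence flags a sialylated-Lewis-compatible glycopeptide
#' spectrum: the hexosamine (HexNAc) series including its water/ketene
#' losses, the sialic acid (NeuAc) pair, and the HexNAc-Hex disaccharide.
#'
#' @return Named list of numeric vectors: hexnac_class, neuac_class,
#'   hexnac_hex_class.
#' @export
oxonium_reference <- function() {
  list(hexnac_class = c(204.0867, 186.0761, 168.0655, 138.0550, 126.0550),
       neuac_class = c(292.1027, 274.0921),
       hexnac_hex_class = c(366.1395))
}

#' Scan a spectrum for oxonium ions
#'
#' For each reference class, returns the peaks lying within the product-ion
#' tolerance of any class member and above a relative intensity floor
#' (fraction of the base peak; default 1% to suppress noise matches).
#'
#' @param s An [ms2_spectrum()].
#' @param tol A [tolerance_settings()].
#' @param reference Class reference list, default [oxonium_reference()].
#' @param min_relative_intensity Floor as a fraction of the base peak.
#' @return Named list of data.frames (mz, intensity, reference_mz) per
#'   class.
#' @export
oxonium_scan <- function(s, tol = tolerance_settings(),
                         reference = oxonium_reference(),
                         min_relative_intensity = 0.01) {
  floor_abs <- if (length(s$intensity)) {
    max(s$intensity) * min_relative_intensity
  } else {
    Inf
  }
  lapply(reference, function(refs) {
    hits <- lapply(refs, function(r) {
      sel <- abs(s$mz - r) <= tol$product_da & s$intensity >= floor_abs
      if (any(sel)) {
        data.frame(mz = s$mz[sel], intensity = s$intensity[sel],
                   reference_mz = r)
      } else {
        NULL
      }
    })
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits)) do.call(rbind, hits)
    else data.frame(mz = numeric(0), intensity = numeric(0),
                    reference_mz = numeric(0))
  })
}

#' Sialylated-Lewis oxonium validation filter
#'
#' TRUE iff the spectrum shows at least one ion from each of the three
#' diagnostic classes: hexosamine, sialic acid, and the hexosamine-hexose
#' disaccharide. A spectrum failing any class is not accepted as evidence
#' of a sialylated-Lewis-bearing glycopeptide.
#'
#' @inheritParams oxonium_scan
#' @return Logical flag.
#' @export
passes_sle_oxonium_filter <- function(s, tol = tolerance_settings(),
                                      reference = oxonium_reference(),
                                      min_relative_intensity = 0.01) {
  det <- oxonium_scan(s, tol, reference, min_relative_intensity)
  all(vapply(det, nrow, integer(1)) >= 1L)
}
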