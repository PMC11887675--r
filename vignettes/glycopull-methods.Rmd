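---
title: "Methods: curating an E-selectin affinity glycoproteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating an E-selectin affinity glycoproteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopull)
```

## The experiment being modeled

Carcinoma cells entering the bloodstream display sialylated Lewis antigens
(sLeA/sLeX) — NeuAc–Gal–(Fuc)GlcNAc termini on N- and O-glycans — which are
the ligands of endothelial E-selectin. An affinity pulldown with an
E-selectin/Fc chimera therefore enriches exactly the glycoproteins a
metastasizing cell would use to adhere to endothelium. Because E-selectin
binding is strictly Ca²⁺-dependent, two negative controls bracket the
experiment: an IgG-isotype IP (non-specific sticking) and the same chimera
without calcium (lectin-independent binding). Chymotryptic glycopeptides
from the captured proteins are analyzed by LC-MS/MS, and the informatics
problem — the part this package implements — is to turn those spectra into
a curated, prioritized list of candidate sLe-carrier glycoproteins.

## Glycan mass arithmetic

A glycan composition is a residue multiset over Hex, HexNAc, dHex (fucose)
and NeuAc; composition says nothing about topology, and nothing here
pretends otherwise. Delta masses are plain sums of monoisotopic *residue*
masses (Hex 162.052824, HexNAc 203.079373, dHex 146.057909, NeuAc
291.095417 Da), which already account for the glycosidic water loss, so
attaching a glycan to a peptide adds exactly the sum. These four constants
reproduce, at three decimals, all five delta masses of the default search
panel (H5N4F1S1 2059.735; H5N4F1S2 2350.830; the three O-glycan
compositions 1167.418, 1458.513, 1969.703 Da). Display rounding is R's
round-half-even at 3 dp, matching how such deltas are conventionally
printed.

Two classification rules operate on compositions alone and are documented
heuristics, deliberately replaceable:

* **sLe compatibility** is a *necessary* condition only: at least one of
  each of Hex, HexNAc, dHex and NeuAc. A composition meeting it may still
  not carry the epitope (the fucose may sit on the core, the sialic acid
  elsewhere); the reason string returned with every verdict states this.
* **N-glycan class**: paucimannose (HexNAc ≤ 2, Hex ≤ 3), oligomannose
  (HexNAc = 2, Hex ≥ 4, no dHex/NeuAc), complex (HexNAc ≥ 4), hybrid
  (HexNAc = 3, Hex ≥ 4), other. Class proportions in real data depend on
  this rule table; swap it if your annotation conventions differ.

## Digestion and masses

Chymotrypsin is modeled with the high-specificity rule — cleavage
C-terminal to F, W, Y, L except before proline — with M/H cleavage
available as an option (`extra_cleavage_residues`), since enzyme
preparations differ. Up to two missed cleavages are enumerated by default.
The peptide length window defaults to 5..60 residues: a practical
search-space bound, not a biological claim. Peptide masses use the standard
amino-acid monoisotopic residue table plus water (18.010565 Da), with
carbamidomethyl-Cys (+57.021464 Da) fixed and Met oxidation (+15.994915 Da)
variable; m/z arithmetic uses the proton mass 1.007276 Da. One glycan per
peptide is assumed throughout — the variable-modification search this
mirrors assigns a single composition per match — so multiply glycosylated
peptides are out of scope.

## Matching and validation

The matcher is intentionally transparent rather than a reimplementation of
a vendor search engine. Candidates (peptide × compatible glycan ×
Met-oxidation state) are indexed sorted by theoretical neutral mass;
precursor lookup is a binary search at 10 ppm; backbone evidence is the
count of singly charged b/y ions (glycan treated as lost on fragmentation)
within 0.02 Da; a match is **high confidence** at ≥ 6 matched backbone
ions (inclusive), else **low**. The threshold of 6 separates a planted
full series from sparse coincidental matches on peptides of the minimum
length (a 5-mer has 8 backbone ions); it is a tier boundary, not a
statistical FDR — target-decoy FDR estimation is a non-goal. Tie-breaking
in output is fixed (|ppm| ascending, backbone count descending, accession)
purely for determinism.

Oxonium validation requires one ion from *each* of three classes —
hexosamine (204.0867 with its water/ketene losses 186.0761, 168.0655,
138.0550, 126.0550), sialic acid (292.1027, 274.0921) and HexNAc-Hex
(366.1395) — within the product tolerance and above a relative intensity
floor of 1% of the base peak (a noise guard; configurable). Whether one
should require specific ions or any class member is a judgment call; the
class-level reading is implemented. Note a consequence of the relative
floor: the filter is invariant to uniform intensity scaling, and adding
peaks no brighter than the existing base peak can never un-pass it, but a
new peak dwarfing everything else could push diagnostic ions under the
floor — that is the intended noise-suppression behavior.

## Curation

"Detected in a run" means ≥ 1 glycopeptide match from a spectrum of that
run; no intensity threshold is applied, because the underlying experiment
reports presence/absence. The final list keeps proteins (i) observed in at
least one pulldown run and zero control runs — exclusivity is enforced at
the protein level, the natural reading of a "solely detected in pulldowns"
rule — and (ii) identified with high confidence, or with low confidence
but at least one oxonium-validated match. Manual spectrum validation in
the original workflow is approximated here by the oxonium filter; that is
an approximation and is labeled as such. The linkage partition reports
O-linked, N-linked, both, and union, and asserts inclusion-exclusion
(`o + n − both == union`) on every call; rows with neither linkage flag
(possible only with unspecified-attachment panels) are an error rather
than silently miscounted.

## Target Score

Target prioritization of this kind is usually described qualitatively —
sum cancer specificity and poor-prognosis association, penalize
healthy-tissue expression — so the implementation is an explicit additive
form with exposed weights:

`total = w_c·cancer + w_p·prognosis + w_m·membrane − w_h·Σ_organs level`

with cancer association an ordinal 0..3 (evidence strength), prognosis the
count of cancers with unfavorable prognostic association, membrane a 0/1
indicator, and healthy expression ordinal 0..3 (not_detected..high) summed
over a vital-organ set defaulting to brain, heart, lung, liver, kidney,
pancreas and colon ("relevant healthy organs" is not a fixed list anywhere;
this set is configurable). Default weights are all 1. Ordinal sums,
indicator scorings and normalized variants are all reachable by
re-weighting, which is why the weights exist. Mapping real HPA annotations
onto these ordinals is the data preparer's responsibility; the package
validates ranges and vocabulary, not biology. Reproducing any particular
published ranking requires the corresponding annotation data and is
explicitly out of scope.

## The synthetic-data generator

The generator exists so every stage has ground truth. It emulates the
*structure* of the experiment, not its physics:

* proteomes of 20 uniform-random sequences of 80–200 residues (each
  guaranteed a cleavage site, an Asn and a Ser/Thr so both linkages are
  plantable);
* true spectra: precursor at the exact glycopeptide m/z (charge 2), the
  full b/y series (intensities 0.1–0.5), all three oxonium classes
  (0.2–0.8), base peak 1.0 — documented constants, not tuned;
* decoys, constructed rather than sampled so labels are unambiguous:
  either the precursor is shifted well outside tolerance (and away from
  every other candidate), or the sialic acid oxonium class is withheld
  and the backbone kept below the high-confidence threshold — a
  full-backbone spectrum without oxonium ions would be *correctly* kept
  by the high-confidence rule, so it cannot serve as a decoy;
* contaminants: true-looking spectra confined to control runs;
* noise: uniform peaks ≤ 5% of base intensity and precursor jitter
  bounded below the matching tolerance;
* planting only candidates whose mass is isolated from all other
  accessions by 3× the precursor tolerance, which keeps protein-level
  ground truth unambiguous.

What it does **not** emulate: chromatography, isotope envelopes,
co-isolation chimeras, intensity realism, shared peptides between
proteins, or site localization. Passing the end-to-end tests therefore
demonstrates that the curation logic is correct, not that the matcher
would perform at any particular level on real LC-MS/MS data.

Each generator call consumes one seeded pseudo-random stream, and the seed
is stamped into every output header, so fixtures are bit-reproducible.

## Problem sizes and numerical choices

Test and acceptance runs use 20-protein proteomes, 8–10 planted spectra,
4 decoys and 2 contaminants per run, repeated over 10 seeds — sizes chosen
so the whole suite exercises every code path in about a minute while
keeping candidate indexes in the hundreds, large enough for the
binary-search matcher to be checked against a linear-scan oracle.
Mass comparisons in tests use an independent oracle built from elemental
compositions and atomic masses, agreeing with the implementation's residue
tables to 1e-6 Da. Precursor window edges are widened by 1e-9 Da before
the exact |ppm| ≤ tol filter so boundary candidates are never lost to
floating-point bracketing.

## Known limitations

Protein inference across shared peptides is not performed (the match's
accession is taken as given); quantification, FDR control, site
localization, multiply charged fragments, and semi-specific digestion are
all out of scope. The sLe-compatibility and N-class rules are
composition-level heuristics. The Target Score is a parameterization of a
qualitatively described algorithm, not a reimplementation of any specific
published scoring table.
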