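---
title: "Profiling peptidase substrate specificity from P4-P4' cleavage windows"
author: "SubsiteProfiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling peptidase substrate specificity from P4-P4' cleavage windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SubsiteProfiler)
```

## The data and the model

A peptidase hydrolyses the peptide bond between two residues of its
substrate. In the Schechter–Berger nomenclature the four substrate
residues N-terminal of the scissile bond occupy the enzyme's S4–S1
pockets (substrate sites P4–P1) and the four C-terminal residues occupy
S1'–S4' (sites P1'–P4'). Curated cleavage collections such as MEROPS
record, for each literature-reported cleavage, the peptidase (as a
MEROPS identifier), the substrate, the position of the P1 residue in the
substrate's own numbering, and the eight residues P4–P4'. Positions
beyond a terminus of the substrate are recorded as `-`; nonstandard
amino acids and synthetic N-/C-terminal blocking groups are reduced to
`X`, giving a closed 22-symbol alphabet.

All statistics in this package are computed on the **nonredundant** set
of cleavages of one peptidase: windows are normalised (every token
outside the 20 standard residues and `-` becomes `X`) and then distinct
8-symbol windows are selected. Normalisation precedes deduplication, so
two records differing only in which blocking group they carry count
once. Distinctness deliberately ignores the substrate identity: the same
window cut in two different proteins is one observation of the enzyme's
preference, not two.

From the nonredundant set the package derives:

* a **frequency matrix** — counts and percentages of each of the 22
  symbols at each of the 8 sites (site columns sum to 100%, with the `-`
  and `X` rows included, matching the layout of the published global
  occupancy table shipped as `meropsGlobalSitePercentages`);
* **restricted sites** — a site occupied by only one or two residues,
  or only by residues of one of six types (acidic DE, basic RKH,
  aliphatic ILV, aromatic FYW, small AGS, other NCQMPT);
* **exclusions** — residues or whole types never observed at a site;
* **dominance** — one residue (or one type) occupying a site in more
  than 90% of cleavages;
* an **activity kind** — exopeptidase categories inferred from subsites
  that never exist (are always `-`);
* **co-operative pairs** — ordered residue pairs at adjacent sites that
  co-occur at least 10 times while neither residue is site-dominant.

## Evidence thresholds and their rationale

The defaults reproduce the standard analysis of the MEROPS cleavage
collection and are deliberate, not tuning parameters:

| parameter | default | unit | why |
|---|---|---|---|
| `minNPreference` | 20 | nonredundant cleavages | below this, a site "occupied by only two residues" is expected by chance |
| `minNExclusion` | 30 | nonredundant cleavages | rare residues (Trp ~0.8% of sites) would otherwise look excluded by sampling alone |
| `dominance` | 0.90 (strict `>`) | fraction | tolerates occasional curation errors in literature data without hiding a near-absolute preference |
| `minPair` | 10 | co-occurrences | raw-count rule for co-operative binding |
| `high` / `low` | 10 / 1 | percent | display highlighting of frequent/infrequent occupants |

Two inequality conventions deserve a note. The highlight rule for
frequent occupants is *inclusive* (`>= 10%`), the convention of the
published table legend, although prose descriptions sometimes say
"more than 10%"; a cell at exactly 10.0% is therefore labelled high.
Dominance is *strict* (`> 90%`): a residue at exactly 0.90 is not
dominant.

## Denominators

Percentages in the frequency matrix use all nonredundant windows as the
denominator, `-` and `X` rows included — that is what makes the printed
site columns sum to 100. Restriction and dominance findings instead use
*occupied-site* denominators (windows where the site is not `-`), so
that an aminopeptidase, whose P4–P2 never exist, is not prevented from
showing a P1' preference. `X` counts as an occupant in both cases, and
a site where a nonstandard group is the modal occupant is reported as a
`nonstandard_preference` — synthetic chromogenic substrates genuinely
put their blocking group into a pocket.

Exclusion findings skip sites with no occupied windows at all: for a
carboxypeptidase it would be vacuous (and misleading) to report every
residue type as "excluded" from P2'–P4'.

Dominant types are reported only when no single residue is itself
dominant at the site; a 95% glycine site is a glycine finding, not also
a "small" finding. Restricted sites of one or two residues are reported
as the residue set, and additionally as the type when both residues
share one (Arg/Lys restriction is equivalently a "basic" restriction);
three or more residues of one type are reported as the type alone.

## Activity-kind inference

A subsite "does not exist" when its `-` fraction reaches
`absenceCutoff` (default 1.0, i.e. never occupied). The nonexistent-site
pattern is matched most-specific-first: P4–P2 and P2'–P4' absent is a
dipeptidase; P4–P2 alone an aminopeptidase; P2'–P4' alone a
carboxypeptidase; P4–P3 a dipeptidyl-peptidase; P3'–P4' a
peptidyl-dipeptidase; P4' alone is reported as
peptidyl-tripeptidase-like (an activity known chiefly as a
characterisation artefact of P4–P3' substrate panels); anything else is
an endopeptidase. With the strict default cutoff a single occupied P2
window demotes an aminopeptidase pattern to dipeptidyl-peptidase; lower
the cutoff (e.g. 0.9) to tolerate sparse mis-curated records.

## Co-operative binding

Plasticity of the active site means a bulky residue in one pocket can
constrain what fits the neighbouring pocket. The detector scans the
seven adjacent site pairs (P1→P1' crosses the scissile bond; P4' has no
partner because P5' is not recorded) for ordered standard-residue pairs
co-occurring in ≥ `minPair` windows. Because a residue that dominates a
site would trivially co-occur with everything, any pair whose residue
occupies its own site in ≥ 90% of the cleavages is suppressed — this
separates co-operativity from plain preference. The rule is raw-count
by design; the observed/expected ratio under site independence
(`n · f_a · f_b`) is attached as advisory metadata only, clearly an
extension rather than part of the detection rule.

## What the synthetic generator emulates — and what it does not

`generateCollection()` exists so that the whole pipeline closes the
loop on data whose ground truth is known. Its defaults are the study
conditions, not dials:

* unplanted sites sample from the published global occupancy profile
  (`meropsGlobalSitePercentages`), with terminal `-` runs drawn to
  match that profile's unoccupied-site marginals — `-` is always a
  contiguous run from the window's outer edge inward, as extraction
  from a real substrate implies; a `uniform` baseline (20 residues,
  no truncation) is available for calibration studies;
* planted restrictions and exclusions shape the sampling support of a
  site (uniform over the allowed set, so that at n = 200 every allowed
  residue is observed and a planted missing-set is detectable rather
  than masked by chance absences of rare residues);
* planted dominance and co-operative pair counts are realised as
  *exact* counts over the distinct windows, not as sampling
  probabilities. This is deliberate: a binomially realised count near a
  detection boundary (a 92% dominance target over 200 windows, a
  10-co-occurrence pair) would make recovery a coin flip, and the
  generator's contract is that planted features are recoverable;
* duplicates are injected at `duplicateFraction` by copying distinct
  records after nonstandard-token injection, so the nonredundant size
  is exactly the distinct count; cleavage classes are drawn at rates
  (25% physiological, 8% pathological, 60% nonphysiological, 7%
  synthetic) chosen to resemble the composition of the curated
  collection, where about a third of mappable cleavages are
  physiological or pathological and synthetic substrates are a few
  percent.

The generator does **not** simulate real substrate sequence
composition, proteomics identification error, or curation bias toward
well-studied enzymes. A passing recovery suite therefore shows the
*detectors* are correct and calibrated against their stated rules; it
does not show that literature collections satisfy those rules'
assumptions.

## Identifier grammar

MEROPS identifiers are parsed case-sensitively into six kinds: regular
protein-species (`S01.151`), nonpeptidase homologs (serial 900–999),
homologous-peptidase complexes (`XT01.001`), mixed-family complexes
(`XP01.001`), compound inhibitors (`LI01.001`) and unsequenced
peptidases (`M9E.004`, catalytic letter + `9` + activity letter).
Unpadded forms canonicalise (`S1.151` → `S01.151`). Two grammar corners
the sources leave open were resolved as follows: the 900-series homolog
rule applies only to family-form identifiers (a complex's serial never
reclassifies it), and within identifiers the family slot is letter +
digits only — subfamily letters (`S1A`) are hierarchy-node attributes,
accepted by `canonicalFamily()` but never part of a protein-species
identifier. `P` is a valid catalytic-type letter for family-form
identifiers (family P1 exists), while `XP` + digits is always the
mixed-complex form.

In the cleavage reader, a single-character window symbol outside the
22-symbol alphabet (say `Z`) is a data error, whereas multi-character
tokens (`Abz`, `pNA`, …) are accepted verbatim as blocking-group names
and normalised to `X` later — single letters have no blocking-group
reading, so an unknown one is far more likely a corrupted row than a
novel reagent.

## Numerical and degenerate-input choices

* Percentages are displayed to one decimal place; internal comparisons
  use full precision. Validity allows a 0.1-point rounding slack on the
  100% column sums.
* An empty window set is an error for `frequencyMatrix()` and
  `inferActivityKind()`, an empty result for the pair detector.
* Deduplication keeps the first occurrence's metadata; to make results
  independent of input order, records are pre-sorted by
  `(accession, p1_position)` unless `stable = TRUE` asks for input
  order. Collapsed records' cleavage classes are preserved in a
  `collapsed_classes` provenance column (the sources do not say whether
  the reference pipeline deduplicates across classes; this package
  does, and keeps the evidence).
* `extractWindow()` refuses `p1Position` equal to the sequence length:
  a scissile bond needs a residue on both sides.
* Ties in the pair table are broken by residue order after the
  (site, descending count) sort, so output is fully deterministic.

## Problem sizes used in the shipped tests

The test-suite simulations use collections of 25–500 windows per
peptidase, 20-seed recovery batches at 200 windows, and 50-seed oracle
comparisons — sizes at which every detection threshold is exercised on
both sides while the whole suite runs in well under a minute. The
published headline tables derive from a 98,378-cleavage release of the
full database; reproducing them requires the FTP download
(`Substrate_search`/`cleavage` comma-delimited exports), which
`readCleavageTable()` ingests via a schema configuration
(`cleavageSchema()`) mapping that dialect's columns onto the record
fields.

## Known limitations

* The reference website's green-shaded preference matrix has no
  published thresholds; only the 10%/1% highlight rules are
  implemented.
* Whether the reference restriction analysis ignores windows containing
  `X` entirely is not documented; here `X` is an occupant, which is the
  conservative choice (it can only widen an occupant set, never
  manufacture a restriction).
* Co-operative pair detection is raw-count, as specified; it inherits
  that rule's blindness to marginal frequency (a pair can pass with an
  observed/expected ratio near 1). Use the advisory ratio column when
  interpreting.
* Family/clan assembly (homology search, structure comparison) is out
  of scope; the hierarchy loader ingests an already-built child/parent
  table.

## A worked run

```{r worked}
specs <- list(
  peptidaseSpec("S01.151", 80,
    plantedRestrictions = list(list(site = "P1", residues = c("R", "K")))),
  peptidaseSpec("M01.001", 60, activityKind = "aminopeptidase"))
cs <- generateCollection(specs, seed = 11)
cs

nr <- makeNonredundant(cs)
rep <- specificityReport(splitByPeptidase(nr)[["S01.151"]])
rep

inferActivityKind(splitByPeptidase(nr)[["M01.001"]])
```
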