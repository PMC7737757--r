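#' @title Alphabets, site labels and residue types
#' @description Constants shared by all modules: the Schechter--Berger site
#'   labels P4--P4', the 22-symbol window alphabet (20 standard residues plus
#'   \code{"-"} for an unoccupied site and \code{"X"} for a nonstandard
#'   residue or blocking group), and the six-way residue-type map used for
#'   type-level specificity findings.
#' @name subsite-constants
NULL

#' Schechter-Berger binding-site labels, N- to C-terminal
#'
#' Eight substrate positions flanking the scissile bond: P4..P1 on the
#' N-terminal side, P1'..P4' on the C-terminal side. Ordinals run 1..8 so
#' adjacent sites differ by 1; P1 and P1' are adjacent across the scissile
#' bond.
#' @export
siteLabels <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

#' The 20 standard amino acids, one-letter codes
#'
#' Ordered alphabetically by three-letter code (Ala, Arg, Asn, ...), the
#' order used in published MEROPS site-occupancy tables.
#' @export
standardResidues <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The closed 22-symbol window alphabet
#'
#' \code{"-"} marks a subsite with no residue (beyond a terminus of the
#' substrate); \code{"X"} marks a nonstandard amino acid or a synthetic
#' N-/C-terminal blocking group.
#' @export
windowAlphabet <- c("-", standardResidues, "X")

#' Six-way residue-type map
#'
#' Named character vector mapping each standard residue to one of
#' \code{acidic} (Asp, Glu), \code{basic} (Arg, Lys, His), \code{aliphatic}
#' (Ile, Leu, Val), \code{aromatic} (Phe, Tyr, Trp), \code{small}
#' (Ala, Gly, Ser) or \code{other} (Asn, Cys, Gln, Met, Pro, Thr).
#' \code{"-"} and \code{"X"} have no type.
#' @export
residueTypes <- c(
  D = "acidic", E = "acidic",
  R = "basic", K = "basic", H = "basic",
  I = "aliphatic", L = "aliphatic", V = "aliphatic",
  F = "aromatic", Y = "aromatic", W = "aromatic",
  A = "small", G = "small", S = "small",
  N = "other", C = "other", Q = "other", M = "other", P = "other",
  T = "other"
)[standardResidues]

#' Activity kinds inferable from subsite occupancy
#' @export
activityKinds <- c("endopeptidase", "aminopeptidase", "carboxypeptidase",
                   "dipeptidase", "dipeptidyl_peptidase",
                   "peptidyl_dipeptidase", "peptidyl_tripeptidase_like")

#' Cleavage classes recorded for curated cleavages
#' @export
cleavageClasses <- c("physiological", "pathological", "nonphysiological",
                     "synthetic")

#' Global site-occupancy percentages across the MEROPS nonredundant
#' cleavage collection
#'
#' Percentages of each window symbol at sites P4-P4' over all peptidases'
#' nonredundant cleavages, as published for MEROPS release 12.2 (98,378
#' curated cleavages). Rows are the 22 window symbols (\code{"-"} first,
#' then the standard residues in three-letter alphabetical order, then
#' \code{"X"}); columns are the sites P4..P4'. Used as the default baseline
#' distribution of the synthetic generator and as a reference input for
#' \code{\link{renderMatrix}} highlighting.
#'
#' @format numeric matrix, 22 rows x 8 columns, percent units.
#' @export
meropsGlobalSitePercentages <- local({
  vals <- c(
    #      P4    P3    P2    P1   P1'   P2'   P3'   P4'
    "-", 10.5,  8.2,  6.5,  0.0,  0.0,  4.3,  5.3,  6.2,
    "A",  7.6,  9.0,  8.5,  7.0, 11.1,  8.9,  7.9,  7.3,
    "R",  4.6,  4.0,  3.7, 17.0,  3.1,  4.1,  3.3,  3.0,
    "N",  2.9,  2.8,  2.8,  4.0,  2.9,  3.0,  3.5,  3.5,
    "D",  4.9,  3.8,  2.7,  8.5,  4.4,  4.6,  5.6,  7.1,
    "C",  1.2,  1.3,  1.2,  0.9,  1.1,  1.0,  1.3,  1.1,
    "E",  6.5,  6.9,  6.0,  8.2,  4.9,  6.7,  7.6,  8.7,
    "Q",  3.9,  4.1,  4.1,  2.8,  3.1,  4.4,  4.5,  4.5,
    "G",  6.7,  6.5,  6.3,  5.8,  7.8,  6.9,  8.3,  7.6,
    "H",  1.9,  1.8,  1.6,  1.2,  1.8,  2.0,  2.0,  1.9,
    "I",  4.4,  4.7,  4.6,  0.7,  5.7,  5.2,  4.4,  4.2,
    "L",  7.8,  8.4, 11.7,  5.6, 11.0,  8.9,  7.9,  6.9,
    "K",  5.2,  5.1,  5.0, 15.7,  6.8,  5.2,  5.1,  5.0,
    "M",  1.9,  2.0,  2.0,  6.0,  2.4,  1.8,  1.7,  1.5,
    "F",  3.1,  3.5,  4.3,  3.8,  4.5,  3.4,  3.2,  2.9,
    "P",  5.8,  5.6,  5.6,  2.0,  1.5,  5.2,  6.2,  7.3,
    "S",  6.0,  6.0,  5.9,  3.6,  9.3,  6.8,  6.8,  6.5,
    "T",  4.4,  4.7,  4.4,  2.6,  4.7,  5.6,  5.2,  5.3,
    "W",  0.8,  0.7,  0.9,  0.7,  0.7,  0.8,  0.8,  0.8,
    "Y",  2.3,  2.2,  2.7,  2.5,  2.8,  2.7,  2.4,  2.1,
    "V",  6.5,  7.6,  8.6,  1.4,  7.2,  8.0,  6.6,  6.1,
    "X",  1.0,  0.9,  0.9,  0.2,  3.0,  0.3,  0.3,  0.4)
  m <- matrix(as.numeric(vals[-seq(1, length(vals), by = 9)]),
              ncol = 8, byrow = TRUE)
  dimnames(m) <- list(vals[seq(1, length(vals), by = 9)], siteLabels)
  m
})

#' Headline counts of the MEROPS release 12.2 holotype collection
#'
#' Identifier and holotype counts for proteolytic enzymes: total MEROPS
#' identifiers, identifiers assigned to uncharacterised nonpeptidase-homolog
#' holotypes from model organisms, peptidases with at least one curated
#' cleavage, total curated cleavages, and family/clan counts.
#' @export
meropsReleaseCounts <- list(
  identifiers = 4684L,
  homolog_holotypes = 1424L,
  peptidases_with_cleavages = 1342L,
  cleavages = 98378L,
  families = 276L,
  clans = 47L
)

#' Coverage of active holotypes by the cleavage collection
#'
#' Computes the number of holotypes known to be active as peptidases
#' (all identifiers minus uncharacterised-homolog holotypes) and the
#' percentage of holotypes with at least one known substrate cleavage,
#' relative both to all holotypes and to active holotypes only.
#'
#' @param identifiers total number of MEROPS identifiers for proteolytic
#'   enzymes.
#' @param homologHolotypes identifiers assigned to uncharacterised
#'   peptidase homologs.
#' @param withCleavages peptidases for which cleavage sites are known.
#' @return list with \code{active_holotypes},
#'   \code{pct_all_with_cleavages} and \code{pct_active_with_cleavages}
#'   (percentages to one decimal place).
#' @examples
#' holotypeCoverage()
#' @export
holotypeCoverage <- function(identifiers = meropsReleaseCounts$identifiers,
                             homologHolotypes =
                               meropsReleaseCounts$homolog_holotypes,
                             withCleavages =
                               meropsReleaseCounts$peptidases_with_cleavages) {
  stopifnot(identifiers >= homologHolotypes, withCleavages >= 0)
  active <- identifiers - homologHolotypes
  list(
    active_holotypes = active,
    pct_all_with_cleavages = round(100 * withCleavages / identifiers, 1),
    pct_active_with_cleavages = round(100 * withCleavages / active, 1)
  )
}
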