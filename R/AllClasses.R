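#' @import methods
#' @importFrom S4Vectors DataFrame mcols
#' @importClassesFrom S4Vectors DFrame
NULL

#' MeropsId: parsed MEROPS identifiers
#'
#' Vectorised S4 container for parsed MEROPS identifiers. Each element
#' carries the raw text, the identifier kind, and whichever of catalytic
#' type, family code, serial number and activity code the grammar defines
#' for that kind (absent fields are \code{NA}).
#'
#' Kinds: \code{protein_species} (regular family-form id, e.g.
#' \code{S01.151}), \code{nonpeptidase_homolog} (family-form id with serial
#' 900-999), \code{complex_homologous} (\code{X} + family, e.g.
#' \code{XT01.001}), \code{complex_mixed} (\code{XP} + number, mixed-family
#' complexes), \code{compound_inhibitor} (\code{L} + inhibitor family, e.g.
#' \code{LI01.001}), and \code{unsequenced} (catalytic letter + \code{9} +
#' activity letter, e.g. \code{M9E.004}).
#'
#' @slot raw character, the input text (whitespace-stripped).
#' @slot kind character, one of the six kinds above.
#' @slot catalyticType character, one of A,C,G,M,N,P,S,T,U,I or NA.
#' @slot family character, canonical family code (e.g. "S01") or NA.
#' @slot serial integer serial number or NA.
#' @slot activityCode character, one of A,B,C,D,E,G (unsequenced ids) or NA.
#' @seealso \code{\link{parseMeropsId}}, \code{\link{formatMeropsId}}
#' @export
setClass("MeropsId",
  slots = c(raw = "character", kind = "character",
            catalyticType = "character", family = "character",
            serial = "integer", activityCode = "character"))

setValidity("MeropsId", function(object) {
  n <- length(object@raw)
  lens <- c(length(object@kind), length(object@catalyticType),
            length(object@family), length(object@serial),
            length(object@activityCode))
  if (any(lens != n))
    return("all slots must have equal length")
  badKind <- setdiff(unique(object@kind),
                     c("protein_species", "nonpeptidase_homolog",
                       "complex_homologous", "complex_mixed",
                       "compound_inhibitor", "unsequenced"))
  if (length(badKind))
    return(paste("unknown kind:", paste(badKind, collapse = ", ")))
  if (any(!is.na(object@serial) & object@serial < 1L))
    return("serial numbers must be positive")
  hom <- object@kind == "nonpeptidase_homolog"
  if (any(hom & (is.na(object@serial) | object@serial < 900L |
                   object@serial > 999L)))
    return("nonpeptidase_homolog requires serial in 900-999")
  TRUE
})

#' CleavageSet: a collection of curated cleavage records
#'
#' Holds one row per cleavage: the 8-symbol P4-P4' substrate window plus
#' record metadata (peptidase identifier, substrate name, accession, P1
#' position, cleavage class). Window symbols are single characters from the
#' closed 22-symbol alphabet, except that multi-character tokens (names of
#' nonstandard residues or synthetic blocking groups, e.g. \code{"Abz"})
#' are tolerated until \code{\link{normalizeWindows}} replaces them with
#' \code{"X"}.
#'
#' @slot windows character matrix, one row per record, 8 columns named
#'   P4..P4'.
#' @slot meta \code{DataFrame} with columns \code{peptidase},
#'   \code{substrate_name}, \code{accession}, \code{p1_position},
#'   \code{cleavage_class} (plus optional provenance columns such as
#'   \code{collapsed_classes} after deduplication, or \code{sequence}
#'   after \code{\link{generateSubstrateContext}}).
#' @seealso \code{\link{CleavageSet}}, \code{\link{readCleavageTable}},
#'   \code{\link{makeNonredundant}}
#' @export
setClass("CleavageSet", slots = c(windows = "matrix", meta = "DFrame"))

setValidity("CleavageSet", function(object) {
  w <- object@windows
  if (!is.character(w) || ncol(w) != 8L)
    return("windows must be a character matrix with 8 columns")
  if (!identical(colnames(w), siteLabels))
    return("window columns must be named P4,P3,P2,P1,P1',P2',P3',P4'")
  if (nrow(object@meta) != nrow(w))
    return("meta and windows must have the same number of rows")
  need <- c("peptidase", "substrate_name", "accession", "p1_position",
            "cleavage_class")
  missing <- setdiff(need, colnames(object@meta))
  if (length(missing))
    return(paste("meta lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(w)) {
    if (any(w[, "P1"] == "-") || any(w[, "P1'"] == "-"))
      return("P1 and P1' must be occupied (no '-' allowed)")
    single <- w[nchar(w) == 1L]
    bad <- setdiff(unique(single), windowAlphabet)
    if (length(bad))
      return(paste0("single-letter window symbols outside alphabet: ",
                    paste(bad, collapse = ", ")))
    badClass <- setdiff(unique(object@meta$cleavage_class), cleavageClasses)
    if (length(badClass))
      return(paste("unknown cleavage_class:",
                   paste(badClass, collapse = ", ")))
  }
  TRUE
})

#' FrequencyMatrix: per-site symbol counts and percentages
#'
#' 22 symbols x 8 sites tally of a nonredundant window set, with the
#' matching percentage table (percent units; each site column sums to 100)
#' and the number of cleavages used as denominator.
#'
#' @slot counts integer matrix, 22 x 8.
#' @slot percentages numeric matrix, 22 x 8, percent units.
#' @slot nCleavages integer, the denominator.
#' @seealso \code{\link{frequencyMatrix}}, \code{\link{renderMatrix}}
#' @export
setClass("FrequencyMatrix",
  slots = c(counts = "matrix", percentages = "matrix",
            nCleavages = "integer"))

setValidity("FrequencyMatrix", function(object) {
  cn <- object@counts
  pc <- object@percentages
  if (!identical(dim(cn), c(22L, 8L)) || !identical(dim(pc), c(22L, 8L)))
    return("counts and percentages must be 22 x 8")
  if (!identical(rownames(cn), windowAlphabet) ||
      !identical(colnames(cn), siteLabels))
    return("rows must be the 22-symbol alphabet, columns the 8 sites")
  if (any(colSums(cn) != object@nCleavages))
    return("each site's counts must sum to nCleavages")
  if (object@nCleavages > 0L) {
    if (any(abs(colSums(pc) - 100) > 0.1))
      return("percentage columns must sum to 100 (+/- 0.1)")
    if (cn["-", "P1"] != 0L || cn["-", "P1'"] != 0L)
      return("'-' cannot occur at P1 or P1'")
  }
  TRUE
})

#' SpecificityReport: per-peptidase specificity findings
#'
#' Bundles, for one peptidase's nonredundant cleavage set, the inferred
#' activity kind and the per-site findings: restricted residues or types,
#' excluded residues or types, dominant residues or types, and nonstandard
#' (blocking-group) preferences.
#'
#' @slot peptidase character, canonical identifier text.
#' @slot nNonredundant integer, size of the nonredundant set.
#' @slot activityKind character, one of \code{\link{activityKinds}}, or NA
#'   when below the evidence threshold.
#' @slot findings \code{DataFrame} with columns \code{site},
#'   \code{finding} (restricted_residues, restricted_type,
#'   excluded_residues, excluded_type, dominant_residue, dominant_type,
#'   nonstandard_preference), \code{residues} (comma-joined one-letter
#'   codes or a type name), \code{fraction} (supporting fraction).
#' @seealso \code{\link{specificityReport}}
#' @export
setClass("SpecificityReport",
  slots = c(peptidase = "character", nNonredundant = "integer",
            activityKind = "character", findings = "DFrame"))

setValidity("SpecificityReport", function(object) {
  if (length(object@peptidase) != 1L)
    return("exactly one peptidase per report")
  if (!is.na(object@activityKind) &&
      !object@activityKind %in% activityKinds)
    return("unknown activity kind")
  need <- c("site", "finding", "residues", "fraction")
  if (!all(need %in% colnames(object@findings)))
    return("findings needs columns site, finding, residues, fraction")
  TRUE
})
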