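## Per-site specificity statistics over a peptidase's nonredundant
## cleavage set: frequency matrices, restricted / excluded / dominant
## binding sites, and exopeptidase activity-kind inference from subsite
## occupancy.

.asWindows <- function(x) {
  w <- if (is(x, "CleavageSet")) x@windows else x
  if (is.null(dim(w))) w <- matrix(w, nrow = 1L)
  if (ncol(w) != 8L) stop("windows must have 8 site columns")
  bad <- setdiff(unique(as.vector(w)), windowAlphabet)
  if (length(bad))
    stop("windows not normalised; symbols outside alphabet: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (run normalizeWindows() first)")
  colnames(w) <- siteLabels
  w
}

.emptyFindings <- function() {
  DataFrame(site = character(0), finding = character(0),
            residues = character(0), fraction = numeric(0))
}

.finding <- function(site, finding, residues, fraction) {
  DataFrame(site = site, finding = finding,
            residues = paste(residues, collapse = ","),
            fraction = fraction)
}

#' Tally a nonredundant window set into a frequency matrix
#'
#' Counts each of the 22 window symbols at each of the 8 sites and
#' expresses the counts as percentages of the number of cleavages, the
#' layout of published MEROPS site-occupancy tables (unoccupied \code{"-"}
#' and nonstandard \code{"X"} rows included, so each site column sums to
#' 100).
#'
#' @param x a \code{CleavageSet} or normalised window matrix (nonempty).
#' @return a \code{\linkS4class{FrequencyMatrix}}.
#' @examples
#' fm <- frequencyMatrix(rbind(c("-","-","-","E","A","-","-","-")))
#' percentages(fm)["E", "P1"]
#' @export
frequencyMatrix <- function(x) {
  w <- .asWindows(x)
  n <- nrow(w)
  if (!n) stop("cannot tally an empty window set")
  counts <- vapply(seq_len(8L), function(j)
    table(factor(w[, j], levels = windowAlphabet)),
    integer(length(windowAlphabet)))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(windowAlphabet, siteLabels)
  new("FrequencyMatrix", counts = counts,
      percentages = counts / n * 100, nCleavages = n)
}

#' @describeIn frequencyMatrix symbol-by-site counts.
#' @param object a \code{FrequencyMatrix}.
#' @param ... ignored.
#' @export
setMethod("counts", "FrequencyMatrix", function(object, ...) object@counts)

#' @describeIn frequencyMatrix symbol-by-site percentages.
#' @export
setMethod("percentages", "FrequencyMatrix", function(x) x@percentages)

#' @describeIn frequencyMatrix denominator (number of cleavages).
#' @export
setMethod("nCleavages", "FrequencyMatrix", function(x) x@nCleavages)

setMethod("show", "FrequencyMatrix", function(object) {
  cat("FrequencyMatrix over", object@nCleavages, "nonredundant cleavages\n")
  print(round(object@percentages, 1))
})

#' Write a frequency matrix as TSV
#'
#' One row per symbol (22), a leading \code{symbol} column and the eight
#' site columns; percentages to one decimal place.
#'
#' @param fm a \code{FrequencyMatrix}.
#' @param file path or connection.
#' @return invisibly, the path.
#' @export
writeFrequencyMatrix <- function(fm, file) {
  stopifnot(is(fm, "FrequencyMatrix"))
  df <- data.frame(symbol = rownames(fm@percentages),
                   round(fm@percentages, 1), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

.siteOccupancy <- function(w, j) {
  sym <- w[, j]
  sym[sym != "-"]
}

#' Detect restricted binding sites
#'
#' A site is restricted when, across a peptidase's nonredundant cleavages,
#' it is occupied by only one or two amino acids
#' (\code{restricted_residues}) or only by amino acids of a single type
#' (\code{restricted_type}). Unoccupied positions (\code{"-"}) are
#' ignored; \code{"X"} counts as an occupant, and when a nonstandard
#' group is the sole or most frequent occupant the site is reported as
#' \code{nonstandard_preference}. Requires at least \code{minN}
#' nonredundant cleavages (default 20); below that no findings are made.
#'
#' @param x a \code{CleavageSet} or normalised window matrix (one
#'   peptidase's nonredundant set).
#' @param minN minimum nonredundant cleavages (default 20).
#' @return \code{DataFrame} of findings (site, finding, residues,
#'   fraction).
#' @export
detectRestrictedSites <- function(x, minN = 20L) {
  w <- .asWindows(x)
  out <- .emptyFindings()
  if (nrow(w) < minN) return(out)
  for (j in seq_len(8L)) {
    occ <- .siteOccupancy(w, j)
    if (!length(occ)) next
    tab <- sort(table(occ), decreasing = TRUE)
    present <- names(tab)
    if ("X" %in% present && tab[["X"]] == max(tab))
      out <- rbind(out, .finding(siteLabels[j], "nonstandard_preference",
                                 "X", tab[["X"]] / length(occ)))
    if (length(present) <= 2L)
      out <- rbind(out, .finding(siteLabels[j], "restricted_residues",
                                 sort(present), 1.0))
    std <- setdiff(present, "X")
    if (length(std) && !"X" %in% present) {
      types <- unique(residueTypes[std])
      if (length(types) == 1L && length(std) >= 2L)
        out <- rbind(out, .finding(siteLabels[j], "restricted_type",
                                   types, 1.0))
    }
  }
  out
}

#' Detect excluded residues and residue types
#'
#' A residue (or type) is excluded from a site when it never occurs there
#' across the nonredundant cleavages. To keep rarely occurring amino acids
#' (e.g. Trp) from producing artefacts, exclusion calls require at least
#' \code{minN = 30} cleavages. A missing set of one or two residues is
#' reported as \code{excluded_residues}; a residue type none of whose
#' members occurs is reported as \code{excluded_type}. Sites that are
#' never occupied at all (nonexistent subsites of exopeptidases) yield no
#' exclusion findings.
#'
#' @param x a \code{CleavageSet} or normalised window matrix.
#' @param minN minimum nonredundant cleavages (default 30); below it an
#'   empty result is returned with a notice.
#' @return \code{DataFrame} of findings.
#' @export
detectExclusions <- function(x, minN = 30L) {
  w <- .asWindows(x)
  out <- .emptyFindings()
  if (nrow(w) < minN) {
    message("detectExclusions: only ", nrow(w),
            " nonredundant cleavages (need ", minN, "); no calls made")
    return(out)
  }
  for (j in seq_len(8L)) {
    occ <- .siteOccupancy(w, j)
    if (!length(occ)) next
    absent <- setdiff(standardResidues, occ)
    if (length(absent) && length(absent) <= 2L)
      out <- rbind(out, .finding(siteLabels[j], "excluded_residues",
                                 sort(absent), 0.0))
    for (ty in unique(residueTypes)) {
      members <- names(residueTypes)[residueTypes == ty]
      if (all(members %in% absent))
        out <- rbind(out, .finding(siteLabels[j], "excluded_type", ty,
                                   0.0))
    }
  }
  out
}

#' Detect dominant residues and residue types
#'
#' A residue dominates a site when it occupies it in more than
#' \code{threshold} (default 0.90, strict inequality) of the cleavages
#' where the site is occupied; a type dominates when its members jointly
#' exceed the threshold and no single residue already does. Fractions use
#' occupied-site denominators (\code{"-"} excluded, \code{"X"} included)
#' so exopeptidase sites are not penalised.
#'
#' @param x a \code{CleavageSet} or normalised window matrix.
#' @param threshold dominance fraction, strict (default 0.90).
#' @param minN minimum nonredundant cleavages (default 20).
#' @return \code{DataFrame} of findings; \code{fraction} is the winning
#'   fraction.
#' @export
detectDominance <- function(x, threshold = 0.90, minN = 20L) {
  w <- .asWindows(x)
  out <- .emptyFindings()
  if (nrow(w) < minN) return(out)
  for (j in seq_len(8L)) {
    occ <- .siteOccupancy(w, j)
    if (!length(occ)) next
    frac <- table(factor(occ, levels = standardResidues)) / length(occ)
    top <- which.max(frac)
    if (frac[top] > threshold) {
      out <- rbind(out, .finding(siteLabels[j], "dominant_residue",
                                 standardResidues[top],
                                 as.numeric(frac[top])))
    } else {
      typeFrac <- tapply(as.numeric(frac), residueTypes, sum)
      topT <- which.max(typeFrac)
      if (typeFrac[topT] > threshold)
        out <- rbind(out, .finding(siteLabels[j], "dominant_type",
                                   names(typeFrac)[topT],
                                   as.numeric(typeFrac[topT])))
    }
  }
  out
}

#' Infer exopeptidase activity kind from subsite occupancy
#'
#' A subsite "does not exist" for a peptidase when it is unoccupied
#' (\code{"-"}) in at least \code{absenceCutoff} of the nonredundant
#' cleavages (default 1.0: always unoccupied). The pattern of nonexistent
#' subsites identifies the activity: P4-P2 absent for an aminopeptidase,
#' P2'-P4' absent for a carboxypeptidase, both for a dipeptidase, P4-P3
#' absent for a dipeptidyl-peptidase, P3'-P4' for a peptidyl-dipeptidase,
#' P4' alone for a peptidyl-tripeptidase-like activity; anything else is
#' an endopeptidase. P1 and P1' are always occupied.
#'
#' @param x a \code{CleavageSet} or normalised window matrix.
#' @param absenceCutoff fraction of cleavages with "-" required to call a
#'   subsite nonexistent (default 1.0).
#' @return character scalar, one of \code{\link{activityKinds}}.
#' @export
inferActivityKind <- function(x, absenceCutoff = 1.0) {
  w <- .asWindows(x)
  if (!nrow(w)) stop("cannot infer activity kind from an empty set")
  absent <- colMeans(w == "-") >= absenceCutoff
  nAbs <- absent[c("P4", "P3", "P2")]
  cAbs <- absent[c("P2'", "P3'", "P4'")]
  if (all(nAbs) && all(cAbs)) return("dipeptidase")
  if (all(nAbs)) return("aminopeptidase")
  if (all(cAbs)) return("carboxypeptidase")
  if (absent[["P4"]] && absent[["P3"]]) return("dipeptidyl_peptidase")
  if (absent[["P3'"]] && absent[["P4'"]]) return("peptidyl_dipeptidase")
  if (absent[["P4'"]]) return("peptidyl_tripeptidase_like")
  "endopeptidase"
}

#' Annotate a frequency matrix with high/low occupancy labels
#'
#' Labels each standard-residue cell of a percentage table: \code{high}
#' when the residue occupies the site in at least \code{high} percent of
#' cleavages (default 10), \code{low} when in less than \code{low}
#' percent (default 1), otherwise \code{plain}. The \code{"-"} and
#' \code{"X"} rows are never labelled. Returns both an aligned text table
#' (high cells wrapped in \code{[ ]}, low cells in \code{( )}) and the
#' machine-readable (site, residue, label) triples.
#'
#' @param x a \code{FrequencyMatrix} or a numeric percentage matrix with
#'   residues (one-letter codes) in rownames and the 8 sites in colnames.
#' @param high percent threshold for the high label, inclusive
#'   (default 10).
#' @param low percent threshold for the low label, exclusive (default 1).
#' @return list with \code{text} (character vector of aligned lines) and
#'   \code{labels} (\code{DataFrame}: site, residue, percent, label).
#' @examples
#' ann <- renderMatrix(meropsGlobalSitePercentages)
#' subset(as.data.frame(ann$labels), label == "high")
#' @export
renderMatrix <- function(x, high = 10, low = 1) {
  pc <- if (is(x, "FrequencyMatrix")) x@percentages else as.matrix(x)
  if (ncol(pc) != 8L) stop("percentage matrix must have 8 site columns")
  colnames(pc) <- siteLabels
  std <- intersect(rownames(pc), standardResidues)
  labels <- do.call(rbind, lapply(std, function(r) {
    p <- pc[r, ]
    DataFrame(site = siteLabels, residue = r, percent = as.numeric(p),
              label = ifelse(p >= high, "high",
                      ifelse(p < low, "low", "plain")))
  }))
  fmtCell <- function(r, j) {
    v <- formatC(pc[r, j], format = "fg", digits = 3)
    if (!r %in% standardResidues) return(v)
    if (pc[r, j] >= high) paste0("[", v, "]")
    else if (pc[r, j] < low) paste0("(", v, ")")
    else v
  }
  body <- t(vapply(rownames(pc),
                   function(r) vapply(seq_len(8L),
                                      function(j) fmtCell(r, j), ""),
                   character(8L)))
  tab <- cbind(symbol = rownames(pc), body)
  colnames(tab) <- c("symbol", siteLabels)
  widths <- apply(nchar(rbind(colnames(tab), tab)), 2L, max)
  lines <- apply(rbind(colnames(tab), tab), 1L, function(row)
    paste(mapply(formatC, row, width = widths), collapse = "  "))
  list(text = unname(lines), labels = labels)
}

#' Full specificity report for one peptidase
#'
#' Deduplicates the peptidase's cleavages (a no-op if already
#' nonredundant), then gathers restricted-site, exclusion and dominance
#' findings and the inferred activity kind, honouring the evidence
#' thresholds: preferences and dominance need at least
#' \code{minNPreference} (default 20) nonredundant cleavages, exclusions
#' at least \code{minNExclusion} (default 30).
#'
#' @param x a \code{CleavageSet} for a single peptidase.
#' @param minNPreference,minNExclusion evidence thresholds.
#' @param dominance dominance fraction, strict (default 0.90).
#' @param absenceCutoff passed to \code{\link{inferActivityKind}}.
#' @return a \code{\linkS4class{SpecificityReport}}.
#' @export
specificityReport <- function(x, minNPreference = 20L,
                              minNExclusion = 30L, dominance = 0.90,
                              absenceCutoff = 1.0) {
  stopifnot(is(x, "CleavageSet"))
  nr <- deduplicate(x)
  n <- length(nr)
  fnd <- rbind(detectRestrictedSites(nr, minN = minNPreference),
               if (n >= minNExclusion) detectExclusions(nr,
                 minN = minNExclusion) else .emptyFindings(),
               detectDominance(nr, threshold = dominance,
                               minN = minNPreference))
  kind <- if (n >= minNPreference)
    inferActivityKind(nr, absenceCutoff) else NA_character_
  new("SpecificityReport",
      peptidase = unique(nr@meta$peptidase),
      nNonredundant = n, activityKind = kind, findings = fnd)
}

#' @describeIn specificityReport peptidase identifier.
#' @export
setMethod("peptidase", "SpecificityReport", function(x) x@peptidase)

#' @describeIn specificityReport nonredundant cleavage count.
#' @export
setMethod("nCleavages", "SpecificityReport", function(x) x@nNonredundant)

#' @describeIn specificityReport the findings table.
#' @export
setMethod("findings", "SpecificityReport", function(x) x@findings)

#' @describeIn specificityReport inferred activity kind.
#' @export
setMethod("activityKind", "SpecificityReport", function(x) x@activityKind)

setMethod("show", "SpecificityReport", function(object) {
  cat("SpecificityReport for ", object@peptidase, " (",
      object@nNonredundant, " nonredundant cleavages, ",
      ifelse(is.na(object@activityKind), "activity kind undetermined",
             object@activityKind), ")\n", sep = "")
  if (nrow(object@findings)) {
    df <- as.data.frame(object@findings)
    df$fraction <- round(df$fraction, 3)
    print(df, row.names = FALSE)
  } else cat("  no per-site findings\n")
})

#' Plain-list form of a specificity report (for JSON export)
#' @param x a \code{SpecificityReport}.
#' @return nested list mirroring the report.
#' @export
reportAsList <- function(x) {
  stopifnot(is(x, "SpecificityReport"))
  list(peptidase = x@peptidase, n_nonredundant = x@nNonredundant,
       activity_kind = x@activityKind,
       findings = as.data.frame(x@findings))
}
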