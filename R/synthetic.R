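## Seeded synthetic cleavage collections with planted specificity
## structure: restrictions, exclusions, dominance, exopeptidase occupancy
## patterns, co-operative residue pairs, duplicate records and
## nonstandard tokens, so every analysis stage can be exercised without a
## database download.

nonstandardTokens <- c("Abz", "pNA", "Hyp", "Orn", "Nle", "Dnp", "Mca",
                       "AMC")

## sites forced to "-" for each exopeptidase activity kind
.absentSites <- function(kind) {
  switch(kind,
         aminopeptidase = c("P4", "P3", "P2"),
         carboxypeptidase = c("P2'", "P3'", "P4'"),
         dipeptidase = c("P4", "P3", "P2", "P2'", "P3'", "P4'"),
         dipeptidyl_peptidase = c("P4", "P3"),
         peptidyl_dipeptidase = c("P3'", "P4'"),
         peptidyl_tripeptidase_like = "P4'",
         character(0))
}

.typeMembers <- function(type) {
  m <- names(residueTypes)[residueTypes == type]
  if (!length(m)) stop("unknown residue type: ", sQuote(type))
  m
}

.featureResidues <- function(feature) {
  if (!is.null(feature$residues)) feature$residues
  else .typeMembers(feature$type)
}

#' Specification of one synthetic peptidase
#'
#' Describes the cleavage collection to simulate for one peptidase: its
#' size, duplicate and nonstandard-token rates, exopeptidase activity
#' kind, and the specificity features to plant. Planted features are
#' validated for mutual consistency (e.g. a planted exclusion may not
#' overlap a planted restriction's residues at the same site).
#'
#' @param identifier MEROPS identifier text (parsed and canonicalised).
#' @param nRecords number of records to generate (before deduplication).
#' @param duplicateFraction fraction of records that are exact duplicates
#'   of another record (default 0).
#' @param nonstandardFraction fraction of records carrying a
#'   nonstandard-residue or blocking-group token (default 0).
#' @param activityKind one of \code{\link{activityKinds}}; exopeptidase
#'   kinds force \code{"-"} at the corresponding nonexistent sites.
#' @param baseline \code{"global"} (default) samples unplanted sites from
#'   the published global site-occupancy profile
#'   (\code{\link{meropsGlobalSitePercentages}}), with terminal
#'   \code{"-"} runs matched to its unoccupied-site marginals;
#'   \code{"uniform"} samples uniformly over the 20 standard residues
#'   with no terminal truncation.
#' @param siteDistributions optional named list (site -> named probability
#'   vector over residues) overriding the baseline at chosen sites.
#' @param plantedRestrictions list of \code{list(site=, residues=)} or
#'   \code{list(site=, type=)}: the site is occupied only by those
#'   residues.
#' @param plantedExclusions list of \code{list(site=, residues=)} or
#'   \code{list(site=, type=)}: those residues never occur; the site is
#'   sampled uniformly over the remaining standard residues.
#' @param plantedDominance list of \code{list(site=, residue=, fraction=)}:
#'   the residue occupies the site in exactly
#'   \code{round(fraction * n_occupied)} of the distinct windows.
#' @param plantedPairs list of \code{list(site=, residue_n=,
#'   residue_n1=, count=)}: the ordered residue pair is planted at the
#'   adjacent site pair in exactly \code{count} distinct windows.
#' @return a validated \code{PeptidaseSpec} (list).
#' @export
peptidaseSpec <- function(identifier, nRecords,
                          duplicateFraction = 0,
                          nonstandardFraction = 0,
                          activityKind = "endopeptidase",
                          baseline = c("global", "uniform"),
                          siteDistributions = NULL,
                          plantedRestrictions = list(),
                          plantedExclusions = list(),
                          plantedDominance = list(),
                          plantedPairs = list()) {
  spec <- list(identifier = formatMeropsId(parseMeropsId(identifier)),
               nRecords = as.integer(nRecords),
               duplicateFraction = duplicateFraction,
               nonstandardFraction = nonstandardFraction,
               activityKind = match.arg(activityKind, activityKinds),
               baseline = match.arg(baseline),
               siteDistributions = siteDistributions,
               plantedRestrictions = plantedRestrictions,
               plantedExclusions = plantedExclusions,
               plantedDominance = plantedDominance,
               plantedPairs = plantedPairs)
  class(spec) <- "PeptidaseSpec"
  validatePeptidaseSpec(spec)
  spec
}

#' Validate a PeptidaseSpec, listing every conflict
#'
#' @param spec a \code{PeptidaseSpec}.
#' @return invisibly TRUE; errors with all detected conflicts otherwise.
#' @export
validatePeptidaseSpec <- function(spec) {
  err <- character(0)
  note <- function(...) err <<- c(err, paste0(...))
  if (spec$nRecords < 1L) note("nRecords must be positive")
  for (f in c("duplicateFraction", "nonstandardFraction"))
    if (spec[[f]] < 0 || spec[[f]] >= 1) note(f, " must be in [0, 1)")
  absent <- .absentSites(spec$activityKind)

  checkSite <- function(site, what) {
    if (!site %in% siteLabels)
      note(what, ": unknown site ", sQuote(site))
    else if (site %in% absent)
      note(what, ": site ", site, " does not exist for a ",
           spec$activityKind)
  }
  exclBySite <- list()
  for (f in spec$plantedExclusions) {
    checkSite(f$site, "planted exclusion")
    res <- .featureResidues(f)
    if (!all(res %in% standardResidues))
      note("planted exclusion at ", f$site, ": unknown residues")
    exclBySite[[f$site]] <- union(exclBySite[[f$site]], res)
    if (length(exclBySite[[f$site]]) >= 19L)
      note("planted exclusion at ", f$site, " leaves <2 residues")
  }
  restrBySite <- list()
  for (f in spec$plantedRestrictions) {
    checkSite(f$site, "planted restriction")
    res <- .featureResidues(f)
    restrBySite[[f$site]] <- union(restrBySite[[f$site]], res)
    overlap <- intersect(res, exclBySite[[f$site]])
    if (length(overlap))
      note("site ", f$site, ": residues ",
           paste(overlap, collapse = ","),
           " both restricted-to and excluded")
  }
  domBySite <- list()
  for (f in spec$plantedDominance) {
    checkSite(f$site, "planted dominance")
    if (f$fraction <= 0.5 || f$fraction > 1)
      note("planted dominance at ", f$site,
           ": fraction must be in (0.5, 1]")
    if (f$residue %in% exclBySite[[f$site]])
      note("site ", f$site, ": dominant residue ", f$residue,
           " is also excluded")
    if (!is.null(restrBySite[[f$site]]) &&
        !f$residue %in% restrBySite[[f$site]])
      note("site ", f$site, ": dominant residue ", f$residue,
           " outside the planted restriction set")
    if (!is.null(domBySite[[f$site]]))
      note("site ", f$site, ": more than one planted dominance")
    domBySite[[f$site]] <- f$residue
  }
  for (f in spec$plantedPairs) {
    checkSite(f$site, "planted pair")
    if (f$site == "P4'") note("planted pair: P4' has no next site")
    nxt <- siteLabels[match(f$site, siteLabels) + 1L]
    checkSite(nxt, "planted pair (next site)")
    if (f$count < 1L) note("planted pair count must be positive")
    for (sr in list(c(f$site, f$residue_n), c(nxt, f$residue_n1))) {
      if (!sr[2L] %in% standardResidues)
        note("planted pair: ", sQuote(sr[2L]), " not a standard residue")
      if (sr[2L] %in% exclBySite[[sr[1L]]])
        note("planted pair residue ", sr[2L], " is excluded at ",
             sr[1L])
      if (!is.null(restrBySite[[sr[1L]]]) &&
          !sr[2L] %in% restrBySite[[sr[1L]]])
        note("planted pair residue ", sr[2L],
             " outside the restriction set at ", sr[1L])
      if (!is.null(domBySite[[sr[1L]]]))
        note("planted pair overlaps planted dominance at ", sr[1L])
    }
  }
  nDistinct <- spec$nRecords -
    round(spec$nRecords * spec$duplicateFraction)
  support <- vapply(siteLabels, function(s) {
    if (s %in% absent) return(1)
    if (!is.null(restrBySite[[s]])) return(length(restrBySite[[s]]))
    20 - length(exclBySite[[s]])
  }, 0)
  if (prod(support) < 2 * nDistinct)
    note("window space too small for ", nDistinct, " distinct windows")
  if (length(err))
    stop("inconsistent PeptidaseSpec for ", spec$identifier, ":\n  ",
         paste(err, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

## run RNG under a fixed seed, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

## probability of a terminal "-" run of length >= 1, 2, 3, taken from the
## global profile's unoccupied-site marginals ("-" runs are contiguous
## from the windows' outermost sites inward)
.runTail <- function(side) {
  dashes <- meropsGlobalSitePercentages["-", ] / 100
  if (side == "N") unname(dashes[c("P4", "P3", "P2")])
  else unname(dashes[c("P4'", "P3'", "P2'")])
}

.sampleRunLengths <- function(n, side, baseline) {
  if (baseline == "uniform") return(integer(n))
  tail <- .runTail(side)               # P(len >= 1), >= 2, >= 3
  u <- stats::runif(n)
  (u < tail[1L]) + (u < tail[2L]) + (u < tail[3L])
}

## occupied-site sampling distribution for one site (probabilities over
## standard residues and X)
.siteDistribution <- function(spec, site, restrBySite, exclBySite) {
  if (!is.null(restrBySite[[site]])) {
    res <- restrBySite[[site]]
    return(stats::setNames(rep(1 / length(res), length(res)), res))
  }
  if (!is.null(exclBySite[[site]])) {
    res <- setdiff(standardResidues, exclBySite[[site]])
    return(stats::setNames(rep(1 / length(res), length(res)), res))
  }
  if (!is.null(spec$siteDistributions[[site]])) {
    p <- spec$siteDistributions[[site]]
    p <- p[setdiff(names(p), "-")]
    return(p / sum(p))
  }
  if (spec$baseline == "uniform")
    return(stats::setNames(rep(0.05, 20L), standardResidues))
  p <- meropsGlobalSitePercentages[c(standardResidues, "X"), site]
  p / sum(p)
}

.generateOne <- function(spec) {
  n <- spec$nRecords
  nDup <- round(n * spec$duplicateFraction)
  nDist <- n - nDup
  absent <- .absentSites(spec$activityKind)
  restrBySite <- exclBySite <- list()
  for (f in spec$plantedRestrictions)
    restrBySite[[f$site]] <- union(restrBySite[[f$site]],
                                   .featureResidues(f))
  for (f in spec$plantedExclusions)
    exclBySite[[f$site]] <- union(exclBySite[[f$site]],
                                  .featureResidues(f))
  domSites <- vapply(spec$plantedDominance, `[[`, "", "site")
  plantedSites <- unique(c(names(restrBySite), names(exclBySite),
                           domSites))

  ## terminal truncation runs (structural for exopeptidases)
  structN <- sum(c("P4", "P3", "P2") %in% absent)
  structC <- sum(c("P2'", "P3'", "P4'") %in% absent)
  runN <- pmax(structN, .sampleRunLengths(nDist, "N", spec$baseline))
  runC <- pmax(structC, .sampleRunLengths(nDist, "C", spec$baseline))
  if (structN) runN <- rep(structN, nDist)   # nonexistent, not truncated
  if (structC) runC <- rep(structC, nDist)
  occupied <- matrix(TRUE, nDist, 8L, dimnames = list(NULL, siteLabels))
  for (l in 1:3) {
    occupied[runN >= l, l] <- FALSE          # P4 inward
    occupied[runC >= l, 9L - l] <- FALSE     # P4' inward
  }

  w <- matrix("-", nDist, 8L, dimnames = list(NULL, siteLabels))
  for (s in siteLabels) {
    rows <- which(occupied[, s])
    if (!length(rows)) next
    p <- .siteDistribution(spec, s, restrBySite, exclBySite)
    w[rows, s] <- sample(names(p), length(rows), replace = TRUE,
                         prob = p)
  }
  ## dominance: exact counts among occupied rows
  for (f in spec$plantedDominance) {
    rows <- which(occupied[, f$site])
    m <- round(f$fraction * length(rows))
    domRows <- sample(rows, m)
    w[domRows, f$site] <- f$residue
    others <- setdiff(rows, domRows)
    pool <- setdiff(standardResidues, f$residue)
    if (length(others))
      w[others, f$site] <- sample(pool, length(others), replace = TRUE)
  }
  ## co-operative pairs: exact counts on designated rows
  pairRows <- integer(0)
  pairLock <- matrix(FALSE, nDist, 8L)
  for (f in spec$plantedPairs) {
    k <- match(f$site, siteLabels)
    elig <- which(occupied[, k] & occupied[, k + 1L] &
                    !seq_len(nDist) %in% pairRows)
    if (length(elig) < f$count)
      stop("not enough rows to plant pair at ", f$site, " for ",
           spec$identifier)
    rows <- sample(elig, f$count)
    w[rows, k] <- f$residue_n
    w[rows, k + 1L] <- f$residue_n1
    pairLock[rows, c(k, k + 1L)] <- TRUE
    pairRows <- c(pairRows, rows)
  }
  ## enforce distinct windows, resampling free sites of collisions
  freeSites <- setdiff(siteLabels, c(absent, domSites))
  for (iter in 1:100) {
    key <- apply(w, 1L, paste, collapse = "\r")
    dup <- which(duplicated(key))
    if (!length(dup)) break
    if (iter == 100L)
      stop("could not realise ", nDist, " distinct windows for ",
           spec$identifier)
    for (i in dup) {
      for (s in freeSites) {
        j <- match(s, siteLabels)
        if (!occupied[i, j] || pairLock[i, j]) next
        p <- .siteDistribution(spec, s, restrBySite, exclBySite)
        w[i, j] <- sample(names(p), 1L, prob = p)
      }
    }
  }
  ## nonstandard tokens at unplanted occupied sites of non-pair rows,
  ## injected before duplication so duplicates stay exact copies; an
  ## injection that would collapse two distinct windows is reverted
  nNon <- round(nDist * spec$nonstandardFraction)
  cand <- setdiff(seq_len(nDist), pairRows)
  if (nNon && length(cand)) {
    tokenRows <- sample(cand, min(nNon, length(cand)))
    for (i in tokenRows) {
      sites <- which(occupied[i, ] & !pairLock[i, ] &
                       !siteLabels %in% plantedSites)
      if (!length(sites)) next
      j <- if (length(sites) == 1L) sites else sample(sites, 1L)
      prev <- w[i, j]
      w[i, j] <- sample(nonstandardTokens, 1L)
      norm <- w
      norm[nchar(norm) > 1L] <- "X"
      if (anyDuplicated(apply(norm, 1L, paste, collapse = "\r")))
        w[i, j] <- prev
    }
  }
  ## duplicates
  dupOf <- if (nDup) sample(nDist, nDup, replace = TRUE) else integer(0)
  wAll <- rbind(w, w[dupOf, , drop = FALSE])
  ord <- sample(nrow(wAll))
  wAll <- wAll[ord, , drop = FALSE]
  cls <- sample(cleavageClasses, nrow(wAll), replace = TRUE,
                prob = c(0.25, 0.08, 0.60, 0.07))
  CleavageSet(wAll, peptidase = spec$identifier,
              substrate_name = sprintf("synthetic substrate %s-%04d",
                                       spec$identifier,
                                       seq_len(nrow(wAll))),
              accession = NA_character_, p1_position = NA_integer_,
              cleavage_class = cls)
}

#' Generate a seeded synthetic cleavage collection
#'
#' Simulates per-peptidase cleavage records realising every planted
#' feature of the given specs: restrictions and exclusions shape the
#' per-site sampling support, dominance fractions and co-operative pair
#' counts are planted as exact counts over the distinct windows,
#' exopeptidase activity kinds force \code{"-"} at nonexistent subsites,
#' and duplicates and nonstandard tokens are injected at the requested
#' rates. Output is reproducible: the same seed gives byte-identical
#' records.
#'
#' @param specs a \code{\link{peptidaseSpec}} or list of them.
#' @param seed integer seed.
#' @return a \code{CleavageSet} (records of all specs concatenated).
#' @examples
#' sp <- peptidaseSpec("S01.151", 50,
#'   plantedRestrictions = list(list(site = "P1", residues = c("R", "K"))))
#' cs <- generateCollection(sp, seed = 1)
#' @export
generateCollection <- function(specs, seed) {
  if (inherits(specs, "PeptidaseSpec")) specs <- list(specs)
  lapply(specs, validatePeptidaseSpec)
  .withSeed(seed, {
    sets <- lapply(specs, .generateOne)
    if (length(sets) == 1L) sets[[1L]] else do.call(c, sets)
  })
}

#' Embed windows in synthetic substrate sequences
#'
#' Gives every record a synthetic protein sequence and a P1 position such
#' that \code{\link{extractWindow}} on them reproduces the record's
#' (normalised) window: fully occupied windows are embedded inside random
#' flanking sequence, and windows with terminal \code{"-"} runs are
#' placed at the corresponding terminus of the sequence. Multi-character
#' nonstandard tokens are embedded as \code{"X"}. Windows with internal
#' gaps (a \code{"-"} between occupied sites) cannot arise from a real
#' substrate and are an error.
#'
#' @param x a \code{CleavageSet}.
#' @param seed integer seed for the random flanks.
#' @return the \code{CleavageSet} with \code{sequence} metadata and
#'   \code{p1_position} filled in.
#' @export
generateSubstrateContext <- function(x, seed) {
  stopifnot(is(x, "CleavageSet"))
  w <- normalizeWindows(x@windows)
  .withSeed(seed, {
    seqs <- character(nrow(w))
    p1s <- integer(nrow(w))
    for (i in seq_len(nrow(w))) {
      sym <- w[i, ]
      occ <- sym != "-"
      runN <- match(TRUE, occ) - 1L
      runC <- 8L - max(which(occ))
      core <- sym[occ]
      if (any(!occ[(runN + 1L):(8L - runC)]))
        stop("record ", i, ": window has an internal gap and cannot be ",
             "embedded in a substrate sequence")
      flankN <- if (runN == 0L)
        paste(sample(standardResidues, sample(0:6, 1L), replace = TRUE),
              collapse = "") else ""
      flankC <- if (runC == 0L)
        paste(sample(standardResidues, sample(0:6, 1L), replace = TRUE),
              collapse = "") else ""
      seqs[i] <- paste0(flankN, paste(core, collapse = ""), flankC)
      p1s[i] <- nchar(flankN) + (4L - runN)
    }
    out <- x
    out@meta$sequence <- seqs
    out@meta$p1_position <- p1s
    out
  })
}

#' Read peptidase specs from a YAML config
#'
#' One peptidase per block; keys mirror the \code{\link{peptidaseSpec}}
#' arguments (\code{identifier}, \code{nRecords},
#' \code{duplicateFraction}, \code{nonstandardFraction},
#' \code{activityKind}, \code{baseline}, \code{plantedRestrictions},
#' \code{plantedExclusions}, \code{plantedDominance},
#' \code{plantedPairs}).
#'
#' @param file path to a YAML file whose top level is a list of spec
#'   blocks.
#' @return list of validated \code{PeptidaseSpec}s.
#' @export
readPeptidaseSpecs <- function(file) {
  raw <- yaml::read_yaml(file)
  lapply(raw, function(block) do.call(peptidaseSpec, block))
}
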