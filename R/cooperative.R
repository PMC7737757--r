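#' Detect co-operative binding between adjacent subsites
#'
#' Scans the seven adjacent site pairs P4-P3 ... P3'-P4' (the P1-P1' pair
#' crosses the scissile bond; P4' has no partner, since the next residue
#' would be P5') for ordered pairs of standard residues that co-occur in
#' at least \code{minPair} of a peptidase's nonredundant cleavages. To
#' separate co-operativity from plain per-site preference, a pair is
#' suppressed when either residue on its own occupies its site in
#' \code{dominanceCutoff} (default 0.90) or more of the cleavages. Site
#' frequencies use the same nonredundant set as the pair counts.
#' \code{"-"} and \code{"X"} never form pairs.
#'
#' The observed/expected ratio (expected count \code{n * freq_a * freq_b}
#' under site independence) is emitted as advisory metadata; it is an
#' extension, not part of the detection rule, which is raw-count based.
#'
#' @param x a \code{CleavageSet} or normalised window matrix (one
#'   peptidase's nonredundant set; an empty set yields an empty result).
#' @param minPair minimum co-occurrence count (default 10).
#' @param dominanceCutoff per-residue site-frequency ceiling, exclusive
#'   (default 0.90).
#' @return \code{DataFrame} sorted by (site ordinal, decreasing pair
#'   count) with columns \code{site} (of residue n), \code{residue_n},
#'   \code{residue_n1}, \code{pair_count}, \code{n_cleavages},
#'   \code{freq_n}, \code{freq_n1}, \code{obs_exp_ratio}.
#' @examples
#' spec <- peptidaseSpec("C14.001", 60,
#'   plantedPairs = list(list(site = "P2", residue_n = "P",
#'                            residue_n1 = "D", count = 12)))
#' nr <- deduplicate(generateCollection(spec, seed = 1))
#' detectCooperativePairs(nr)
#' @export
detectCooperativePairs <- function(x, minPair = 10L,
                                   dominanceCutoff = 0.90) {
  w <- .asWindows(x)
  empty <- DataFrame(site = character(0), residue_n = character(0),
                     residue_n1 = character(0), pair_count = integer(0),
                     n_cleavages = integer(0), freq_n = numeric(0),
                     freq_n1 = numeric(0), obs_exp_ratio = numeric(0))
  n <- nrow(w)
  if (!n) return(empty)
  res <- empty
  for (k in seq_len(7L)) {
    a <- w[, k]
    b <- w[, k + 1L]
    keep <- a %in% standardResidues & b %in% standardResidues
    if (!any(keep)) next
    tab <- table(a[keep], b[keep])
    hits <- which(tab >= minPair, arr.ind = TRUE)
    if (!nrow(hits)) next
    freqA <- table(factor(a, levels = standardResidues)) / n
    freqB <- table(factor(b, levels = standardResidues)) / n
    for (h in seq_len(nrow(hits))) {
      ra <- rownames(tab)[hits[h, 1L]]
      rb <- colnames(tab)[hits[h, 2L]]
      fa <- as.numeric(freqA[ra])
      fb <- as.numeric(freqB[rb])
      if (fa >= dominanceCutoff || fb >= dominanceCutoff) next
      cnt <- as.integer(tab[hits[h, 1L], hits[h, 2L]])
      res <- rbind(res, DataFrame(
        site = siteLabels[k], residue_n = ra, residue_n1 = rb,
        pair_count = cnt, n_cleavages = n, freq_n = fa, freq_n1 = fb,
        obs_exp_ratio = cnt / (n * fa * fb)))
    }
  }
  ord <- order(match(res$site, siteLabels), -res$pair_count,
               res$residue_n, res$residue_n1)
  res[ord, ]
}

#' Write co-operative pairs in the published table layout
#'
#' TSV with columns identifier, name, cleavages, frequency (the
#' co-occurrence count), site, residue n, residue n + 1.
#'
#' @param pairs result of \code{\link{detectCooperativePairs}}.
#' @param peptidaseId identifier text for the first column.
#' @param name recommended name for the second column.
#' @param file path or connection.
#' @return invisibly, the path.
#' @export
writeCooperativeTable <- function(pairs, peptidaseId, name, file) {
  df <- data.frame(identifier = rep(peptidaseId, nrow(pairs)),
                   name = rep(name, nrow(pairs)),
                   cleavages = pairs$n_cleavages,
                   frequency = pairs$pair_count,
                   site = pairs$site,
                   residue_n = pairs$residue_n,
                   residue_n1 = pairs$residue_n1,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
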