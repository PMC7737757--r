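#' Normalise window symbols to the closed 22-symbol alphabet
#'
#' Replaces every token that is not one of the 20 standard residues or
#' \code{"-"} with the letter \code{"X"}: nonstandard amino acids and
#' synthetic N-/C-terminal blocking groups (e.g. \code{"Abz"},
#' \code{"pNA"}, \code{"Hyp"}) all become \code{"X"}. Standard residues
#' and \code{"-"} pass through unchanged. Normalisation precedes
#' deduplication, so two windows differing only in which nonstandard
#' group they carry collapse to one.
#'
#' @param windows character matrix with 8 columns, or a length-8 vector.
#' @return character matrix over the 22-symbol alphabet, same shape.
#' @examples
#' normalizeWindows(c("Abz", "G", "I", "V", "R", "A", "-", "-"))
#' @export
normalizeWindows <- function(windows) {
  vec <- is.null(dim(windows))
  if (vec) {
    if (length(windows) != 8L)
      stop("a substrate window has exactly 8 sites")
    windows <- matrix(windows, nrow = 1L)
  }
  if (ncol(windows) != 8L)
    stop("a substrate window has exactly 8 sites")
  out <- windows
  out[!out %in% c(standardResidues, "-")] <- "X"
  colnames(out) <- siteLabels
  if (vec) stats::setNames(out[1L, ], siteLabels) else out
}

#' @rdname normalizeWindows
#' @param x a \code{CleavageSet}.
#' @return \code{normalizeCleavages}: the \code{CleavageSet} with
#'   normalised windows.
#' @export
normalizeCleavages <- function(x) {
  stopifnot(is(x, "CleavageSet"))
  initialize(x, windows = normalizeWindows(x@windows))
}

#' Deduplicate the cleavages of one peptidase
#'
#' Builds the nonredundant cleavage set: after normalisation, exactly one
#' record is kept per distinct P4-P4' window. Distinctness compares the
#' 8-symbol window only; two cleavages of different substrates with
#' identical windows count once. The first occurrence's metadata survives
#' (records are pre-sorted by \code{(accession, p1_position)} when
#' \code{stable = FALSE}, making the result order-independent); the
#' cleavage classes of all collapsed records are recorded in a
#' \code{collapsed_classes} provenance column.
#'
#' @param x a \code{CleavageSet} whose records all share one peptidase
#'   identifier (mixed identifiers are an error; use
#'   \code{\link{makeNonredundant}} for whole collections).
#' @param stable logical; TRUE keeps first occurrences in input order,
#'   FALSE (default) applies the \code{(accession, p1_position)} tie-break
#'   first so unordered inputs yield identical results.
#' @return the nonredundant \code{CleavageSet}.
#' @export
deduplicate <- function(x, stable = FALSE) {
  stopifnot(is(x, "CleavageSet"))
  if (length(unique(x@meta$peptidase)) > 1L)
    stop("deduplicate() expects the cleavages of a single peptidase; ",
         "got ", length(unique(x@meta$peptidase)),
         " identifiers (use makeNonredundant() for mixed collections)")
  x <- normalizeCleavages(x)
  if (!length(x)) return(x)
  if (!stable) {
    ord <- order(ifelse(is.na(x@meta$accession), "~", x@meta$accession),
                 ifelse(is.na(x@meta$p1_position), .Machine$integer.max,
                        x@meta$p1_position))
    x <- x[ord]
  }
  key <- apply(x@windows, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  collapsed <- vapply(split(x@meta$cleavage_class, key), function(cl)
    paste(sort(unique(cl)), collapse = ","), "")
  out <- x[first]
  out@meta$collapsed_classes <- unname(collapsed[key[first]])
  out
}

#' Nonredundant sets for every peptidase in a collection
#'
#' Applies \code{\link{deduplicate}} within each peptidase of a mixed
#' collection and concatenates the results.
#'
#' @param x a \code{CleavageSet}.
#' @param stable passed to \code{\link{deduplicate}}.
#' @return a \code{CleavageSet} with one record per (peptidase, distinct
#'   normalised window).
#' @export
makeNonredundant <- function(x, stable = FALSE) {
  stopifnot(is(x, "CleavageSet"))
  if (!length(x)) return(normalizeCleavages(x))
  parts <- lapply(splitByPeptidase(x), deduplicate, stable = stable)
  do.call(c, unname(parts))
}
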