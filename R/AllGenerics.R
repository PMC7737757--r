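#' @importFrom BiocGenerics counts
NULL

#' Extract the P4-P4' window matrix
#' @param x a \code{CleavageSet}.
#' @return character matrix, one row per record, columns P4..P4'.
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))

#' Peptidase identifiers of a collection or report
#' @param x a \code{CleavageSet} or \code{SpecificityReport}.
#' @return character vector of identifier texts.
#' @export
setGeneric("peptidase", function(x) standardGeneric("peptidase"))

#' Cleavage classes of the records
#' @param x a \code{CleavageSet}.
#' @return character vector.
#' @export
setGeneric("cleavageClass", function(x) standardGeneric("cleavageClass"))

#' Percentage table of a frequency matrix
#' @param x a \code{FrequencyMatrix}.
#' @return numeric 22 x 8 matrix, percent units.
#' @export
setGeneric("percentages", function(x) standardGeneric("percentages"))

#' Denominator of a frequency matrix or report
#' @param x a \code{FrequencyMatrix} or \code{SpecificityReport}.
#' @return integer count of nonredundant cleavages.
#' @export
setGeneric("nCleavages", function(x) standardGeneric("nCleavages"))

#' Per-site findings of a specificity report
#' @param x a \code{SpecificityReport}.
#' @return \code{DataFrame} of site-level findings.
#' @export
setGeneric("findings", function(x) standardGeneric("findings"))

#' Inferred activity kind of a specificity report
#' @param x a \code{SpecificityReport}.
#' @return character scalar, one of \code{\link{activityKinds}} or NA.
#' @export
setGeneric("activityKind", function(x) standardGeneric("activityKind"))
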