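## MEROPS identifier grammar.
##
## Family-form:        <type letter><number>.<serial>     e.g. S01.151
##   serial 900-999 marks a nonpeptidase homolog.
## Homologous complex: X<family>.<serial>                 e.g. XT01.001
## Mixed complex:      XP<number>.<serial>                e.g. XP01.001
## Compound inhibitor: L<I-family>.<serial>               e.g. LI01.001
## Unsequenced:        <type letter>9<activity>.<serial>  e.g. M9E.004
##   activity letters: A aminopeptidase, B dipeptidase, C dipeptidyl-
##   peptidase, D peptidyl-dipeptidase, E carboxypeptidase, G endopeptidase.

catalyticTypeLetters <- c("A", "C", "G", "M", "N", "P", "S", "T", "U")
activityCodeLetters <- c("A", "B", "C", "D", "E", "G")

padFamilyNumber <- function(letter, number) {
  digits <- max(1L, 3L - nchar(letter))
  paste0(letter, formatC(as.integer(number), width = digits, flag = "0"))
}

## Parse one identifier; returns a list of fields, or the reason it is
## malformed (character) when strict = FALSE.
.parseOne <- function(text, strict = TRUE) {
  fail <- function(msg) {
    if (strict) stop("malformed MEROPS identifier ", sQuote(text), ": ",
                     msg, call. = FALSE)
    msg
  }
  if (is.na(text) || !nzchar(text)) return(fail("empty text"))
  parts <- strsplit(text, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    return(fail("expected exactly one dot"))
  if (!grepl("^[0-9]{1,3}$", parts[2L]))
    return(fail(paste0("nonnumeric or overlong serial ",
                       sQuote(parts[2L]))))
  serial <- as.integer(parts[2L])
  if (serial < 1L)
    return(fail("serial must be a positive integer"))
  head <- parts[1L]

  out <- list(raw = text, kind = NA_character_,
              catalyticType = NA_character_, family = NA_character_,
              serial = serial, activityCode = NA_character_)

  if (grepl("^L", head)) {              # compound inhibitor
    m <- regmatches(head, regexec("^L(I)([0-9]{1,3})$", head))[[1L]]
    if (!length(m))
      return(fail(paste0("invalid compound-inhibitor family ",
                         sQuote(substring(head, 2L)))))
    out$kind <- "compound_inhibitor"
    out$catalyticType <- "I"
    out$family <- padFamilyNumber("I", m[3L])
    return(out)
  }
  if (grepl("^XP[0-9]", head)) {        # mixed-family complex
    m <- regmatches(head, regexec("^XP([0-9]{1,3})$", head))[[1L]]
    if (!length(m))
      return(fail(paste0("invalid mixed-complex number ",
                         sQuote(substring(head, 3L)))))
    out$kind <- "complex_mixed"
    out$catalyticType <- "P"
    out$family <- padFamilyNumber("P", m[2L])
    return(out)
  }
  if (grepl("^X", head)) {              # homologous complex
    m <- regmatches(head,
                    regexec("^X([ACGMNSTUI])([0-9]{1,3})$", head))[[1L]]
    if (!length(m))
      return(fail(paste0("invalid complex family ",
                         sQuote(substring(head, 2L)))))
    out$kind <- "complex_homologous"
    out$catalyticType <- m[2L]
    out$family <- padFamilyNumber(m[2L], m[3L])
    return(out)
  }
  m <- regmatches(head, regexec("^([ACGMNPSTU])9([ABCDEG])$", head))[[1L]]
  if (length(m)) {                      # unsequenced peptidase
    out$kind <- "unsequenced"
    out$catalyticType <- m[2L]
    out$family <- head
    out$activityCode <- m[3L]
    return(out)
  }
  m <- regmatches(head, regexec("^([ACGMNPSTUI])([0-9]{1,3})$",
                                head))[[1L]]
  if (!length(m)) {
    letter <- substring(head, 1L, 1L)
    if (!letter %in% c(catalyticTypeLetters, "I", "X", "L"))
      return(fail(paste0(sQuote(letter), " is not a catalytic-type letter")))
    return(fail(paste0("invalid family code ", sQuote(head))))
  }
  out$catalyticType <- m[2L]
  out$family <- padFamilyNumber(m[2L], m[3L])
  out$kind <- if (serial >= 900L) "nonpeptidase_homolog"
              else "protein_species"
  out
}

#' Parse MEROPS identifiers
#'
#' Parses identifier text into a \code{\linkS4class{MeropsId}} object,
#' classifying each identifier as a protein-species, nonpeptidase homolog
#' (serial 900-999), homologous-peptidase complex (\code{X} prefix),
#' mixed-family complex (\code{XP} prefix), compound inhibitor (\code{L}
#' prefix) or unsequenced peptidase (catalytic letter + \code{9} +
#' activity letter). Parsing is case-sensitive (identifiers are uppercase);
#' leading and trailing whitespace is stripped. Unpadded family numbers and
#' serials are accepted and canonicalised (\code{"S1.151"} parses to the
#' same identifier as \code{"S01.151"}).
#'
#' @param text character vector of identifier strings.
#' @return a \code{MeropsId} of the same length.
#' @examples
#' id <- parseMeropsId(c("S01.151", "XT01.001", "M9E.004", "S01.901"))
#' idKind(id)
#' formatMeropsId(id)
#' @export
parseMeropsId <- function(text) {
  text <- trimws(as.character(text))
  parsed <- lapply(text, .parseOne, strict = TRUE)
  new("MeropsId",
      raw = vapply(parsed, `[[`, "", "raw"),
      kind = vapply(parsed, `[[`, "", "kind"),
      catalyticType = vapply(parsed, `[[`, "", "catalyticType"),
      family = vapply(parsed, `[[`, "", "family"),
      serial = vapply(parsed, `[[`, 0L, "serial"),
      activityCode = vapply(parsed, `[[`, "", "activityCode"))
}

#' Classify identifier text without raising errors
#'
#' Like \code{\link{parseMeropsId}} but returns the kind per element, with
#' \code{"malformed"} for text the grammar rejects. Useful for validating
#' whole columns.
#'
#' @param text character vector.
#' @return character vector of kinds (or \code{"malformed"}).
#' @examples
#' classifyMeropsId(c("A01.002", "Q1.1"))
#' @export
classifyMeropsId <- function(text) {
  text <- trimws(as.character(text))
  vapply(text, function(t) {
    p <- .parseOne(t, strict = FALSE)
    if (is.character(p)) "malformed" else p$kind
  }, "", USE.NAMES = FALSE)
}

#' Canonicalise a family code
#'
#' Pads the numeric part of a family code with zeros so the code is at
#' least three characters (\code{"S1"} becomes \code{"S01"}); codes already
#' three or more characters are unchanged. A trailing subfamily letter
#' (e.g. \code{"S1A"}) is accepted and retained after the padded number.
#'
#' @param text character vector of family codes.
#' @return character vector of canonical codes.
#' @examples
#' canonicalFamily(c("S1", "M10", "C3", "S1A"))
#' @export
canonicalFamily <- function(text) {
  text <- trimws(as.character(text))
  vapply(text, function(t) {
    m <- regmatches(t, regexec("^([ACGMNPSTUI])([0-9]{1,3})([A-Z]?)$",
                               t))[[1L]]
    if (!length(m))
      stop("not a family code: ", sQuote(t), call. = FALSE)
    paste0(padFamilyNumber(m[2L], m[3L]), m[4L])
  }, "", USE.NAMES = FALSE)
}

#' Format identifiers in canonical text form
#'
#' Writes each identifier with the family padded to at least three
#' characters and the serial zero-padded to three digits, restoring any
#' kind prefix (\code{X} for complexes, \code{L} for compound inhibitors).
#' \code{formatMeropsId(parseMeropsId(s))} is the canonical form of
#' \code{s}.
#'
#' @param id a \code{MeropsId}.
#' @return character vector of canonical identifier texts.
#' @export
formatMeropsId <- function(id) {
  stopifnot(is(id, "MeropsId"))
  if (any(is.na(id@kind) | is.na(id@family) | is.na(id@serial)))
    stop("incomplete identifier cannot be formatted")
  prefix <- ifelse(id@kind %in% c("complex_homologous", "complex_mixed"),
                   "X",
            ifelse(id@kind == "compound_inhibitor", "L", ""))
  paste0(prefix, id@family, ".", sprintf("%03d", id@serial))
}

#' Kind, family and serial accessors for MeropsId
#' @param x a \code{MeropsId}.
#' @return character (or integer for \code{idSerial}) vector.
#' @rdname idKind
#' @export
idKind <- function(x) { stopifnot(is(x, "MeropsId")); x@kind }

#' @rdname idKind
#' @export
idFamily <- function(x) { stopifnot(is(x, "MeropsId")); x@family }

#' @rdname idKind
#' @export
idSerial <- function(x) { stopifnot(is(x, "MeropsId")); x@serial }

#' @rdname idKind
#' @export
idCatalyticType <- function(x) { stopifnot(is(x, "MeropsId")); x@catalyticType }

#' @rdname idKind
#' @export
idActivityCode <- function(x) { stopifnot(is(x, "MeropsId")); x@activityCode }

#' @describeIn parseMeropsId number of identifiers.
#' @param x a \code{MeropsId}.
#' @export
setMethod("length", "MeropsId", function(x) length(x@raw))

#' @describeIn parseMeropsId subset identifiers.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "MeropsId", function(x, i, j, ..., drop = TRUE) {
  new("MeropsId", raw = x@raw[i], kind = x@kind[i],
      catalyticType = x@catalyticType[i], family = x@family[i],
      serial = x@serial[i], activityCode = x@activityCode[i])
})

#' @describeIn parseMeropsId canonical text form.
#' @export
setMethod("as.character", "MeropsId", function(x) formatMeropsId(x))

setMethod("show", "MeropsId", function(object) {
  n <- length(object)
  cat("MeropsId of length ", n, "\n", sep = "")
  if (n) {
    shown <- utils::head(seq_len(n), 10L)
    cat(paste0("  ", formatMeropsId(object[shown]),
               "  [", object@kind[shown], "]"), sep = "\n")
    if (n > 10L) cat("  ...\n")
  }
})

#' Load a classification hierarchy from a child,parent table
#'
#' Reads a two-column CSV (\code{child,parent}) describing the clan /
#' subclan / family / subfamily / protein-species hierarchy and infers the
#' level of each node from its name: a parseable identifier is a
#' protein-species; a family code with a trailing subfamily letter is a
#' subfamily; a plain family code is a family; two letters are a clan, and
#' anything else below a clan is a subclan. Subfamily letters live on the
#' hierarchy node, not in identifiers.
#'
#' @param file path to a CSV with columns \code{child} and \code{parent}
#'   (empty parent for root nodes).
#' @return \code{DataFrame} with columns \code{name}, \code{parent},
#'   \code{level} and, for protein-species rows, \code{identifier}
#'   (canonical text).
#' @export
readHierarchy <- function(file) {
  df <- utils::read.csv(file, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% colnames(df)))
    stop("hierarchy file needs columns 'child' and 'parent'")
  name <- trimws(df$child)
  parent <- trimws(df$parent)
  parent[!nzchar(parent)] <- NA_character_
  level <- vapply(name, .hierarchyLevel, "", USE.NAMES = FALSE)
  ident <- rep(NA_character_, length(name))
  ps <- level == "protein_species"
  if (any(ps)) ident[ps] <- formatMeropsId(parseMeropsId(name[ps]))
  DataFrame(name = name, parent = parent, level = level,
            identifier = ident)
}

.hierarchyLevel <- function(nm) {
  if (classifyMeropsId(nm) != "malformed") return("protein_species")
  if (grepl("^[ACGMNPSTUI][0-9]{1,3}[A-Z]$", nm)) return("subfamily")
  if (grepl("^[ACGMNPSTUI][0-9]{1,3}$", nm)) return("family")
  if (grepl("^[A-Z]{2}$", nm)) return("clan")
  "subclan"
}
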