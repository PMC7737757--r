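#' Construct a CleavageSet
#'
#' Builds a \code{\linkS4class{CleavageSet}} from a window matrix (or a
#' character vector for a single record) and per-record metadata. This is
#' the low-level constructor; most collections come from
#' \code{\link{readCleavageTable}} or \code{\link{generateCollection}}.
#'
#' @param windows character matrix with 8 columns (sites P4..P4', N- to
#'   C-terminal), or a length-8 character vector.
#' @param peptidase character vector of identifier texts (recycled).
#' @param substrate_name,accession character vectors (recycled; accession
#'   may be NA, e.g. for synthetic substrates).
#' @param p1_position integer vector of P1 residue positions in the
#'   substrate entry's own 1-based numbering (NA when unknown).
#' @param cleavage_class one of \code{\link{cleavageClasses}} per record;
#'   defaults to \code{"nonphysiological"} when NA.
#' @return a \code{CleavageSet}.
#' @examples
#' cs <- CleavageSet(rbind(c("A","A","A","R","S","S","S","S")),
#'                   peptidase = "S01.151")
#' @export
CleavageSet <- function(windows, peptidase,
                        substrate_name = NA_character_,
                        accession = NA_character_,
                        p1_position = NA_integer_,
                        cleavage_class = NA_character_) {
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1L)
  windows <- as.matrix(windows)
  storage.mode(windows) <- "character"
  if (ncol(windows) != 8L)
    stop("a substrate window has exactly 8 sites (P4..P4')")
  colnames(windows) <- siteLabels
  rownames(windows) <- NULL
  n <- nrow(windows)
  cleavage_class <- rep_len(as.character(cleavage_class), n)
  cleavage_class[is.na(cleavage_class)] <- "nonphysiological"
  meta <- DataFrame(
    peptidase = rep_len(as.character(peptidase), n),
    substrate_name = rep_len(as.character(substrate_name), n),
    accession = rep_len(as.character(accession), n),
    p1_position = rep_len(as.integer(p1_position), n),
    cleavage_class = cleavage_class)
  if (any(!is.na(meta$p1_position) & meta$p1_position < 1L))
    stop("p1_position must be >= 1")
  new("CleavageSet", windows = windows, meta = meta)
}

#' @describeIn CleavageSet window matrix accessor.
#' @param x a \code{CleavageSet}.
#' @export
setMethod("windows", "CleavageSet", function(x) x@windows)

#' @describeIn CleavageSet peptidase identifier per record.
#' @export
setMethod("peptidase", "CleavageSet", function(x) x@meta$peptidase)

#' @describeIn CleavageSet cleavage class per record.
#' @export
setMethod("cleavageClass", "CleavageSet", function(x) x@meta$cleavage_class)

#' @describeIn CleavageSet number of records.
#' @export
setMethod("length", "CleavageSet", function(x) nrow(x@windows))

#' @describeIn CleavageSet record metadata (\code{DataFrame}).
#' @export
setMethod("mcols", "CleavageSet", function(x, ...) x@meta)

#' @describeIn CleavageSet subset records.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CleavageSet", function(x, i, j, ..., drop = TRUE) {
  new("CleavageSet",
      windows = x@windows[i, , drop = FALSE],
      meta = x@meta[i, , drop = FALSE])
})

#' Concatenate cleavage sets
#' @param x,... \code{CleavageSet} objects.
#' @return a single \code{CleavageSet}.
#' @export
setMethod("c", "CleavageSet", function(x, ...) {
  sets <- c(list(x), list(...))
  metas <- lapply(sets, slot, "meta")
  cols <- Reduce(union, lapply(metas, colnames))
  metas <- lapply(metas, function(m) {
    for (col in setdiff(cols, colnames(m))) m[[col]] <- NA
    m[, cols, drop = FALSE]
  })
  new("CleavageSet",
      windows = do.call(rbind, lapply(sets, slot, "windows")),
      meta = do.call(rbind, metas))
})

setMethod("show", "CleavageSet", function(object) {
  n <- length(object)
  npep <- length(unique(object@meta$peptidase))
  cat("CleavageSet with ", n, " cleavage record",
      if (n != 1L) "s", " for ", npep, " peptidase",
      if (npep != 1L) "s", "\n", sep = "")
  if (n) {
    shown <- utils::head(seq_len(n), 6L)
    txt <- apply(object@windows[shown, , drop = FALSE], 1L, function(w)
      paste0(paste(w[1:4], collapse = ""), "|",
             paste(w[5:8], collapse = "")))
    cat(paste0("  ", format(object@meta$peptidase[shown]), "  ", txt,
               "  [", object@meta$cleavage_class[shown], "]"),
        sep = "\n")
    if (n > 6L) cat("  ...\n")
  }
})

#' Split a collection by peptidase
#'
#' @param x a \code{CleavageSet}.
#' @return named list of per-peptidase \code{CleavageSet}s, ordered by
#'   identifier.
#' @export
splitByPeptidase <- function(x) {
  stopifnot(is(x, "CleavageSet"))
  ids <- sort(unique(x@meta$peptidase))
  stats::setNames(lapply(ids, function(p) x[x@meta$peptidase == p]), ids)
}

#' Extract a P4-P4' window from a substrate sequence
#'
#' Takes the four residues on each side of the scissile bond, which lies
#' between positions \code{p1Position} and \code{p1Position + 1} of the
#' substrate (1-based numbering). Positions beyond either terminus are
#' recorded as \code{"-"}.
#'
#' @param sequence character scalar, the substrate residue sequence.
#' @param p1Position integer, position of the P1 residue;
#'   \code{1 <= p1Position < nchar(sequence)} (cleavage at the last residue
#'   would leave no P1').
#' @return named character vector of 8 symbols (sites P4..P4').
#' @examples
#' extractWindow("MKR", 2)   # (-,-,M,K | R,-,-,-)
#' @export
extractWindow <- function(sequence, p1Position) {
  stopifnot(length(sequence) == 1L, length(p1Position) == 1L)
  p1 <- as.integer(p1Position)
  len <- nchar(sequence)
  if (p1 < 1L || p1 > len)
    stop("p1Position must lie within the sequence (1..", len, ")")
  if (p1 == len)
    stop("p1Position is the last residue: the scissile bond needs a ",
         "residue on both sides")
  pos <- (p1 - 3L):(p1 + 4L)
  sym <- ifelse(pos >= 1L & pos <= len,
                substring(sequence, pos, pos), "-")
  stats::setNames(sym, siteLabels)
}

#' Default canonical column schema for cleavage tables
#'
#' Maps CSV column names to record fields. The canonical layout used by
#' \code{\link{writeCleavageTable}} has columns \code{peptidase_id},
#' \code{substrate_name}, \code{accession}, \code{p1_position}, the eight
#' site columns \code{p4,p3,p2,p1,p1p,p2p,p3p,p4p}, and
#' \code{cleavage_class}. Pass a modified schema to
#' \code{\link{readCleavageTable}} to ingest other comma-delimited
#' dialects (e.g. the MEROPS FTP \code{Substrate_search} export) by naming
#' which of their columns hold each field.
#'
#' @param peptidase,substrate_name,accession,p1_position,cleavage_class
#'   column names holding the record fields (accession, p1_position and
#'   cleavage_class may be NA if the file lacks them).
#' @param sites character vector of 8 column names holding the window
#'   symbols, N- to C-terminal.
#' @return named list schema.
#' @export
cleavageSchema <- function(peptidase = "peptidase_id",
                           substrate_name = "substrate_name",
                           accession = "accession",
                           p1_position = "p1_position",
                           sites = c("p4", "p3", "p2", "p1",
                                     "p1p", "p2p", "p3p", "p4p"),
                           cleavage_class = "cleavage_class") {
  stopifnot(length(sites) == 8L)
  list(peptidase = peptidase, substrate_name = substrate_name,
       accession = accession, p1_position = p1_position,
       sites = sites, cleavage_class = cleavage_class)
}

#' Read a comma-delimited cleavage table
#'
#' Reads cleavage records from CSV, mapping columns to fields through a
#' schema (\code{\link{cleavageSchema}}). Each row is validated: the
#' peptidase identifier must parse, the window must have no \code{"-"} at
#' P1 or P1', and single-character window symbols must belong to the
#' closed 22-symbol alphabet. Multi-character tokens (nonstandard-residue
#' or blocking-group names such as \code{"Abz"}) are accepted verbatim and
#' left for \code{\link{normalizeWindows}}.
#'
#' @param file path or connection to comma-delimited text (UTF-8).
#' @param schema column mapping from \code{\link{cleavageSchema}}.
#' @param strict logical; if TRUE (default) any invalid row is an error,
#'   otherwise invalid rows are skipped with a warning naming the line
#'   numbers and reasons.
#' @return a \code{CleavageSet}; with \code{strict = FALSE} the attribute
#'   \code{"rejected"} holds a data.frame of skipped line numbers and
#'   reasons.
#' @export
readCleavageTable <- function(file, schema = cleavageSchema(),
                              strict = TRUE) {
  df <- utils::read.csv(file, colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c(schema$peptidase, schema$substrate_name, schema$sites)
  miss <- setdiff(mandatory, colnames(df))
  if (length(miss))
    stop("cleavage table lacks mandatory columns: ",
         paste(miss, collapse = ", "))
  n <- nrow(df)
  getCol <- function(nm, default = NA_character_) {
    if (!is.na(nm) && nm %in% colnames(df)) df[[nm]]
    else rep(default, n)
  }
  win <- as.matrix(df[, schema$sites, drop = FALSE])
  storage.mode(win) <- "character"
  win[is.na(win) | !nzchar(win)] <- "-"
  colnames(win) <- siteLabels

  pep <- trimws(getCol(schema$peptidase))
  p1raw <- getCol(schema$p1_position)
  cls <- getCol(schema$cleavage_class)
  cls[is.na(cls) | !nzchar(cls)] <- "nonphysiological"

  reasons <- character(n)
  kinds <- classifyMeropsId(pep)
  reasons[kinds == "malformed"] <-
    paste0("unparseable peptidase identifier '", pep[kinds == "malformed"],
           "'")
  for (i in seq_len(n)) {
    if (nzchar(reasons[i])) next
    w <- win[i, ]
    single <- w[nchar(w) == 1L]
    bad <- setdiff(single, windowAlphabet)
    if (length(bad)) {
      reasons[i] <- paste0("window symbol '", bad[1L],
                           "' outside the 22-symbol alphabet")
    } else if (w[["P1"]] == "-" || w[["P1'"]] == "-") {
      reasons[i] <- "unoccupied P1 or P1' (the scissile bond needs both)"
    } else if (!cls[i] %in% cleavageClasses) {
      reasons[i] <- paste0("unknown cleavage_class '", cls[i], "'")
    }
  }
  p1 <- suppressWarnings(as.integer(p1raw))
  badP1 <- !is.na(p1raw) & nzchar(p1raw) & (is.na(p1) | p1 < 1L)
  reasons[badP1 & !nzchar(reasons)] <- "p1_position not a positive integer"

  bad <- which(nzchar(reasons))
  if (length(bad)) {
    msg <- paste0("line ", bad + 1L, ": ", reasons[bad])
    if (strict)
      stop("invalid cleavage rows:\n  ", paste(msg, collapse = "\n  "))
    warning("skipped ", length(bad), " invalid row(s):\n  ",
            paste(utils::head(msg, 10L), collapse = "\n  "),
            if (length(bad) > 10L) "\n  ...")
  }
  keep <- setdiff(seq_len(n), bad)
  canon <- pep
  if (length(keep))
    canon[keep] <- formatMeropsId(parseMeropsId(pep[keep]))
  cs <- CleavageSet(win[keep, , drop = FALSE],
                    peptidase = canon[keep],
                    substrate_name = getCol(schema$substrate_name)[keep],
                    accession = {
                      acc <- getCol(schema$accession)[keep]
                      acc[!is.na(acc) & !nzchar(acc)] <- NA_character_
                      acc
                    },
                    p1_position = p1[keep],
                    cleavage_class = cls[keep])
  if (!strict)
    attr(cs, "rejected") <- data.frame(line = bad + 1L,
                                       reason = reasons[bad])
  cs
}

#' Write a cleavage table in the canonical CSV layout
#'
#' Writes records so that \code{readCleavageTable(writeCleavageTable(x))}
#' reproduces them field for field. An empty collection yields a
#' header-only file.
#'
#' @param x a \code{CleavageSet}.
#' @param file path or connection.
#' @return invisibly, the path.
#' @export
writeCleavageTable <- function(x, file) {
  stopifnot(is(x, "CleavageSet"))
  schema <- cleavageSchema()
  w <- x@windows
  df <- data.frame(x@meta$peptidase, x@meta$substrate_name,
                   ifelse(is.na(x@meta$accession), "", x@meta$accession),
                   x@meta$p1_position,
                   w[, 1L], w[, 2L], w[, 3L], w[, 4L],
                   w[, 5L], w[, 6L], w[, 7L], w[, 8L],
                   x@meta$cleavage_class,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(schema$peptidase, schema$substrate_name,
                    schema$accession, schema$p1_position, schema$sites,
                    schema$cleavage_class)
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE, na = "")
  invisible(file)
}
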