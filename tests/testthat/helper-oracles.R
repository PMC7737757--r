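## Independent brute-force oracles used to cross-check the package's
## implementations, plus small fixture builders. The oracles deliberately
## share no code with the package internals.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
SITES <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

## --- identifier grammar oracle -------------------------------------
## Full-string regex classifier, precedence: compound inhibitor (L),
## complex (X / XP), unsequenced (letter-9-activity), then family-form
## with the 900-series homolog rule.
oracleIdKind <- function(text) {
  vapply(text, function(t) {
    t <- trimws(t)
    if (grepl("^LI[0-9]{1,3}\\.[0-9]{1,3}$", t) &&
        as.integer(sub(".*\\.", "", t)) >= 1L)
      return("compound_inhibitor")
    if (grepl("^XP[0-9]{1,3}\\.[0-9]{1,3}$", t) &&
        as.integer(sub(".*\\.", "", t)) >= 1L)
      return("complex_mixed")
    if (grepl("^X[ACGMNSTUI][0-9]{1,3}\\.[0-9]{1,3}$", t) &&
        as.integer(sub(".*\\.", "", t)) >= 1L)
      return("complex_homologous")
    if (grepl("^[ACGMNPSTU]9[ABCDEG]\\.[0-9]{1,3}$", t) &&
        as.integer(sub(".*\\.", "", t)) >= 1L)
      return("unsequenced")
    if (grepl("^[ACGMNPSTUI][0-9]{1,3}\\.[0-9]{1,3}$", t)) {
      serial <- as.integer(sub(".*\\.", "", t))
      if (serial < 1L) return("malformed")
      return(if (serial >= 900L) "nonpeptidase_homolog"
             else "protein_species")
    }
    "malformed"
  }, "", USE.NAMES = FALSE)
}

## corpus of valid and malformed identifier strings (seeded)
makeIdCorpus <- function(n = 200L, seed = 11L) {
  set.seed(seed)
  fam <- function() paste0(sample(c("A", "C", "G", "M", "N", "P", "S",
                                    "T", "U", "I"), 1L),
                           sample(1:110, 1L))
  ser <- function(lo = 1L, hi = 899L)
    sprintf("%03d", sample(lo:hi, 1L))
  makers <- list(
    function() paste0(fam(), ".", ser()),                    # regular
    function() paste0(fam(), ".", ser(900L, 999L)),          # homolog
    function() paste0("X", sample(c("T", "M", "S", "C"), 1L),
                      sprintf("%02d", sample(1:60, 1L)), ".", ser()),
    function() paste0("XP", sprintf("%02d", sample(1:20, 1L)),
                      ".", ser()),
    function() paste0("LI", sprintf("%02d", sample(1:90, 1L)),
                      ".", ser()),
    function() paste0(sample(c("A", "C", "G", "M", "S", "T"), 1L), "9",
                      sample(c("A", "B", "C", "D", "E", "G"), 1L),
                      ".", ser()),
    function() paste0("Q", sample(1:9, 1L), ".", sample(1:9, 1L)),
    function() paste0(fam(), sample(1:999, 1L)),             # no dot
    function() paste0(fam(), ".", sample(letters, 1L)),      # bad serial
    function() paste0(tolower(fam()), ".", ser()),           # lowercase
    function() paste0(fam(), ".", "0"),                      # serial 0
    function() paste0("X", sample(1:99, 1L), ".", ser()),    # X no letter
    function() paste0(fam(), ".", sample(1000:5000, 1L)))    # overlong
  vapply(seq_len(n), function(i) makers[[1L + (i %% length(makers))]](),
         "")
}

## --- window oracles -------------------------------------------------
## brute-force dictionary tally: symbol x site counts
oracleTally <- function(w) {
  out <- matrix(0L, nrow = 22L, ncol = 8L,
                dimnames = list(c("-", AA20, "X"), SITES))
  for (i in seq_len(nrow(w)))
    for (j in 1:8)
      out[w[i, j], j] <- out[w[i, j], j] + 1L
  out
}

## brute-force set-of-tuples deduplication (first occurrence kept)
oracleUniqueWindows <- function(w) {
  seen <- character(0)
  keep <- logical(nrow(w))
  for (i in seq_len(nrow(w))) {
    k <- paste(w[i, ], collapse = "|")
    if (!k %in% seen) {
      seen <- c(seen, k)
      keep[i] <- TRUE
    }
  }
  w[keep, , drop = FALSE]
}

## exhaustive double loop over all 7 adjacent site pairs x 20 x 20
## ordered residue pairs
oraclePairs <- function(w, minPair = 10L, cutoff = 0.90) {
  n <- nrow(w)
  rows <- list()
  for (k in 1:7) {
    for (a in AA20) {
      fa <- sum(w[, k] == a) / n
      for (b in AA20) {
        cnt <- sum(w[, k] == a & w[, k + 1L] == b)
        if (cnt < minPair) next
        fb <- sum(w[, k + 1L] == b) / n
        if (fa >= cutoff || fb >= cutoff) next
        rows[[length(rows) + 1L]] <-
          data.frame(site = SITES[k], residue_n = a, residue_n1 = b,
                     pair_count = cnt, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(site = character(0), residue_n = character(0),
                      residue_n1 = character(0),
                      pair_count = integer(0)))
  do.call(rbind, rows)
}

## --- fixture builders -----------------------------------------------
## random normalised window matrix; P1 and P1' always occupied
randomWindows <- function(n, seed, pDash = 0.08, pX = 0.03) {
  set.seed(seed)
  syms <- c("-", AA20, "X")
  p <- c(pDash, rep((1 - pDash - pX) / 20, 20L), pX)
  w <- matrix(sample(syms, n * 8L, replace = TRUE, prob = p),
              ncol = 8L, dimnames = list(NULL, SITES))
  for (j in c(4L, 5L))
    w[w[, j] == "-", j] <- sample(AA20, sum(w[, j] == "-"),
                                  replace = TRUE)
  w
}

## windows with a fixed symbol planted at one site
plantAtSite <- function(w, site, symbols) {
  w[, site] <- rep_len(symbols, nrow(w))
  w
}

findingsDf <- function(x) as.data.frame(x)

hasFinding <- function(fnd, site, finding, residues = NULL) {
  fnd <- as.data.frame(fnd)
  hit <- fnd$site == site & fnd$finding == finding
  if (!is.null(residues))
    hit <- hit & fnd$residues == paste(sort(residues), collapse = ",")
  any(hit)
}
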