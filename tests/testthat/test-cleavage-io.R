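test_that("extractWindow takes four residues either side of the scissile bond", {
  expect_identical(unname(extractWindow("AAAARBBBBC", 5)),
                   c("A", "A", "A", "R", "B", "B", "B", "B"))
  expect_identical(unname(extractWindow("MKR", 2)),
                   c("-", "-", "M", "K", "R", "-", "-", "-"))
  expect_identical(unname(extractWindow("RS", 1)),
                   c("-", "-", "-", "R", "S", "-", "-", "-"))
})

test_that("extractWindow rejects positions without a residue on both sides", {
  expect_error(extractWindow("MKR", 3), "both sides")
  expect_error(extractWindow("MKR", 0), "within the sequence")
  expect_error(extractWindow("MKR", 9), "within the sequence")
})

test_that("windows have 8 sites and min(4,p1)+min(4,len-p1) occupied positions", {
  set.seed(5)
  for (i in 1:40) {
    len <- sample(2:30, 1)
    p1 <- sample(seq_len(len - 1L), 1)
    sq <- paste(sample(LETTERS[1:20], len, replace = TRUE),
                collapse = "")
    w <- extractWindow(sq, p1)
    expect_length(w, 8L)
    expect_identical(sum(w != "-"),
                     min(4L, p1) + min(4L, len - p1))
  }
})

writeFixtureCsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(c(paste("peptidase_id,substrate_name,accession,p1_position",
                     "p4,p3,p2,p1,p1p,p2p,p3p,p4p,cleavage_class",
                     sep = ","), lines), f)
  f
}

test_that("valid rows become records; offending rows are named by line", {
  f <- writeFixtureCsv(c(
    "S01.151,albumin,P02768,25,A,A,A,R,S,S,S,S,physiological",
    "S01.151,albumin,P02768,40,G,I,V,K,S,A,-,-,physiological",
    "C14.001,gasdermin,Q9,10,I,V,P,D,G,L,N,D,physiological"))
  cs <- readCleavageTable(f)
  expect_s4_class(cs, "CleavageSet")
  expect_length(cs, 3L)
  expect_identical(peptidase(cs)[3], "C14.001")

  bad <- writeFixtureCsv(c(
    "S01.151,albumin,P02768,25,A,A,A,R,S,S,S,S,physiological",
    "S01.151,albumin,P02768,30,A,A,A,R,Z,S,S,S,physiological"))
  expect_error(readCleavageTable(bad), "line 3.*'Z'")

  dashP1 <- writeFixtureCsv("S01.151,albumin,P02768,25,A,A,A,-,S,S,S,S,")
  expect_error(readCleavageTable(dashP1), "P1")
})

test_that("lenient mode skips invalid rows and reports them", {
  f <- writeFixtureCsv(c(
    "S01.151,albumin,P02768,25,A,A,A,R,S,S,S,S,physiological",
    "NOTANID,x,,1,A,A,A,R,S,S,S,S,synthetic",
    "S01.151,albumin,P02768,31,A,A,A,R,-,S,S,S,synthetic"))
  expect_warning(cs <- readCleavageTable(f, strict = FALSE), "skipped 2")
  expect_length(cs, 1L)
  rej <- attr(cs, "rejected")
  expect_identical(rej$line, c(3L, 4L))
})

test_that("multi-character blocking-group tokens pass the reader", {
  f <- writeFixtureCsv("S01.151,Abz-GIVR-pNA,,4,Abz,G,I,R,pNA,-,-,-,synthetic")
  cs <- readCleavageTable(f)
  expect_identical(unname(windows(cs)[1, "P4"]), "Abz")
  expect_identical(unname(normalizeWindows(windows(cs))[1, c(1, 5)]),
                   c("X", "X"))
})

test_that("missing mandatory columns are a configuration error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("peptidase_id,substrate_name", f)
  expect_error(readCleavageTable(f), "mandatory columns")
})

test_that("read-write round-trip is the identity on valid collections", {
  ## header-only file for an empty collection
  empty <- CleavageSet(matrix(character(0), 0, 8), character(0))
  f <- withr::local_tempfile(fileext = ".csv")
  writeCleavageTable(empty, f)
  expect_length(readCleavageTable(f), 0L)
  expect_identical(readLines(f)[1],
                   paste0('"peptidase_id","substrate_name","accession",',
                          '"p1_position","p4","p3","p2","p1","p1p",',
                          '"p2p","p3p","p4p","cleavage_class"'))

  one <- CleavageSet(c("A", "A", "A", "R", "S", "S", "S", "S"),
                     peptidase = "S01.151", substrate_name = "substrate",
                     accession = "P12345", p1_position = 25L,
                     cleavage_class = "physiological")
  writeCleavageTable(one, f)
  back <- readCleavageTable(f)
  expect_identical(windows(back), windows(one))
  expect_identical(as.data.frame(mcols(back)), as.data.frame(mcols(one)))

  spec <- peptidaseSpec("M10.005", 100, duplicateFraction = 0.1,
                        nonstandardFraction = 0.05)
  cs <- generateCollection(spec, seed = 8)
  writeCleavageTable(cs, f)
  back <- readCleavageTable(f)
  expect_identical(windows(back), windows(cs))
  expect_identical(as.data.frame(mcols(back)), as.data.frame(mcols(cs)))
})

test_that("CleavageSet enforces the window invariants", {
  expect_error(CleavageSet(matrix("A", 2, 7), "S01.151"), "8 sites")
  w <- matrix("A", 1, 8)
  w[1, 4] <- "-"
  expect_error(CleavageSet(w, "S01.151"), "P1")
  w[1, 4] <- "B"
  expect_error(CleavageSet(w, "S01.151"), "alphabet")
})
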