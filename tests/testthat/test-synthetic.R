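test_that("the generator is deterministic under a fixed seed", {
  spec <- peptidaseSpec("S01.151", 120, duplicateFraction = 0.1,
                        nonstandardFraction = 0.05)
  a <- generateCollection(spec, seed = 5)
  b <- generateCollection(spec, seed = 5)
  expect_identical(windows(a), windows(b))
  expect_identical(as.data.frame(mcols(a)), as.data.frame(mcols(b)))
  c <- generateCollection(spec, seed = 6)
  expect_false(identical(windows(a), windows(c)))
})

test_that("exopeptidase kinds force '-' at the nonexistent subsites", {
  amino <- generateCollection(
    peptidaseSpec("M01.001", 50, activityKind = "aminopeptidase"),
    seed = 2)
  expect_true(all(windows(amino)[, c("P4", "P3", "P2")] == "-"))
  expect_true(all(windows(amino)[, "P1"] != "-"))
  carb <- generateCollection(
    peptidaseSpec("M14.001", 50, activityKind = "carboxypeptidase"),
    seed = 2)
  expect_true(all(windows(carb)[, c("P2'", "P3'", "P4'")] == "-"))
})

test_that("planted features are realised and recovered downstream", {
  spec <- peptidaseSpec("S01.151", 50,
    plantedRestrictions = list(list(site = "P1",
                                    residues = c("R", "K"))))
  nr <- deduplicate(generateCollection(spec, seed = 3))
  expect_true(hasFinding(detectRestrictedSites(nr), "P1",
                         "restricted_residues", c("K", "R")))

  spec2 <- peptidaseSpec("C14.001", 200,
    plantedPairs = list(list(site = "P2", residue_n = "P",
                             residue_n1 = "D", count = 15)))
  nr2 <- deduplicate(generateCollection(spec2, seed = 4))
  pairs <- as.data.frame(detectCooperativePairs(nr2))
  hit <- pairs[pairs$site == "P2" & pairs$residue_n == "P" &
                 pairs$residue_n1 == "D", ]
  expect_identical(nrow(hit), 1L)
  expect_gte(hit$pair_count, 15L)
})

test_that("duplicate and nonstandard rates are honoured", {
  spec <- peptidaseSpec("M10.003", 200, duplicateFraction = 0.2,
                        nonstandardFraction = 0.1)
  cs <- generateCollection(spec, seed = 9)
  expect_length(cs, 200L)
  expect_length(deduplicate(cs), 160L)
  nTok <- sum(apply(windows(cs), 1, function(r) any(nchar(r) > 1)))
  expect_equal(nTok, 20L, tolerance = 0.25)
})

test_that("generated collections pass cleavage table validation unchanged", {
  specs <- list(
    peptidaseSpec("S01.151", 60, nonstandardFraction = 0.08),
    peptidaseSpec("M01.001", 40, activityKind = "aminopeptidase"))
  cs <- generateCollection(specs, seed = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCleavageTable(cs, f)
  back <- readCleavageTable(f, strict = TRUE)   # zero errors
  expect_identical(windows(back), windows(cs))
})

test_that("inconsistent specs fail validation with every conflict listed", {
  err <- tryCatch(
    peptidaseSpec("S01.151", 50,
      activityKind = "aminopeptidase",
      plantedRestrictions = list(list(site = "P3",
                                      residues = c("A", "G"))),
      plantedExclusions = list(list(site = "P1'",
                                    residues = c("L", "V"))),
      plantedDominance = list(list(site = "P1'", residue = "L",
                                   fraction = 0.95))),
    error = conditionMessage)
  expect_match(err, "P3 does not exist")
  expect_match(err, "dominant residue L is also excluded")
})

test_that("substrate context embeds windows at consistent positions", {
  spec <- peptidaseSpec("S01.151", 100)
  cs <- generateCollection(spec, seed = 12)
  ctx <- generateSubstrateContext(cs, seed = 13)
  m <- mcols(ctx)
  ok <- vapply(seq_len(length(ctx)), function(i)
    identical(unname(extractWindow(m$sequence[i], m$p1_position[i])),
              unname(normalizeWindows(windows(ctx)[i, ]))), TRUE)
  expect_identical(sum(ok), 100L)

  ## N-terminally padded windows sit at the sequence start
  w <- rbind(c("-", "-", "M", "K", "R", "A", "G", "S"))
  padded <- generateSubstrateContext(CleavageSet(w, "M01.001"),
                                     seed = 14)
  expect_identical(mcols(padded)$p1_position, 2L)
  expect_identical(substr(mcols(padded)$sequence, 1, 3), "MKR")

  ## internal gaps cannot come from a real substrate
  gap <- CleavageSet(rbind(c("A", "-", "A", "R", "S", "S", "S", "S")),
                     "S01.151")
  expect_error(generateSubstrateContext(gap, seed = 1), "internal gap")
})

test_that("spec files in YAML load into validated specs", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- identifier: S01.151",
    "  nRecords: 30",
    "  plantedRestrictions:",
    "  - site: P1",
    "    residues: [R, K]",
    "- identifier: M01.001",
    "  nRecords: 25",
    "  activityKind: aminopeptidase"), f)
  specs <- readPeptidaseSpecs(f)
  expect_length(specs, 2L)
  expect_identical(specs[[2]]$activityKind, "aminopeptidase")
  cs <- generateCollection(specs, seed = 21)
  expect_length(cs, 55L)
})
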