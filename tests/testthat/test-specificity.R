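test_that("frequency matrices tally symbols per site as percentages", {
  one <- frequencyMatrix(rbind(c("-", "-", "-", "E", "A", "-", "-", "-")))
  expect_equal(percentages(one)["E", "P1"], 100)
  expect_equal(percentages(one)["A", "P1'"], 100)
  expect_equal(percentages(one)["-", "P4"], 100)
  expect_identical(nCleavages(one), 1L)

  four <- frequencyMatrix(rbind(
    c("A", "A", "A", "R", "S", "S", "S", "S"),
    c("A", "A", "A", "R", "S", "S", "S", "S"),
    c("A", "A", "A", "K", "S", "S", "S", "S"),
    c("G", "A", "A", "K", "S", "S", "S", "S")))
  expect_equal(percentages(four)["R", "P1"], 50)
  expect_equal(percentages(four)["K", "P1"], 50)
  expect_error(frequencyMatrix(matrix(character(0), 0, 8)), "empty")
})

test_that("frequency matrices match the dictionary-tally oracle cell for cell", {
  w <- randomWindows(25, seed = 31)
  fm <- frequencyMatrix(w)
  expect_identical(counts(fm), oracleTally(w))
  expect_equal(percentages(fm), oracleTally(w) / 25 * 100)
})

test_that("percentage columns always sum to 100 and counts to n", {
  for (seed in 1:8) {
    n <- sample(5:300, 1)
    fm <- frequencyMatrix(randomWindows(n, seed = seed))
    expect_true(all(abs(colSums(percentages(fm)) - 100) < 0.1))
    expect_true(all(colSums(counts(fm)) == n))
    expect_identical(counts(fm)["-", "P1"], 0L)
    expect_identical(counts(fm)["-", "P1'"], 0L)
  }
})

test_that("sites occupied by one or two residues are reported as restricted", {
  w <- randomWindows(25, seed = 41)
  w <- plantAtSite(w, "P1", c("R", "K"))
  fnd <- detectRestrictedSites(w)
  expect_true(hasFinding(fnd, "P1", "restricted_residues", c("K", "R")))
  expect_true(hasFinding(fnd, "P1", "restricted_type", "basic"))

  w2 <- plantAtSite(randomWindows(25, seed = 42), "P2'",
                    c("A", "G", "S"))
  fnd2 <- detectRestrictedSites(w2)
  expect_true(hasFinding(fnd2, "P2'", "restricted_type", "small"))
  expect_false(hasFinding(fnd2, "P2'", "restricted_residues"))

  ## below the 20-cleavage evidence threshold: no findings at all
  expect_identical(nrow(detectRestrictedSites(w[1:19, ])), 0L)
})

test_that("a modal nonstandard group is reported as the apparent preference", {
  w <- randomWindows(30, seed = 43)
  w <- plantAtSite(w, "P1'", c("X", "X", "A"))
  fnd <- detectRestrictedSites(w)
  expect_true(hasFinding(fnd, "P1'", "nonstandard_preference", "X"))
})

test_that("never-observed residues and types are reported as exclusions", {
  ## every residue but Trp present at every site
  nonW <- setdiff(standardResidues, "W")
  w <- vapply(1:8, function(j) rep_len(c(nonW[j:19], nonW[1:(j - 1)],
                                         nonW[1]), 40), character(40))
  colnames(w) <- SITES
  fnd <- detectExclusions(w)
  for (s in SITES)
    expect_true(hasFinding(fnd, s, "excluded_residues", "W"),
                info = s)

  w2 <- randomWindows(40, seed = 52)
  w2[w2[, "P3'"] %in% c("D", "E", "W"), "P3'"] <- "G"
  fnd2 <- detectExclusions(w2)
  expect_true(hasFinding(fnd2, "P3'", "excluded_type", "acidic"))

  ## a site showing all 20 residues yields no exclusion there
  w3 <- randomWindows(40, seed = 53)
  w3[, "P2"] <- rep_len(standardResidues, 40)
  expect_false(any(as.data.frame(detectExclusions(w3))$site == "P2"))

  expect_message(out <- detectExclusions(w[1:29, ]), "29")
  expect_identical(nrow(out), 0L)
})

test_that("dominance requires strictly more than the threshold fraction", {
  w <- randomWindows(100, seed = 61)
  w[, "P1"] <- c(rep("E", 92), rep("D", 4), rep("A", 4))
  fnd <- detectDominance(w)
  expect_true(hasFinding(fnd, "P1", "dominant_residue", "E"))
  frac <- as.data.frame(fnd)
  expect_equal(frac$fraction[frac$site == "P1" &
                               frac$finding == "dominant_residue"], 0.92)

  ## exactly 90% is not dominance
  w[, "P1"] <- c(rep("E", 90), rep("A", 10))
  expect_false(hasFinding(detectDominance(w), "P1", "dominant_residue"))

  ## a type can dominate where no single residue does
  w[, "P1"] <- c(rep("R", 50), rep("K", 42), rep("G", 8))
  fnd3 <- detectDominance(w)
  expect_true(hasFinding(fnd3, "P1", "dominant_type", "basic"))
  expect_false(hasFinding(fnd3, "P1", "dominant_residue"))
})

test_that("planted 95% dominance is recovered from a generated collection", {
  spec <- peptidaseSpec("S08.001", 200,
    plantedDominance = list(list(site = "P1'", residue = "G",
                                 fraction = 0.95)))
  nr <- deduplicate(generateCollection(spec, seed = 77))
  fnd <- detectDominance(nr)
  expect_true(hasFinding(fnd, "P1'", "dominant_residue", "G"))
})

test_that("dominance implies modality and detectors ignore record order", {
  for (seed in 1:5) {
    w <- randomWindows(120, seed = seed + 70)
    if (seed %% 2) w <- plantAtSite(w, "P2", c(rep("L", 19), "V"))
    fnd <- as.data.frame(detectDominance(w))
    for (i in seq_len(nrow(fnd))) {
      if (fnd$finding[i] != "dominant_residue") next
      occ <- w[, fnd$site[i]]
      occ <- occ[occ != "-"]
      expect_identical(names(which.max(table(occ))), fnd$residues[i])
    }
    perm <- w[sample(nrow(w)), ]
    expect_equal(as.data.frame(detectRestrictedSites(perm)),
                 as.data.frame(detectRestrictedSites(w)))
    expect_equal(as.data.frame(detectExclusions(perm)),
                 as.data.frame(detectExclusions(w)))
    expect_equal(as.data.frame(detectDominance(perm)),
                 as.data.frame(detectDominance(w)))
  }
})

test_that("occupancy patterns identify exopeptidase activity kinds", {
  base <- randomWindows(30, seed = 81)
  blank <- function(w, sites) { w[, sites] <- "-"; w }
  expect_identical(inferActivityKind(base), "endopeptidase")
  expect_identical(inferActivityKind(blank(base, c("P4", "P3", "P2"))),
                   "aminopeptidase")
  expect_identical(inferActivityKind(blank(base, c("P2'", "P3'", "P4'"))),
                   "carboxypeptidase")
  expect_identical(
    inferActivityKind(blank(base, c("P4", "P3", "P2",
                                    "P2'", "P3'", "P4'"))),
    "dipeptidase")
  expect_identical(inferActivityKind(blank(base, c("P4", "P3"))),
                   "dipeptidyl_peptidase")
  expect_identical(inferActivityKind(blank(base, c("P3'", "P4'"))),
                   "peptidyl_dipeptidase")
  expect_identical(inferActivityKind(blank(base, "P4'")),
                   "peptidyl_tripeptidase_like")
  ## one occupied window keeps a site in existence at the default
  ## cutoff, so the pattern falls back to the next matching kind
  w <- blank(base, c("P4", "P3", "P2"))
  w[1, "P2"] <- "A"
  expect_identical(inferActivityKind(w), "dipeptidyl_peptidase")
  expect_identical(inferActivityKind(w, absenceCutoff = 0.9),
                   "aminopeptidase")
})

test_that("matrix rendering labels cells by the 10%/1% occupancy rules", {
  pc <- meropsGlobalSitePercentages
  ann <- renderMatrix(pc)
  lab <- as.data.frame(ann$labels)
  expect_identical(lab$label[lab$residue == "R" & lab$site == "P1"],
                   "high")   # 17%
  expect_identical(lab$label[lab$residue == "W" & lab$site == "P3"],
                   "low")    # 0.7%
  expect_identical(lab$label[lab$residue == "K" & lab$site == "P2"],
                   "plain")  # 5%
  ## boundary: exactly 10% is high, exactly 1% is plain
  toy <- matrix(10, 22, 8, dimnames = dimnames(pc))
  toy["C", ] <- 1
  annToy <- renderMatrix(toy)$labels
  expect_true(all(annToy$label[annToy$residue == "A"] == "high"))
  expect_true(all(annToy$label[annToy$residue == "C"] == "plain"))
  ## "-" and "X" rows are never labelled
  expect_false(any(ann$labels$residue %in% c("-", "X")))
  expect_length(ann$text, 23L)
})

test_that("specificityReport bundles findings and honours thresholds", {
  spec <- peptidaseSpec("A01.009", 60, activityKind = "aminopeptidase",
    plantedRestrictions = list(list(site = "P1'",
                                    residues = c("L", "F"))))
  cs <- generateCollection(spec, seed = 91)
  rep <- specificityReport(cs)
  expect_s4_class(rep, "SpecificityReport")
  expect_identical(peptidase(rep), "A01.009")
  expect_identical(activityKind(rep), "aminopeptidase")
  expect_true(hasFinding(findings(rep), "P1'", "restricted_residues",
                         c("F", "L")))
  ## too few cleavages: no findings, kind undetermined
  small <- specificityReport(cs[1:10])
  expect_identical(nrow(findings(small)), 0L)
  expect_true(is.na(activityKind(small)))
})
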