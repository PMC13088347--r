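test_that("the declared rule evaluates to its closed form", {
  # poly-A: all composition terms zero -> logistic(intercept)
  expect_equal(groundTruthPSScore(ProteinSequence("a", strrep("A", 20)))$score,
               plogis(-2), tolerance = 1e-12)
  expect_equal(groundTruthPSScore(ProteinSequence("a", strrep("A", 20)))$label,
               0)
  # all-aromatic: fArom = 1 -> logistic(8 - 2)
  expect_equal(groundTruthPSScore(ProteinSequence("y", strrep("Y", 10)))$score,
               plogis(6), tolerance = 1e-12)
  expect_equal(groundTruthPSScore(ProteinSequence("y", strrep("Y", 10)))$label,
               1)
  # G/S window term: 8 contiguous G in 16 fills one window -> logistic(4 - 2)
  expect_equal(groundTruthPSScore(
    ProteinSequence("g", paste0(strrep("G", 8), strrep("A", 8))))$score,
    plogis(2), tolerance = 1e-12)
  # charge term: 4 K in 16 -> logistic(-3 * 4/16 - 2)
  expect_equal(groundTruthPSScore(
    ProteinSequence("k", paste0(strrep("K", 4), strrep("A", 12))))$score,
    plogis(-3 * 0.25 - 2), tolerance = 1e-12)
})

test_that("the rule is invariant to sequence reversal", {
  for (i in 1:20) {
    s <- randomSequence(30, seed = i)
    rev <- paste(rev(strsplit(residues(s), "")[[1]]), collapse = "")
    expect_equal(groundTruthPSScore(ProteinSequence("r", rev))$score,
                 groundTruthPSScore(s)$score)
  }
})

test_that("ideal-helix contact maps equal the closed-form band", {
  expect_equal(helixBandWidth(), 6L)
  geoms <- list(c(1.5, 100, 2.3), c(1.2, 120, 2.0), c(2.0, 99.1, 1.5))
  for (g in geoms) {
    s <- helixBandWidth(10, g[1], g[2], g[3])
    st <- generateToyStructure("helix", 30, rise = g[1], turnDeg = g[2],
                               radius = g[3], seed = 1)
    e <- contactEntries(computeRCM(st))
    band <- (abs(outer(1:30, 1:30, "-")) <= s) * 1
    expect_identical(unname(e), band)
    # cross-check against the raw distance oracle
    d <- as.matrix(stats::dist(calphaCoords(st)))
    expect_identical(unname(e == 1), unname(d <= 10))
  }
})

test_that("self-avoiding chains respect step length and exclusion", {
  st <- generateToyStructure("chain", 50, seed = 12)
  co <- calphaCoords(st)
  steps <- sqrt(rowSums((co[-1, ] - co[-50, ])^2))
  expect_equal(steps, rep(3.8, 49), tolerance = 1e-9)
  d <- as.matrix(stats::dist(co))
  nonadj <- abs(outer(1:50, 1:50, "-")) > 1
  expect_true(min(d[nonadj & upper.tri(d)]) >= 3.0)
})

test_that("generators are bit-reproducible under seed", {
  a <- generateToyStructure("chain", 20, seed = 5)
  b <- generateToyStructure("chain", 20, seed = 5)
  expect_identical(calphaCoords(a), calphaCoords(b))
  c2 <- generateToyStructure("chain", 20, seed = 6)
  expect_false(identical(calphaCoords(a), calphaCoords(c2)))

  d1 <- sampleLabeledDatasets(12, 8, 8, seed = 3)
  d2 <- sampleLabeledDatasets(12, 8, 8, seed = 3)
  expect_identical(vapply(d1$target, `[[`, character(1), "key"),
                   vapply(d2$target, `[[`, character(1), "key"))
  d3 <- sampleLabeledDatasets(12, 8, 8, seed = 4)
  expect_false(identical(vapply(d1$target, `[[`, character(1), "key"),
                         vapply(d3$target, `[[`, character(1), "key")))
})

test_that("every generated label is recomputable from the closed form", {
  ds <- sampleLabeledDatasets(30, 16, 16, seed = 17)
  rule <- syntheticRuleConfig()
  for (r in ds$target) {
    delta <- abs(groundTruthPSScore(r$seq, rule)$score -
                   groundTruthPSScore(r$parent, rule)$score)
    expect_equal(r$label, as.numeric(delta >= rule$deltaThreshold))
    # the key token reproduces the mutant from the parent
    expect_identical(residues(applyMutations(r$parent, r$key)),
                     residues(r$seq))
  }
  a1rule <- pathogenicityRuleConfig()
  for (r in ds$aux1$records) {
    expect_equal(r$label, groundTruthPSScore(r$seq, a1rule)$label)
  }
  for (r in ds$aux2$records) {
    expect_equal(r$label, groundTruthPSScore(r$seq)$label)
  }
  # class balance within the documented band
  for (set in list(ds$target, ds$aux1$records, ds$aux2$records)) {
    bal <- mean(vapply(set, `[[`, numeric(1), "label"))
    expect_gte(bal, 0.4)
    expect_lte(bal, 0.6)
  }
})

test_that("the retraining panel is exactly 1:1 with valid distinct tokens", {
  mp <- makeRetrainingPanel(seed = 2)
  expect_equal(nrow(mp$panel), 138L)
  expect_equal(sum(mp$panel$label == 1), 69L)
  expect_equal(sum(mp$panel$label == 0), 69L)
  expect_false(anyDuplicated(mp$panel$token) > 0)
  for (i in seq_len(nrow(mp$panel))) {
    mut <- applyMutations(mp$parent, mp$panel$token[i])
    delta <- abs(groundTruthPSScore(mut, mp$rule)$score -
                   groundTruthPSScore(mp$parent, mp$rule)$score)
    expect_equal(mp$panel$label[i],
                 as.numeric(delta >= mp$rule$deltaThreshold))
  }
  small <- makeRetrainingPanel(n = 10, seed = 3)
  expect_equal(sum(small$panel$label), 5)
  expect_error(makeRetrainingPanel(n = 7), "even")
})

test_that("the band graph builder reproduces helix connectivity", {
  gb <- bandGraphBuilder(6)
  s <- randomSequence(20, seed = 44)
  g <- gb(s)
  sep <- graphEdges(g)[, 2] - graphEdges(g)[, 1]
  expect_true(all(sep <= 6))
  expect_equal(sum(sep == 1), 19)
  # edge count = sum over separations 1..6
  expect_equal(nrow(graphEdges(g)), sum(sapply(1:6, function(k) 20 - k)))
})

test_that("fixture bundles land on disk in consumable formats", {
  out <- tempfile("fix")
  paths <- makeFixtures(out, seed = 10)
  expect_true(all(file.exists(unlist(paths))))
  # the PDB round-trips through the C-alpha reader (3-decimal precision)
  st <- readCalpha(paths$helix_pdb, chain = "A")
  helix <- generateToyStructure("helix", 30,
                                seed = llpsdesign:::deriveSeed(10, 1))
  expect_equal(calphaCoords(st), calphaCoords(helix), tolerance = 1e-3)
  expect_equal(residues(structureSequence(st)),
               residues(structureSequence(helix)))
  panel <- readMutationTable(paths$panel)
  expect_equal(nrow(panel), 138L)
  rcm <- readRCM(paths$rcm)
  expect_equal(nResidues(rcm), 30L)
})
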