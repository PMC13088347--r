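test_that("C-alpha reading reproduces a hand-written fixture", {
  m <- readCalpha(threeResiduePDB(), chain = "A")
  expect_equal(unname(calphaCoords(m)),
               rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 12)))
  expect_equal(residues(structureSequence(m)), "AGS")
  expect_true(all(resolvedMask(m)))
})

test_that("residues without a C-alpha record come back unresolved", {
  p <- writePDBLines(c(
    atomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atomLine(2, "N", "GLY", "A", 2, 0, 0, 2),   # no CA for residue 2
    atomLine(3, "CA", "SER", "A", 3, 0, 0, 12)))
  m <- readCalpha(p, chain = "A")
  expect_equal(resolvedMask(m), c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(calphaCoords(m)[2, ])))
})

test_that("altlocs resolve to highest occupancy, first on ties", {
  p <- writePDBLines(c(
    atomLine(1, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.6, alt = "A"),
    atomLine(2, "CA", "ALA", "A", 1, 9, 0, 0, occ = 0.4, alt = "B"),
    atomLine(3, "CA", "GLY", "A", 2, 0, 0, 5)))
  m <- readCalpha(p, chain = "A")
  expect_equal(calphaCoords(m)[1, 1], 1)

  ptie <- writePDBLines(c(
    atomLine(1, "CA", "ALA", "A", 1, 2, 0, 0, occ = 0.5, alt = "A"),
    atomLine(2, "CA", "ALA", "A", 1, 7, 0, 0, occ = 0.5, alt = "B"),
    atomLine(3, "CA", "GLY", "A", 2, 0, 0, 5)))
  mt <- readCalpha(ptie, chain = "A")
  expect_equal(calphaCoords(mt)[1, 1], 2)
})

test_that("missing chains and C-alpha-free files are structured errors", {
  p <- threeResiduePDB()
  expect_error(readCalpha(p, chain = "B"), "chain 'B' not found")
  pn <- writePDBLines(atomLine(1, "N", "ALA", "A", 1, 0, 0, 0))
  expect_error(readCalpha(pn, chain = "A"), "no C-alpha")
})

test_that("the contact rule is inclusive at 10 Angstrom with diagonal 1", {
  s <- ProteinSequence("t", "AAA")
  m <- StructureModel(s, rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 12)))
  e <- contactEntries(computeRCM(m))
  expect_equal(e[1, 2], 1)  # 5 A
  expect_equal(e[2, 3], 1)  # 7 A
  expect_equal(e[1, 3], 0)  # 12 A
  expect_equal(diag(e), rep(1, 3))
  # boundary: exactly 10 A is a contact
  mb <- StructureModel(ProteinSequence("b", "AA"),
                       rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(contactEntries(computeRCM(mb))[1, 2], 1)
  expect_error(computeRCM(m, threshold = -1), "positive")
})

test_that("a single resolved residue yields the 1x1 diagonal matrix", {
  m <- StructureModel(ProteinSequence("one", "W"), rbind(c(1, 2, 3)))
  expect_equal(contactEntries(computeRCM(m)), matrix(1, 1, 1))
})

test_that("unresolved residues are masked, never zero-filled", {
  s <- ProteinSequence("t", "AAAA")
  co <- rbind(c(0, 0, 0), c(NA, NA, NA), c(0, 0, 3), c(0, 0, 20))
  m <- StructureModel(s, co)
  rcm <- computeRCM(m)
  expect_equal(contactMask(rcm), c(TRUE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(contactEntries(rcm)[2, ])))
  expect_true(all(is.na(contactEntries(rcm)[, 2])))
  expect_equal(contactEntries(rcm)[1, 3], 1)
  expect_equal(contactEntries(rcm)[3, 4], 0)
})

test_that("contact matrices equal the brute-force distance oracle", {
  for (i in 1:20) {
    st <- randomCloudStructure(sample(10:80, 1), seed = i)
    rcm <- computeRCM(st)
    d <- as.matrix(stats::dist(calphaCoords(st)))
    expect_identical(unname(contactEntries(rcm) == 1),
                     unname(d <= 10))
    expect_identical(contactEntries(rcm), t(contactEntries(rcm)))
    expect_true(all(contactEntries(rcm) %in% c(0, 1)))
  }
})

test_that("edge sets grow monotonically with the threshold", {
  st <- randomCloudStructure(40, seed = 99)
  for (pair in list(c(5, 8), c(8, 10), c(10, 14))) {
    e1 <- contactEntries(computeRCM(st, pair[1]))
    e2 <- contactEntries(computeRCM(st, pair[2]))
    expect_true(all(e2[e1 == 1] == 1))
  }
})

test_that("residue graphs take contacts plus guaranteed backbone edges", {
  s <- ProteinSequence("t", "AAA")
  m <- StructureModel(s, rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 12)))
  g <- buildResidueGraph(computeRCM(m), s)
  expect_equal(unname(graphEdges(g)), rbind(c(1L, 2L), c(2L, 3L)))
  expect_true(all(backboneEdges(g)))

  # all-zero off-diagonal: backbone only
  s4 <- ProteinSequence("t", "AAAA")
  e <- diag(4)
  rcm0 <- new("ResidueContactMatrix", entries = e, threshold = 10,
              mask = rep(TRUE, 4))
  g0 <- buildResidueGraph(rcm0, s4)
  expect_equal(unname(graphEdges(g0)),
               rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
})

test_that("graph edge count equals the union oracle on random matrices", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 30
    up <- matrix(0, n, n)
    up[upper.tri(up)] <- rbinom(n * (n - 1) / 2, 1, 0.1)
    e <- up + t(up) + diag(n)
    rcm <- new("ResidueContactMatrix", entries = e, threshold = 10,
               mask = rep(TRUE, n))
    s <- randomSequence(n, seed = rep)
    g <- buildResidueGraph(rcm, s)
    contacts <- which(upper.tri(e) & e == 1, arr.ind = TRUE)
    union_ct <- unique(rbind(contacts,
                             cbind(seq_len(n - 1), seq_len(n - 1) + 1L)))
    expect_equal(nrow(graphEdges(g)), nrow(union_ct))
    # every node has an incident edge
    expect_true(all(seq_len(n) %in% as.vector(graphEdges(g))))
  }
})

test_that("graph construction commutes with residue relabeling", {
  st <- randomCloudStructure(20, seed = 55)
  rcm <- computeRCM(st)
  seq <- structureSequence(st)
  g <- buildResidueGraph(rcm, seq)
  set.seed(6)
  perm <- sample(20)
  # build from permuted inputs
  inv <- order(perm)
  e2 <- contactEntries(rcm)[inv, inv]
  rcm2 <- new("ResidueContactMatrix", entries = e2, threshold = 10,
              mask = contactMask(rcm)[inv])
  chars <- strsplit(residues(seq), "")[[1]]
  seq2 <- ProteinSequence("perm", paste(chars[inv], collapse = ""))
  gPermBuild <- buildResidueGraph(rcm2, seq2)
  # note: backbone edges are positional, so compare contact edges only
  ce1 <- graphEdges(g)[!backboneEdges(g) |
                         contactEntries(rcm)[graphEdges(g)] == 1, ,
                       drop = FALSE]
  pe <- cbind(perm[ce1[, 1]], perm[ce1[, 2]])
  swap <- pe[, 1] > pe[, 2]
  pe[swap, ] <- pe[swap, c(2, 1)]
  ce2 <- graphEdges(gPermBuild)[
    contactEntries(rcm2)[graphEdges(gPermBuild)] == 1, , drop = FALSE]
  expect_setequal(paste(pe[, 1], pe[, 2]), paste(ce2[, 1], ce2[, 2]))
})

test_that("graph building validates dimensions", {
  st <- randomCloudStructure(10, seed = 1)
  expect_error(buildResidueGraph(computeRCM(st), randomSequence(9, seed = 2)),
               "does not match")
})

test_that("node features are finite with one row per amino acid", {
  ft <- nodeFeatureTable()
  expect_equal(dim(ft), c(20L, 24L))
  expect_true(all(is.finite(ft)))
  expect_equal(rownames(ft), llpsdesign:::AA20)
  # one-hot block
  expect_equal(unname(ft[, 1:20]), diag(20))
})

test_that("contact matrices round-trip through the text format", {
  st <- randomCloudStructure(15, seed = 8)
  rcm <- computeRCM(st, threshold = 9.5)
  path <- tempfile(fileext = ".txt")
  writeRCM(rcm, path)
  back <- readRCM(path)
  expect_equal(contactEntries(back), contactEntries(rcm))
  expect_equal(contactThreshold(back), 9.5)
  g <- buildResidueGraph(rcm, structureSequence(st))
  ep <- tempfile(fileext = ".txt")
  writeEdgeList(g, ep)
  df <- utils::read.table(ep, header = TRUE)
  expect_equal(nrow(df), nrow(graphEdges(g)))
})
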