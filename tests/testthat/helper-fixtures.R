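# Shared fixtures: tiny PDB files written on the fly and small random
# structures. All randomness is seeded per call site.

writePDBLines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# one ATOM record in fixed-width PDB format
atomLine <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1.00, alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", name), alt, resname, chain, resno, x, y, z,
          occ, 0.0)
}

# the 3-residue fixture with C-alpha at (0,0,0), (0,0,5), (0,0,12)
threeResiduePDB <- function() {
  writePDBLines(c(
    atomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atomLine(2, "CA", "GLY", "A", 2, 0, 0, 5),
    atomLine(3, "CA", "SER", "A", 3, 0, 0, 12)))
}

randomCloudStructure <- function(n, seed, spread = 12) {
  set.seed(seed)
  seq <- ProteinSequence(paste0("cloud", seed),
                         paste(sample(llpsdesign:::AA20, n, replace = TRUE),
                               collapse = ""))
  StructureModel(seq, matrix(stats::runif(n * 3, 0, spread), n, 3))
}

# independent string-edit oracle: applies tokens in descending position
# order using plain substring surgery
stringEditOracle <- function(residueString, tokens) {
  pos <- as.integer(gsub("[^0-9]", "", tokens))
  for (k in order(pos, decreasing = TRUE)) {
    tok <- tokens[k]
    p <- pos[k]
    if (grepl("-$", tok)) {
      residueString <- paste0(substr(residueString, 1, p - 1),
                              substr(residueString, p + 1,
                                     nchar(residueString)))
    } else {
      alt <- substr(tok, nchar(tok), nchar(tok))
      substr(residueString, p, p) <- alt
    }
  }
  residueString
}

# numerical gradient of fn at params[[nm]][k]
numGrad <- function(fn, params, nm, k, eps = 1e-6) {
  p1 <- params
  p1[[nm]][k] <- p1[[nm]][k] + eps
  p2 <- params
  p2[[nm]][k] <- p2[[nm]][k] - eps
  (fn(p1) - fn(p2)) / (2 * eps)
}

relErr <- function(a, b) abs(a - b) / max(1e-8, abs(a) + abs(b))

# permute a residue graph's node labels with permutation perm (new index of
# old node i is perm[i])
permuteGraph <- function(g, perm) {
  nf <- nodeFeatures(g)
  nf2 <- nf
  nf2[perm, ] <- nf
  e <- graphEdges(g)
  e2 <- cbind(perm[e[, 1]], perm[e[, 2]])
  swap <- e2[, 1] > e2[, 2]
  e2[swap, ] <- e2[swap, c(2, 1)]
  ord <- order(e2[, 1], e2[, 2])
  new("ResidueGraph", nodeFeatures = nf2,
      edges = matrix(as.integer(e2[ord, ]), ncol = 2),
      backbone = backboneEdges(g)[ord])
}
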