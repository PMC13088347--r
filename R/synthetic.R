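# Synthetic-fixture generators. They define the study conditions for every
# test in the package: toy chain structures with analytically known contact
# maps, a DECLARED closed-form ground-truth PS scoring rule for sequences
# (the test oracle, not a scientific claim), labeled pretraining and
# auxiliary datasets, and a protein-specific retraining panel of 138
# mutants at exact 1:1 class balance.

#' Declared ground-truth scoring rule
#'
#' `score = logistic(wAromatic * fArom + wGS * fGSwin - wCharge * fCharge +
#' intercept)` where `fArom` is the aromatic (F/W/Y) fraction, `fGSwin` the
#' highest glycine/serine fraction over any contiguous window of `window`
#' residues (low-complexity surrogate), and `fCharge` the absolute net
#' charge per residue (D/E = -1, K/R = +1). The defaults (8, 4, 3, -2) are
#' the printed study conditions; `deltaThreshold` is the probability-scale
#' change that counts as a "significant PS-ability change" for mutant
#' labels.
#'
#' @param wAromatic,wGS,wCharge,intercept rule weights.
#' @param window low-complexity window length in residues.
#' @param deltaThreshold significance threshold on the probability scale.
#' @return A named list of class `SyntheticRule`.
#' @export
syntheticRuleConfig <- function(wAromatic = 8, wGS = 4, wCharge = 3,
                                intercept = -2, window = 8,
                                deltaThreshold = 0.1) {
  stopifnot(window >= 1, deltaThreshold > 0, deltaThreshold < 1)
  structure(list(wAromatic = wAromatic, wGS = wGS, wCharge = wCharge,
                 intercept = intercept, window = window,
                 deltaThreshold = deltaThreshold),
            class = "SyntheticRule")
}

#' The target-shifted rule used for transfer-learning benchmarks
#'
#' Perturbs the base rule by `wAromatic - 4` and `wCharge + 2` so a model
#' pretrained on the base rule is measurably mis-calibrated on the target
#' protein.
#'
#' @param rule base rule (default [syntheticRuleConfig()]).
#' @return A `SyntheticRule`.
#' @export
shiftedRuleConfig <- function(rule = syntheticRuleConfig()) {
  rule$wAromatic <- rule$wAromatic - 4
  rule$wCharge <- rule$wCharge + 2
  rule
}

#' The correlated pathogenicity-surrogate rule
#'
#' Same closed form with mildly perturbed weights
#' (`wAromatic - 2`, `wGS + 1`, `wCharge + 1`).
#'
#' @param rule base rule.
#' @return A `SyntheticRule`.
#' @export
pathogenicityRuleConfig <- function(rule = syntheticRuleConfig()) {
  rule$wAromatic <- rule$wAromatic - 2
  rule$wGS <- rule$wGS + 1
  rule$wCharge <- rule$wCharge + 1
  rule
}

ruleLogit <- function(chars, rule) {
  L <- length(chars)
  fArom <- mean(chars %in% AROMATIC_AA)
  w <- min(rule$window, L)
  isGS <- as.numeric(chars %in% c("G", "S"))
  cs <- cumsum(c(0, isGS))
  fGS <- max(cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  fCharge <- abs(sum(AA_CHARGE[chars])) / L
  rule$wAromatic * fArom + rule$wGS * fGS - rule$wCharge * fCharge +
    rule$intercept
}

#' Ground-truth PS score and label of a sequence
#'
#' Pure, deterministic evaluation of the declared closed form; the label is
#' `score >= 0.5`.
#'
#' @param seq a [ProteinSequence-class] or residue string.
#' @param rule a [syntheticRuleConfig()].
#' @return List with `score` in `[0,1]` and binary `label`.
#' @examples
#' groundTruthPSScore(ProteinSequence("polyA", strrep("A", 20)))$score
#' @export
groundTruthPSScore <- function(seq, rule = syntheticRuleConfig()) {
  chars <- if (is(seq, "ProteinSequence")) residueChars(seq)
           else strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% AA20)) stopf("non-canonical residues in sequence")
  s <- logistic(ruleLogit(chars, rule))
  list(score = s, label = as.numeric(s >= 0.5))
}

helixCoordinates <- function(n, rise = 1.5, turnDeg = 100, radius = 2.3) {
  i <- seq_len(n) - 1
  theta <- i * turnDeg * pi / 180
  cbind(radius * cos(theta), radius * sin(theta), rise * i)
}

#' Closed-form contact band width of an ideal helix
#'
#' For the ideal helix parameterization (radius `r`, per-residue rise and
#' turn), the C-alpha distance at sequence separation `k` is
#' `sqrt((rise k)^2 + 2 r^2 (1 - cos(k turn)))`, monotone-dominated by the
#' axial term, so the contact map under a distance threshold is exactly the
#' band `|i - j| <= s` with `s` the largest separation whose distance stays
#' within the threshold.
#'
#' @param threshold contact cutoff in Angstrom.
#' @param rise rise per residue (Angstrom).
#' @param turnDeg turn per residue (degrees).
#' @param radius helix radius (Angstrom).
#' @return Integer band half-width `s`.
#' @export
helixBandWidth <- function(threshold = 10, rise = 1.5, turnDeg = 100,
                           radius = 2.3) {
  kmax <- ceiling(threshold / rise)
  d <- function(k) sqrt((rise * k)^2 +
                          2 * radius^2 * (1 - cos(k * turnDeg * pi / 180)))
  s <- 0L
  for (k in seq_len(kmax + 1)) {
    if (d(k) <= threshold) s <- k else break
  }
  s
}

#' Generate a random sequence
#'
#' @param n length.
#' @param seed integer seed.
#' @param alphabet residue pool (default all 20).
#' @return A [ProteinSequence-class].
#' @export
randomSequence <- function(n, seed = NULL, alphabet = AA20) {
  withSeed(seed, ProteinSequence(
    sprintf("rnd%d", stats::rbinom(1, 1e6, 0.5)),
    paste(sample(alphabet, n, replace = TRUE), collapse = "")))
}

#' Generate a toy chain structure
#'
#' Two families: `"helix"` (ideal helix; its contact map is the closed-form
#' band of [helixBandWidth()]) and `"chain"` (a self-avoiding random chain
#' with fixed step length and an exclusion radius; generation errors out if
#' self-avoidance cannot be satisfied after bounded retries).
#'
#' @param family `"helix"` or `"chain"`.
#' @param n chain length (>= 2).
#' @param seq optional [ProteinSequence-class]; a random sequence of length
#'   `n` is drawn otherwise.
#' @param rise,turnDeg,radius helix geometry.
#' @param step,exclusion chain geometry (Angstrom).
#' @param seed integer seed.
#' @return A [StructureModel-class].
#' @export
generateToyStructure <- function(family = c("helix", "chain"), n,
                                 seq = NULL, rise = 1.5, turnDeg = 100,
                                 radius = 2.3, step = 3.8, exclusion = 3.0,
                                 seed = NULL) {
  family <- match.arg(family)
  stopifnot(n >= 2)
  withSeed(seed, {
    if (is.null(seq)) {
      seq <- ProteinSequence(sprintf("%s%d", family, n),
                             paste(sample(AA20, n, replace = TRUE),
                                   collapse = ""))
    }
    if (seqLength(seq) != n) stopf("sequence length must equal n")
    coords <- if (family == "helix") {
      helixCoordinates(n, rise, turnDeg, radius)
    } else {
      selfAvoidingChain(n, step, exclusion)
    }
    StructureModel(seq, coords)
  })
}

selfAvoidingChain <- function(n, step, exclusion, maxTries = 200) {
  for (attempt in seq_len(20)) {
    coords <- matrix(NA_real_, n, 3)
    coords[1, ] <- 0
    ok <- TRUE
    for (i in seq_len(n - 1) + 1) {
      placed <- FALSE
      for (t in seq_len(maxTries)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- coords[i - 1, ] + step * u
        prev <- coords[seq_len(i - 2), , drop = FALSE]
        if (nrow(prev) == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= exclusion) {
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(coords)
  }
  stopf("could not generate a self-avoiding chain of length %d", n)
}

#' Graph builder with band contacts
#'
#' Returns a function mapping a sequence to a [ResidueGraph-class] whose
#' edges are all pairs with `|i - j| <= bandWidth` — the contact pattern of
#' the ideal-helix family. Used to attach deterministic, analytically known
#' contact structure to generated sequences.
#'
#' @param bandWidth band half-width (default: the ideal-helix band under
#'   the 10 Angstrom rule).
#' @param features node feature table.
#' @return `function(seq) -> ResidueGraph`.
#' @export
bandGraphBuilder <- function(bandWidth = helixBandWidth(),
                             features = nodeFeatureTable()) {
  force(bandWidth)
  force(features)
  function(seq) {
    n <- seqLength(seq)
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ij <- ij[(ij[, 2] - ij[, 1]) <= bandWidth, , drop = FALSE]
    ord <- order(ij[, 1], ij[, 2])
    ij <- ij[ord, , drop = FALSE]
    storage.mode(ij) <- "integer"
    dimnames(ij) <- NULL
    chars <- residueChars(seq)
    feat <- features[chars, , drop = FALSE]
    rownames(feat) <- NULL
    new("ResidueGraph", nodeFeatures = feat, edges = ij,
        backbone = (ij[, 2] - ij[, 1]) == 1L)
  }
}

#' Paired sequence/contact-matrix examples from the helix family
#'
#' Random sequences on ideal-helix backbones with the matching contact
#' matrices — the pseudo-label training set for the contact predictor.
#'
#' @param n number of examples.
#' @param lengthRange inclusive range of chain lengths.
#' @param seed integer seed.
#' @param threshold contact threshold in Angstrom.
#' @return List of examples `list(seq =, rcm =)`.
#' @export
helixExamples <- function(n, lengthRange = c(30, 60), seed = 1,
                          threshold = 10) {
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      L <- sample(lengthRange[1]:lengthRange[2], 1)
      st <- generateToyStructure("helix", L)
      list(seq = structureSequence(st), rcm = computeRCM(st, threshold))
    })
  })
}

# neutral residues: no aromatic, no G/S, no charge
NEUTRAL_AA <- setdiff(AA20, c(AROMATIC_AA, "G", "S", "D", "E", "K", "R"))

# Construct a sequence whose rule logit falls in [lo, hi]: a contiguous G/S
# block plus scattered aromatic and charged residues on a neutral
# background. Enumerate feasible composition triples, pick one uniformly,
# then place residues at random.
composeSequence <- function(L, rule, lo, hi, id = "syn") {
  w <- min(rule$window, L)
  grid <- expand.grid(a = 0:min(6, L), g = 0:w, c = 0:min(4, L))
  grid <- grid[grid$a + grid$g + grid$c <= L, , drop = FALSE]
  lg <- rule$wAromatic * grid$a / L + rule$wGS * grid$g / w -
    rule$wCharge * grid$c / L + rule$intercept
  feas <- which(lg >= lo & lg <= hi)
  if (!length(feas)) stopf("no feasible composition for logit in [%g, %g]",
                           lo, hi)
  pick <- grid[if (length(feas) == 1) feas else sample(feas, 1), ]
  chars <- sample(NEUTRAL_AA, L, replace = TRUE)
  off <- sample.int(L - pick$g + 1, 1)
  if (pick$g > 0) {
    chars[off:(off + pick$g - 1)] <- sample(c("G", "S"), pick$g,
                                            replace = TRUE)
  }
  rest <- setdiff(seq_len(L), if (pick$g > 0) off:(off + pick$g - 1)
                  else integer(0))
  extra <- sample(rest, pick$a + pick$c)
  if (pick$a > 0) {
    chars[extra[seq_len(pick$a)]] <- sample(AROMATIC_AA, pick$a,
                                            replace = TRUE)
  }
  if (pick$c > 0) {
    chars[extra[pick$a + seq_len(pick$c)]] <- sample(c("K", "R"), pick$c,
                                                     replace = TRUE)
  }
  ProteinSequence(id, paste(chars, collapse = ""))
}

# Fast enumeration of all single-site edits (19L substitutions + L
# deletions) with the rule's score change; avoids S4 construction so whole
# panels can be scanned cheaply. Returns token and signed delta.
ruleScanSingleEdits <- function(chars, rule) {
  L <- length(chars)
  s0 <- logistic(ruleLogit(chars, rule))
  tokens <- character(0)
  deltas <- numeric(0)
  for (pos in seq_len(L)) {
    for (alt in setdiff(AA20, chars[pos])) {
      v <- chars
      v[pos] <- alt
      tokens <- c(tokens, paste0(chars[pos], pos, alt))
      deltas <- c(deltas, logistic(ruleLogit(v, rule)) - s0)
    }
    v <- chars[-pos]
    tokens <- c(tokens, paste0(chars[pos], pos, "-"))
    deltas <- c(deltas, logistic(ruleLogit(v, rule)) - s0)
  }
  data.frame(token = tokens, delta = deltas)
}

# draw one target record of the requested class: a near-boundary parent is
# generated, every single-site edit is enumerated and labeled by the rule's
# score change, and one edit of the wanted class is sampled uniformly;
# parents admitting no edit of that class are redrawn (bounded).
drawTargetRecord <- function(i, want, rule, seqLen, graphBuilder) {
  for (try in seq_len(40)) {
    parent <- composeSequence(seqLen, rule, -0.7, 0.7,
                              id = sprintf("t%d", i))
    scan <- ruleScanSingleEdits(residueChars(parent), rule)
    # separability margin: negatives keep a clear distance below the
    # significance threshold rather than crowding the boundary
    pool <- if (want) {
      scan$token[abs(scan$delta) >= rule$deltaThreshold]
    } else {
      scan$token[abs(scan$delta) <= rule$deltaThreshold / 2]
    }
    if (!length(pool)) next
    tok <- if (length(pool) == 1) pool else sample(pool, 1)
    mut <- applyMutations(parent, tok)
    return(list(graph = graphBuilder(mut), ref = graphBuilder(parent),
                label = as.numeric(want), key = tok, seq = mut,
                parent = parent))
  }
  stopf("could not draw a target record of class %d", want)
}

#' Sample the target and auxiliary labeled datasets
#'
#' The target task: single-edit mutants of near-boundary parents, labeled
#' positive when the rule's score changes by at least `deltaThreshold`
#' (significant PS-ability change); classes alternate so the panel is
#' balanced by construction, with edits of the wanted class drawn uniformly
#' from the parent's full single-site edit space. The first auxiliary task:
#' sequences labeled by the correlated pathogenicity-surrogate rule. The
#' second: sequences labeled directly by the base rule (PS vs non-PS
#' surrogate). Class balance is verified to lie within 40-60%; every label
#' is recomputable from the declared closed forms. Graphs carry the
#' ideal-helix band contact structure.
#'
#' @param nTarget,nAux1,nAux2 record counts (>= 4).
#' @param seed integer seed.
#' @param rule base [syntheticRuleConfig()].
#' @param seqLen sequence length of generated records.
#' @param graphBuilder function mapping sequences to graphs.
#' @return List with `target` (records with `graph`, `ref`, `label`,
#'   `key`, `seq`, `parent`), `aux1`, `aux2` (each an
#'   [auxiliaryDataset()]).
#' @export
sampleLabeledDatasets <- function(nTarget = 200, nAux1 = 100, nAux2 = 100,
                                  seed = 1, rule = syntheticRuleConfig(),
                                  seqLen = 24,
                                  graphBuilder = bandGraphBuilder()) {
  stopifnot(nTarget >= 4, nAux1 >= 4, nAux2 >= 4)
  withSeed(seed, {
    target <- balancedResample(nTarget, function(i) {
      drawTargetRecord(i, want = i %% 2, rule = rule, seqLen = seqLen,
                       graphBuilder = graphBuilder)
    })
    a1rule <- pathogenicityRuleConfig(rule)
    drawLabeled <- function(i, rl, prefix) {
      want <- i %% 2
      rng <- if (want == 1) c(0.05, 3) else c(-3, -0.05)
      s <- composeSequence(seqLen, rl, rng[1], rng[2],
                           id = sprintf("%s%d", prefix, i))
      list(graph = graphBuilder(s),
           label = groundTruthPSScore(s, rl)$label, seq = s)
    }
    aux1 <- balancedResample(nAux1, function(i) drawLabeled(i, a1rule, "a1_"))
    aux2 <- balancedResample(nAux2, function(i) drawLabeled(i, rule, "a2_"))
    list(target = target,
         aux1 = auxiliaryDataset("pathogenicity", aux1),
         aux2 = auxiliaryDataset("ps_classification", aux2))
  })
}

# draw n records with balance in [0.4, 0.6], resampling whole batches a
# bounded number of times
balancedResample <- function(n, drawOne, maxRounds = 50) {
  for (round in seq_len(maxRounds)) {
    recs <- lapply(seq_len(n), drawOne)
    labs <- vapply(recs, function(r) r$label, numeric(1))
    bal <- mean(labs)
    if (bal >= 0.4 && bal <= 0.6) return(recs)
  }
  stopf("class balance 40-60%% unreachable after %d rounds", maxRounds)
}

#' Build a protein-specific retraining panel
#'
#' Exactly `n` single-site mutants of one parent with exactly `n/2`
#' positive and `n/2` negative labels (1:1 class ratio), the positives
#' being mutations whose score under the target-shifted rule changes by at
#' least `deltaThreshold`. All single-site candidates (19L substitutions +
#' L deletions) are enumerated and labeled by the shifted rule; within each
#' class, edits whose significance status *differs* between the base rule
#' and the shifted rule are sampled first (the panel exists to expose
#' protein-specific behaviour a model pretrained on the base rule has not
#' seen), topped up with concordant edits, all without replacement — so
#' every token is distinct and validates against the parent.
#'
#' @param parent parent [ProteinSequence-class] (length >= 20); a suitable
#'   near-boundary parent is generated when `NULL`.
#' @param n panel size (even; default 138).
#' @param seed integer seed.
#' @param rule the shifted rule (default [shiftedRuleConfig()]).
#' @param baseRule the rule the base model was pretrained on, used only to
#'   identify discordant edits.
#' @param parentLength length of the generated parent.
#' @return List with `panel` (data.frame `parent_id`, `token`, `label`),
#'   `parent`, and `rule`.
#' @export
makeRetrainingPanel <- function(parent = NULL, n = 138, seed = 1,
                                rule = shiftedRuleConfig(),
                                baseRule = syntheticRuleConfig(),
                                parentLength = 24) {
  if (n %% 2 != 0) stopf("a 1:1 panel needs an even n; got %d", n)
  withSeed(seed, {
    half <- n %/% 2
    generated <- is.null(parent)
    for (try in seq_len(if (generated) 50 else 1)) {
      if (generated) {
        parent <- composeSequence(parentLength, rule, -0.8, 0.6,
                                  id = "panel_parent")
      }
      if (seqLength(parent) < 20) {
        stopf("parent must have at least 20 residues")
      }
      scan <- ruleScanSingleEdits(residueChars(parent), rule)
      lab <- as.numeric(abs(scan$delta) >= rule$deltaThreshold)
      pos <- which(lab == 1)
      neg <- which(lab == 0)
      if (length(pos) >= half && length(neg) >= half) break
      if (!generated || try == 50) {
        stopf("parent admits only %d positive / %d negative single edits; %d each needed",
              length(pos), length(neg), half)
      }
    }
    baseScan <- ruleScanSingleEdits(residueChars(parent), baseRule)
    labBase <- as.numeric(abs(baseScan$delta) >= rule$deltaThreshold)
    discordant <- lab != labBase
    pickClass <- function(idx) {
      d <- idx[discordant[idx]]
      conc <- idx[!discordant[idx]]
      if (length(d) >= half) {
        sample(d, half)
      } else {
        c(d, sample(conc, half - length(d)))
      }
    }
    take <- sample(c(pickClass(pos), pickClass(neg)))  # shuffle row order
    panel <- data.frame(parent_id = seqId(parent),
                        token = scan$token[take],
                        label = lab[take])
    list(panel = panel, parent = parent, rule = rule)
  })
}

#' Write a bundle of fixtures to disk
#'
#' Emits FASTA sequences, toy-structure PDB files, a contact matrix in the
#' package's text format, and the retraining panel CSV — the formats every
#' other module consumes.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed.
#' @return Invisibly, the named list of written paths.
#' @export
makeFixtures <- function(outDir, seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  helix <- generateToyStructure("helix", 30, seed = deriveSeed(seed, 1))
  chain <- generateToyStructure("chain", 30, seed = deriveSeed(seed, 2))
  paths$helix_pdb <- file.path(outDir, "toy_helix.pdb")
  paths$chain_pdb <- file.path(outDir, "toy_chain.pdb")
  writeCalphaPDB(helix, paths$helix_pdb)
  writeCalphaPDB(chain, paths$chain_pdb)
  paths$fasta <- file.path(outDir, "sequences.fasta")
  writeProteinFasta(list(structureSequence(helix),
                         structureSequence(chain)), paths$fasta)
  paths$rcm <- file.path(outDir, "toy_helix_rcm.txt")
  writeRCM(computeRCM(helix), paths$rcm)
  mp <- makeRetrainingPanel(seed = deriveSeed(seed, 3))
  paths$panel <- file.path(outDir, "retraining_panel.csv")
  writeMutationTable(mp$panel, paths$panel)
  paths$panel_parent <- file.path(outDir, "panel_parent.fasta")
  writeProteinFasta(mp$parent, paths$panel_parent)
  invisible(paths)
}

#' Write C-alpha-only PDB for a structure model
#'
#' @param model a [StructureModel-class].
#' @param path output PDB path.
#' @return Invisibly, `path`.
#' @export
writeCalphaPDB <- function(model, path) {
  coords <- calphaCoords(model)
  keep <- resolvedMask(model)
  chars <- residueChars(structureSequence(model))
  aa3 <- bio3d::aa123(chars)
  idx <- which(keep)
  xyz <- as.vector(t(coords[idx, , drop = FALSE]))
  bio3d::write.pdb(file = path, xyz = xyz, resno = idx,
                   resid = aa3[idx], elety = rep("CA", length(idx)),
                   chain = rep("A", length(idx)))
  invisible(path)
}
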