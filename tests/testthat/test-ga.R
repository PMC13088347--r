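# plug-in oracle scorer: the declared synthetic rule
ruleScorer <- function(seq) groundTruthPSScore(seq)$score

test_that("fitness is the signed score difference with exact identities", {
  s1 <- ProteinSequence("a", "AAAA")
  s2 <- ProteinSequence("b", "WWWW")
  fv <- fitnessValue(s2, s1, function(x) {
    if (residues(x) == "WWWW") 0.82 else 0.31
  })
  expect_equal(fv$value, 0.51)
  expect_equal(fitnessValue(s1, s1, function(x) 0.42)$value, 0)
  expect_error(fitnessValue(s1, s2, function(x) 1.7), "\\[0,1\\]")
})

test_that("fitness stays in [-1, 1] over random candidates and scorers", {
  set.seed(13)
  parent <- randomSequence(12, seed = 1)
  # a deterministic pseudo-random scorer into [0,1]
  scorer <- function(x) {
    h <- sum(utf8ToInt(residues(x)) * seq_len(seqLength(x)))
    (h %% 1009) / 1008
  }
  scan <- exhaustiveSingleSiteScan(parent, scorer)  # 240 candidates
  expect_true(all(scan$fitness >= -1 & scan$fitness <= 1))
})

test_that("initial populations are valid, seeded, and uniform", {
  parent <- ProteinSequence("p", "ACDEFGHI")
  cfg <- gaConfig(populationSize = 10, maxEdits = 1, seed = 3)
  pop <- initializePopulation(parent, cfg)
  expect_length(pop, 10)
  for (cand in pop) {
    expect_length(cand, 1)
    expect_silent(applyMutations(parent, MutationSet(cand)))
  }
  pop2 <- initializePopulation(parent, cfg)
  expect_identical(lapply(pop, llpsdesign:::candKey),
                   lapply(pop2, llpsdesign:::candKey))

  # per-position frequencies over many single-edit draws are uniform
  big <- gaConfig(populationSize = 3000, maxEdits = 1, seed = 8)
  draws <- initializePopulation(parent, big)
  pos <- vapply(draws, function(c) mutationPosition(c[[1]]), integer(1))
  counts <- tabulate(pos, nbins = 8)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
  expect_error(initializePopulation(ProteinSequence("x", "AC"),
                                    gaConfig(maxEdits = 3)), "shorter")
})

test_that("the substitution-bias hook reweights alternative residues", {
  parent <- ProteinSequence("p", "ACDEFGHI")
  bias <- matrix(0, 20, 20, dimnames = list(llpsdesign:::AA20,
                                            llpsdesign:::AA20))
  bias[, "W"] <- 1  # all mass on tryptophan
  cfg <- gaConfig(populationSize = 30, maxEdits = 1,
                  allowedKinds = "substitution",
                  substitutionBias = bias, seed = 4)
  pop <- initializePopulation(parent, cfg)
  alts <- vapply(pop, function(c) altResidue(c[[1]]), character(1))
  expect_true(all(alts == "W"))
  # default remains uniform (many distinct alternatives appear)
  cfgU <- gaConfig(populationSize = 60, maxEdits = 1,
                   allowedKinds = "substitution", seed = 4)
  altsU <- vapply(initializePopulation(parent, cfgU),
                  function(c) altResidue(c[[1]]), character(1))
  expect_gt(length(unique(altsU)), 5)
  expect_error(gaConfig(substitutionBias = matrix(1, 2, 2)),
               "substitutionBias")
})

test_that("elites survive unchanged and best fitness never decreases", {
  parent <- randomSequence(10, seed = 5)
  cfg <- gaConfig(populationSize = 10, generations = 30, maxEdits = 2,
                  eliteFraction = 0.2, seed = 6)
  rep <- runGA(parent, cfg, ruleScorer)
  expect_true(all(diff(rep$trace$best) >= -1e-12))
  # elitism directly: top-2 of a generation appear in the next
  pop <- initializePopulation(parent, cfg)
  cache <- new.env(); cache$fit <- list(); cache$calls <- 0L
  fit <- llpsdesign:::evalCandidates(pop, parent, ruleScorer, "increase",
                                     cache)
  set.seed(1)
  nxt <- stepGeneration(pop, fit, parent, cfg)
  ord <- order(-fit, vapply(pop, length, integer(1)))
  expect_identical(llpsdesign:::candKey(nxt[[1]]),
                   llpsdesign:::candKey(pop[[ord[1]]]))
  expect_identical(llpsdesign:::candKey(nxt[[2]]),
                   llpsdesign:::candKey(pop[[ord[2]]]))
})

test_that("crossover children are subsets of the parental edit union", {
  p1 <- MutationSet("A3G")@specs
  p2 <- MutationSet("K5-")@specs
  cfg <- gaConfig(maxEdits = 2, seed = 1)
  seen <- character(0)
  set.seed(4)
  for (i in 1:50) {
    child <- llpsdesign:::crossoverCandidates(p1, p2, 0.2, 0.1, cfg)
    key <- llpsdesign:::candKey(child)
    seen <- c(seen, key)
    toks <- strsplit(key, ",")[[1]]
    expect_true(all(toks %in% c("A3G", "K5-")))
    expect_gte(length(toks), 1)
  }
  # all three non-empty subsets occur
  expect_setequal(unique(seen), c("A3G", "K5-", "A3G,K5-"))
})

test_that("the GA recovers the exhaustive single-site optimum", {
  parent <- ProteinSequence("toy", "ACDKFGHI")
  scan <- exhaustiveSingleSiteScan(parent, ruleScorer)
  expect_equal(nrow(scan), 160L)  # 19*8 + 8
  cfg <- gaConfig(populationSize = 40, generations = 30, maxEdits = 1,
                  seed = 17)
  rep <- runGA(parent, cfg, ruleScorer)
  expect_equal(rep$candidates$fitness[1], scan$fitness[1], tolerance = 1e-12)
  # decrease direction matches the argmin
  scanDown <- exhaustiveSingleSiteScan(parent, ruleScorer,
                                       direction = "decrease")
  cfgDown <- gaConfig(populationSize = 40, generations = 30, maxEdits = 1,
                      direction = "decrease", seed = 17)
  repDown <- runGA(parent, cfgDown, ruleScorer)
  expect_equal(repDown$candidates$fitness[1], scanDown$fitness[1],
               tolerance = 1e-12)
})

test_that("a constant scorer yields zero fitness and tie-broken ranking", {
  parent <- ProteinSequence("toy", "ACDKFGHI")
  cfg <- gaConfig(populationSize = 20, generations = 5, maxEdits = 2,
                  seed = 23)
  rep <- runGA(parent, cfg, function(x) 0.5)
  expect_true(all(rep$candidates$fitness == 0))
  # ranking follows fewer edits, then lexicographic token order
  ne <- rep$candidates$nEdits
  expect_true(all(diff(ne) >= 0))
  for (k in unique(ne)) {
    toks <- rep$candidates$tokens[ne == k]
    expect_identical(toks, sort(toks))
  }
  # determinism of the whole report
  rep2 <- runGA(parent, cfg, function(x) 0.5)
  expect_identical(rep$candidates, rep2$candidates)
})

test_that("the fitness cache never rescores a candidate", {
  parent <- ProteinSequence("toy", "ACDKFGHI")
  calls <- new.env(); calls$n <- 0L
  scorer <- function(x) { calls$n <- calls$n + 1L; ruleScorer(x) }
  cfg <- gaConfig(populationSize = 20, generations = 10, maxEdits = 1,
                  seed = 2)
  rep <- runGA(parent, cfg, scorer)
  # one call per unique candidate plus one for the parent
  expect_lte(calls$n, rep$nUniqueCandidates + rep$nScorerCalls)
  expect_lte(rep$nScorerCalls, rep$nUniqueCandidates)
})

test_that("GA is at least as good as equal-budget random search", {
  parent <- randomSequence(12, seed = 77)
  for (sd in 1:5) {
    cfg <- gaConfig(populationSize = 30, generations = 10, maxEdits = 2,
                    seed = sd)
    rep <- runGA(parent, cfg, ruleScorer)
    budget <- rep$nScorerCalls
    rnd <- withr::with_seed(1000 + sd, {
      best <- -Inf
      chars <- strsplit(residues(parent), "")[[1]]
      for (i in seq_len(budget)) {
        cand <- llpsdesign:::randomCandidate(chars, cfg)
        x <- applyMutations(parent, MutationSet(cand))
        best <- max(best, ruleScorer(x) - ruleScorer(parent))
      }
      best
    })
    expect_gte(max(rep$trace$best) + 1e-12, rnd)
  }
})

test_that("a hydropathy-monotone scorer ranks substitutions accordingly", {
  parent <- ProteinSequence("m", "AAAAAAAA")
  hydro <- llpsdesign:::AA_HYDROPATHY
  scorer <- function(x) {
    chars <- strsplit(residues(x), "")[[1]]
    if (length(chars) < 2) return(0.5)
    plogis(hydro[[chars[2]]] / 2)
  }
  scan <- exhaustiveSingleSiteScan(parent, scorer,
                                   allowedKinds = "substitution")
  pos2 <- scan[grepl("^A2", scan$token), ]
  alts <- substr(pos2$token, 3, 3)
  expect_identical(alts, names(sort(hydro[setdiff(names(hydro), "A")],
                                    decreasing = TRUE)))
})
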