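# Genetic-algorithm search over mutation space. The objective is the
# change in predicted phase-separation score caused by the mutation set,
# fit(x) = PSDM(x) - PSDM(x_org); the GA maximizes it ("increase") or its
# negation ("decrease"), but the reported fitness is always the signed
# quantity. An exhaustive single-site scan provides the verification
# oracle.

#' GA configuration
#'
#' Defaults: population 200, 50 generations, tournament size 3, crossover
#' rate 0.9, per-candidate mutation rate 0.3, 5% elitism. Tie-breaking
#' everywhere is: higher fitness, then fewer edits, then lexicographic
#' token order — few-site mutants are preferred by construction.
#'
#' @param populationSize population size (>= 2).
#' @param generations number of generations.
#' @param tournamentSize tournament size for parent selection.
#' @param crossoverRate probability a child is produced by crossover.
#' @param mutationRate per-candidate probability of an edit mutation.
#' @param eliteFraction fraction copied unchanged each generation (in
#'   `[0, 0.5]`).
#' @param maxEdits maximum number of simultaneous edits per candidate.
#' @param allowedKinds edit kinds: `"substitution"`, `"deletion"` or both.
#' @param direction `"increase"` or `"decrease"` of the PS score.
#' @param substitutionBias optional 20 x 20 non-negative matrix (rows and
#'   columns named by one-letter code): when supplied, the alternative
#'   residue of a random substitution at reference `r` is drawn with
#'   probability proportional to `substitutionBias[r, ]` instead of
#'   uniformly, e.g. an amino-acid exchangeability matrix to bias the
#'   search toward naturally observed substitutions. `NULL` (the default)
#'   keeps uniform sampling.
#' @param seed integer seed (mandatory in reports).
#' @return A named list of class `GAConfig`.
#' @export
gaConfig <- function(populationSize = 200, generations = 50,
                     tournamentSize = 3, crossoverRate = 0.9,
                     mutationRate = 0.3, eliteFraction = 0.05, maxEdits = 2,
                     allowedKinds = c("substitution", "deletion"),
                     direction = c("increase", "decrease"),
                     substitutionBias = NULL, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(populationSize >= 2, generations >= 1, tournamentSize >= 1,
            crossoverRate >= 0, crossoverRate <= 1, mutationRate >= 0,
            mutationRate <= 1, eliteFraction >= 0, eliteFraction <= 0.5,
            maxEdits >= 1,
            all(allowedKinds %in% c("substitution", "deletion")))
  if (!is.null(substitutionBias)) {
    if (!is.matrix(substitutionBias) ||
        !all(AA20 %in% rownames(substitutionBias)) ||
        !all(AA20 %in% colnames(substitutionBias)) ||
        any(substitutionBias < 0)) {
      stopf("substitutionBias must be a non-negative matrix with the 20 amino acids as row/column names")
    }
  }
  structure(list(populationSize = populationSize, generations = generations,
                 tournamentSize = tournamentSize,
                 crossoverRate = crossoverRate, mutationRate = mutationRate,
                 eliteFraction = eliteFraction, maxEdits = maxEdits,
                 allowedKinds = allowedKinds, direction = direction,
                 substitutionBias = substitutionBias,
                 seed = as.integer(seed)),
            class = "GAConfig")
}

#' Mutation fitness: change in phase-separation score
#'
#' `fit(x) = scorer(x) - scorer(x_org)`; exactly 0 when `x` equals the
#' parent, and bounded in `[-1, 1]` for any scorer into `[0, 1]`.
#'
#' @param x mutated [ProteinSequence-class].
#' @param xOrg parent [ProteinSequence-class].
#' @param scorer function mapping a ProteinSequence to a score in `[0,1]`.
#' @return List with `value`, `psMutant`, `psParent`.
#' @export
fitnessValue <- function(x, xOrg, scorer) {
  px <- scorer(x)
  po <- scorer(xOrg)
  if (is(px, "PSScore")) px <- psValue(px)
  if (is(po, "PSScore")) po <- psValue(po)
  if (px < 0 || px > 1 || po < 0 || po > 1) {
    stopf("scorer must map into [0,1]")
  }
  list(value = px - po, psMutant = px, psParent = po)
}

# canonical key and display order for a candidate's edits
candTokens <- function(specs) {
  pos <- vapply(specs, mutationPosition, integer(1))
  vapply(specs[order(pos)], formatMutation, character(1))
}

candKey <- function(specs) paste(candTokens(specs), collapse = ",")

# one random valid edit at a position not in `used`; substitution
# alternatives are uniform unless cfg carries a substitutionBias matrix
randomEdit <- function(chars, used, cfg) {
  avail <- setdiff(seq_along(chars), used)
  if (!length(avail)) return(NULL)
  pos <- if (length(avail) == 1) avail else sample(avail, 1)
  kinds <- cfg$allowedKinds
  kind <- if (length(kinds) == 1) kinds else sample(kinds, 1)
  ref <- chars[pos]
  if (kind == "substitution") {
    alts <- setdiff(AA20, ref)
    if (is.null(cfg$substitutionBias)) {
      alt <- sample(alts, 1)
    } else {
      w <- cfg$substitutionBias[ref, alts]
      if (sum(w) <= 0) w <- rep(1, length(alts))
      alt <- sample(alts, 1, prob = w)
    }
    new("MutationSpec", kind = "substitution", position = as.integer(pos),
        ref = ref, alt = alt)
  } else {
    new("MutationSpec", kind = "deletion", position = as.integer(pos),
        ref = ref, alt = NA_character_)
  }
}

randomCandidate <- function(chars, cfg) {
  nEdits <- sample.int(cfg$maxEdits, 1)
  specs <- list()
  for (i in seq_len(nEdits)) {
    sp <- randomEdit(chars, vapply(specs, mutationPosition, integer(1)),
                     cfg)
    if (is.null(sp)) break
    specs <- c(specs, sp)
  }
  specs
}

#' Initialize a GA population of random mutants
#'
#' Each candidate carries 1 to `maxEdits` edits with positions, kinds and
#' (for substitutions) the 19 alternative residues drawn uniformly.
#' Candidates are distinct where possible (bounded resampling of
#' duplicates).
#'
#' @param xOrg parent [ProteinSequence-class].
#' @param cfg a [gaConfig()].
#' @param seed integer seed (default from config).
#' @return List of candidates, each a list of `MutationSpec`.
#' @export
initializePopulation <- function(xOrg, cfg, seed = cfg$seed) {
  chars <- residueChars(xOrg)
  if (length(chars) < cfg$maxEdits) {
    stopf("sequence shorter than maxEdits")
  }
  withSeed(seed, {
    pop <- list()
    keys <- character(0)
    for (i in seq_len(cfg$populationSize)) {
      cand <- randomCandidate(chars, cfg)
      tries <- 0
      while (candKey(cand) %in% keys && tries < 20) {
        cand <- randomCandidate(chars, cfg)
        tries <- tries + 1
      }
      pop[[i]] <- cand
      keys <- c(keys, candKey(cand))
    }
    pop
  })
}

# evaluation with caching; cacheEnv$calls counts unique scorer invocations
evalCandidates <- function(pop, xOrg, scorer, direction, cacheEnv) {
  vapply(pop, function(specs) {
    key <- candKey(specs)
    if (!is.null(cacheEnv$fit[[key]])) return(cacheEnv$fit[[key]])
    x <- applyMutations(xOrg, MutationSet(specs))
    fv <- fitnessValue(x, xOrg, scorer)
    cacheEnv$calls <- cacheEnv$calls + 1L
    cacheEnv$fit[[key]] <- fv$value
    fv$value
  }, numeric(1))
}

# objective used for selection (signed fitness, negated for "decrease")
objective <- function(fit, direction) if (direction == "decrease") -fit else fit

# tie-break comparator order: higher objective, fewer edits, lexicographic key
candOrder <- function(obj, pop) {
  nedit <- vapply(pop, length, integer(1))
  keys <- vapply(pop, candKey, character(1))
  order(-obj, nedit, keys)
}

tournamentPick <- function(pop, obj, k) {
  idx <- sample.int(length(pop), min(k, length(pop)))
  sub <- candOrder(obj[idx], pop[idx])
  idx[sub[1]]
}

crossoverCandidates <- function(p1, p2, obj1, obj2, cfg) {
  # fitter parent's edits win position conflicts and survive the edit cap
  if (obj2 > obj1) {
    tmp <- p1; p1 <- p2; p2 <- tmp
  }
  keep1 <- p1[stats::runif(length(p1)) < 0.5]
  keep2 <- p2[stats::runif(length(p2)) < 0.5]
  pos1 <- vapply(keep1, mutationPosition, integer(1))
  keep2 <- keep2[!vapply(keep2, mutationPosition, integer(1)) %in% pos1]
  child <- c(keep1, keep2)
  if (length(child) > cfg$maxEdits) {
    child <- child[seq_len(cfg$maxEdits)]
  }
  if (!length(child)) {
    child <- p1[sample.int(length(p1), 1)]
  }
  child
}

mutateCandidate <- function(specs, chars, cfg) {
  ops <- c("add", "remove", "resample")
  if (length(specs) >= cfg$maxEdits) ops <- setdiff(ops, "add")
  if (length(specs) <= 1) ops <- setdiff(ops, "remove")
  op <- if (length(ops) == 1) ops else sample(ops, 1)
  used <- vapply(specs, mutationPosition, integer(1))
  if (op == "add") {
    sp <- randomEdit(chars, used, cfg)
    if (!is.null(sp)) specs <- c(specs, sp)
  } else if (op == "remove") {
    specs <- specs[-sample.int(length(specs), 1)]
  } else {
    i <- sample.int(length(specs), 1)
    sp <- randomEdit(chars, used[-i], cfg)
    if (!is.null(sp)) specs[[i]] <- sp
  }
  specs
}

#' Advance one GA generation
#'
#' Elites (the top `eliteFraction`) are copied unchanged; parents are chosen
#' by tournament; crossover lets a child inherit each parental edit
#' independently with probability 0.5 (position conflicts resolved in
#' favour of the fitter parent, capped at `maxEdits`); with probability
#' `mutationRate` one edit is added, removed or resampled. With elitism the
#' best fitness never decreases across generations.
#'
#' @param pop list of candidates (lists of `MutationSpec`).
#' @param fit fitness of each candidate (signed).
#' @param xOrg parent sequence.
#' @param cfg a [gaConfig()].
#' @return List of candidates of the same size.
#' @export
stepGeneration <- function(pop, fit, xOrg, cfg) {
  chars <- residueChars(xOrg)
  obj <- objective(fit, cfg$direction)
  ord <- candOrder(obj, pop)
  nElite <- min(length(pop), ceiling(cfg$eliteFraction * length(pop)))
  nxt <- pop[ord[seq_len(nElite)]]
  while (length(nxt) < length(pop)) {
    i1 <- tournamentPick(pop, obj, cfg$tournamentSize)
    if (stats::runif(1) < cfg$crossoverRate) {
      i2 <- tournamentPick(pop, obj, cfg$tournamentSize)
      child <- crossoverCandidates(pop[[i1]], pop[[i2]], obj[i1], obj[i2],
                                   cfg)
    } else {
      child <- pop[[i1]]
    }
    if (stats::runif(1) < cfg$mutationRate) {
      child <- mutateCandidate(child, chars, cfg)
    }
    nxt[[length(nxt) + 1]] <- child
  }
  nxt
}

#' Run the genetic algorithm
#'
#' Full loop with fitness caching (each unique candidate is scored once).
#' The report ranks the unique candidates encountered, carries the
#' per-generation best/mean fitness trace, and echoes the configuration and
#' seed.
#'
#' @param xOrg parent [ProteinSequence-class].
#' @param cfg a [gaConfig()].
#' @param scorer function (or [PSScore-class]-returning closure) mapping a
#'   sequence to `[0, 1]`; see [scorePS()].
#' @param topN number of ranked candidates reported.
#' @return List of class `RecommendationReport`: `candidates` (data.frame
#'   of tokens, fitness, edit count, mixed-kind flag), `trace`, `config`,
#'   `seed`, `nScorerCalls`.
#' @export
runGA <- function(xOrg, cfg, scorer, topN = 10) {
  cache <- new.env()
  cache$fit <- list()
  cache$calls <- 0L
  withSeed(cfg$seed, {
    pop <- {
      # inline (seed already set): same construction as initializePopulation
      chars <- residueChars(xOrg)
      if (length(chars) < cfg$maxEdits) stopf("sequence shorter than maxEdits")
      out <- list()
      keys <- character(0)
      for (i in seq_len(cfg$populationSize)) {
        cand <- randomCandidate(chars, cfg)
        tries <- 0
        while (candKey(cand) %in% keys && tries < 20) {
          cand <- randomCandidate(chars, cfg)
          tries <- tries + 1
        }
        out[[i]] <- cand
        keys <- c(keys, candKey(cand))
      }
      out
    }
    fit <- evalCandidates(pop, xOrg, scorer, cfg$direction, cache)
    trace <- data.frame(generation = integer(0), best = numeric(0),
                        mean = numeric(0))
    record <- function(gen) {
      obj <- objective(fit, cfg$direction)
      trace[nrow(trace) + 1, ] <<- list(gen, fit[which.max(obj)], mean(fit))
    }
    record(0L)
    for (gen in seq_len(cfg$generations)) {
      pop <- stepGeneration(pop, fit, xOrg, cfg)
      fit <- evalCandidates(pop, xOrg, scorer, cfg$direction, cache)
      record(gen)
    }
    # rank all unique evaluated candidates
    keys <- names(cache$fit)
    fits <- unlist(cache$fit, use.names = FALSE)
    specs_by_key <- lapply(keys, function(k) {
      MutationSet(strsplit(k, ",", fixed = TRUE)[[1]])@specs
    })
    obj <- objective(fits, cfg$direction)
    ord <- candOrder(obj, specs_by_key)
    take <- ord[seq_len(min(topN, length(ord)))]
    kinds <- vapply(specs_by_key[take], function(sp) {
      length(unique(vapply(sp, mutationKind, character(1)))) > 1
    }, logical(1))
    cand_df <- data.frame(
      tokens = keys[take],
      fitness = fits[take],
      nEdits = vapply(specs_by_key[take], length, integer(1)),
      mixedKinds = kinds)
    structure(list(candidates = cand_df, trace = trace,
                   config = unclass(cfg), seed = cfg$seed,
                   nScorerCalls = cache$calls,
                   nUniqueCandidates = length(keys)),
              class = "RecommendationReport")
  })
}

#' Exhaustively score every single-site edit
#'
#' All `19 * L` substitutions plus `L` deletions (when enabled), exactly
#' ranked under the GA's tie-break. The brute-force oracle against which
#' [runGA()] is verified.
#'
#' @param xOrg parent [ProteinSequence-class] (length <= 500).
#' @param scorer scoring function into `[0, 1]`.
#' @param allowedKinds edit kinds to enumerate.
#' @param direction ranking direction.
#' @return data.frame of `token`, `fitness`, ranked best-first.
#' @export
exhaustiveSingleSiteScan <- function(xOrg, scorer,
                                     allowedKinds = c("substitution",
                                                      "deletion"),
                                     direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  chars <- residueChars(xOrg)
  if (length(chars) > 500) stopf("sequence too long for exhaustive scan")
  specs <- list()
  for (pos in seq_along(chars)) {
    if ("substitution" %in% allowedKinds) {
      for (alt in setdiff(AA20, chars[pos])) {
        specs[[length(specs) + 1]] <-
          new("MutationSpec", kind = "substitution",
              position = as.integer(pos), ref = chars[pos], alt = alt)
      }
    }
    if ("deletion" %in% allowedKinds) {
      specs[[length(specs) + 1]] <-
        new("MutationSpec", kind = "deletion", position = as.integer(pos),
            ref = chars[pos], alt = NA_character_)
    }
  }
  po <- scorer(xOrg)
  if (is(po, "PSScore")) po <- psValue(po)
  fits <- vapply(specs, function(sp) {
    px <- scorer(applyMutations(xOrg, MutationSet(list(sp))))
    if (is(px, "PSScore")) px <- psValue(px)
    px - po
  }, numeric(1))
  singles <- lapply(specs, list)
  ord <- candOrder(objective(fits, direction), singles)
  data.frame(token = vapply(specs[ord], formatMutation, character(1)),
             fitness = fits[ord])
}
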