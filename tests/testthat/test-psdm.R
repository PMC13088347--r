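smallCfg <- graphEncoderConfig(hiddenDim = 10, depth = 3, seed = 5)
gb3 <- bandGraphBuilder(3)

test_that("graph embeddings are permutation-invariant and non-degenerate", {
  model <- initPSDM(smallCfg)
  g <- gb3(randomSequence(15, seed = 9))
  set.seed(2)
  for (rep in 1:5) {
    g2 <- permuteGraph(g, sample(15))
    expect_lt(max(abs(encodeGraph(model, g) - encodeGraph(model, g2))),
              1e-5)
  }
  # distinct random graphs embed apart
  dists <- sapply(1:20, function(i) {
    e1 <- encodeGraph(model, gb3(randomSequence(12, seed = 1000 + i)))
    e2 <- encodeGraph(model, gb3(randomSequence(12, seed = 2000 + i)))
    sqrt(sum((e1 - e2)^2))
  })
  expect_true(all(dists > 1e-6))
})

test_that("single-node graphs encode without error", {
  model <- initPSDM(smallCfg)
  g1 <- new("ResidueGraph",
            nodeFeatures = nodeFeatureTable()["W", , drop = FALSE],
            edges = matrix(integer(0), 0, 2), backbone = logical(0))
  expect_true(all(is.finite(encodeGraph(model, g1))))
})

test_that("augmented views obey the identity, seeding and backbone rules", {
  g <- gb3(randomSequence(30, seed = 3))
  same <- augmentView(g, 0, 0, seed = 1)
  expect_identical(graphEdges(same), graphEdges(g))
  expect_identical(nodeFeatures(same), nodeFeatures(g))

  v1 <- augmentView(g, 0.5, 0.2, seed = 42)
  v2 <- augmentView(g, 0.5, 0.2, seed = 42)
  expect_identical(graphEdges(v1), graphEdges(v2))
  expect_identical(nodeFeatures(v1), nodeFeatures(v2))

  # backbone never dropped; node count preserved
  expect_equal(nNodes(v1), 30L)
  bb <- graphEdges(g)[backboneEdges(g), , drop = FALSE]
  kept <- paste(graphEdges(v1)[, 1], graphEdges(v1)[, 2])
  expect_true(all(paste(bb[, 1], bb[, 2]) %in% kept))
})

test_that("edge survival matches the binomial oracle across seeds", {
  g <- gb3(randomSequence(40, seed = 4))
  nNonBB <- sum(!backboneEdges(g))
  p <- 0.3
  surv <- sapply(1:50, function(sd) {
    v <- augmentView(g, p, 0, seed = sd)
    sum(!backboneEdges(v))
  })
  tot <- sum(surv)
  # 99% binomial interval on the pooled survivals
  bounds <- qbinom(c(0.005, 0.995), 50 * nNonBB, 1 - p)
  expect_gte(tot, bounds[1])
  expect_lte(tot, bounds[2])
})

test_that("the NT-Xent loss matches a scalar hand computation", {
  # two anchors, two views each, fixed embeddings, temperature 0.5
  Z <- rbind(c(1, 0), c(0.8, 0.6), c(0, 1), c(-0.6, 0.8))
  tau <- 0.5
  U <- Z / sqrt(rowSums(Z^2))
  S <- U %*% t(U) / tau
  handLoss <- 0
  pos <- c(2, 1, 4, 3)
  for (i in 1:4) {
    denom <- sum(exp(S[i, -i]))
    handLoss <- handLoss - log(exp(S[i, pos[i]]) / denom) / 4
  }
  nt <- llpsdesign:::ntXent(Z, tau)
  expect_equal(nt$loss, handLoss, tolerance = 1e-12)
})

test_that("tower and contrastive gradients match numerical differentiation", {
  params <- initPSDM(smallCfg)@params
  cfgU <- unclass(smallCfg)
  mkrec <- function(i, withRef = TRUE) {
    list(graph = gb3(randomSequence(12, seed = 100 + i)),
         ref = if (withRef) gb3(randomSequence(12, seed = 200 + i)),
         label = i %% 2)
  }
  recs <- lapply(1:4, mkrec)
  auxrecs <- lapply(1:4, mkrec, withRef = FALSE)
  set.seed(8)
  for (case in list(list(head = "t", rr = recs),
                    list(head = "a1", rr = auxrecs),
                    list(head = "ps", rr = auxrecs))) {
    tp <- llpsdesign:::batchTowerPass(params, cfgU, case$rr, case$head)
    lossAt <- function(p) {
      llpsdesign:::batchTowerPass(p, cfgU, case$rr, case$head,
                                  computeGrad = FALSE)$loss
    }
    for (nm in sample(names(tp$grads), 6)) {
      k <- sample(length(tp$grads[[nm]]), 1)
      expect_lt(relErr(numGrad(lossAt, params, nm, k), tp$grads[[nm]][k]),
                1e-3)
    }
  }
  views <- list(gb3(randomSequence(10, seed = 1)),
                gb3(randomSequence(10, seed = 1)),
                gb3(randomSequence(10, seed = 2)),
                gb3(randomSequence(10, seed = 2)))
  cp <- llpsdesign:::contrastivePass(params, cfgU, views)
  lossC <- function(p) {
    llpsdesign:::contrastivePass(p, cfgU, views, computeGrad = FALSE)$loss
  }
  for (nm in sample(names(cp$grads), 6)) {
    k <- sample(length(cp$grads[[nm]]), 1)
    expect_lt(relErr(numGrad(lossC, params, nm, k), cp$grads[[nm]][k]),
              1e-3)
  }
})

test_that("twin-tower weights zero out components exactly", {
  model <- initPSDM(smallCfg)
  recs <- lapply(1:4, function(i) {
    list(graph = gb3(randomSequence(12, seed = i)),
         ref = gb3(randomSequence(12, seed = 50 + i)), label = i %% 2)
  })
  aux <- lapply(1:4, function(i) {
    list(graph = gb3(randomSequence(12, seed = 80 + i)), label = i %% 2)
  })
  views <- list(gb3(randomSequence(10, seed = 1)),
                gb3(randomSequence(10, seed = 1)),
                gb3(randomSequence(10, seed = 2)),
                gb3(randomSequence(10, seed = 2)))
  full <- twinTowerLoss(model, recs, aux, aux, views,
                        weights = c(target = 1, aux1 = 0.5, aux2 = 0.5,
                                    contrastive = 0.5))
  tOnly <- twinTowerLoss(model, recs, aux, aux, views,
                         weights = c(target = 1, aux1 = 0, aux2 = 0,
                                     contrastive = 0))
  expect_equal(tOnly$total, full$components[["target"]])
  expect_equal(tOnly$total, tOnly$components[["target"]])
  expect_true(is.na(tOnly$components[["aux1"]]))
  expect_equal(sum(full$components * c(1, 0.5, 0.5, 0.5)), full$total)
  expect_error(twinTowerLoss(model, recs, weights = c(target = 0, aux1 = 0,
                                                      aux2 = 0,
                                                      contrastive = 0)),
               "zero")
})

test_that("a perfectly predicted batch sits at the BCE floor", {
  model <- initPSDM(smallCfg)
  aux <- lapply(1:4, function(i) {
    list(graph = gb3(randomSequence(12, seed = 80 + i)), label = i %% 2)
  })
  # force perfect predictions by planting a huge-bias head
  p <- model@params
  p$head_ps_w <- p$head_ps_w * 0
  p$head_ps_b <- 50
  model2 <- new("PSDMModel", params = p, config = model@config)
  ones <- lapply(aux, function(r) { r$label <- 1; r })
  l <- llpsdesign:::batchTowerPass(p, model@config, ones, "ps",
                                   computeGrad = FALSE)$loss
  expect_lt(l, 1e-10)
})

test_that("training is seeded, reproducible, and rejects bad input", {
  ds <- sampleLabeledDatasets(16, 8, 8, seed = 6, seqLen = 14)
  cfg <- graphEncoderConfig(hiddenDim = 8, depth = 2, epochs = 2,
                            batchSize = 4, contrastivePairs = 2, seed = 11)
  f1 <- trainPSDM(ds$target, ds$aux1, ds$aux2, cfg)
  f2 <- trainPSDM(ds$target, ds$aux1, ds$aux2, cfg)
  expect_identical(f1$model@params, f2$model@params)
  expect_identical(f1$report$valAUROC, f2$report$valAUROC)
  # single-class target is an error
  bad <- lapply(ds$target, function(r) { r$label <- 1; r })
  expect_error(trainPSDM(bad, ds$aux1, ds$aux2, cfg), "both classes")
  # zero-weight training equals plain supervised training on the target
  cfg0 <- cfg
  cfg0$weights <- c(target = 1, aux1 = 0, aux2 = 0, contrastive = 0)
  g1 <- trainPSDM(ds$target, NULL, NULL, cfg0)
  g2 <- trainPSDM(ds$target, ds$aux1, ds$aux2, cfg0)
  expect_identical(g1$report$loss$target, g2$report$loss$target)
  expect_identical(g1$model@params, g2$model@params)
})

test_that("the ablation harness reports all configurations", {
  ds <- sampleLabeledDatasets(12, 8, 8, seed = 19, seqLen = 12)
  cfg <- graphEncoderConfig(hiddenDim = 8, depth = 2, epochs = 1,
                            batchSize = 4, contrastivePairs = 2, seed = 3)
  ab <- ablatePSDM(ds$target, ds$aux1, ds$aux2, cfg)
  expect_equal(ab$config, c("full", "no_gin", "no_gat", "no_attn",
                            "no_contrastive"))
  expect_true(all(is.finite(ab$valAUROC)))
  # parameter counts differ as configured
  expect_false(ab$nParams[2] == ab$nParams[1])
  expect_false(ab$nParams[3] == ab$nParams[1])
  expect_lt(ab$nParams[4], ab$nParams[1])
  expect_equal(ab$nParams[5], ab$nParams[1])
})

test_that("scorePS runs the full pipeline deterministically", {
  psdm <- initPSDM(graphEncoderConfig(hiddenDim = 8, depth = 2, seed = 4))
  cm <- initContactModel(contactModelConfig(embedDim = 8, nHeads = 2,
                                            seed = 5))
  s <- randomSequence(18, seed = 12)
  sc1 <- scorePS(psdm, s, "predicted", contactModel = cm)
  sc2 <- scorePS(psdm, s, "predicted", contactModel = cm)
  expect_identical(psValue(sc1), psValue(sc2))
  expect_gte(psValue(sc1), 0)
  expect_lte(psValue(sc1), 1)

  st <- generateToyStructure("helix", 18, seq = s)
  sc3 <- scorePS(psdm, s, "structure", structure = st)
  expect_gte(psValue(sc3), 0)
  expect_lte(psValue(sc3), 1)

  chars <- strsplit(residues(s), "")[[1]]
  tok <- paste0(chars[5], 5, "-")
  sc4 <- scorePS(psdm, s, "structure", muts = tok, structure = st)
  expect_true(is.finite(psValue(sc4)))

  # mutation validation errors propagate
  wrong <- setdiff(llpsdesign:::AA20, chars[5])[1]
  expect_error(scorePS(psdm, s, "structure", muts = paste0(wrong, 5, "-"),
                       structure = st), "reference mismatch")
  expect_error(scorePS(psdm, s, "predicted"), "contactModel")
})

test_that("scores are invariant under residue relabeling of the graph", {
  model <- initPSDM(smallCfg)
  g <- gb3(randomSequence(14, seed = 31))
  set.seed(3)
  g2 <- permuteGraph(g, sample(14))
  e1 <- encodeGraph(model, g)
  e2 <- encodeGraph(model, g2)
  s1 <- plogis(sum(model@params$head_ps_w * e1) + model@params$head_ps_b)
  s2 <- plogis(sum(model@params$head_ps_w * e2) + model@params$head_ps_b)
  expect_equal(s1, s2, tolerance = 1e-8)
})
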