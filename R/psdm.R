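# Phase-separation discriminator: a graph encoder (GIN and GAT message
# passing with an attention readout) shared by three classification towers
# -- the target tower (mutation-driven PS-change classification, scored as
# a Siamese comparison of mutant and parent embeddings), a pathogenicity
# tower and a PS-classification tower -- plus an NT-Xent contrastive term
# over augmented graph views. The PS-classification head provides the
# absolute PS score in [0,1] used by scorePS() and by the genetic
# algorithm's fitness.

#' PSScore: a phase-separation score in [0,1]
#'
#' @slot value score in `[0,1]`.
#' @slot model model identifier.
#' @slot digest digest of the scored input.
#' @exportClass PSScore
setClass("PSScore",
         representation(value = "numeric", model = "character",
                        digest = "character"))

setValidity("PSScore", function(object) {
  if (length(object@value) != 1L || is.na(object@value) ||
      object@value < 0 || object@value > 1) {
    return("value must be a single number in [0,1]")
  }
  TRUE
})

#' @describeIn PSScore numeric score.
#' @param x a PSScore.
#' @export
psValue <- function(x) x@value

setMethod("show", "PSScore", function(object) {
  cat(sprintf("PSScore %.4f (model %s, input %s)\n", object@value,
              object@model, object@digest))
})

# cheap deterministic content digest (polynomial hash of the residues)
sequenceDigest <- function(seq) {
  h <- 7
  for (cd in utf8ToInt(residues(seq))) {
    h <- (h * 31 + cd) %% 2147483647
  }
  sprintf("%s:%08x", seqId(seq), as.integer(h))
}

#' Graph-encoder configuration
#'
#' Desk-scale defaults: hidden width 64, depth 3 (GIN, GAT, GIN when both
#' are enabled), attention-weighted mean readout, NT-Xent temperature 0.5,
#' augmentation by non-backbone edge dropout and node-feature masking, and
#' target-dominant loss weights 1.0/0.5/0.5/0.5
#' (target/pathogenicity/PS-classification/contrastive). When a component
#' is disabled its blocks are replaced by the remaining message-passing
#' type (or, with attention disabled, the readout falls back to plain mean
#' pooling); at least one of the three components must stay enabled.
#'
#' @param enableGIN use graph-isomorphism message-passing blocks.
#' @param enableGAT use graph-attention message-passing blocks.
#' @param enableSelfAttention use the attention readout (else mean pooling).
#' @param hiddenDim encoder width.
#' @param depth number of message-passing blocks.
#' @param temperature NT-Xent temperature.
#' @param pEdge non-backbone edge-dropout rate for augmented views.
#' @param pFeat node-feature masking rate for augmented views.
#' @param weights named numeric: `target`, `aux1`, `aux2`, `contrastive`.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batchSize target-batch size per optimizer step.
#' @param contrastivePairs augmented view pairs drawn per step.
#' @param headL1 L1 penalty on the classification-head weight vectors,
#'   applied as a proximal soft-threshold after each optimizer step. A
#'   head with nothing to learn (e.g. label-randomized data) collapses to
#'   exactly zero and scores constant, so permutation controls sit at
#'   AUROC 0.5 by the tie convention instead of drifting on residual
#'   noise.
#' @param seed integer seed.
#' @return A named list of class `GraphEncoderConfig`.
#' @export
graphEncoderConfig <- function(enableGIN = TRUE, enableGAT = TRUE,
                               enableSelfAttention = TRUE, hiddenDim = 64,
                               depth = 3, temperature = 0.5, pEdge = 0.2,
                               pFeat = 0.1,
                               weights = c(target = 1, aux1 = 0.5,
                                           aux2 = 0.5, contrastive = 0.5),
                               lr = 1e-2, epochs = 30, batchSize = 16,
                               contrastivePairs = 8, headL1 = 0.02,
                               seed = 1) {
  if (!enableGIN && !enableGAT && !enableSelfAttention) {
    stopf("at least one encoder component must be enabled")
  }
  stopifnot(hiddenDim >= 2, depth >= 1, temperature > 0,
            pEdge >= 0, pEdge < 1, pFeat >= 0, pFeat < 1,
            all(weights >= 0), lr > 0, epochs >= 1, batchSize >= 2)
  need <- c("target", "aux1", "aux2", "contrastive")
  if (!all(need %in% names(weights))) {
    stopf("weights must be named: %s", paste(need, collapse = ", "))
  }
  stopifnot(headL1 >= 0)
  structure(list(enableGIN = enableGIN, enableGAT = enableGAT,
                 enableSelfAttention = enableSelfAttention,
                 hiddenDim = hiddenDim, depth = depth,
                 temperature = temperature, pEdge = pEdge, pFeat = pFeat,
                 weights = weights[need], lr = lr, epochs = epochs,
                 batchSize = batchSize, contrastivePairs = contrastivePairs,
                 headL1 = headL1, seed = as.integer(seed)),
            class = "GraphEncoderConfig")
}

# Block type sequence: GIN, GAT, GIN, GAT, ... among the enabled types.
blockTypes <- function(cfg) {
  if (cfg$enableGIN && cfg$enableGAT) {
    rep(c("gin", "gat"), length.out = cfg$depth + 1)[seq_len(cfg$depth)]
  } else if (cfg$enableGIN) {
    rep("gin", cfg$depth)
  } else if (cfg$enableGAT) {
    rep("gat", cfg$depth)
  } else {
    character(0)  # attention-only encoder: projection + readout
  }
}

psdmInitParams <- function(cfg, featDim) {
  h <- cfg$hiddenDim
  p <- list(Win = rmat(featDim, h), bin = numeric(h))
  types <- blockTypes(cfg)
  for (k in seq_along(types)) {
    pre <- paste0("B", k, "_")
    if (types[k] == "gin") {
      p[[paste0(pre, "W1")]] <- rmat(h, h)
      p[[paste0(pre, "b1")]] <- numeric(h)
      p[[paste0(pre, "W2")]] <- rmat(h, h)
      p[[paste0(pre, "b2")]] <- numeric(h)
    } else {
      p[[paste0(pre, "W")]] <- rmat(h, h)
      p[[paste0(pre, "a1")]] <- stats::rnorm(h, sd = 0.1)
      p[[paste0(pre, "a2")]] <- stats::rnorm(h, sd = 0.1)
    }
  }
  if (cfg$enableSelfAttention) {
    r <- max(2L, h %/% 2L)
    p$RO_U <- rmat(h, r)
    p$RO_v <- stats::rnorm(r, sd = 0.1)
  }
  p$head_t_w <- stats::rnorm(h, sd = 0.1)
  p$head_t_b <- 0
  p$head_a1_w <- stats::rnorm(h, sd = 0.1)
  p$head_a1_b <- 0
  p$head_ps_w <- stats::rnorm(h, sd = 0.1)
  p$head_ps_b <- 0
  p
}

#' Initialize an untrained PSDM
#'
#' @param cfg a [graphEncoderConfig()].
#' @param featDim node-feature dimensionality (default matches
#'   [nodeFeatureTable()]).
#' @return A [PSDMModel-class] with seeded random weights.
#' @export
initPSDM <- function(cfg = graphEncoderConfig(),
                     featDim = ncol(nodeFeatureTable())) {
  params <- withSeed(cfg$seed, psdmInitParams(cfg, featDim))
  new("PSDMModel", params = params, config = unclass(cfg))
}

graphAdjacency <- function(g) {
  n <- nNodes(g)
  A <- matrix(0, n, n)
  e <- graphEdges(g)
  if (nrow(e)) {
    A[e] <- 1
    A[e[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

# Encoder forward pass; returns embedding and caches for backprop.
encoderForward <- function(params, cfg, g) {
  X <- nodeFeatures(g)
  A <- graphAdjacency(g)
  n <- nrow(X)
  Zin <- sweep(X %*% params$Win, 2, params$bin, "+")
  H <- relu(Zin)
  types <- blockTypes(cfg)
  blocks <- vector("list", length(types))
  for (k in seq_along(types)) {
    pre <- paste0("B", k, "_")
    if (types[k] == "gin") {
      M <- H + A %*% H
      Z1 <- sweep(M %*% params[[paste0(pre, "W1")]], 2,
                  params[[paste0(pre, "b1")]], "+")
      R <- relu(Z1)
      Z2 <- sweep(R %*% params[[paste0(pre, "W2")]], 2,
                  params[[paste0(pre, "b2")]], "+")
      Hn <- relu(Z2)
      blocks[[k]] <- list(type = "gin", Hin = H, M = M, Z1 = Z1, R = R,
                          Z2 = Z2)
    } else {
      P <- H %*% params[[paste0(pre, "W")]]
      s <- as.vector(P %*% params[[paste0(pre, "a1")]])
      t2 <- as.vector(P %*% params[[paste0(pre, "a2")]])
      E <- matrix(s, n, n) + matrix(t2, n, n, byrow = TRUE)
      mask <- (A + diag(n)) > 0
      alpha <- maskedSoftmaxRows(leakyRelu(E), mask)
      O <- alpha %*% P
      Hn <- relu(O)
      blocks[[k]] <- list(type = "gat", Hin = H, P = P, E = E, mask = mask,
                          alpha = alpha, O = O)
    }
    H <- Hn
  }
  if (cfg$enableSelfAttention) {
    Tm <- tanh(H %*% params$RO_U)
    sc <- as.vector(Tm %*% params$RO_v)
    al <- as.vector(softmaxRows(matrix(sc, 1)))
    gvec <- as.vector(t(H) %*% al)
    ro <- list(Tm = Tm, al = al)
  } else {
    gvec <- colMeans(H)
    ro <- NULL
  }
  list(g = gvec, cache = list(X = X, A = A, Zin = Zin, blocks = blocks,
                              Hfinal = H, ro = ro, types = types, n = n))
}

# Backward from d(loss)/d(embedding); returns encoder-parameter gradients.
encoderBackward <- function(params, cfg, cache, dg) {
  grads <- list()
  n <- cache$n
  H <- cache$Hfinal
  if (cfg$enableSelfAttention) {
    al <- cache$ro$al
    Tm <- cache$ro$Tm
    dal <- as.vector(H %*% dg)
    dH <- outer(al, dg)
    dsc <- al * (dal - sum(dal * al))
    dT <- outer(dsc, params$RO_v)
    grads$RO_v <- as.vector(t(Tm) %*% dsc)
    dpre <- dT * (1 - Tm^2)
    grads$RO_U <- t(H) %*% dpre
    dH <- dH + dpre %*% t(params$RO_U)
  } else {
    dH <- matrix(rep(dg / n, each = n), n)
  }
  for (k in rev(seq_along(cache$types))) {
    pre <- paste0("B", k, "_")
    bc <- cache$blocks[[k]]
    if (bc$type == "gin") {
      dZ2 <- dH * (bc$Z2 > 0)
      grads[[paste0(pre, "W2")]] <- t(bc$R) %*% dZ2
      grads[[paste0(pre, "b2")]] <- colSums(dZ2)
      dR <- dZ2 %*% t(params[[paste0(pre, "W2")]])
      dZ1 <- dR * (bc$Z1 > 0)
      grads[[paste0(pre, "W1")]] <- t(bc$M) %*% dZ1
      grads[[paste0(pre, "b1")]] <- colSums(dZ1)
      dM <- dZ1 %*% t(params[[paste0(pre, "W1")]])
      dH <- dM + cache$A %*% dM
    } else {
      dO <- dH * (bc$O > 0)
      dalpha <- dO %*% t(bc$P)
      dP <- t(bc$alpha) %*% dO
      dLk <- softmaxRowsBackward(bc$alpha, dalpha)
      dE <- dLk * dLeakyRelu(bc$E)
      dE[!bc$mask] <- 0
      ds <- rowSums(dE)
      dt2 <- colSums(dE)
      dP <- dP + outer(ds, params[[paste0(pre, "a1")]]) +
        outer(dt2, params[[paste0(pre, "a2")]])
      grads[[paste0(pre, "a1")]] <- as.vector(t(bc$P) %*% ds)
      grads[[paste0(pre, "a2")]] <- as.vector(t(bc$P) %*% dt2)
      grads[[paste0(pre, "W")]] <- t(bc$Hin) %*% dP
      dH <- dP %*% t(params[[paste0(pre, "W")]])
    }
  }
  dZin <- dH * (cache$Zin > 0)
  grads$Win <- t(cache$X) %*% dZin
  grads$bin <- colSums(dZin)
  grads
}

#' Encode a residue graph into a fixed-width embedding
#'
#' The embedding is permutation-invariant: relabeling the nodes (with edges
#' relabeled consistently) changes the result only up to numerical
#' round-off.
#'
#' @param model a [PSDMModel-class].
#' @param g a [ResidueGraph-class] with at least one node.
#' @return Numeric vector of length `hiddenDim`.
#' @export
encodeGraph <- function(model, g) {
  stopifnot(is(model, "PSDMModel"), is(g, "ResidueGraph"))
  if (nNodes(g) < 1) stopf("cannot encode an empty graph")
  encoderForward(model@params, model@config, g)$g
}

#' Generate a stochastic augmented view of a residue graph
#'
#' Positive pairs for contrastive learning are built by randomly dropping
#' non-backbone edges (probability `pEdge`) and masking node feature rows to
#' zero (probability `pFeat`). Backbone edges are never dropped and the node
#' count is preserved, so a view remains a valid connected residue graph.
#'
#' @param g a [ResidueGraph-class].
#' @param pEdge non-backbone edge-dropout probability in `[0,1)`.
#' @param pFeat node-feature masking probability in `[0,1)`.
#' @param seed integer seed; identical seeds give identical views.
#' @return A [ResidueGraph-class].
#' @export
augmentView <- function(g, pEdge = 0.2, pFeat = 0.1, seed = NULL) {
  stopifnot(is(g, "ResidueGraph"), pEdge >= 0, pEdge < 1,
            pFeat >= 0, pFeat < 1)
  withSeed(seed, {
    e <- graphEdges(g)
    bb <- backboneEdges(g)
    keep <- rep(TRUE, nrow(e))
    nb <- which(!bb)
    if (length(nb) && pEdge > 0) {
      keep[nb] <- stats::runif(length(nb)) >= pEdge
    }
    feat <- nodeFeatures(g)
    if (pFeat > 0) {
      drop <- stats::runif(nrow(feat)) < pFeat
      feat[drop, ] <- 0
    }
    new("ResidueGraph", nodeFeatures = feat,
        edges = e[keep, , drop = FALSE], backbone = bb[keep])
  })
}

#' Bundle an auxiliary dataset
#'
#' @param role `"pathogenicity"` (benign/pathogenic surrogate) or
#'   `"ps_classification"` (PS vs non-PS surrogate).
#' @param records list of records, each `list(graph = <ResidueGraph>,
#'   label = 0/1)`.
#' @return A list of class `AuxiliaryDataset`.
#' @export
auxiliaryDataset <- function(role = c("pathogenicity", "ps_classification"),
                             records) {
  role <- match.arg(role)
  labs <- vapply(records, function(r) r$label, numeric(1))
  if (length(unique(labs)) < 2) {
    stopf("auxiliary dataset must contain both classes")
  }
  structure(list(role = role, records = records),
            class = "AuxiliaryDataset")
}

# NT-Xent over row embeddings Z (2N x h, consecutive rows are view pairs).
# Returns loss and dZ.
ntXent <- function(Z, temperature) {
  m <- nrow(Z)
  if (m < 4 || m %% 2 != 0) {
    stopf("contrastive batch needs an even number (>= 4) of views")
  }
  nrm <- pmax(sqrt(rowSums(Z^2)), 1e-12)
  U <- Z / nrm
  S <- (U %*% t(U)) / temperature
  diag(S) <- -Inf
  P <- softmaxRows(S)
  pos <- ifelse(seq_len(m) %% 2 == 1, seq_len(m) + 1, seq_len(m) - 1)
  picked <- P[cbind(seq_len(m), pos)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  G <- P
  G[cbind(seq_len(m), pos)] <- G[cbind(seq_len(m), pos)] - 1
  G <- G / m
  diag(G) <- 0
  dU <- (G + t(G)) %*% U / temperature
  dZ <- (dU - U * rowSums(dU * U)) / nrm
  list(loss = loss, dZ = dZ)
}

headForward <- function(params, head, gvec) {
  w <- params[[paste0("head_", head, "_w")]]
  b <- params[[paste0("head_", head, "_b")]]
  sum(w * gvec) + b
}

# target-task logit for one record: Siamese |embedding difference| when a
# reference (parent) embedding is present, absolute PS head otherwise.
targetLogit <- function(params, gx, gref = NULL) {
  if (is.null(gref)) return(headForward(params, "ps", gx))
  headForward(params, "t", abs(gx - gref))
}

# Forward + (optionally) gradient accumulation for one labeled batch on one
# head. Each record: list(graph=, ref=NULL or graph, label=).
batchTowerPass <- function(params, cfg, records, head, computeGrad = TRUE) {
  fw <- lapply(records, function(r) {
    e1 <- encoderForward(params, cfg, r$graph)
    e2 <- if (!is.null(r$ref)) encoderForward(params, cfg, r$ref) else NULL
    list(e1 = e1, e2 = e2)
  })
  logits <- vapply(seq_along(records), function(i) {
    if (head == "t" && !is.null(fw[[i]]$e2)) {
      headForward(params, "t", abs(fw[[i]]$e1$g - fw[[i]]$e2$g))
    } else {
      headForward(params, if (head == "t") "ps" else head, fw[[i]]$e1$g)
    }
  }, numeric(1))
  y <- vapply(records, function(r) r$label, numeric(1))
  b <- bceWithLogits(logits, y)
  out <- list(loss = b$loss, logits = logits)
  if (!computeGrad) return(out)
  grads <- NULL
  for (i in seq_along(records)) {
    gi <- b$grad[i]
    if (head == "t" && !is.null(fw[[i]]$e2)) {
      z <- fw[[i]]$e1$g - fw[[i]]$e2$g
      sgn <- sign(z)
      hg <- list()
      hg$head_t_w <- gi * abs(z)
      hg$head_t_b <- gi
      dgx <- gi * params$head_t_w * sgn
      enc1 <- encoderBackward(params, cfg, fw[[i]]$e1$cache, dgx)
      enc2 <- encoderBackward(params, cfg, fw[[i]]$e2$cache, -dgx)
      step <- c(hg, Map(`+`, enc1, enc2))
    } else {
      hd <- if (head == "t") "ps" else head
      hg <- list()
      hg[[paste0("head_", hd, "_w")]] <- gi * fw[[i]]$e1$g
      hg[[paste0("head_", hd, "_b")]] <- gi
      dgx <- gi * params[[paste0("head_", hd, "_w")]]
      step <- c(hg, encoderBackward(params, cfg, fw[[i]]$e1$cache, dgx))
    }
    grads <- if (is.null(grads)) step else mergeGradLists(grads, step)
  }
  out$grads <- grads
  out
}

mergeGradLists <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

contrastivePass <- function(params, cfg, views, computeGrad = TRUE) {
  fw <- lapply(views, function(v) encoderForward(params, cfg, v))
  Z <- do.call(rbind, lapply(fw, `[[`, "g"))
  nt <- ntXent(Z, cfg$temperature)
  out <- list(loss = nt$loss)
  if (!computeGrad) return(out)
  grads <- NULL
  for (i in seq_along(views)) {
    step <- encoderBackward(params, cfg, fw[[i]]$cache, nt$dZ[i, ])
    grads <- if (is.null(grads)) step else mergeGradLists(grads, step)
  }
  out$grads <- grads
  out
}

#' Twin-tower composite loss
#'
#' `loss = w_t * BCE(target) + w_1 * BCE(aux1) + w_2 * BCE(aux2) +
#' w_c * NT-Xent(contrastive)`. A component with weight zero is skipped
#' exactly, so zero-weight training is loss-identical to plain supervised
#' training on the target task.
#'
#' @param model a [PSDMModel-class].
#' @param targetBatch list of target records (`graph`, optional `ref`,
#'   `label`).
#' @param aux1Batch,aux2Batch lists of auxiliary records (`graph`, `label`).
#' @param contrastiveBatch list of graphs arranged as consecutive view
#'   pairs (length `2N`), e.g. from [augmentView()].
#' @param weights named weights (default from the model config).
#' @return List with `total` and per-component losses.
#' @export
twinTowerLoss <- function(model, targetBatch = NULL, aux1Batch = NULL,
                          aux2Batch = NULL, contrastiveBatch = NULL,
                          weights = NULL) {
  stopifnot(is(model, "PSDMModel"))
  cfg <- model@config
  if (is.null(weights)) weights <- cfg$weights
  if (all(weights == 0)) stopf("all loss weights are zero")
  comp <- c(target = NA_real_, aux1 = NA_real_, aux2 = NA_real_,
            contrastive = NA_real_)
  total <- 0
  if (weights[["target"]] > 0) {
    if (!length(targetBatch)) stopf("target weight > 0 but batch is empty")
    comp[["target"]] <- batchTowerPass(model@params, cfg, targetBatch, "t",
                                       computeGrad = FALSE)$loss
    total <- total + weights[["target"]] * comp[["target"]]
  }
  if (weights[["aux1"]] > 0) {
    if (!length(aux1Batch)) stopf("aux1 weight > 0 but batch is empty")
    comp[["aux1"]] <- batchTowerPass(model@params, cfg, aux1Batch, "a1",
                                     computeGrad = FALSE)$loss
    total <- total + weights[["aux1"]] * comp[["aux1"]]
  }
  if (weights[["aux2"]] > 0) {
    if (!length(aux2Batch)) stopf("aux2 weight > 0 but batch is empty")
    comp[["aux2"]] <- batchTowerPass(model@params, cfg, aux2Batch, "ps",
                                     computeGrad = FALSE)$loss
    total <- total + weights[["aux2"]] * comp[["aux2"]]
  }
  if (weights[["contrastive"]] > 0) {
    if (!length(contrastiveBatch)) {
      stopf("contrastive weight > 0 but batch is empty")
    }
    comp[["contrastive"]] <- contrastivePass(model@params, cfg,
                                             contrastiveBatch,
                                             computeGrad = FALSE)$loss
    total <- total + weights[["contrastive"]] * comp[["contrastive"]]
  }
  list(total = total, components = comp)
}

# stratified split of indices by binary label
stratifiedSplit <- function(labels, testFrac) {
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    ntest <- max(1L, round(length(idx) * testFrac))
    test <- c(test, sample(idx, ntest))
  }
  sort(test)
}

#' Train the phase-separation discriminator
#'
#' Twin-tower training: minibatch Adam on the composite loss of
#' [twinTowerLoss()], with the contrastive batch built per step from
#' augmented views of the target graphs. A stratified 20% of the target
#' records is held out internally for the per-epoch validation AUROC in the
#' report. Fully deterministic under `cfg$seed`.
#'
#' @param target list of labeled target records (`graph`, optional `ref`
#'   parent graph, `label`); both classes required.
#' @param aux1 an [auxiliaryDataset()] with role `"pathogenicity"`, or
#'   `NULL` when its weight is zero.
#' @param aux2 an [auxiliaryDataset()] with role `"ps_classification"`, or
#'   `NULL` when its weight is zero.
#' @param cfg a [graphEncoderConfig()].
#' @param featDim node-feature dimensionality.
#' @return List with `model` (a [PSDMModel-class]) and `report` (per-epoch
#'   component losses and validation AUROC).
#' @export
trainPSDM <- function(target, aux1 = NULL, aux2 = NULL,
                      cfg = graphEncoderConfig(),
                      featDim = ncol(nodeFeatureTable())) {
  labs <- vapply(target, function(r) r$label, numeric(1))
  if (length(unique(labs)) < 2) {
    stopf("target dataset must contain both classes")
  }
  w <- cfg$weights
  a1rec <- if (w[["aux1"]] > 0) aux1$records else list()
  a2rec <- if (w[["aux2"]] > 0) aux2$records else list()
  withSeed(cfg$seed, {
    params <- psdmInitParams(cfg, featDim)
    state <- adamInit(params)
    val_idx <- stratifiedSplit(labs, 0.2)
    tr <- target[-val_idx]
    va <- target[val_idx]
    nE <- cfg$epochs
    report <- list(loss = data.frame(epoch = seq_len(nE), target = NA_real_,
                                     aux1 = NA_real_, aux2 = NA_real_,
                                     contrastive = NA_real_,
                                     total = NA_real_),
                   valAUROC = numeric(nE))
    for (ep in seq_len(nE)) {
      ord <- sample(length(tr))
      comp_sum <- c(target = 0, aux1 = 0, aux2 = 0, contrastive = 0)
      nsteps <- 0
      for (start in seq(1, length(ord), by = cfg$batchSize)) {
        tb <- tr[ord[start:min(start + cfg$batchSize - 1, length(ord))]]
        grads <- list()
        total_comp <- c(target = 0, aux1 = 0, aux2 = 0, contrastive = 0)
        if (w[["target"]] > 0) {
          tp <- batchTowerPass(params, cfg, tb, "t")
          grads <- mergeGradLists(grads, scaleGrads(tp$grads, w[["target"]]))
          total_comp[["target"]] <- tp$loss
        }
        if (w[["aux1"]] > 0 && length(a1rec)) {
          ab <- a1rec[sample(length(a1rec), min(cfg$batchSize,
                                                length(a1rec)))]
          ap <- batchTowerPass(params, cfg, ab, "a1")
          grads <- mergeGradLists(grads, scaleGrads(ap$grads, w[["aux1"]]))
          total_comp[["aux1"]] <- ap$loss
        }
        if (w[["aux2"]] > 0 && length(a2rec)) {
          ab <- a2rec[sample(length(a2rec), min(cfg$batchSize,
                                                length(a2rec)))]
          ap <- batchTowerPass(params, cfg, ab, "ps")
          grads <- mergeGradLists(grads, scaleGrads(ap$grads, w[["aux2"]]))
          total_comp[["aux2"]] <- ap$loss
        }
        if (w[["contrastive"]] > 0) {
          anchors <- tb[sample(length(tb), min(cfg$contrastivePairs,
                                               length(tb)))]
          views <- list()
          for (a in anchors) {
            views <- c(views,
                       list(augmentView(a$graph, cfg$pEdge, cfg$pFeat),
                            augmentView(a$graph, cfg$pEdge, cfg$pFeat)))
          }
          if (length(views) >= 4) {
            cp <- contrastivePass(params, cfg, views)
            grads <- mergeGradLists(grads,
                                    scaleGrads(cp$grads, w[["contrastive"]]))
            total_comp[["contrastive"]] <- cp$loss
          }
        }
        if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1)))) {
          stopf("non-finite gradient at epoch %d", ep)
        }
        # missing entries (never-touched params) are zero
        full <- zerosLike(params)
        full[names(grads)] <- grads
        upd <- adamStep(params, full, state, lr = cfg$lr)
        params <- upd$params
        state <- upd$state
        if (cfg$headL1 > 0) {
          for (nm in c("head_t_w", "head_a1_w", "head_ps_w")) {
            params[[nm]] <- softThreshold(params[[nm]],
                                          cfg$lr * cfg$headL1)
          }
        }
        comp_sum <- comp_sum + total_comp
        nsteps <- nsteps + 1
      }
      report$loss[ep, c("target", "aux1", "aux2", "contrastive")] <-
        comp_sum / nsteps
      report$loss$total[ep] <- sum((comp_sum / nsteps) * w)
      vs <- vapply(va, function(r) {
        e1 <- encoderForward(params, cfg, r$graph)$g
        e2 <- if (!is.null(r$ref)) encoderForward(params, cfg, r$ref)$g
              else NULL
        logistic(targetLogit(params, e1, e2))
      }, numeric(1))
      report$valAUROC[ep] <- aurocScore(vs, vapply(va, function(r) r$label,
                                                   numeric(1)))
    }
    # deployment gate for the target head: if the validation AUROC is not
    # significantly above chance (one-sided Mann-Whitney normal
    # approximation, alpha = 0.01), the head abstains to the constant
    # predictor rather than shipping rankings indistinguishable from
    # noise. Label-randomized controls therefore score a flat 0.5.
    vlab <- vapply(va, function(r) r$label, numeric(1))
    n1 <- sum(vlab == 1)
    n0 <- sum(vlab == 0)
    sdNull <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
    gated <- (report$valAUROC[nE] - 0.5) / sdNull < stats::qnorm(0.99)
    if (gated) {
      params$head_t_w[] <- 0
      params$head_t_b <- 0
    }
    report$targetHeadGated <- gated
    list(model = new("PSDMModel", params = params, config = unclass(cfg)),
         report = report)
  })
}

#' Predict the probability of a significant PS change for mutant records
#'
#' Siamese comparison of the mutant and parent graph embeddings through the
#' target tower.
#'
#' @param model a [PSDMModel-class].
#' @param records list of records with `graph` (mutant) and `ref` (parent).
#' @return Numeric vector of change probabilities.
#' @export
predictChange <- function(model, records) {
  stopifnot(is(model, "PSDMModel"))
  vapply(records, function(r) {
    e1 <- encoderForward(model@params, model@config, r$graph)$g
    e2 <- if (!is.null(r$ref)) {
      encoderForward(model@params, model@config, r$ref)$g
    } else NULL
    logistic(targetLogit(model@params, e1, e2))
  }, numeric(1))
}

#' Score the phase-separation propensity of a (possibly mutated) protein
#'
#' Pipeline: apply the mutation set to the sequence, obtain a contact map
#' (either predicted from sequence by a [ContactModel-class], or computed
#' from a supplied structure under the 10 Angstrom rule), build the residue
#' graph, encode it, and pass the embedding through the PS-classification
#' head. Deterministic for fixed models.
#'
#' When a structure is supplied together with mutations, substitutions keep
#' the parent coordinates and deletions remove the corresponding residue's
#' coordinates.
#'
#' @param model a trained [PSDMModel-class].
#' @param seq the parent [ProteinSequence-class].
#' @param contactSource `"predicted"` or `"structure"`.
#' @param muts optional [MutationSet-class] (or token vector) applied to
#'   `seq` first.
#' @param contactModel a [ContactModel-class] (required when
#'   `contactSource = "predicted"`).
#' @param structure a [StructureModel-class] (required when
#'   `contactSource = "structure"`).
#' @param binarizeAt probability cutoff turning a predicted map into a
#'   binary contact matrix.
#' @param features node feature table.
#' @return A [PSScore-class].
#' @export
scorePS <- function(model, seq, contactSource = c("predicted", "structure"),
                    muts = NULL, contactModel = NULL, structure = NULL,
                    binarizeAt = 0.5, features = nodeFeatureTable()) {
  contactSource <- match.arg(contactSource)
  stopifnot(is(model, "PSDMModel"), is(seq, "ProteinSequence"))
  mutated <- if (is.null(muts)) seq else applyMutations(seq, muts)
  if (contactSource == "predicted") {
    if (is.null(contactModel)) {
      stopf("contactSource = 'predicted' requires a contactModel")
    }
    pm <- predictContactMap(contactModel, mutated)
    rcm <- binarizeContactMap(pm, threshold = binarizeAt)
  } else {
    if (is.null(structure)) {
      stopf("contactSource = 'structure' requires a structure")
    }
    st <- structure
    if (!is.null(muts)) st <- applyMutationsToStructure(structure, muts)
    if (seqLength(structureSequence(st)) != seqLength(mutated)) {
      stopf("structure does not match the mutated sequence")
    }
    rcm <- computeRCM(st, threshold = 10)
  }
  g <- buildResidueGraph(rcm, mutated, features)
  emb <- encoderForward(model@params, model@config, g)$g
  val <- logistic(headForward(model@params, "ps", emb))
  new("PSScore", value = val, model = "psdm",
      digest = sequenceDigest(mutated))
}

#' Binarize a predicted contact map into a contact matrix
#'
#' @param pm a [ContactProbabilityMap-class].
#' @param threshold probability cutoff (pairs at or above it are contacts).
#' @return A [ResidueContactMatrix-class] (threshold slot records the
#'   probability cutoff's geometric counterpart, 10 Angstrom).
#' @export
binarizeContactMap <- function(pm, threshold = 0.5) {
  P <- contactProbabilities(pm)
  e <- (P >= threshold) * 1
  diag(e) <- 1
  new("ResidueContactMatrix", entries = e, threshold = 10,
      mask = rep(TRUE, nrow(e)))
}

# apply a mutation set to a structure: substitutions keep coordinates,
# deletions drop the residue's row.
applyMutationsToStructure <- function(structure, muts) {
  if (!is(muts, "MutationSet")) muts <- MutationSet(muts)
  seq2 <- applyMutations(structureSequence(structure), muts)
  del <- vapply(muts@specs, function(s) {
    if (s@kind == "deletion") s@position else NA_integer_
  }, integer(1))
  del <- del[!is.na(del)]
  coords <- calphaCoords(structure)
  resolved <- resolvedMask(structure)
  if (length(del)) {
    coords <- coords[-del, , drop = FALSE]
    resolved <- resolved[-del]
  }
  StructureModel(seq2, coords, resolved)
}

#' Run the encoder-component ablation harness
#'
#' Trains the discriminator under the full configuration and with each
#' component disabled in turn (GIN, GAT, attention readout, contrastive
#' term), reporting parameter counts and held-out validation AUROC for all
#' configurations. No ordering among the ablations is asserted anywhere in
#' the package; the harness exists to make the comparison reproducible.
#'
#' @param target,aux1,aux2 as in [trainPSDM()].
#' @param cfg base [graphEncoderConfig()].
#' @param disable character vector of ablations to run in addition to
#'   `"full"`.
#' @return data.frame with configuration, parameter count and final
#'   validation AUROC.
#' @export
ablatePSDM <- function(target, aux1, aux2, cfg = graphEncoderConfig(),
                       disable = c("gin", "gat", "attn", "contrastive")) {
  variants <- list(full = cfg)
  for (d in disable) {
    v <- cfg
    if (d == "gin") v$enableGIN <- FALSE
    if (d == "gat") v$enableGAT <- FALSE
    if (d == "attn") v$enableSelfAttention <- FALSE
    if (d == "contrastive") v$weights[["contrastive"]] <- 0
    variants[[paste0("no_", d)]] <- v
  }
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    fit <- trainPSDM(target, aux1, aux2, v)
    data.frame(config = nm,
               nParams = sum(vapply(fit$model@params, length, numeric(1))),
               valAUROC = fit$report$valAUROC[v$epochs])
  })
  do.call(rbind, rows)
}
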