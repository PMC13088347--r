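# A lightweight sequence-to-contact transformer trained with
# structure-derived contact matrices as pseudo-labels. No multiple sequence
# alignment is used: the input is the single sequence, embedded per residue
# and combined with sinusoidal positional encodings; pairwise contact
# logits are a bilinear form of the encoded residues plus a learned
# relative-position bias, symmetrized by logit averaging before the sigmoid
# so the output map is symmetric by construction.

#' ContactProbabilityMap: symmetric residue-contact probabilities
#'
#' @slot entries symmetric n x n matrix in `[0,1]`; diagonal reported as 1
#'   but never scored.
#' @slot provenance list with at least `model` and `seed`.
#' @exportClass ContactProbabilityMap
setClass("ContactProbabilityMap",
         representation(entries = "matrix", provenance = "list"))

setValidity("ContactProbabilityMap", function(object) {
  e <- object@entries
  if (nrow(e) != ncol(e)) return("entries must be square")
  if (any(e < 0 | e > 1)) return("entries must lie in [0,1]")
  if (max(abs(e - t(e))) > 1e-12) return("entries must be symmetric")
  TRUE
})

#' @describeIn ContactProbabilityMap probability matrix.
#' @param x a ContactProbabilityMap.
#' @export
contactProbabilities <- function(x) x@entries

setMethod("show", "ContactProbabilityMap", function(object) {
  cat(sprintf("ContactProbabilityMap: %d residues (model %s, seed %s)\n",
              nrow(object@entries),
              as.character(object@provenance$model),
              as.character(object@provenance$seed)))
})

#' Contact-model configuration
#'
#' Desk-scale defaults: 32-dimensional embeddings, 2 attention layers with
#' 4 heads, feed-forward width 64, maximum sequence length 256. The
#' positive-class weight for the pairwise cross-entropy defaults to the
#' per-example non-contact/contact ratio (contacts are sparse); pass a
#' number to fix it.
#'
#' @param embedDim embedding width (divisible by `nHeads`).
#' @param nLayers number of self-attention layers.
#' @param nHeads attention heads per layer.
#' @param ffDim position-wise feed-forward hidden width.
#' @param maxLength maximum sequence length accepted.
#' @param maxRelPos relative-position bias is shared beyond this separation.
#' @param dropout feed-forward dropout rate during training.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batchSize minibatch size (gradients averaged within a batch).
#' @param posWeight positive-class weight, or `NULL` for the automatic
#'   per-example ratio.
#' @param seed integer seed recorded in every artifact the model produces.
#' @return A named list of class `ContactModelConfig`.
#' @export
contactModelConfig <- function(embedDim = 32, nLayers = 2, nHeads = 4,
                               ffDim = 64, maxLength = 256, maxRelPos = 32,
                               dropout = 0, lr = 3e-3, epochs = 60,
                               batchSize = 8, posWeight = NULL, seed = 1) {
  stopifnot(embedDim >= 1, nLayers >= 1, nHeads >= 1, ffDim >= 1,
            maxLength >= 2, maxRelPos >= 1, dropout >= 0, dropout < 1,
            lr > 0, epochs >= 1, batchSize >= 1)
  if (embedDim %% nHeads != 0) stopf("embedDim must be divisible by nHeads")
  structure(list(embedDim = embedDim, nLayers = nLayers, nHeads = nHeads,
                 ffDim = ffDim, maxLength = maxLength, maxRelPos = maxRelPos,
                 dropout = dropout, lr = lr, epochs = epochs,
                 batchSize = batchSize, posWeight = posWeight,
                 seed = as.integer(seed)),
            class = "ContactModelConfig")
}

sinusoidalEncoding <- function(n, d) {
  pos <- seq_len(n) - 1
  pe <- matrix(0, n, d)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= d) pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}

contactInitParams <- function(cfg) {
  d <- cfg$embedDim
  p <- list(Emb = rmat(20, d))
  rownames(p$Emb) <- AA20
  for (l in seq_len(cfg$nLayers)) {
    pre <- paste0("L", l, "_")
    p[[paste0(pre, "Wq")]] <- rmat(d, d)
    p[[paste0(pre, "Wk")]] <- rmat(d, d)
    p[[paste0(pre, "Wv")]] <- rmat(d, d)
    p[[paste0(pre, "Wo")]] <- rmat(d, d)
    p[[paste0(pre, "W1")]] <- rmat(d, cfg$ffDim)
    p[[paste0(pre, "b1")]] <- numeric(cfg$ffDim)
    p[[paste0(pre, "W2")]] <- rmat(cfg$ffDim, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
  }
  p$PairB <- rmat(d, d, sd = 0.05)
  p$PairBias <- 0
  p$RelPos <- numeric(cfg$maxRelPos + 1)
  p
}

#' Initialize an untrained contact model
#'
#' @param cfg a [contactModelConfig()].
#' @return A [ContactModel-class] with seeded random weights.
#' @export
initContactModel <- function(cfg = contactModelConfig()) {
  params <- withSeed(cfg$seed, contactInitParams(cfg))
  new("ContactModel", params = params, config = unclass(cfg))
}

# Forward pass. Returns pairwise logits (symmetric) and caches for backprop.
# `dropMasks` (training only) is a list of per-layer ff dropout masks.
contactForward <- function(params, cfg, idx, dropMasks = NULL) {
  L <- length(idx)
  X <- params$Emb[idx, , drop = FALSE] + sinusoidalEncoding(L, cfg$embedDim)
  nh <- cfg$nHeads
  dh <- cfg$embedDim / nh
  cache <- list(idx = idx, X0 = X, layers = vector("list", cfg$nLayers))
  for (l in seq_len(cfg$nLayers)) {
    pre <- paste0("L", l, "_")
    Xin <- X
    Q <- Xin %*% params[[paste0(pre, "Wq")]]
    K <- Xin %*% params[[paste0(pre, "Wk")]]
    V <- Xin %*% params[[paste0(pre, "Wv")]]
    H <- matrix(0, L, cfg$embedDim)
    A <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      sc <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
      A[[h]] <- softmaxRows(sc)
      H[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
    }
    attnOut <- H %*% params[[paste0(pre, "Wo")]]
    X1 <- Xin + attnOut
    Z1 <- sweep(X1 %*% params[[paste0(pre, "W1")]], 2,
                params[[paste0(pre, "b1")]], "+")
    R <- relu(Z1)
    Rd <- R
    if (!is.null(dropMasks) && cfg$dropout > 0) {
      Rd <- R * dropMasks[[l]] / (1 - cfg$dropout)
    }
    Fo <- sweep(Rd %*% params[[paste0(pre, "W2")]], 2,
                params[[paste0(pre, "b2")]], "+")
    X <- X1 + Fo
    cache$layers[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, A = A, H = H,
                              X1 = X1, Z1 = Z1, Rd = Rd)
  }
  Z <- X %*% params$PairB %*% t(X)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  rp_idx <- pmin(sep, cfg$maxRelPos) + 1
  S <- (Z + t(Z)) / 2 + params$PairBias +
    matrix(params$RelPos[rp_idx], L, L)
  cache$Xfinal <- X
  cache$rp_idx <- rp_idx
  list(S = S, cache = cache)
}

# Backward pass from d(loss)/dS (full matrix). Returns named gradient list.
contactBackward <- function(params, cfg, cache, dS, dropMasks = NULL) {
  L <- nrow(dS)
  nh <- cfg$nHeads
  dh <- cfg$embedDim / nh
  g <- zerosLike(params)

  # pair head
  dZ <- (dS + t(dS)) / 2
  X <- cache$Xfinal
  g$PairBias <- sum(dS)
  rp <- numeric(cfg$maxRelPos + 1)
  tab <- tapply(as.vector(dS), as.vector(cache$rp_idx), sum)
  rp[as.integer(names(tab))] <- tab
  g$RelPos <- rp
  g$PairB <- t(X) %*% dZ %*% X
  dX <- dZ %*% X %*% t(params$PairB) + t(dZ) %*% X %*% params$PairB

  for (l in rev(seq_len(cfg$nLayers))) {
    pre <- paste0("L", l, "_")
    cc <- cache$layers[[l]]
    # feed-forward (residual)
    dF <- dX
    g[[paste0(pre, "W2")]] <- t(cc$Rd) %*% dF
    g[[paste0(pre, "b2")]] <- colSums(dF)
    dRd <- dF %*% t(params[[paste0(pre, "W2")]])
    if (!is.null(dropMasks) && cfg$dropout > 0) {
      dRd <- dRd * dropMasks[[l]] / (1 - cfg$dropout)
    }
    dZ1 <- dRd * (cc$Z1 > 0)
    g[[paste0(pre, "W1")]] <- t(cc$X1) %*% dZ1
    g[[paste0(pre, "b1")]] <- colSums(dZ1)
    dX1 <- dX + dZ1 %*% t(params[[paste0(pre, "W1")]])
    # attention (residual)
    dAttnOut <- dX1
    g[[paste0(pre, "Wo")]] <- t(cc$H) %*% dAttnOut
    dH <- dAttnOut %*% t(params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, L, cfg$embedDim)
    dK <- matrix(0, L, cfg$embedDim)
    dV <- matrix(0, L, cfg$embedDim)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Ah <- cc$A[[h]]
      dHh <- dH[, cols, drop = FALSE]
      dV[, cols] <- t(Ah) %*% dHh
      dAh <- dHh %*% t(cc$V[, cols, drop = FALSE])
      dSc <- softmaxRowsBackward(Ah, dAh) / sqrt(dh)
      dQ[, cols] <- dSc %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- t(dSc) %*% cc$Q[, cols, drop = FALSE]
    }
    g[[paste0(pre, "Wq")]] <- t(cc$Xin) %*% dQ
    g[[paste0(pre, "Wk")]] <- t(cc$Xin) %*% dK
    g[[paste0(pre, "Wv")]] <- t(cc$Xin) %*% dV
    dX <- dX1 + dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]])
  }
  # embeddings
  dEmb <- matrix(0, 20, cfg$embedDim)
  for (i in seq_len(L)) dEmb[cache$idx[i], ] <- dEmb[cache$idx[i], ] + dX[i, ]
  g$Emb <- dEmb
  g
}

seqToIdx <- function(seq, cfg) {
  L <- seqLength(seq)
  if (L < 2) stopf("sequence must have at least 2 residues")
  if (L > cfg$maxLength) {
    stopf("sequence length %d exceeds the model capacity (%d)", L,
          cfg$maxLength)
  }
  match(residueChars(seq), AA20)
}

#' Predict a residue-contact probability map from sequence alone
#'
#' Pairwise logits are averaged with their transpose before the sigmoid, so
#' the returned map is symmetric regardless of attention asymmetry. The
#' diagonal is reported as 1 by convention and is never scored. Prediction
#' is deterministic for a fixed model.
#'
#' @param model a [ContactModel-class].
#' @param seq a [ProteinSequence-class] (length between 2 and the configured
#'   maximum).
#' @return A [ContactProbabilityMap-class].
#' @export
predictContactMap <- function(model, seq) {
  stopifnot(is(model, "ContactModel"), is(seq, "ProteinSequence"))
  cfg <- model@config
  idx <- seqToIdx(seq, cfg)
  fw <- contactForward(model@params, cfg, idx)
  P <- logistic(fw$S)
  diag(P) <- 1
  new("ContactProbabilityMap", entries = P,
      provenance = list(model = "contact-transformer", seed = cfg$seed))
}

# loss and dS for one training example; pairs touching masked residues and
# the diagonal are excluded.
contactExampleLoss <- function(S, truth, mask, posWeight = NULL) {
  L <- nrow(S)
  sel <- upper.tri(S) & outer(mask, mask, "&")
  y <- truth[sel]
  s <- S[sel]
  if (is.null(posWeight)) {
    npos <- sum(y == 1)
    posWeight <- if (npos > 0 && npos < length(y)) {
      (length(y) - npos) / npos
    } else 1
  }
  b <- bceWithLogits(s, y, posWeight)
  dS <- matrix(0, L, L)
  dS[sel] <- b$grad
  list(loss = b$loss, dS = dS)
}

#' Train the contact predictor on pseudo-labeled examples
#'
#' Optimizes per-pair binary cross-entropy over off-diagonal unmasked
#' residue pairs with a positive-class weight (contacts are sparse), using
#' Adam on shuffled minibatches. Fully deterministic for a fixed
#' `cfg$seed`.
#'
#' @param examples a list of training examples, each a list with elements
#'   `seq` (a [ProteinSequence-class]) and `rcm` (its pseudo-label
#'   [ResidueContactMatrix-class]); at least 2 examples.
#' @param cfg a [contactModelConfig()].
#' @return A list with `model` (a [ContactModel-class]), `trace` (mean
#'   epoch loss), and `initialLoss`/`finalLoss`.
#' @export
trainContactModel <- function(examples, cfg = contactModelConfig()) {
  if (length(examples) < 2) stopf("need at least 2 training examples")
  prep <- lapply(examples, function(ex) {
    stopifnot(is(ex$seq, "ProteinSequence"), is(ex$rcm, "ResidueContactMatrix"))
    if (seqLength(ex$seq) != nResidues(ex$rcm)) {
      stopf("example sequence and contact-matrix sizes disagree")
    }
    truth <- contactEntries(ex$rcm)
    truth[is.na(truth)] <- 0
    list(idx = seqToIdx(ex$seq, cfg), truth = truth,
         mask = contactMask(ex$rcm))
  })
  withSeed(cfg$seed, {
    params <- contactInitParams(cfg)
    state <- adamInit(params)
    trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(prep))
      eploss <- 0
      for (start in seq(1, length(ord), by = cfg$batchSize)) {
        batch <- ord[start:min(start + cfg$batchSize - 1, length(ord))]
        grads <- zerosLike(params)
        bloss <- 0
        for (b in batch) {
          px <- prep[[b]]
          dm <- NULL
          if (cfg$dropout > 0) {
            dm <- lapply(seq_len(cfg$nLayers), function(l) {
              matrix(stats::rbinom(length(px$idx) * cfg$ffDim, 1,
                                   1 - cfg$dropout),
                     length(px$idx), cfg$ffDim)
            })
          }
          fw <- contactForward(params, cfg, px$idx, dm)
          el <- contactExampleLoss(fw$S, px$truth, px$mask, cfg$posWeight)
          if (!is.finite(el$loss)) {
            stopf("non-finite training loss at epoch %d", ep)
          }
          grads <- addGrads(grads, contactBackward(params, cfg, fw$cache,
                                                   el$dS, dm))
          bloss <- bloss + el$loss
        }
        grads <- scaleGrads(grads, 1 / length(batch))
        upd <- adamStep(params, grads, state, lr = cfg$lr)
        params <- upd$params
        state <- upd$state
        eploss <- eploss + bloss
      }
      trace[ep] <- eploss / length(prep)
    }
    list(model = new("ContactModel", params = params, config = unclass(cfg)),
         trace = trace, initialLoss = trace[1],
         finalLoss = trace[cfg$epochs])
  })
}

#' Top-k contact precision
#'
#' Ranks the off-diagonal upper-triangle pairs with sequence separation
#' `|i - j| >= minSeparation` by predicted probability (ties broken by lower
#' `i`, then lower `j`) and reports the fraction of the k best that are true
#' contacts. This is the standard contact-assessment statistic; the default
#' separation of 6 follows the medium/long-range convention, and 0 compares
#' against the raw contact matrix.
#'
#' @param pred a [ContactProbabilityMap-class] or a symmetric numeric
#'   matrix.
#' @param truth a [ResidueContactMatrix-class] or a 0/1 matrix.
#' @param k number of top pairs to score.
#' @param minSeparation minimum sequence separation of eligible pairs.
#' @return Precision in `[0,1]`.
#' @export
topkContactPrecision <- function(pred, truth, k = 10, minSeparation = 6) {
  P <- if (is(pred, "ContactProbabilityMap")) contactProbabilities(pred)
       else as.matrix(pred)
  mask <- rep(TRUE, nrow(P))
  if (is(truth, "ResidueContactMatrix")) {
    mask <- contactMask(truth)
    Tm <- contactEntries(truth)
  } else {
    Tm <- as.matrix(truth)
  }
  if (!all(dim(P) == dim(Tm))) stopf("prediction/truth dimensions disagree")
  stopifnot(k >= 1, minSeparation >= 0)
  n <- nrow(P)
  ij <- which(upper.tri(P), arr.ind = TRUE)
  sep_ok <- (ij[, 2] - ij[, 1]) >= minSeparation
  mask_ok <- mask[ij[, 1]] & mask[ij[, 2]]
  ij <- ij[sep_ok & mask_ok, , drop = FALSE]
  if (nrow(ij) < k) {
    stopf("only %d eligible pairs after separation filtering; k = %d",
          nrow(ij), k)
  }
  p <- P[ij]
  ord <- order(-p, ij[, 1], ij[, 2])
  top <- ij[ord[seq_len(k)], , drop = FALSE]
  mean(Tm[top] == 1)
}
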