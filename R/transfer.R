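# Protein-specific transfer learning: balance a small labeled mutant panel
# 1:1, freeze the lower encoder blocks of a trained discriminator, and
# fine-tune the remaining blocks plus the target tower on the panel.

#' Transfer-learning configuration
#'
#' Default freeze policy: the input projection and the first 2 of 3 encoder
#' blocks are frozen; the last block, readout and target head are tuned.
#' The tune/held-out split is stratified 80/20 and seeded.
#'
#' @param freezeBlocks number of encoder blocks frozen from the input side
#'   (must be < the model's depth).
#' @param epochs fine-tuning epochs (0 returns the base model unchanged).
#' @param lr Adam learning rate.
#' @param patience early-stopping patience on the tuning loss.
#' @param batchSize minibatch size.
#' @param heldoutFrac held-out fraction of the panel.
#' @param seed integer seed.
#' @return A named list of class `TLConfig`.
#' @export
tlConfig <- function(freezeBlocks = 2, epochs = 25, lr = 2e-3, patience = 10,
                     batchSize = 16, heldoutFrac = 0.2, seed = 1) {
  stopifnot(freezeBlocks >= 0, epochs >= 0, lr > 0, patience >= 1,
            batchSize >= 1, heldoutFrac > 0, heldoutFrac < 1)
  structure(list(freezeBlocks = freezeBlocks, epochs = epochs, lr = lr,
                 patience = patience, batchSize = batchSize,
                 heldoutFrac = heldoutFrac, seed = as.integer(seed)),
            class = "TLConfig")
}

#' Balance a labeled set 1:1 by undersampling the majority class
#'
#' The majority class is uniformly subsampled (seeded) down to the minority
#' size; no record is duplicated. Works on a list of records with a
#' `label` element or a data.frame with a `label` column.
#'
#' @param records list of records or data.frame.
#' @param seed integer seed.
#' @return Balanced object of the same type, positives and negatives equal.
#' @export
balanceOneToOne <- function(records, seed = 1) {
  labs <- if (is.data.frame(records)) records$label
          else vapply(records, function(r) r$label, numeric(1))
  if (length(unique(labs)) < 2) {
    stopf("cannot balance a single-class set")
  }
  ipos <- which(labs == 1)
  ineg <- which(labs == 0)
  m <- min(length(ipos), length(ineg))
  keep <- withSeed(seed, {
    sort(c(if (length(ipos) > m) sample(ipos, m) else ipos,
           if (length(ineg) > m) sample(ineg, m) else ineg))
  })
  if (is.data.frame(records)) records[keep, , drop = FALSE]
  else records[keep]
}

# parameter names frozen under the policy: input projection + first k blocks
frozenParamNames <- function(params, freezeBlocks, tuneHeads = "target") {
  nm <- names(params)
  frozen <- c("Win", "bin")
  for (k in seq_len(freezeBlocks)) {
    frozen <- c(frozen, nm[startsWith(nm, paste0("B", k, "_"))])
  }
  if (identical(tuneHeads, "target")) {
    frozen <- c(frozen, "head_a1_w", "head_a1_b", "head_ps_w", "head_ps_b")
  }
  intersect(frozen, nm)
}

#' Turn a mutant panel table into Siamese training records
#'
#' @param panel data.frame with columns `token` and `label` (e.g. from
#'   [makeRetrainingPanel()] or [readMutationTable()]).
#' @param parent the parent [ProteinSequence-class].
#' @param graphBuilder function mapping a ProteinSequence to a
#'   [ResidueGraph-class] (default: helix-band contacts, see
#'   [bandGraphBuilder()]).
#' @return List of records (`graph`, `ref`, `label`, `key`).
#' @export
panelToRecords <- function(panel, parent, graphBuilder = bandGraphBuilder()) {
  parentGraph <- graphBuilder(parent)
  lapply(seq_len(nrow(panel)), function(i) {
    mut <- applyMutations(parent, panel$token[i])
    list(graph = graphBuilder(mut), ref = parentGraph,
         label = panel$label[i], key = panel$token[i])
  })
}

#' Fine-tune a trained discriminator on a protein-specific mutant panel
#'
#' Freezes the input projection and the first `freezeBlocks` encoder blocks
#' (their parameters are bitwise unchanged afterwards), then fine-tunes the
#' remaining blocks, the readout and the target (change-classification)
#' tower with Adam on the tuning split. A stratified quarter of the tuning
#' split is reserved for checkpoint selection: the returned model is the
#' epoch snapshot (including the unmodified starting model) with the
#' lowest selection loss, guarding against overfitting tiny panels. The
#' held-out split is never seen during tuning or selection; the report
#' carries before/after held-out AUROC and F1.
#'
#' @param base a trained [PSDMModel-class].
#' @param records balanced list of Siamese records (`graph`, `ref`,
#'   `label`, optional `key`), e.g. from [panelToRecords()] after
#'   [balanceOneToOne()].
#' @param cfg a [tlConfig()].
#' @return List with `model` (tuned [PSDMModel-class]), `report`
#'   (before/after held-out AUROC and F1, loss trace), `tuningKeys`,
#'   `heldout` (the held-out records).
#' @export
fineTune <- function(base, records, cfg = tlConfig()) {
  stopifnot(is(base, "PSDMModel"))
  mcfg <- base@config
  depth <- length(blockTypes(mcfg))
  if (cfg$freezeBlocks >= depth && depth > 0) {
    stopf("freezeBlocks (%d) must be smaller than the encoder depth (%d)",
          cfg$freezeBlocks, depth)
  }
  labs <- vapply(records, function(r) r$label, numeric(1))
  if (length(unique(labs)) < 2) stopf("panel must contain both classes")
  withSeed(cfg$seed, {
    hold_idx <- stratifiedSplit(labs, cfg$heldoutFrac)
    tune <- records[-hold_idx]
    heldout <- records[hold_idx]
    # a quarter of the tuning split is set aside for checkpoint selection:
    # the deployed model is the one with the lowest selection loss, and the
    # starting model competes, so fine-tuning cannot silently overfit a
    # small panel into a worse model
    tlabs <- vapply(tune, function(r) r$label, numeric(1))
    sel_idx <- stratifiedSplit(tlabs, 0.25)
    sel <- tune[sel_idx]
    train <- tune[-sel_idx]
    frozen <- frozenParamNames(base@params, cfg$freezeBlocks)
    params <- base@params
    state <- adamInit(params)
    sel_labs <- vapply(sel, function(r) r$label, numeric(1))
    # selection score: AUROC on the selection split (the deployment
    # metric), with BCE loss as tiebreak
    selScore <- function(p) {
      bp <- batchTowerPass(p, mcfg, sel, "t", computeGrad = FALSE)
      c(auroc = aurocScore(plogis(bp$logits), sel_labs), loss = bp$loss)
    }
    trace <- numeric(0)
    best <- selScore(params)
    bestParams <- params
    stale <- 0
    if (cfg$epochs > 0) {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample(length(train))
        eploss <- 0
        nb <- 0
        for (start in seq(1, length(ord), by = cfg$batchSize)) {
          tb <- train[ord[start:min(start + cfg$batchSize - 1,
                                    length(ord))]]
          tp <- batchTowerPass(params, mcfg, tb, "t")
          full <- zerosLike(params)
          full[names(tp$grads)] <- tp$grads
          upd <- adamStep(params, full, state, lr = cfg$lr, frozen = frozen)
          params <- upd$params
          state <- upd$state
          l1 <- if (is.null(mcfg$headL1)) 0 else mcfg$headL1
          if (l1 > 0) {
            for (nm in setdiff(c("head_t_w", "head_a1_w", "head_ps_w"),
                               frozen)) {
              params[[nm]] <- softThreshold(params[[nm]], cfg$lr * l1)
            }
          }
          eploss <- eploss + tp$loss
          nb <- nb + 1
        }
        trace <- c(trace, eploss / nb)
        cur <- selScore(params)
        if (cur[["auroc"]] > best[["auroc"]] + 1e-9 ||
            (abs(cur[["auroc"]] - best[["auroc"]]) <= 1e-9 &&
             cur[["loss"]] < best[["loss"]] - 1e-6)) {
          best <- cur
          bestParams <- params
          stale <- 0
        } else {
          stale <- stale + 1
          if (stale >= cfg$patience) break
        }
      }
    }
    params <- bestParams
    tuned <- new("PSDMModel", params = params, config = mcfg)
    hl <- vapply(heldout, function(r) r$label, numeric(1))
    sc_before <- predictChange(base, heldout)
    sc_after <- predictChange(tuned, heldout)
    report <- list(
      aurocBefore = aurocScore(sc_before, hl),
      aurocAfter = aurocScore(sc_after, hl),
      f1Before = f1Score(sc_before, hl),
      f1After = f1Score(sc_after, hl),
      lossTrace = trace,
      frozen = frozen,
      nTune = length(tune), nHeldout = length(heldout))
    keys <- vapply(tune, function(r) {
      if (is.null(r$key)) NA_character_ else r$key
    }, character(1))
    list(model = tuned, report = report, tuningKeys = keys[!is.na(keys)],
         heldout = heldout)
  })
}

#' Quantify the transfer gain on a held-out set
#'
#' Evaluates the base and tuned models on identical held-out records with
#' identical thresholds. Disjointness between tuning and held-out sets is
#' enforced via record keys, not assumed.
#'
#' @param base,tuned [PSDMModel-class] objects.
#' @param heldout list of Siamese records.
#' @param tuningKeys keys of the records used for tuning (from
#'   [fineTune()]); overlap with held-out keys is an error.
#' @param threshold F1 decision threshold.
#' @return List of paired metrics: AUROC and F1 before/after, and their
#'   differences.
#' @export
evaluateTransferGain <- function(base, tuned, heldout, tuningKeys = NULL,
                                 threshold = 0.5) {
  hk <- vapply(heldout, function(r) {
    if (is.null(r$key)) NA_character_ else r$key
  }, character(1))
  if (!is.null(tuningKeys)) {
    overlap <- intersect(tuningKeys, hk[!is.na(hk)])
    if (length(overlap)) {
      stopf("leakage: held-out records also used for tuning: %s",
            paste(utils::head(overlap, 5), collapse = ", "))
    }
  }
  hl <- vapply(heldout, function(r) r$label, numeric(1))
  sb <- predictChange(base, heldout)
  sa <- predictChange(tuned, heldout)
  list(aurocBefore = aurocScore(sb, hl), aurocAfter = aurocScore(sa, hl),
       f1Before = f1Score(sb, hl, threshold),
       f1After = f1Score(sa, hl, threshold),
       aurocGain = aurocScore(sa, hl) - aurocScore(sb, hl),
       f1Gain = f1Score(sa, hl, threshold) - f1Score(sb, hl, threshold))
}
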