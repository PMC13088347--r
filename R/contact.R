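# C-alpha extraction, residue contact matrices, residue graphs.

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one C-alpha per residue, in author residue order, for one chain.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (first in file order on ties). Residues present in the file without a
#' C-alpha record, and residues missing entirely from a numbering gap, are
#' returned unresolved (mask `FALSE`, `NA` coordinates); numbering-gap
#' residues of unknown identity are written as glycine placeholders.
#'
#' Parsing is delegated to [bio3d::read.pdb()]; the altloc/occupancy and gap
#' rules above are applied on its atom table.
#'
#' @param path PDB file path.
#' @param chain chain identifier (default `"A"`).
#' @param id sequence identifier; defaults to `<file stem>_<chain>`.
#' @return A [StructureModel-class].
#' @export
readCalpha <- function(path, chain = "A", id = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stopf("cannot parse PDB '%s': %s",
                                            path, conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stopf("chain '%s' not found in '%s'", chain, path)
  if (is.null(id)) {
    id <- paste0(sub("\\.[^.]*$", "", basename(path)), "_", chain)
  }

  # residue order: first appearance of each (resno, insert) in the file
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  res_first <- !duplicated(key)
  res_keys <- key[res_first]
  res_no <- at$resno[res_first]
  res_id3 <- at$resid[res_first]

  # fill numbering gaps with unresolved placeholder residues
  full_no <- seq(min(res_no), max(res_no))
  known <- match(full_no, res_no)
  aa1 <- rep("G", length(full_no))
  present <- !is.na(known)
  aa1[present] <- bio3d::aa321(res_id3[known[present]])
  if (any(aa1 == "X")) {
    stopf("non-canonical residue(s) in chain '%s' of '%s'", chain, path)
  }

  coords <- matrix(NA_real_, nrow = length(full_no), ncol = 3)
  resolved <- rep(FALSE, length(full_no))
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stopf("no C-alpha atoms in chain '%s' of '%s'", chain, path)
  for (i in which(present)) {
    rows <- ca[ca$resno == full_no[i], , drop = FALSE]
    if (!nrow(rows)) next
    occ <- rows$o
    occ[is.na(occ)] <- 1
    best <- which.max(occ)  # ties: first in file order
    coords[i, ] <- as.numeric(rows[best, c("x", "y", "z")])
    resolved[i] <- TRUE
  }
  StructureModel(ProteinSequence(id, paste(aa1, collapse = "")),
                 coords, resolved)
}

#' Compute the residue contact matrix
#'
#' Two residues are in contact when the Euclidean distance between their
#' C-alpha atoms is less than or equal to the threshold (inclusive at the
#' boundary; "within 10 Angstrom" is read inclusively). The diagonal is set
#' to 1 by convention (self-distance zero) but is never scored. Rows and
#' columns of unresolved residues are masked (`NA` entries), never
#' zero-filled, so absent coordinates are not mistaken for absent contacts.
#'
#' @param model a [StructureModel-class].
#' @param threshold distance cutoff in Angstrom (default 10).
#' @return A [ResidueContactMatrix-class].
#' @examples
#' s <- ProteinSequence("t", "AAA")
#' m <- StructureModel(s, rbind(c(0,0,0), c(0,0,5), c(0,0,12)))
#' contactEntries(computeRCM(m))
#' @export
computeRCM <- function(model, threshold = 10) {
  stopifnot(is(model, "StructureModel"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stopf("threshold must be a positive scalar (Angstrom)")
  }
  mask <- resolvedMask(model)
  if (!any(mask)) stopf("no resolved residues")
  n <- length(mask)
  entries <- matrix(NA_real_, n, n)
  idx <- which(mask)
  d <- as.matrix(stats::dist(calphaCoords(model)[idx, , drop = FALSE]))
  entries[idx, idx] <- (d <= threshold) * 1
  diag(entries)[idx] <- 1
  new("ResidueContactMatrix", entries = entries, threshold = threshold,
      mask = mask)
}

#' Per-amino-acid node feature table
#'
#' A 20 x 24 matrix (rows named by one-letter code): 20-dim one-hot
#' encoding, Kyte-Doolittle hydropathy, formal side-chain charge at pH 7,
#' aromaticity flag, and TOP-IDP disorder propensity. The four scalar
#' columns are z-scored across the alphabet. The table is the single place
#' residue featurization is defined, so alternative scales can be swapped in
#' by passing a different matrix to [buildResidueGraph()].
#'
#' @return Numeric matrix with rownames `AA20` order.
#' @export
nodeFeatureTable <- function() {
  onehot <- diag(20)
  rownames(onehot) <- AA20
  colnames(onehot) <- paste0("aa_", AA20)
  z <- function(v) as.numeric(scale(v))
  scalars <- cbind(hydropathy = z(AA_HYDROPATHY[AA20]),
                   charge = z(AA_CHARGE[AA20]),
                   aromatic = z(as.numeric(AA20 %in% AROMATIC_AA)),
                   disorder = z(AA_DISORDER[AA20]))
  cbind(onehot, scalars)
}

#' Build a featurized residue graph from a contact matrix
#'
#' Edges are the off-diagonal contacts of the matrix (pairs touching masked
#' residues excluded) united with backbone edges between sequential
#' neighbours. Backbone edges are always present — including between
#' unresolved residues — so the graph stays connected for message passing.
#'
#' @param rcm a [ResidueContactMatrix-class].
#' @param seq the matching [ProteinSequence-class] (`nResidues(rcm)` must
#'   equal `seqLength(seq)`).
#' @param features per-amino-acid feature table (default
#'   [nodeFeatureTable()]).
#' @return A [ResidueGraph-class].
#' @export
buildResidueGraph <- function(rcm, seq, features = nodeFeatureTable()) {
  stopifnot(is(rcm, "ResidueContactMatrix"), is(seq, "ProteinSequence"))
  n <- nResidues(rcm)
  if (n != seqLength(seq)) {
    stopf("contact matrix size (%d) does not match sequence length (%d)",
          n, seqLength(seq))
  }
  chars <- residueChars(seq)
  if (!all(chars %in% rownames(features))) {
    stopf("feature table lacks rows for some residues")
  }
  feat <- features[chars, , drop = FALSE]
  rownames(feat) <- NULL

  e <- contactEntries(rcm)
  e[is.na(e)] <- 0
  contact_idx <- which(upper.tri(e) & e == 1, arr.ind = TRUE)
  edges <- contact_idx
  if (n >= 2) {
    bb <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    edges <- rbind(edges, bb)
  }
  if (nrow(edges)) {
    keykeep <- !duplicated(paste(edges[, 1], edges[, 2]))
    edges <- edges[keykeep, , drop = FALSE]
    ord <- order(edges[, 1], edges[, 2])
    edges <- edges[ord, , drop = FALSE]
    backbone <- (edges[, 2] - edges[, 1]) == 1L
  } else {
    backbone <- logical(0)
  }
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  new("ResidueGraph", nodeFeatures = feat, edges = edges,
      backbone = backbone)
}

#' Write / read a contact matrix as whitespace-delimited text
#'
#' One header line (`n threshold`), then the dense matrix with `NA` marking
#' masked entries.
#'
#' @param rcm a [ResidueContactMatrix-class].
#' @param path output path.
#' @return Invisibly, `path` (`writeRCM`); a
#'   [ResidueContactMatrix-class] (`readRCM`).
#' @export
writeRCM <- function(rcm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %g", nResidues(rcm), contactThreshold(rcm)), con)
  utils::write.table(contactEntries(rcm), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeRCM
#' @export
readRCM <- function(path) {
  header <- scan(path, what = numeric(), nlines = 1, quiet = TRUE)
  n <- as.integer(header[1])
  threshold <- header[2]
  m <- as.matrix(utils::read.table(path, skip = 1, header = FALSE,
                                   na.strings = "NA"))
  dimnames(m) <- NULL
  if (nrow(m) != n || ncol(m) != n) stopf("matrix size disagrees with header")
  mask <- !apply(m, 1, function(r) all(is.na(r)))
  new("ResidueContactMatrix", entries = m, threshold = threshold, mask = mask)
}

#' Export a residue graph's edges as text
#'
#' Three whitespace-separated columns: `i j backbone` (1-based, `i < j`).
#'
#' @param g a [ResidueGraph-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeEdgeList <- function(g, path) {
  df <- data.frame(i = graphEdges(g)[, 1], j = graphEdges(g)[, 2],
                   backbone = as.integer(backboneEdges(g)))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
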