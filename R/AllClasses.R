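#' @import methods
NULL

#' ProteinSequence: an identified amino-acid sequence
#'
#' Holds a protein identifier and its ordered residue string over the 20
#' canonical one-letter codes. Positions are 1-based throughout the public
#' interface.
#'
#' @slot id character(1) label.
#' @slot residues character(1) string of canonical one-letter codes.
#' @exportClass ProteinSequence
setClass("ProteinSequence",
         representation(id = "character", residues = "character"))

setValidity("ProteinSequence", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id)) {
    return("id must be a single non-empty string")
  }
  checkResidueString(object@residues)
})

#' Construct a ProteinSequence
#'
#' @param id sequence identifier.
#' @param residues one-letter residue string (canonical 20 amino acids only).
#' @return A [ProteinSequence-class] object.
#' @examples
#' ProteinSequence("toy", "MRHAGE")
#' @export
ProteinSequence <- function(id, residues) {
  new("ProteinSequence", id = as.character(id),
      residues = toupper(as.character(residues)))
}

#' @describeIn ProteinSequence sequence identifier.
#' @param x a ProteinSequence.
#' @export
seqId <- function(x) x@id

#' @describeIn ProteinSequence residue string.
#' @export
residues <- function(x) x@residues

#' @describeIn ProteinSequence residue count.
#' @export
seqLength <- function(x) nchar(x@residues)

# residues as a character vector, one element per position
residueChars <- function(x) strsplit(x@residues, "", fixed = TRUE)[[1]]

setMethod("show", "ProteinSequence", function(object) {
  n <- seqLength(object)
  head <- if (n > 40) paste0(substr(object@residues, 1, 40), "...")
          else object@residues
  cat(sprintf("ProteinSequence '%s' (%d residues)\n  %s\n",
              object@id, n, head))
})

#' MutationSpec: one substitution or single-residue deletion
#'
#' Token grammar: `<ref><position><alt>` for substitutions (e.g. `R106C`:
#' arginine 106 to cysteine) and `<ref><position>-` for deletions (e.g.
#' `H5-`: histidine 5 deleted). Positions are 1-based.
#'
#' @slot kind `"substitution"` or `"deletion"`.
#' @slot position 1-based residue index.
#' @slot ref reference one-letter code.
#' @slot alt alternative one-letter code (`NA` for deletions).
#' @exportClass MutationSpec
setClass("MutationSpec",
         representation(kind = "character", position = "integer",
                        ref = "character", alt = "character"))

setValidity("MutationSpec", function(object) {
  if (!object@kind %in% c("substitution", "deletion")) {
    return("kind must be 'substitution' or 'deletion'")
  }
  if (length(object@position) != 1L || is.na(object@position) ||
      object@position < 1L) {
    return("position must be a positive integer")
  }
  if (!object@ref %in% AA20) return("ref must be a canonical amino acid")
  if (object@kind == "substitution") {
    if (is.na(object@alt) || !object@alt %in% AA20) {
      return("substitution alt must be a canonical amino acid")
    }
    if (object@alt == object@ref) return("ref and alt must differ")
  } else if (!is.na(object@alt)) {
    return("deletions carry no alt residue")
  }
  TRUE
})

#' @describeIn MutationSpec mutation kind.
#' @param x a MutationSpec.
#' @export
mutationKind <- function(x) x@kind

#' @describeIn MutationSpec 1-based position.
#' @export
mutationPosition <- function(x) x@position

#' @describeIn MutationSpec reference residue.
#' @export
refResidue <- function(x) x@ref

#' @describeIn MutationSpec alternative residue (NA for deletions).
#' @export
altResidue <- function(x) x@alt

setMethod("show", "MutationSpec", function(object) {
  cat(sprintf("MutationSpec %s (%s)\n", formatMutation(object), object@kind))
})

#' MutationSet: an ordered set of mutations on one parent sequence
#'
#' No two entries may share a position; application order is descending
#' position so deletions never shift the coordinates of entries applied
#' later.
#'
#' @slot specs list of [MutationSpec-class].
#' @exportClass MutationSet
setClass("MutationSet", representation(specs = "list"))

setValidity("MutationSet", function(object) {
  if (!all(vapply(object@specs, is, logical(1), class2 = "MutationSpec"))) {
    return("all entries must be MutationSpec objects")
  }
  pos <- vapply(object@specs, mutationPosition, integer(1))
  if (anyDuplicated(pos)) {
    return(sprintf("duplicate mutation position(s): %s",
                   paste(unique(pos[duplicated(pos)]), collapse = ", ")))
  }
  TRUE
})

#' Construct a MutationSet
#'
#' @param specs a list of [MutationSpec-class] objects, or a character vector
#'   of tokens which are parsed with [parseMutation()].
#' @return A [MutationSet-class].
#' @examples
#' MutationSet(c("R106C", "H5-"))
#' @export
MutationSet <- function(specs = list()) {
  if (is.character(specs)) specs <- lapply(specs, parseMutation)
  if (is(specs, "MutationSpec")) specs <- list(specs)
  new("MutationSet", specs = specs)
}

setMethod("length", "MutationSet", function(x) length(x@specs))

#' @describeIn MutationSet canonical tokens of the entries.
#' @param x a MutationSet.
#' @export
mutationTokens <- function(x) {
  vapply(x@specs, formatMutation, character(1))
}

setMethod("show", "MutationSet", function(object) {
  cat(sprintf("MutationSet with %d mutation(s): %s\n", length(object),
              paste(mutationTokens(object), collapse = ", ")))
})

#' StructureModel: per-residue C-alpha coordinates for a sequence
#'
#' @slot sequence the [ProteinSequence-class].
#' @slot coords numeric n x 3 matrix of C-alpha coordinates in Angstrom;
#'   rows of unresolved residues are NA.
#' @slot resolved logical n; FALSE where no C-alpha was observed.
#' @exportClass StructureModel
setClass("StructureModel",
         representation(sequence = "ProteinSequence", coords = "matrix",
                        resolved = "logical"))

setValidity("StructureModel", function(object) {
  n <- seqLength(object@sequence)
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n) {
    return("coords must be a numeric n x 3 matrix matching sequence length")
  }
  if (length(object@resolved) != n) {
    return("resolved mask length must equal sequence length")
  }
  bad <- object@resolved & apply(object@coords, 1, function(r) any(is.na(r)))
  if (any(bad)) return("resolved residues must have complete coordinates")
  bad2 <- !object@resolved & apply(object@coords, 1, function(r) !all(is.na(r)))
  if (any(bad2)) return("unresolved residues must have NA coordinates")
  TRUE
})

#' Construct a StructureModel
#'
#' @param sequence a [ProteinSequence-class].
#' @param coords numeric n x 3 C-alpha coordinate matrix (Angstrom); NA rows
#'   mark unresolved residues.
#' @param resolved optional logical mask; defaults to rows with complete
#'   coordinates.
#' @return A [StructureModel-class].
#' @export
StructureModel <- function(sequence, coords, resolved = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(resolved)) resolved <- stats::complete.cases(coords)
  coords[!resolved, ] <- NA_real_
  new("StructureModel", sequence = sequence, coords = coords,
      resolved = as.logical(resolved))
}

#' @describeIn StructureModel C-alpha coordinate matrix.
#' @param x a StructureModel.
#' @export
calphaCoords <- function(x) x@coords

#' @describeIn StructureModel per-residue resolution mask.
#' @export
resolvedMask <- function(x) x@resolved

#' @describeIn StructureModel the underlying sequence.
#' @export
structureSequence <- function(x) x@sequence

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel '%s': %d residues, %d resolved\n",
              seqId(object@sequence), seqLength(object@sequence),
              sum(object@resolved)))
})

#' ResidueContactMatrix: binary C-alpha adjacency under a distance cutoff
#'
#' Residue pairs are adjacent when their C-alpha atoms lie within the
#' threshold (inclusive; default 10 Angstrom). The diagonal is fixed to 1
#' but carries no information and is excluded from training and evaluation.
#' Rows/columns of unresolved residues are masked (mask FALSE), never
#' zero-filled.
#'
#' @slot entries symmetric 0/1 matrix; entries involving masked residues
#'   are NA.
#' @slot threshold distance cutoff in Angstrom.
#' @slot mask logical per-residue validity.
#' @exportClass ResidueContactMatrix
setClass("ResidueContactMatrix",
         representation(entries = "matrix", threshold = "numeric",
                        mask = "logical"))

setValidity("ResidueContactMatrix", function(object) {
  e <- object@entries
  n <- nrow(e)
  if (ncol(e) != n) return("entries must be square")
  if (length(object@mask) != n) return("mask length must equal n")
  if (length(object@threshold) != 1L || object@threshold <= 0) {
    return("threshold must be a positive scalar")
  }
  ok <- object@mask
  sub <- e[ok, ok, drop = FALSE]
  if (any(is.na(sub))) return("entries between resolved residues must be 0/1")
  if (!all(sub %in% c(0, 1))) return("entries must be binary")
  if (!isTRUE(all.equal(sub, t(sub)))) return("entries must be symmetric")
  if (n && any(diag(e)[ok] != 1)) return("diagonal must be 1 for resolved residues")
  TRUE
})

#' @describeIn ResidueContactMatrix the 0/1 matrix (NA where masked).
#' @param x a ResidueContactMatrix.
#' @export
contactEntries <- function(x) x@entries

#' @describeIn ResidueContactMatrix distance cutoff in Angstrom.
#' @export
contactThreshold <- function(x) x@threshold

#' @describeIn ResidueContactMatrix per-residue validity mask.
#' @export
contactMask <- function(x) x@mask

#' @describeIn ResidueContactMatrix residue count.
#' @export
nResidues <- function(x) nrow(x@entries)

setMethod("show", "ResidueContactMatrix", function(object) {
  n <- nrow(object@entries)
  ok <- object@mask
  nc <- if (n >= 2) sum(object@entries[ok, ok][upper.tri(diag(sum(ok)))])
        else 0
  cat(sprintf(
    "ResidueContactMatrix: %d residues (%d masked), threshold %g A, %d contacts\n",
    n, sum(!ok), object@threshold, nc))
})

#' ResidueGraph: featurized residue graph
#'
#' Nodes carry per-residue feature vectors; undirected edges come from a
#' contact matrix (masked pairs excluded) plus guaranteed backbone edges
#' between sequential neighbours, so every node of a chain with n >= 2 has
#' at least one incident edge.
#'
#' @slot nodeFeatures numeric n x d matrix.
#' @slot edges integer m x 2 matrix with i < j, no self-loops, unique rows.
#' @slot backbone logical m; TRUE for sequential-neighbour edges.
#' @exportClass ResidueGraph
setClass("ResidueGraph",
         representation(nodeFeatures = "matrix", edges = "matrix",
                        backbone = "logical"))

setValidity("ResidueGraph", function(object) {
  n <- nrow(object@nodeFeatures)
  e <- object@edges
  if (nrow(e) > 0) {
    if (ncol(e) != 2L) return("edges must have two columns")
    if (any(e[, 1] >= e[, 2])) return("edges must satisfy i < j (no self-loops)")
    if (any(e < 1L) || any(e > n)) return("edge endpoints out of range")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) return("duplicate edges")
  }
  if (length(object@backbone) != nrow(e)) {
    return("backbone flag length must equal edge count")
  }
  TRUE
})

#' @describeIn ResidueGraph node feature matrix (n x d).
#' @param x a ResidueGraph.
#' @export
nodeFeatures <- function(x) x@nodeFeatures

#' @describeIn ResidueGraph undirected edge list (m x 2, i < j).
#' @export
graphEdges <- function(x) x@edges

#' @describeIn ResidueGraph logical flag of backbone edges.
#' @export
backboneEdges <- function(x) x@backbone

#' @describeIn ResidueGraph node count.
#' @export
nNodes <- function(x) nrow(x@nodeFeatures)

setMethod("show", "ResidueGraph", function(object) {
  cat(sprintf("ResidueGraph: %d nodes, %d edges (%d backbone), %d features/node\n",
              nNodes(object), nrow(object@edges), sum(object@backbone),
              ncol(object@nodeFeatures)))
})

#' ContactModel: lightweight sequence-to-contact transformer
#'
#' @slot params named list of weight arrays.
#' @slot config model configuration (see [contactModelConfig()]).
#' @exportClass ContactModel
setClass("ContactModel", representation(params = "list", config = "list"))

setMethod("show", "ContactModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf(
    "ContactModel: %d-dim embeddings, %d layer(s), %d head(s), max length %d (%d parameters, seed %s)\n",
    cfg$embedDim, cfg$nLayers, cfg$nHeads, cfg$maxLength, np,
    as.character(cfg$seed)))
})

#' PSDMModel: graph-encoder phase-separation discriminator
#'
#' @slot params named list of weight arrays.
#' @slot config encoder configuration (see [graphEncoderConfig()]).
#' @exportClass PSDMModel
setClass("PSDMModel", representation(params = "list", config = "list"))

setMethod("show", "PSDMModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, numeric(1)))
  comps <- c(if (cfg$enableGIN) "GIN", if (cfg$enableGAT) "GAT",
             if (cfg$enableSelfAttention) "attention-readout")
  cat(sprintf("PSDMModel: hidden %d, depth %d [%s] (%d parameters, seed %s)\n",
              cfg$hiddenDim, cfg$depth, paste(comps, collapse = "+"), np,
              as.character(cfg$seed)))
})
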