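# Mutation notation: parsing, formatting, application.

# All Unicode hyphen/dash variants are normalized to ASCII "-" before
# matching; figure legends in the literature often use typographic hyphens.
normalizeDashes <- function(x) {
  gsub("[‐‑‒–—―−﹘﹣－]", "-", x)
}

#' Parse a mutation token
#'
#' Accepts the compact notation used for protein point mutations:
#' `R106C` is a substitution (arginine at position 106 mutated to cysteine),
#' `H5-` is a single-residue deletion (histidine at position 5 deleted).
#' Any Unicode hyphen/dash variant in a deletion token is normalized to the
#' ASCII hyphen before matching.
#'
#' @param token a single token such as `"R106C"` or `"H5-"`.
#' @return A [MutationSpec-class].
#' @examples
#' parseMutation("R106C")
#' parseMutation("H5-")
#' @seealso [formatMutation()], [applyMutations()]
#' @export
parseMutation <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token)) {
    stopf("mutation token must be a single string")
  }
  tok <- normalizeDashes(trimws(token))
  m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)(-|[A-Za-z])$", tok))[[1]]
  if (length(m) != 4L) {
    stopf("malformed mutation token: '%s'", token)
  }
  ref <- toupper(m[2])
  pos <- suppressWarnings(as.integer(m[3]))
  if (is.na(pos) || pos < 1L) {
    stopf("invalid position in mutation token: '%s'", token)
  }
  if (!ref %in% AA20) {
    stopf("non-canonical reference residue '%s' in token '%s'", ref, token)
  }
  if (m[4] == "-") {
    new("MutationSpec", kind = "deletion", position = pos, ref = ref,
        alt = NA_character_)
  } else {
    alt <- toupper(m[4])
    if (!alt %in% AA20) {
      stopf("non-canonical alternative residue '%s' in token '%s'", alt, token)
    }
    if (alt == ref) {
      stopf("reference and alternative residues are identical in token '%s'",
            token)
    }
    new("MutationSpec", kind = "substitution", position = pos, ref = ref,
        alt = alt)
  }
}

#' Format a mutation as its canonical token
#'
#' Inverse of [parseMutation()]: `parseMutation(formatMutation(x))` recovers
#' `x`, and formatting a parsed token reproduces the (dash-normalized) token.
#'
#' @param spec a [MutationSpec-class].
#' @return The canonical ASCII token.
#' @export
formatMutation <- function(spec) {
  stopifnot(is(spec, "MutationSpec"))
  if (spec@kind == "deletion") {
    sprintf("%s%d-", spec@ref, spec@position)
  } else {
    sprintf("%s%d%s", spec@ref, spec@position, spec@alt)
  }
}

#' Apply a mutation set to a sequence
#'
#' Substitutions replace the residue in place; each deletion removes exactly
#' one residue and shortens the sequence by one. Entries are applied in
#' descending position order so deletions never shift the coordinates of the
#' remaining entries; positions in the set always refer to the parent
#' sequence. Every entry's reference residue is validated against the parent
#' before anything is applied.
#'
#' @param seq a [ProteinSequence-class] (the parent).
#' @param muts a [MutationSet-class], a character vector of tokens, or a
#'   single [MutationSpec-class].
#' @param id identifier for the mutant; default appends the tokens to the
#'   parent id.
#' @return The mutated [ProteinSequence-class].
#' @examples
#' applyMutations(ProteinSequence("p", "MHAHE"), "H2-")
#' @export
applyMutations <- function(seq, muts, id = NULL) {
  stopifnot(is(seq, "ProteinSequence"))
  if (!is(muts, "MutationSet")) muts <- MutationSet(muts)
  chars <- residueChars(seq)
  n <- length(chars)
  specs <- muts@specs
  if (!length(specs)) {
    return(ProteinSequence(if (is.null(id)) seq@id else id, seq@residues))
  }
  pos <- vapply(specs, mutationPosition, integer(1))
  out_of_range <- pos > n
  if (any(out_of_range)) {
    stopf("mutation position(s) out of range for '%s' (length %d): %s",
          seq@id, n,
          paste(vapply(specs[out_of_range], formatMutation, character(1)),
                collapse = ", "))
  }
  found <- chars[pos]
  expected <- vapply(specs, refResidue, character(1))
  bad <- found != expected
  if (any(bad)) {
    msgs <- sprintf("position %d: expected %s, found %s",
                    pos[bad], expected[bad], found[bad])
    stopf("reference mismatch for '%s': %s", seq@id,
          paste(msgs, collapse = "; "))
  }
  ord <- order(pos, decreasing = TRUE)
  for (k in ord) {
    sp <- specs[[k]]
    if (sp@kind == "substitution") {
      chars[sp@position] <- sp@alt
    } else {
      chars <- chars[-sp@position]
    }
  }
  if (is.null(id)) {
    id <- paste0(seq@id, "|", paste(mutationTokens(muts), collapse = ","))
  }
  ProteinSequence(id, paste(chars, collapse = ""))
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A list of [ProteinSequence-class] objects, named by identifier.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  out <- lapply(seq_along(aa), function(i) {
    ProteinSequence(ids[i], as.character(aa[[i]]))
  })
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a [ProteinSequence-class] or list of them.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (is(seqs, "ProteinSequence")) seqs <- list(seqs)
  aa <- Biostrings::AAStringSet(vapply(seqs, residues, character(1)))
  names(aa) <- vapply(seqs, seqId, character(1))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a mutation table
#'
#' CSV with columns `protein_id`, `token`, and optionally `label`. Tokens
#' are dash-normalized and syntax-checked at read time.
#'
#' @param path CSV path.
#' @return A data.frame with columns `protein_id`, `token` (canonicalized)
#'   and, if present in the file, `label`.
#' @export
readMutationTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  idcol <- intersect(c("protein_id", "parent_id"), names(df))
  if (!length(idcol) || !"token" %in% names(df)) {
    stopf("mutation table must have columns: protein_id (or parent_id), token")
  }
  idcol <- idcol[1]
  df$token <- vapply(df$token, function(t) formatMutation(parseMutation(t)),
                     character(1), USE.NAMES = FALSE)
  keep <- c(idcol, "token")
  if ("label" %in% names(df)) {
    if (!all(df$label %in% c(0, 1))) stopf("labels must be binary 0/1")
    keep <- c(keep, "label")
  }
  df[, keep]
}

#' Write a mutation table
#'
#' @param df data.frame with `protein_id`, `token` and optionally `label`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeMutationTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
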