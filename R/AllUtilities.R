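# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AROMATIC_AA <- c("F", "W", "Y")

# Formal charge at pH 7 (side chain); His treated as neutral.
AA_CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0,
               K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
               T = 0, V = 0, W = 0, Y = 0)

# Kyte-Doolittle hydropathy.
AA_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7,
                   V = 4.2, W = -0.9, Y = -1.3)

# TOP-IDP disorder propensity (Campen et al. 2008); higher = more
# disorder-promoting.
AA_DISORDER <- c(A = 0.06, C = 0.02, D = 0.192, E = 0.736, F = -0.697,
                 G = 0.166, H = 0.303, I = -0.486, K = 0.586, L = -0.326,
                 M = -0.397, N = 0.007, P = 0.987, Q = 0.318, R = 0.180,
                 S = 0.341, T = 0.059, V = -0.121, W = -0.884, Y = -0.510)

#' @keywords internal
#' @noRd
checkResidueString <- function(residues) {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    return("residues must be a single non-NA character string")
  }
  if (nchar(residues) < 1L) {
    return("sequence must contain at least one residue")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad)) {
    return(sprintf("non-canonical residue code(s): %s",
                   paste(bad, collapse = ", ")))
  }
  TRUE
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates expr as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
deriveSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(k)) %% 2147483399) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

logistic <- function(x) 1 / (1 + exp(-x))
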