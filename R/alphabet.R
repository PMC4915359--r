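#' @useDynLib rabscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# The 20 standard residues in alphabetical one-letter order.  This order is
# the fixed tie-break everywhere a deterministic residue choice is needed
# (consensus argmax ties, motif alternatives).
RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.blosum_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the 20 standard residues
#'
#' Returns the 20x20 integer BLOSUM62 matrix (rows/columns in alphabetical
#' residue order), taken from the matrix shipped with Biostrings.  This is the
#' default scoring matrix for all pairwise alignments and for the "similar
#' residue" relation (a pair is similar when its entry is > 0).
#'
#' @return Integer matrix with `dimnames` the 20 residues and a `name`
#'   attribute `"BLOSUM62"`.
#' @export
blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[RESIDUES, RESIDUES]
    storage.mode(m) <- "integer"
    attr(m, "name") <- "BLOSUM62"
    .blosum_cache$m <- m
  }
  .blosum_cache$m
}

#' Residues scored as similar to a residue
#'
#' The set of residues whose substitution score against `residue` is strictly
#' positive (the residue itself included, since diagonal entries are
#' positive).  Used to build motif "allowed" sets: identical consensus residue
#' plus conservative alternatives such as R/K, I/L and Y/F.
#'
#' @param residue Single upper-case residue letter.
#' @param m Substitution matrix, default [blosum62()].
#' @return Character vector of residues, alphabetical order.
#' @export
similar_residues <- function(residue, m = blosum62()) {
  stopifnot(residue %in% RESIDUES)
  RESIDUES[m[residue, RESIDUES] > 0]
}

# Split a sequence string into single characters.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Validate a protein sequence over the 20-letter alphabet; errors name the
# first offending symbol and its (1-based) position.
check_protein <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop(what, " must be a single nonempty string", call. = FALSE)
  ch <- seq_chars(s)
  bad <- which(!(ch %in% RESIDUES))
  if (length(bad))
    stop(sprintf("%s contains invalid residue '%s' at position %d",
                 what, ch[bad[1]], bad[1]), call. = FALSE)
  invisible(ch)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG state is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Small stable string hash (polynomial, mod 2^20): used to derive independent
# per-family RNG streams from one master seed, so adding one family to a
# configuration does not perturb the sequences of another.
stable_hash <- function(x) {
  h <- 0
  for (k in utf8ToInt(x)) h <- (h * 31 + k) %% 1048576
  h
}

#' Derive a reproducible stream seed from a master seed and a name
#'
#' @param seed Master integer seed.
#' @param name Stream name (for example a family name).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  as.integer((as.numeric(seed) + stable_hash(name)) %% 2147483647)
}
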