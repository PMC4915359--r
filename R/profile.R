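#' Multiple sequence alignment container
#'
#' Equal-length gapped rows over the 20-letter alphabet plus `-`.  Alignments
#' are consumed, not built: construct them upstream (for example with MAFFT)
#' or, for the indel-free synthetic families, with [pad_alignment()].
#'
#' @param sequences Character vector of gapped rows (equal width).
#' @param ids Row identifiers; default `names(sequences)` or `seq_1` style.
#' @return Object of class `multiple_alignment` with fields `ids`, `rows`,
#'   `n_columns`.
#' @export
multiple_alignment <- function(sequences, ids = NULL) {
  if (length(sequences) < 2L)
    stop("an alignment needs at least 2 rows", call. = FALSE)
  if (is.null(ids))
    ids <- if (!is.null(names(sequences))) names(sequences)
           else sprintf("seq_%d", seq_along(sequences))
  w <- unique(nchar(sequences))
  if (length(w) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  ok <- c(RESIDUES, "-")
  for (k in seq_along(sequences)) {
    ch <- seq_chars(sequences[k])
    bad <- which(!(ch %in% ok))
    if (length(bad))
      stop(sprintf("row '%s' contains invalid character '%s' at column %d",
                   ids[k], ch[bad[1]], bad[1]), call. = FALSE)
    if (all(ch == "-"))
      stop(sprintf("row '%s' is all gaps", ids[k]), call. = FALSE)
  }
  structure(list(ids = as.character(ids),
                 rows = unname(as.character(sequences)),
                 n_columns = w),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment: %d rows x %d columns\n",
              length(x$rows), x$n_columns))
  invisible(x)
}

#' Right-pad unaligned sequences into a trivial alignment
#'
#' For star-topology synthetic families without indels the natural alignment
#' places every scaffold position in its own column; rows are padded with
#' trailing gaps to the longest sequence, so hypervariable tails end up in
#' high-gap-fraction columns (as in a real hypervariable region).
#'
#' @param sequences Ungapped sequences.
#' @param ids Row identifiers.
#' @return A [multiple_alignment()].
#' @export
pad_alignment <- function(sequences, ids = NULL) {
  w <- max(nchar(sequences))
  padded <- vapply(sequences, function(s)
    paste0(s, strrep("-", w - nchar(s))), "", USE.NAMES = FALSE)
  if (is.null(ids)) ids <- names(sequences)
  multiple_alignment(padded, ids)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

#' Build a position-specific profile model from an alignment
#'
#' Match columns are the alignment columns whose gap fraction is strictly
#' below `match_gap_threshold`.  Per match column, emission probabilities are
#' `(count + pseudocount * background) / (n_ungapped + pseudocount)`, so each
#' emission row sums to one and is strictly positive for any positive
#' pseudocount.
#'
#' @param msa A [multiple_alignment()].
#' @param match_gap_threshold Columns with gap fraction below this are match
#'   columns; default 0.5.
#' @param pseudocount Pseudocount weight; default 1.
#' @param background Length-20 probability vector (alphabetical residue
#'   order), `"uniform"` (default) or `"data"` (overall residue frequencies
#'   of the alignment).
#' @param family_name Label stored in the model.
#' @return Object of class `profile_model`: `match_columns` (increasing MSA
#'   column indices), `emission` (20 x K matrix), `background`,
#'   `pseudocount`, `family_name`.
#' @export
build_profile <- function(msa, match_gap_threshold = 0.5, pseudocount = 1,
                          background = "uniform", family_name = "family") {
  stopifnot(inherits(msa, "multiple_alignment"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  m <- msa_matrix(msa)
  counts <- vapply(seq_len(ncol(m)), function(j)
    tabulate(match(m[, j], RESIDUES), nbins = 20L), integer(20))
  rownames(counts) <- RESIDUES
  gap_fraction <- colMeans(m == "-")
  match_columns <- which(gap_fraction < match_gap_threshold)
  if (!length(match_columns))
    stop("no match columns: every column exceeds the gap threshold",
         call. = FALSE)
  bg <- if (identical(background, "uniform")) {
    stats::setNames(rep(1 / 20, 20), RESIDUES)
  } else if (identical(background, "data")) {
    tot <- rowSums(counts)
    stats::setNames(tot / sum(tot), RESIDUES)
  } else {
    stopifnot(is.numeric(background), length(background) == 20L,
              abs(sum(background) - 1) < 1e-9)
    stats::setNames(as.numeric(background), RESIDUES)
  }
  emission <- vapply(match_columns, function(j) {
    n <- sum(counts[, j])
    (counts[, j] + pseudocount * bg) / (n + pseudocount)
  }, numeric(20))
  rownames(emission) <- RESIDUES
  structure(list(match_columns = as.integer(match_columns),
                 emission = emission, background = bg,
                 pseudocount = pseudocount, family_name = family_name,
                 n_alignment_columns = msa$n_columns,
                 n_sequences = length(msa$rows)),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile_model '%s': %d match columns of %d (pseudocount %g)\n",
              x$family_name, length(x$match_columns),
              x$n_alignment_columns, x$pseudocount))
  invisible(x)
}

#' Plurality-rule consensus of a profile
#'
#' Per match column the most probable residue; ties broken alphabetically.
#' Residues with emission probability strictly greater than 0.5 are written
#' upper case, all others lower case.
#'
#' @param p A `profile_model`.
#' @return Object of class `consensus_sequence`: `sequence` (case-coded
#'   string), `residues` (upper-case), `probabilities` (per-column argmax
#'   probability).
#' @export
consensus <- function(p) {
  stopifnot(inherits(p, "profile_model"))
  idx <- apply(p$emission, 2L, which.max)   # first max = alphabetical tie-break
  prob <- p$emission[cbind(idx, seq_along(idx))]
  res <- RESIDUES[idx]
  cased <- ifelse(prob > 0.5, res, tolower(res))
  structure(list(sequence = paste(cased, collapse = ""),
                 residues = res, probabilities = unname(prob),
                 family_name = p$family_name),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("consensus (%s), %d columns:\n%s\n",
              x$family_name, nchar(x$sequence), x$sequence))
  invisible(x)
}

#' @export
as.character.consensus_sequence <- function(x, ...) x$sequence

column_freqs <- function(column, include_gaps = FALSE) {
  if (is.numeric(column)) {
    counts <- column[column > 0]
  } else {
    ch <- if (length(column) == 1L && nchar(column[1]) > 1L)
      seq_chars(column) else as.character(column)
    if (!include_gaps) ch <- ch[!(ch %in% c("-", "."))]
    if (!length(ch)) return(numeric(0))
    counts <- table(ch)
  }
  if (!length(counts) || sum(counts) == 0) return(numeric(0))
  as.numeric(counts) / sum(counts)
}

#' Shannon entropy of an alignment column
#'
#' `H(X) = -sum p(x_i) log2 p(x_i)` in bits over the empirical residue
#' frequencies of the column.  Gaps are treated as missing and excluded from
#' the frequencies by default; `include_gaps = TRUE` scores the gap as a 21st
#' symbol instead.
#'
#' @param column Character vector of residues (or a single string), or a
#'   named/plain numeric vector of residue counts.
#' @param include_gaps Count `-` as a symbol instead of excluding it.
#' @return Entropy in bits, in `[0, log2 20]` (gap-free case).
#' @export
column_entropy <- function(column, include_gaps = FALSE) {
  p <- column_freqs(column, include_gaps)
  if (!length(p))
    stop("column entropy is undefined for an all-gap column", call. = FALSE)
  -sum(p * log2(p))
}

#' Per-column entropy profile of an alignment
#'
#' @param msa A [multiple_alignment()].
#' @param include_gaps Passed to [column_entropy()].
#' @return Numeric vector, one value per alignment column; all-gap columns
#'   are `NA`.
#' @export
entropy_profile <- function(msa, include_gaps = FALSE) {
  m <- msa_matrix(msa)
  vapply(seq_len(ncol(m)), function(j) {
    p <- column_freqs(m[, j], include_gaps)
    if (!length(p)) NA_real_ else -sum(p * log2(p))
  }, 0)
}

#' Information content of an alignment column
#'
#' Logo-style information `R = sum p log2(p / background)`; with the default
#' uniform background this equals `log2 20 - H(column)`.  No small-sample
#' correction is applied.  Letter heights for logo export are `p * R`.
#'
#' @param column As in [column_entropy()].
#' @param background Length-20 background probabilities (alphabetical order)
#'   or `NULL` for uniform.
#' @return List with `bits` and named `heights`.
#' @export
information_content <- function(column, background = NULL) {
  if (is.numeric(column) && !is.null(names(column))) {
    counts <- column[RESIDUES]
    counts[is.na(counts)] <- 0
  } else {
    ch <- if (length(column) == 1L && nchar(column[1]) > 1L)
      seq_chars(column) else as.character(column)
    ch <- ch[!(ch %in% c("-", "."))]
    counts <- vapply(RESIDUES, function(r) sum(ch == r), 0)
  }
  if (sum(counts) == 0)
    stop("information content is undefined for an all-gap column",
         call. = FALSE)
  p <- counts / sum(counts)
  bg <- if (is.null(background)) rep(1 / 20, 20) else {
    stopifnot(length(background) == 20L)
    as.numeric(background)
  }
  nz <- p > 0
  bits <- sum(p[nz] * log2(p[nz] / bg[nz]))
  list(bits = bits, heights = stats::setNames(p * bits, RESIDUES))
}

#' Score a sequence against a profile model
#'
#' Global affine-gap dynamic programme between the profile's match columns
#' and the sequence.  Pairing residue `x` with match column `j` scores
#' `log2(emission_j(x) / background(x))` bits; residues outside the standard
#' alphabet (B, Z, X, U, ...) score 0 bits at any column (background odds).
#' Insertions emit against the background (0 net bits) and deletions consume
#' a column; both pay affine gap penalties, first gap position
#' `gap_open + gap_extend`.  Traceback ties prefer the diagonal.
#'
#' @param p A `profile_model`.
#' @param s Sequence string (nonempty).
#' @param gap_open,gap_extend Gap penalties in bits; defaults 4 and 0.25.
#' @return Object of class `profile_alignment`: `bits` (total log-odds
#'   score), `path` (data.frame `column` = match-column ordinal, `position` =
#'   sequence position, `NA` marking gaps), `coverage` (fraction of match
#'   columns aligned to a residue), `span` (matched sequence region, 1-based
#'   inclusive).
#' @export
score_sequence <- function(p, s, gap_open = 4, gap_extend = 0.25) {
  stopifnot(inherits(p, "profile_model"))
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("sequence must be a single nonempty string", call. = FALSE)
  ch <- seq_chars(s)
  idx <- match(ch, RESIDUES)           # NA -> unknown, scored as background
  logodds <- log2(p$emission / p$background)   # 20 x K
  K <- ncol(logodds)
  S <- matrix(0, nrow = K, ncol = length(ch))
  known <- !is.na(idx)
  S[, known] <- t(logodds[idx[known], , drop = FALSE])
  res <- gotoh_align_cpp(S, gap_open, gap_extend, local = FALSE)
  pr <- res$pairs
  path <- data.frame(
    column = ifelse(pr[, 1] > 0, pr[, 1], NA_integer_),
    position = ifelse(pr[, 2] > 0, pr[, 2], NA_integer_))
  matched <- !is.na(path$column) & !is.na(path$position)
  span <- if (any(matched)) range(path$position[matched])
          else c(NA_integer_, NA_integer_)
  structure(list(bits = res$score, path = path,
                 coverage = sum(matched) / K,
                 span = span, family_name = p$family_name),
            class = "profile_alignment")
}

#' @export
print.profile_alignment <- function(x, ...) {
  cat(sprintf("profile_alignment vs '%s': %.2f bits, coverage %.2f, span %d-%d\n",
              x$family_name, x$bits, x$coverage, x$span[1], x$span[2]))
  invisible(x)
}
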