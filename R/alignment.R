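new_alignment_result <- function(aligned_a, aligned_b, score, mode,
                                 start_a, end_a, start_b, end_b) {
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score, mode = mode,
                 start_a = start_a, end_a = end_a,
                 start_b = start_b, end_b = end_b),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment, score %.2f\n", x$mode, x$score))
  cat(sprintf("a [%d-%d]: %s\n", x$start_a, x$end_a, x$aligned_a))
  cat(sprintf("b [%d-%d]: %s\n", x$start_b, x$end_b, x$aligned_b))
  invisible(x)
}

pair_score_matrix <- function(a_ch, b_ch, m) {
  mm <- m[a_ch, b_ch, drop = FALSE]
  matrix(as.numeric(mm), nrow = length(a_ch))
}

run_pairwise <- function(a, b, m, gap_open, gap_extend, local) {
  a_ch <- check_protein(a, "sequence a")
  b_ch <- check_protein(b, "sequence b")
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be nonnegative", call. = FALSE)
  res <- gotoh_align_cpp(pair_score_matrix(a_ch, b_ch, m),
                         gap_open, gap_extend, local)
  p <- res$pairs
  if (nrow(p) == 0L)
    return(new_alignment_result("", "", 0, if (local) "local" else "global",
                                NA_integer_, NA_integer_,
                                NA_integer_, NA_integer_))
  aa <- ifelse(p[, 1] > 0, a_ch[pmax(p[, 1], 1L)], "-")
  bb <- ifelse(p[, 2] > 0, b_ch[pmax(p[, 2], 1L)], "-")
  ia <- p[p[, 1] > 0, 1]
  ib <- p[p[, 2] > 0, 2]
  new_alignment_result(paste(aa, collapse = ""), paste(bb, collapse = ""),
                       res$score, if (local) "local" else "global",
                       if (length(ia)) min(ia) else NA_integer_,
                       if (length(ia)) max(ia) else NA_integer_,
                       if (length(ib)) min(ib) else NA_integer_,
                       if (length(ib)) max(ib) else NA_integer_)
}

#' Global (Needleman-Wunsch) pairwise alignment with affine gaps
#'
#' Three-state Gotoh dynamic programme; a gap of length L costs
#' `gap_open + L * gap_extend`.  Traceback ties are broken deterministically:
#' diagonal first, then gap in `b`, then gap in `a`.  Defaults mirror the
#' EMBOSS `needle`/`water` convention (BLOSUM62, open 10, extend 0.5).
#'
#' @param a,b Protein sequences (20-letter alphabet); unknown letters raise
#'   an error naming the symbol and position.
#' @param m Substitution matrix, default [blosum62()].
#' @param gap_open,gap_extend Nonnegative gap penalties.
#' @return An `alignment_result`: gapped `aligned_a`/`aligned_b` of equal
#'   length, `score`, `mode`, and 1-based inclusive `start_*`/`end_*`
#'   coordinates of the aligned region in each input.
#' @export
align_global <- function(a, b, m = blosum62(), gap_open = 10, gap_extend = 0.5)
  run_pairwise(a, b, m, gap_open, gap_extend, local = FALSE)

#' Local (Smith-Waterman) pairwise alignment with affine gaps
#'
#' As [align_global()] but returns the maximal-scoring local region; when no
#' pairing scores positive the empty alignment with score 0 is returned.
#'
#' @inheritParams align_global
#' @return An `alignment_result` (empty strings and `NA` coordinates for the
#'   empty alignment).
#' @export
align_local <- function(a, b, m = blosum62(), gap_open = 10, gap_extend = 0.5)
  run_pairwise(a, b, m, gap_open, gap_extend, local = TRUE)

alignment_columns <- function(r) {
  list(a = seq_chars(r$aligned_a), b = seq_chars(r$aligned_b))
}

#' Percent identity of an alignment
#'
#' 100 x identical columns / denominator.  With `mode = "aligned_columns"`
#' (EMBOSS convention) the denominator is the full number of alignment
#' columns, gap columns included; with `"shorter_seq"` it is the ungapped
#' length of the shorter aligned row.
#'
#' @param r An `alignment_result`.
#' @param mode Denominator convention.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(r, mode = c("aligned_columns", "shorter_seq")) {
  mode <- match.arg(mode)
  if (!nzchar(r$aligned_a))
    stop("percent identity is undefined for an empty alignment", call. = FALSE)
  cols <- alignment_columns(r)
  ident <- sum(cols$a == cols$b & cols$a != "-")
  den <- switch(mode,
                aligned_columns = length(cols$a),
                shorter_seq = min(sum(cols$a != "-"), sum(cols$b != "-")))
  100 * ident / den
}

#' Percent similarity of an alignment
#'
#' 100 x columns whose residue pair scores > 0 in the substitution matrix,
#' over all alignment columns; gap columns are never similar.  Always at
#' least the percent identity (diagonal entries are positive).
#'
#' @param r An `alignment_result`.
#' @param m Substitution matrix, default [blosum62()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_similarity <- function(r, m = blosum62()) {
  if (!nzchar(r$aligned_a))
    stop("percent similarity is undefined for an empty alignment", call. = FALSE)
  cols <- alignment_columns(r)
  both <- cols$a != "-" & cols$b != "-"
  sim <- sum(m[cbind(cols$a[both], cols$b[both])] > 0)
  100 * sim / length(cols$a)
}
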