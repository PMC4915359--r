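#' Pairwise similarity matrix between family consensus sequences
#'
#' All-against-all local and global alignments of the (ungapped, upper-cased)
#' consensus sequences, reporting percent identity and percent similarity
#' under the conventions of [percent_identity()] (aligned-columns
#' denominator) and [percent_similarity()].  Each unordered pair is computed
#' once, so the matrices are exactly symmetric; diagonals are 100.
#'
#' @param consensi Named character vector (or list of `consensus_sequence`s)
#'   of family consensus sequences.
#' @param m Substitution matrix.
#' @param gap_open,gap_extend Alignment gap penalties.
#' @return Object of class `family_similarity`: matrices `local_identity`,
#'   `local_similarity`, `global_identity`, `global_similarity`.
#' @export
family_similarity_matrix <- function(consensi, m = blosum62(),
                                     gap_open = 10, gap_extend = 0.5) {
  seqs <- vapply(consensi, function(x)
    toupper(if (inherits(x, "consensus_sequence")) x$sequence else x), "")
  nms <- names(seqs)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("consensus sequences must be named by family", call. = FALSE)
  n <- length(seqs)
  mk <- function() matrix(100, n, n, dimnames = list(nms, nms))
  out <- list(local_identity = mk(), local_similarity = mk(),
              global_identity = mk(), global_similarity = mk())
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      loc <- align_local(seqs[i], seqs[j], m, gap_open, gap_extend)
      glo <- align_global(seqs[i], seqs[j], m, gap_open, gap_extend)
      vals <- c(local_identity = percent_identity(loc),
                local_similarity = percent_similarity(loc, m),
                global_identity = percent_identity(glo),
                global_similarity = percent_similarity(glo, m))
      for (k in names(vals)) {
        out[[k]][i, j] <- vals[[k]]
        out[[k]][j, i] <- vals[[k]]
      }
    }
  }
  structure(out, class = "family_similarity")
}

#' @export
print.family_similarity <- function(x, ...) {
  cat("family similarity (local %identity / %similarity):\n")
  print(round(x$local_identity, 1))
  print(round(x$local_similarity, 1))
  invisible(x)
}

#' Long-format view of a family similarity matrix
#'
#' @param fs A `family_similarity`.
#' @return Data frame: `family_a`, `family_b`, the four percentages.
#' @export
similarity_long <- function(fs) {
  nms <- rownames(fs$local_identity)
  grid <- expand.grid(family_a = nms, family_b = nms,
                      stringsAsFactors = FALSE)
  for (k in names(fs))
    grid[[k]] <- fs[[k]][cbind(grid$family_a, grid$family_b)]
  grid
}

#' Star joint alignment of consensus sequences
#'
#' Builds a cross-family column correspondence by aligning every consensus
#' globally to a reference consensus and merging the pairwise alignments
#' around the reference (a progressive star alignment).  This is a
#' convenience stand-in for a curated joint alignment: star merging is exact
#' for indel-free families but does not realign insertions between non-
#' reference pairs.
#'
#' @param consensi Named character vector (or `consensus_sequence` list).
#' @param reference Name of the reference family (default first).
#' @param m,gap_open,gap_extend Alignment parameters.
#' @return A [multiple_alignment()] whose rows are the upper-cased consensus
#'   sequences, named by family, reference first.
#' @export
consensus_joint_alignment <- function(consensi, reference = NULL,
                                      m = blosum62(),
                                      gap_open = 10, gap_extend = 0.5) {
  seqs <- vapply(consensi, function(x)
    toupper(if (inherits(x, "consensus_sequence")) x$sequence else x), "")
  if (is.null(reference)) reference <- names(seqs)[1]
  stopifnot(reference %in% names(seqs))
  ref <- seqs[[reference]]
  others <- setdiff(names(seqs), reference)
  L <- nchar(ref)
  # For each non-reference row: residues inserted after each reference
  # position (slot 0 = before the first) and the aligned residue per
  # reference position ('-' for deletions).
  parsed <- lapply(others, function(nm) {
    al <- align_global(ref, seqs[[nm]], m, gap_open, gap_extend)
    a <- seq_chars(al$aligned_a)
    b <- seq_chars(al$aligned_b)
    ins <- vector("list", L + 1L)
    for (k in seq_len(L + 1L)) ins[[k]] <- character(0)
    aligned <- character(L)
    rp <- 0L
    for (k in seq_along(a)) {
      if (a[k] == "-") ins[[rp + 1L]] <- c(ins[[rp + 1L]], b[k])
      else { rp <- rp + 1L; aligned[rp] <- b[k] }
    }
    list(ins = ins, aligned = aligned)
  })
  names(parsed) <- others
  slot_width <- vapply(seq_len(L + 1L), function(k)
    max(0L, vapply(parsed, function(p) length(p$ins[[k]]), 0L)), 0L)
  build_row <- function(aligned, ins) {
    pieces <- character(0)
    for (k in seq_len(L + 1L)) {
      gap_pad <- strrep("-", slot_width[k] - length(ins[[k]]))
      pieces <- c(pieces, paste(ins[[k]], collapse = ""), gap_pad)
      if (k <= L) pieces <- c(pieces, aligned[k])
    }
    paste(pieces, collapse = "")
  }
  rows <- c(stats::setNames(
    build_row(seq_chars(ref), rep(list(character(0)), L + 1L)), reference),
    vapply(others, function(nm)
      build_row(parsed[[nm]]$aligned, parsed[[nm]]$ins), ""))
  multiple_alignment(rows, ids = names(rows))
}

#' RabF-position conservation across families
#'
#' For every family, counts the motif positions whose consensus residue is
#' identical to the Rab consensus residue, and those merely similar
#' (BLOSUM62 score > 0 but not identical), using a joint alignment of the
#' consensus sequences as the cross-family column correspondence.
#'
#' @param profiles Named list of family `profile_model`s (must contain
#'   `reference`).
#' @param motifs List of [motif_definition()]s on the reference profile.
#' @param joint Optional [multiple_alignment()] of the consensus sequences
#'   (rows named by family).  When `NULL` a star alignment around the
#'   reference is computed with [consensus_joint_alignment()].
#' @param reference Reference family name, default `"Rab"`.
#' @param m Substitution matrix for the similarity relation.
#' @return Data frame: `family`, `motif`, `n_positions`, `identical`,
#'   `similar`, plus a `total` row per family.
#' @export
motif_conservation_table <- function(profiles, motifs, joint = NULL,
                                     reference = "Rab", m = blosum62()) {
  stopifnot(reference %in% names(profiles))
  consensi <- lapply(profiles, consensus)
  if (is.null(joint))
    joint <- consensus_joint_alignment(consensi, reference = reference)
  stopifnot(inherits(joint, "multiple_alignment"),
            all(names(profiles) %in% joint$ids))
  jm <- msa_matrix(joint)
  rownames(jm) <- joint$ids
  ref_row <- toupper(jm[reference, ])
  # joint column of the k-th reference consensus position
  ref_cols <- which(ref_row != "-")
  ref_res <- consensi[[reference]]$residues
  stopifnot(length(ref_cols) == length(ref_res))
  out <- list()
  for (fam in names(profiles)) {
    fam_row <- toupper(jm[fam, ])
    per_motif <- lapply(motifs, function(mo) {
      fres <- fam_row[ref_cols[mo$columns]]
      rres <- ref_res[mo$columns]
      ident <- fres == rres
      sim <- !ident & fres != "-" &
        m[cbind(rres, ifelse(fres == "-", rres, fres))] > 0
      data.frame(family = fam, motif = mo$name,
                 n_positions = length(mo$columns),
                 identical = sum(ident), similar = sum(sim),
                 stringsAsFactors = FALSE)
    })
    fam_df <- do.call(rbind, per_motif)
    total <- data.frame(family = fam, motif = "total",
                        n_positions = sum(fam_df$n_positions),
                        identical = sum(fam_df$identical),
                        similar = sum(fam_df$similar),
                        stringsAsFactors = FALSE)
    out[[fam]] <- rbind(fam_df, total)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' C-terminal features of a sequence
#'
#' Classifies the terminal residues against the standard Rab prenylation
#' motif classes, in priority order `CC` > `CXC` > `CCXX` > `XXCC` >
#' `other-terminal-Cys` (any cysteine in the last three residues), else
#' `none`; note a terminal `CC` always matches class `CC`, so `XXCC` is
#' subsumed.  Also counts basic residues (K/R/H) in the tail beyond the
#' G domain and flags a polybasic region (>= 3 K/R within the last 10
#' residues).
#'
#' @param sequence Residue string.
#' @param domain_end Last position of the G domain (1-based); the tail is
#'   everything after it.
#' @return List: `domain_end`, `tail_length`, `cys_motif_class`,
#'   `basic_residue_count`, `polybasic`.
#' @export
cterm_features <- function(sequence, domain_end) {
  ch <- seq_chars(toupper(sequence))
  n <- length(ch)
  domain_end <- as.integer(domain_end)
  if (domain_end < 0L || domain_end > n)
    stop("domain_end must lie within the sequence", call. = FALSE)
  at <- function(k) if (k >= 1L) ch[k] else ""   # k counted from the end
  cls <- if (n >= 2L && at(n - 1L) == "C" && at(n) == "C") "CC"
    else if (n >= 3L && at(n - 2L) == "C" && at(n) == "C") "CXC"
    else if (n >= 4L && at(n - 3L) == "C" && at(n - 2L) == "C") "CCXX"
    else if (n >= 4L && at(n - 1L) == "C" && at(n) == "C") "XXCC"
    else if (any(ch[seq.int(max(1L, n - 2L), n)] == "C")) "other-terminal-Cys"
    else "none"
  tail_ch <- if (domain_end < n) ch[(domain_end + 1L):n] else character(0)
  last10 <- ch[seq.int(max(1L, n - 9L), n)]
  list(domain_end = domain_end,
       tail_length = n - domain_end,
       cys_motif_class = cls,
       basic_residue_count = sum(tail_ch %in% c("K", "R", "H")),
       polybasic = sum(last10 %in% c("K", "R")) >= 3L)
}

#' C-terminal report for a set of records
#'
#' @param records Data frame with `id`, `sequence`.
#' @param domain_end Integer vector (recycled) of G-domain end positions.
#' @return Data frame, one row per sequence.
#' @export
cterm_report <- function(records, domain_end) {
  domain_end <- rep_len(domain_end, nrow(records))
  rows <- lapply(seq_len(nrow(records)), function(k) {
    f <- cterm_features(records$sequence[k], domain_end[k])
    data.frame(id = records$id[k], domain_end = f$domain_end,
               tail_length = f$tail_length,
               cys_motif_class = f$cys_motif_class,
               basic_residue_count = f$basic_residue_count,
               polybasic = f$polybasic, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phylogenetic profile of classification results
#'
#' Aggregates final labels by species: per-species counts of each label,
#' total, and presence flags for at least one Rab (subfamily-annotated) and
#' at least one Rab-like protein.  Rows are ordered by species name.
#'
#' @param results Data frame from [classify_sequences()] (columns `species`,
#'   `final_label`).
#' @return Data frame: `species`, one `n_<label>` column per observed label,
#'   `n_total`, `has_rab`, `has_rablike`.
#' @export
phylo_profile <- function(results) {
  if (!nrow(results))
    return(data.frame(species = character(0), n_total = integer(0),
                      has_rab = logical(0), has_rablike = logical(0),
                      stringsAsFactors = FALSE))
  tab <- table(results$species, results$final_label)
  species <- sort(rownames(tab))
  tab <- tab[species, , drop = FALSE]
  df <- data.frame(species = species, stringsAsFactors = FALSE)
  for (lab in colnames(tab))
    df[[paste0("n_", gsub("[^A-Za-z0-9]+", "_", lab))]] <- as.integer(tab[, lab])
  df$n_total <- as.integer(rowSums(tab))
  rab_cols <- grepl("^Rab:", colnames(tab))
  df$has_rab <- if (any(rab_cols))
    rowSums(tab[, rab_cols, drop = FALSE]) >= 1L else FALSE
  df$has_rablike <- if ("Rab-like" %in% colnames(tab))
    tab[, "Rab-like"] >= 1L else FALSE
  rownames(df) <- NULL
  df
}
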