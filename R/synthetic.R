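#' Specification of one synthetic GTPase-like family
#'
#' A family is defined by an ancestral G-domain scaffold, a set of
#' family-specific motif blocks written into that scaffold, a per-site
#' substitution rate, and optional C-terminal features (a hypervariable tail
#' and a terminal cysteine motif of the prenylation-site kind).  Sequences of
#' the family are independent draws from this star-shaped model: the scaffold
#' with motifs is mutated per site, protected motif blocks are left intact,
#' the hypervariable tail is mutated at an elevated rate from a family
#' ancestral tail, and the cysteine motif is appended verbatim.
#'
#' @param family_name Family label; also the default species tag.
#' @param scaffold Ancestral sequence, 20-letter alphabet (typically 160-220
#'   residues for a G domain).
#' @param motif_blocks List of blocks, each a list with `name`, `start`
#'   (1-based scaffold position), `consensus` (residue string) and
#'   `protected` (logical; protected blocks receive zero substitutions).
#'   An optional per-block `rate` overrides the family rate for ablation
#'   experiments on unprotected blocks.
#' @param mutation_rate Per-site substitution probability in `[0, 1)`.
#' @param cterm_tail_length Length of the hypervariable C-terminal tail,
#'   >= 0.  One ancestral tail is drawn uniformly per family and mutated per
#'   sequence at five times the family rate (capped at 0.75), so tails are
#'   poorly conserved at realistic rates yet identical at rate 0.
#' @param cterm_cys_motif One of `"none"`, `"CC"`, `"CXC"`, `"CCXX"`,
#'   `"XXCC"`; appended at the very C terminus, `X` instantiated with a
#'   random non-cysteine residue.  With `"none"` the terminal 4-residue
#'   window is guaranteed cysteine-free (substitutions there are redrawn
#'   from the 18 non-cysteine alternatives) so the planted class is exact
#'   ground truth.
#' @param n_sequences Number of sequences to emit.
#' @param seed Integer seed of the family's RNG stream.
#' @param species Species tag carried into FASTA headers.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(family_name, scaffold, motif_blocks = list(),
                        mutation_rate = 0.1, cterm_tail_length = 0,
                        cterm_cys_motif = c("none", "CC", "CXC", "CCXX", "XXCC"),
                        n_sequences = 50, seed = 1, species = family_name) {
  cterm_cys_motif <- match.arg(cterm_cys_motif)
  check_protein(scaffold, sprintf("scaffold of '%s'", family_name))
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)", call. = FALSE)
  if (cterm_tail_length < 0) stop("cterm_tail_length must be >= 0", call. = FALSE)
  if (n_sequences < 1) stop("n_sequences must be >= 1", call. = FALSE)
  L <- nchar(scaffold)
  spans <- matrix(0, nrow = 0, ncol = 2)
  for (b in motif_blocks) {
    stopifnot(is.list(b), !is.null(b$name), !is.null(b$start), !is.null(b$consensus))
    check_protein(b$consensus, sprintf("motif '%s'", b$name))
    end <- b$start + nchar(b$consensus) - 1L
    if (b$start < 1L || end > L)
      stop(sprintf("motif '%s' exceeds scaffold bounds", b$name), call. = FALSE)
    if (nrow(spans) && any(b$start <= spans[, 2] & end >= spans[, 1]))
      stop(sprintf("motif '%s' overlaps another block", b$name), call. = FALSE)
    spans <- rbind(spans, c(b$start, end))
  }
  structure(list(family_name = family_name, scaffold = scaffold,
                 motif_blocks = motif_blocks, mutation_rate = mutation_rate,
                 cterm_tail_length = as.integer(cterm_tail_length),
                 cterm_cys_motif = cterm_cys_motif,
                 n_sequences = as.integer(n_sequences),
                 seed = as.integer(seed), species = species),
            class = "family_spec")
}

#' @export
print.family_spec <- function(x, ...) {
  cat(sprintf("family_spec '%s': %d aa scaffold, %d motif blocks, rate %.3f,\n",
              x$family_name, nchar(x$scaffold), length(x$motif_blocks),
              x$mutation_rate))
  cat(sprintf("  tail %d, C-term motif %s, n = %d, seed %d\n",
              x$cterm_tail_length, x$cterm_cys_motif, x$n_sequences, x$seed))
  invisible(x)
}

#' Ancestral sequence of a family (scaffold with motif blocks written in)
#'
#' @param spec A [family_spec()].
#' @return Residue string.
#' @export
ancestral_sequence <- function(spec) {
  ch <- seq_chars(spec$scaffold)
  for (b in spec$motif_blocks) {
    idx <- b$start:(b$start + nchar(b$consensus) - 1L)
    ch[idx] <- seq_chars(b$consensus)
  }
  paste(ch, collapse = "")
}

# Positions (1-based) covered by protected blocks.
protected_positions <- function(spec) {
  out <- integer(0)
  for (b in spec$motif_blocks)
    if (isTRUE(b$protected))
      out <- c(out, b$start:(b$start + nchar(b$consensus) - 1L))
  out
}

# Core mutation step on a character vector, drawing from the current RNG
# stream: each unprotected position is substituted with probability `rate` by
# a uniform draw over the other 19 residues.
mutate_chars <- function(ch, rate, protected = integer(0)) {
  if (rate == 0) return(ch)
  hit <- stats::runif(length(ch)) < rate
  if (length(protected)) hit[protected] <- FALSE
  for (p in which(hit)) ch[p] <- sample(RESIDUES[RESIDUES != ch[p]], 1L)
  ch
}

#' Mutate a sequence with per-site uniform substitutions
#'
#' Each unprotected position is independently replaced, with probability
#' `rate`, by a residue drawn uniformly from the other 19.  Protected
#' positions are never changed.  Deterministic for a given seed.
#'
#' @param sequence Residue string over the 20-letter alphabet.
#' @param rate Substitution probability in `[0, 1)`.
#' @param protected Integer vector of protected positions (1-based).
#' @param seed Integer seed.
#' @return Mutated residue string.
#' @export
mutate_sequence <- function(sequence, rate, protected = integer(0), seed = 1) {
  ch <- check_protein(sequence)
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)", call. = FALSE)
  if (length(protected) && (any(protected < 1) || any(protected > length(ch))))
    stop("protected positions outside sequence", call. = FALSE)
  with_seed(seed, paste(mutate_chars(ch, rate, protected), collapse = ""))
}

# Instantiate a terminal cysteine motif; X positions get random non-C residues.
cys_motif_chars <- function(kind) {
  non_c <- RESIDUES[RESIDUES != "C"]
  switch(kind,
         none = character(0),
         CC   = c("C", "C"),
         CXC  = c("C", sample(non_c, 1L), "C"),
         CCXX = c("C", "C", sample(non_c, 2L, replace = TRUE)),
         XXCC = c(sample(non_c, 2L, replace = TRUE), "C", "C"))
}

#' Generate one synthetic family with ground truth
#'
#' Draws `n_sequences` independent sequences from a [family_spec()] and a
#' truth table recomputable from the emitted residues: the true family label,
#' one intact flag per motif block (emitted block equals its consensus), the
#' planted C-terminal cysteine flag and the C-terminal length beyond the
#' G domain.
#'
#' @param spec A [family_spec()].
#' @return List with `records` (data.frame: `id`, `species`, `sequence`) and
#'   `truth` (data.frame: `id`, `family`, `species`, per-block intact flags in
#'   `motifs_intact`, `n_motifs`, `n_motifs_intact`, `has_cys_motif`,
#'   `cterm_length`, `domain_end`).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  anc <- seq_chars(ancestral_sequence(spec))
  prot <- protected_positions(spec)
  L <- length(anc)
  non_c <- RESIDUES[RESIDUES != "C"]
  blocks <- spec$motif_blocks
  # the tail diverges much faster than the domain (hypervariable region)
  tail_rate <- min(0.75, 5 * spec$mutation_rate)
  with_seed(spec$seed, {
    tail_anc <- if (spec$cterm_tail_length > 0)
      sample(RESIDUES, spec$cterm_tail_length, replace = TRUE) else character(0)
    cys_anc <- cys_motif_chars(spec$cterm_cys_motif)
    seqs <- character(spec$n_sequences)
    intact <- matrix(NA, spec$n_sequences, length(blocks))
    for (k in seq_len(spec$n_sequences)) {
      ch <- mutate_chars(anc, spec$mutation_rate, prot)
      # per-block override rate for ablation-style experiments
      for (b in blocks) {
        if (!is.null(b$rate) && !isTRUE(b$protected)) {
          idx <- b$start:(b$start + nchar(b$consensus) - 1L)
          ch[idx] <- mutate_chars(seq_chars(b$consensus), b$rate)
        }
      }
      tail_ch <- mutate_chars(tail_anc, tail_rate)
      full <- c(ch, tail_ch, cys_anc)
      if (spec$cterm_cys_motif == "none") {
        # ground-truth guarantee: no spurious terminal cysteines
        win <- seq.int(max(1L, length(full) - 3L), length(full))
        win <- setdiff(win, prot)
        for (p in win[full[win] == "C"]) full[p] <- sample(non_c, 1L)
      }
      seqs[k] <- paste(full, collapse = "")
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        got <- paste(full[b$start:(b$start + nchar(b$consensus) - 1L)],
                     collapse = "")
        intact[k, bi] <- identical(got, b$consensus)
      }
    }
    ids <- sprintf("%s_%03d", spec$family_name, seq_len(spec$n_sequences))
    records <- data.frame(id = ids, species = spec$species, sequence = seqs,
                          stringsAsFactors = FALSE)
    motif_str <- if (length(blocks)) {
      nm <- vapply(blocks, `[[`, "", "name")
      apply(intact, 1L, function(r)
        paste(sprintf("%s:%d", nm, as.integer(r)), collapse = ";"))
    } else rep("", spec$n_sequences)
    truth <- data.frame(
      id = ids, family = spec$family_name, species = spec$species,
      motifs_intact = motif_str,
      n_motifs = length(blocks),
      n_motifs_intact = if (length(blocks)) rowSums(intact) else 0L,
      has_cys_motif = spec$cterm_cys_motif != "none",
      cterm_length = nchar(seqs) - L,
      domain_end = L,
      stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Generate a labelled synthetic dataset with negatives
#'
#' Concatenates the requested families (each drawn from an RNG stream derived
#' from the master seed and the family name, so families are mutually
#' independent) and appends `n_random_negatives` i.i.d. uniform-random
#' sequences whose lengths are resampled from the emitted positives.
#'
#' @param specs List of [family_spec()]s with distinct family names.
#' @param n_random_negatives Number of random negative sequences.
#' @param seed Master seed; per-family stream seeds are derived from it
#'   unless `use_spec_seeds = TRUE`.
#' @param use_spec_seeds Keep the seeds stored in the specs instead of
#'   deriving them from `seed`.
#' @param fasta,truth Optional output paths; when given, a 60-column wrapped
#'   FASTA and a tab-separated truth table are written (byte-identical for
#'   identical inputs and seed).
#' @return Invisibly, list with `records` and `truth` data frames,
#'   row-aligned with FASTA order.
#' @export
generate_dataset <- function(specs, n_random_negatives = 0, seed = 1,
                             use_spec_seeds = FALSE,
                             fasta = NULL, truth = NULL) {
  if (!length(specs)) stop("at least one family_spec is required", call. = FALSE)
  nms <- vapply(specs, `[[`, "", "family_name")
  if (anyDuplicated(nms))
    stop("duplicate family names: ", paste(unique(nms[duplicated(nms)]),
                                           collapse = ", "), call. = FALSE)
  fams <- lapply(specs, function(sp) {
    if (!use_spec_seeds) sp$seed <- derive_seed(seed, sp$family_name)
    generate_family(sp)
  })
  records <- do.call(rbind, lapply(fams, `[[`, "records"))
  truth_df <- do.call(rbind, lapply(fams, `[[`, "truth"))
  if (n_random_negatives > 0) {
    neg <- with_seed(derive_seed(seed, "negative"), {
      lens <- sample(nchar(records$sequence), n_random_negatives, replace = TRUE)
      vapply(lens, function(l)
        paste(sample(RESIDUES, l, replace = TRUE), collapse = ""), "")
    })
    ids <- sprintf("negative_%03d", seq_len(n_random_negatives))
    records <- rbind(records, data.frame(
      id = ids, species = "random", sequence = neg, stringsAsFactors = FALSE))
    truth_df <- rbind(truth_df, data.frame(
      id = ids, family = "negative", species = "random", motifs_intact = "",
      n_motifs = 0L, n_motifs_intact = 0L, has_cys_motif = FALSE,
      cterm_length = 0L, domain_end = nchar(neg), stringsAsFactors = FALSE))
  }
  rownames(records) <- rownames(truth_df) <- NULL
  if (!is.null(fasta)) write_fasta(records, fasta)
  if (!is.null(truth)) write_truth(truth_df, truth)
  invisible(list(records = records, truth = truth_df))
}

#' Randomise motif positions outside their allowed residue sets
#'
#' Ablation helper: every given position is replaced by a residue drawn
#' uniformly from the residues *not* in that position's allowed set, so the
#' ablated motif deterministically fails the motif match rule.
#'
#' @param sequence Residue string.
#' @param positions Integer vector of 1-based sequence positions.
#' @param allowed List (same length) of allowed residue sets per position, or
#'   a single set recycled; defaults to the current residue only.
#' @param seed Integer seed.
#' @return Mutated residue string.
#' @export
ablate_motif <- function(sequence, positions, allowed = NULL, seed = 1) {
  ch <- check_protein(sequence)
  stopifnot(all(positions >= 1), all(positions <= length(ch)))
  if (is.null(allowed)) allowed <- as.list(ch[positions])
  if (!is.list(allowed)) allowed <- rep(list(allowed), length(positions))
  stopifnot(length(allowed) == length(positions))
  with_seed(seed, {
    for (k in seq_along(positions)) {
      pool <- setdiff(RESIDUES, toupper(allowed[[k]]))
      ch[positions[k]] <- sample(pool, 1L)
    }
    paste(ch, collapse = "")
  })
}
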