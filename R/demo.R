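#' The five RabF-like motif blocks planted in the synthetic Rab family
#'
#' Block consensus strings follow the canonical RabF motifs of the Rab
#' family (RabF1 `IGVDF` ... RabF5 `LVYDIT`), placed in the switch-region
#' stretch of the synthetic G-domain scaffold.
#'
#' @return List of blocks (`name`, `start`, `consensus`, `protected`).
#' @export
rabf_blocks <- function() {
  list(list(name = "RabF1", start = 37L, consensus = "IGVDF",  protected = TRUE),
       list(name = "RabF2", start = 55L, consensus = "KLQIW",  protected = TRUE),
       list(name = "RabF3", start = 63L, consensus = "RFRSIT", protected = TRUE),
       list(name = "RabF4", start = 73L, consensus = "YYRGA",  protected = TRUE),
       list(name = "RabF5", start = 80L, consensus = "LVYDIT", protected = TRUE))
}

# Family-specific blocks for the non-Rab families: same spans as the RabF
# blocks, residues drawn from the family's own seeded stream (independent of
# the Rab motifs, as in real paralogous families).
family_blocks <- function(family_name, seed) {
  rb <- rabf_blocks()
  with_seed(derive_seed(seed, paste0("blocks_", family_name)), {
    lapply(rb, function(b) {
      len <- nchar(b$consensus)
      list(name = paste0(family_name, "_", b$name), start = b$start,
           consensus = paste(sample(RESIDUES, len, replace = TRUE),
                             collapse = ""),
           protected = TRUE)
    })
  })
}

#' Common G-domain-like scaffold of the synthetic superfamily
#'
#' A random 175-residue backbone shared by all synthetic families, carrying
#' the superfamily-wide guanine-nucleotide-binding boxes (a P-loop-like
#' `GDSGVGKT` and `GNKID`/`SAK`-like boxes) outside the family motif spans,
#' and no cysteine in the terminal window.
#'
#' @param seed Integer seed.
#' @param length Scaffold length (default 175).
#' @return Residue string.
#' @export
demo_scaffold <- function(seed = 42, length = 175) {
  with_seed(derive_seed(seed, "scaffold"), {
    ch <- sample(RESIDUES, length, replace = TRUE)
    plant <- function(ch, start, s) {
      idx <- start:(start + nchar(s) - 1L)
      ch[idx] <- seq_chars(s)
      ch
    }
    ch <- plant(ch, 15L, "GDSGVGKT")     # P-loop-like box (shared)
    if (length >= 114L) ch <- plant(ch, 110L, "GNKID")
    if (length >= 142L) ch <- plant(ch, 140L, "SAK")
    win <- seq.int(max(1L, length - 3L), length)
    non_c <- RESIDUES[RESIDUES != "C"]
    for (p in win[ch[win] == "C"]) ch[p] <- sample(non_c, 1L)
    paste(ch, collapse = "")
  })
}

#' Default synthetic family specifications
#'
#' Five RAS-superfamily families (Rab, Ras, Rho, Ran, Arf) sharing the
#' common scaffold and differing by their protected motif blocks at the
#' RabF spans.  The Rab family carries the RabF blocks, a 20-residue
#' hypervariable tail and a terminal `CC` prenylation motif; the other
#' families carry their own blocks, shorter tails and no cysteine motif.
#'
#' @param n_sequences Sequences per family.
#' @param mutation_rate Per-site substitution rate (default 0.10).
#' @param seed Master seed (block composition and scaffold derive from it).
#' @return Named list of [family_spec()]s.
#' @export
demo_family_specs <- function(n_sequences = 50, mutation_rate = 0.10,
                              seed = 42) {
  scaffold <- demo_scaffold(seed)
  tails <- c(Rab = 20L, Ras = 10L, Rho = 10L, Ran = 8L, Arf = 0L)
  cys <- c(Rab = "CC", Ras = "none", Rho = "none", Ran = "none",
           Arf = "none")
  specs <- lapply(names(tails), function(fam) {
    blocks <- if (fam == "Rab") rabf_blocks() else family_blocks(fam, seed)
    family_spec(fam, scaffold, blocks,
                mutation_rate = mutation_rate,
                cterm_tail_length = tails[[fam]],
                cterm_cys_motif = cys[[fam]],
                n_sequences = n_sequences, seed = derive_seed(seed, fam))
  })
  stats::setNames(specs, names(tails))
}

# Subfamily-diagnostic blocks: four protected 3-residue blocks outside the
# RabF spans and the shared G boxes.
subfamily_blocks <- function(subfamily_name, seed) {
  starts <- c(95L, 120L, 130L, 150L)
  with_seed(derive_seed(seed, paste0("sub_", subfamily_name)), {
    lapply(seq_along(starts), function(k)
      list(name = sprintf("%s_diag%d", subfamily_name, k),
           start = starts[k],
           consensus = paste(sample(RESIDUES, 3L, replace = TRUE),
                             collapse = ""),
           protected = TRUE))
  })
}

#' Synthetic Rab subfamily specifications
#'
#' Subfamilies share the Rab ancestral sequence (scaffold plus RabF blocks)
#' and add four protected 3-residue diagnostic blocks each; members diverge
#' at a lower rate, emulating the tighter within-subfamily conservation of
#' real Rab subfamilies.
#'
#' @param n_sequences Sequences per subfamily.
#' @param mutation_rate Within-subfamily rate (default 0.05).
#' @param seed Master seed.
#' @param names Subfamily names.
#' @return Named list of [family_spec()]s.
#' @export
demo_subfamily_specs <- function(n_sequences = 30, mutation_rate = 0.05,
                                 seed = 42,
                                 names = c("RabSF1", "RabSF2", "RabSF3")) {
  scaffold <- demo_scaffold(seed)
  specs <- lapply(names, function(sf)
    family_spec(sf, scaffold,
                c(rabf_blocks(), subfamily_blocks(sf, seed)),
                mutation_rate = mutation_rate,
                cterm_tail_length = 20L, cterm_cys_motif = "CC",
                n_sequences = n_sequences, seed = derive_seed(seed, sf)))
  stats::setNames(specs, names)
}

#' Archaeal-mode Rab-like family specification
#'
#' The Rab scaffold with all five RabF blocks protected, but no
#' subfamily-diagnostic signal, no hypervariable tail and no C-terminal
#' cysteines - the sequence profile of the archaeal Rab-like proteins.
#'
#' @param n_sequences Sequences to emit.
#' @param mutation_rate Per-site rate (default 0.10).
#' @param seed Master seed.
#' @return A [family_spec()] named `RabL`.
#' @export
demo_rablike_spec <- function(n_sequences = 50, mutation_rate = 0.10,
                              seed = 42) {
  family_spec("RabL", demo_scaffold(seed), rabf_blocks(),
              mutation_rate = mutation_rate,
              cterm_tail_length = 0L, cterm_cys_motif = "none",
              n_sequences = n_sequences, seed = derive_seed(seed, "RabL"),
              species = "synthetic archaeon")
}

#' Build the demo model bundle from freshly generated training families
#'
#' Generates training draws for the five families and the three Rab
#' subfamilies, pads them into alignments, builds all profiles (superfamily
#' profile from a balanced pool across families), derives the RabF motif
#' definitions from the Rab profile, and assembles a [model_bundle()] with
#' default thresholds.
#'
#' @param seed Master seed for the training draws.
#' @param n_train Training sequences per family.
#' @param mutation_rate Family-level rate.
#' @param subfamily_rate Within-subfamily rate.
#' @param n_pool Per-family sequences pooled into the superfamily profile.
#' @param thresholds Threshold overrides for [model_bundle()].
#' @return List: `bundle`, `train` (named list of record data frames),
#'   `specs`, `subfamily_specs`.
#' @export
build_demo_bundle <- function(seed = 42, n_train = 30, mutation_rate = 0.10,
                              subfamily_rate = 0.05, n_pool = 10,
                              thresholds = list()) {
  specs <- demo_family_specs(n_train, mutation_rate, seed)
  sub_specs <- demo_subfamily_specs(n_train, subfamily_rate, seed)
  train <- lapply(specs, function(sp) {
    sp$seed <- derive_seed(seed, paste0("train_", sp$family_name))
    generate_family(sp)$records
  })
  sub_train <- lapply(sub_specs, function(sp) {
    sp$seed <- derive_seed(seed, paste0("train_", sp$family_name))
    generate_family(sp)$records
  })
  prof_of <- function(records, name) {
    msa <- pad_alignment(records$sequence, ids = records$id)
    build_profile(msa, family_name = name)
  }
  family_profiles <- lapply(names(train), function(f)
    prof_of(train[[f]], f))
  names(family_profiles) <- names(train)
  subfamily_profiles <- lapply(names(sub_train), function(f)
    prof_of(sub_train[[f]], f))
  names(subfamily_profiles) <- names(sub_train)
  pool <- do.call(rbind, lapply(train, function(r)
    r[seq_len(min(n_pool, nrow(r))), ]))
  superfamily <- prof_of(pool, "RAS_superfamily")
  motifs <- motifs_from_profile(family_profiles$Rab, rabf_blocks())
  list(bundle = model_bundle(superfamily, family_profiles,
                             subfamily_profiles, motifs,
                             thresholds = thresholds),
       train = c(train, sub_train),
       specs = specs, subfamily_specs = sub_specs)
}

#' Generate the demo evaluation dataset
#'
#' Fresh draws (independent of any training seed namespace) of the five
#' families plus the archaeal-mode Rab-like family and uniform-random
#' negatives, with ground truth.
#'
#' @param seed Master seed.
#' @param n_test Sequences per family.
#' @param mutation_rate Per-site rate.
#' @param n_negatives Random negatives.
#' @param fasta,truth Optional output paths.
#' @return List with `records` and `truth` (see [generate_dataset()]).
#' @export
demo_test_dataset <- function(seed = 42, n_test = 50, mutation_rate = 0.10,
                              n_negatives = 100, fasta = NULL, truth = NULL) {
  specs <- c(demo_family_specs(n_test, mutation_rate, seed),
             list(RabL = demo_rablike_spec(n_test, mutation_rate, seed)))
  generate_dataset(specs, n_random_negatives = n_negatives,
                   seed = derive_seed(seed, "test"),
                   fasta = fasta, truth = truth)
}

#' Synthetic C-alpha coordinate pair for superposition demos
#'
#' A self-avoiding-walk-like C-alpha trace with 3.8-Angstrom steps, and a
#' copy moved by a random rigid motion plus isotropic coordinate noise -
#' emulating two crystallographically similar G-domain folds.
#'
#' @param seed Integer seed.
#' @param n Number of residues (default 80).
#' @param noise_sd Per-coordinate Gaussian noise in Angstrom (default 0.25,
#'   an RMSD of roughly `sqrt(3) * noise_sd` before refitting).
#' @return List: `a`, `b` (`coordinate_set`-shaped data frames), `rotation`,
#'   `translation` actually applied.
#' @export
demo_structure_pair <- function(seed = 42, n = 80, noise_sd = 0.25) {
  with_seed(derive_seed(seed, "structure"), {
    steps <- matrix(stats::rnorm(3 * n), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 3.8
    xyz <- apply(steps, 2, cumsum)
    a <- data.frame(resno = seq_len(n), insert = "", resid = "ALA",
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
    ang <- stats::runif(3, 0, 2 * pi)
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, byrow = TRUE)
    R <- Rz(ang[1]) %*% Ry(ang[2]) %*% Rz(ang[3])
    tr <- stats::runif(3, -20, 20)
    M <- as.matrix(a[, c("x", "y", "z")]) %*% t(R) +
      matrix(tr, n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    b <- a
    b$x <- M[, 1]; b$y <- M[, 2]; b$z <- M[, 3]
    cls <- c("coordinate_set", "data.frame")
    class(a) <- cls; class(b) <- cls
    attr(a, "chain") <- attr(b, "chain") <- "A"
    attr(a, "source") <- "synthetic"; attr(b, "source") <- "synthetic"
    list(a = a, b = b, rotation = R, translation = tr)
  })
}
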