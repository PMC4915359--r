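test_that("mutate_sequence honours rate, protection and determinism", {
  expect_identical(mutate_sequence("ACDEF", rate = 0, seed = 1), "ACDEF")
  expect_identical(mutate_sequence("AAAA", rate = 0.99, protected = 1:4,
                                   seed = 7), "AAAA")
  expect_identical(mutate_sequence("ACDEFGHIKL", 0.3, seed = 11),
                   mutate_sequence("ACDEFGHIKL", 0.3, seed = 11))
  expect_error(mutate_sequence("ACDEF", rate = 1), "rate")
  expect_error(mutate_sequence("ACDEF", rate = -0.1), "rate")
  expect_error(mutate_sequence("ACDEF", 0.1, protected = 9L), "protected")
  expect_error(mutate_sequence("AC1EF", 0.1), "position 3")
})

test_that("observed substitution fraction matches the binomial model", {
  n <- 2000L
  rate <- 0.1
  s <- paste(rep("A", n), collapse = "")
  mut <- mutate_sequence(s, rate, seed = 123)
  frac <- mean(strsplit(mut, "")[[1]] != "A")
  sd3 <- 3 * sqrt(rate * (1 - rate) / n)
  expect_lt(abs(frac - rate), sd3)
  # and a formal binomial test across another seed
  k <- sum(strsplit(mutate_sequence(s, rate, seed = 456), "")[[1]] != "A")
  expect_gt(binom.test(k, n, rate)$p.value, 0.01)
})

test_that("family_spec validates motif blocks and parameters", {
  sc <- demo_scaffold(1)
  expect_s3_class(family_spec("F", sc, rabf_blocks()), "family_spec")
  expect_error(family_spec("F", sc, list(list(name = "m", start = 174L,
                                              consensus = "AAAA"))),
               "bounds")
  overlapping <- list(list(name = "a", start = 10L, consensus = "AAAA",
                           protected = TRUE),
                      list(name = "b", start = 12L, consensus = "CCC",
                           protected = TRUE))
  expect_error(family_spec("F", sc, overlapping), "overlap")
  expect_error(family_spec("F", sc, mutation_rate = 1), "mutation_rate")
  expect_error(family_spec("F", "ACB-DEF"), "invalid residue")
})

test_that("generate_family plants motifs, tails and cysteine motifs", {
  sc <- demo_scaffold(3)
  # rate 0: identical copies of scaffold + tail
  sp0 <- family_spec("F", sc, rabf_blocks(), mutation_rate = 0,
                     cterm_tail_length = 6, n_sequences = 5, seed = 2)
  fam0 <- generate_family(sp0)
  expect_length(unique(fam0$records$sequence), 1L)
  expect_equal(nchar(fam0$records$sequence[1]), nchar(sc) + 6L)

  # requested CC motif is always terminal; truth flag set
  spc <- family_spec("F", sc, rabf_blocks(), mutation_rate = 0.1,
                     cterm_tail_length = 10, cterm_cys_motif = "CC",
                     n_sequences = 20, seed = 5)
  famc <- generate_family(spc)
  expect_true(all(endsWith(famc$records$sequence, "CC")))
  expect_true(all(famc$truth$has_cys_motif))
  expect_true(all(famc$truth$cterm_length == 12L))

  # protected blocks stay intact at high rate; flags recomputable
  expect_true(all(famc$truth$n_motifs_intact == 5L))
  for (k in seq_len(nrow(famc$records))) {
    got <- vapply(rabf_blocks(), function(b)
      substr(famc$records$sequence[k], b$start,
             b$start + nchar(b$consensus) - 1L) == b$consensus, TRUE)
    expect_equal(sum(got), famc$truth$n_motifs_intact[k])
  }

  # determinism
  expect_identical(generate_family(spc)$records, famc$records)

  # "none" guarantees a cysteine-free terminal window
  spn <- family_spec("F", sc, rabf_blocks(), mutation_rate = 0.3,
                     cterm_tail_length = 0, cterm_cys_motif = "none",
                     n_sequences = 40, seed = 6)
  tails <- substring(generate_family(spn)$records$sequence,
                     nchar(sc) - 3L, nchar(sc))
  expect_false(any(grepl("C", tails)))
})

test_that("unprotected blocks can decay and truth tracks it", {
  sc <- demo_scaffold(9)
  blocks <- lapply(rabf_blocks(), function(b) { b$protected <- FALSE; b })
  sp <- family_spec("F", sc, blocks, mutation_rate = 0.3,
                    n_sequences = 30, seed = 4)
  fam <- generate_family(sp)
  expect_true(any(fam$truth$n_motifs_intact < 5L))
  # flags still recomputable from the sequences
  for (k in sample(nrow(fam$records), 5)) {
    got <- vapply(blocks, function(b)
      substr(fam$records$sequence[k], b$start,
             b$start + nchar(b$consensus) - 1L) == b$consensus, TRUE)
    expect_equal(sum(got), fam$truth$n_motifs_intact[k])
  }
})

test_that("generate_dataset counts, determinism and stream independence", {
  sc <- demo_scaffold(2)
  mk <- function(nm) family_spec(nm, sc, n_sequences = 10, seed = 1,
                                 mutation_rate = 0.1)
  specs <- list(mk("A"), mk("B"), mk("C"))
  f1 <- tempfile(fileext = ".fasta"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fasta"); t2 <- tempfile(fileext = ".tsv")
  d1 <- generate_dataset(specs, n_random_negatives = 10, seed = 99,
                         fasta = f1, truth = t1)
  generate_dataset(specs, n_random_negatives = 10, seed = 99,
                   fasta = f2, truth = t2)
  expect_equal(nrow(d1$records), 40L)
  expect_equal(nrow(d1$truth), 40L)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
  expect_identical(d1$records$id, d1$truth$id)   # row-aligned

  # FASTA round-trip preserves ids, species and residues
  back <- read_fasta(f1)
  expect_identical(back$id, d1$records$id)
  expect_identical(back$species, d1$records$species)
  expect_identical(back$sequence, d1$records$sequence)

  # adding a family must not perturb the others (derived streams)
  d2 <- generate_dataset(list(mk("A"), mk("B"), mk("C"), mk("D")), seed = 99)
  expect_identical(d2$records$sequence[d2$truth$family == "A"],
                   d1$records$sequence[d1$truth$family == "A"])

  expect_error(generate_dataset(list(mk("A"), mk("A")), seed = 1),
               "duplicate")
})
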