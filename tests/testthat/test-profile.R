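toy_msa <- function(rows) multiple_alignment(rows)

test_that("multiple_alignment validates shape and alphabet", {
  expect_error(multiple_alignment("ACDE"), "at least 2")
  expect_error(multiple_alignment(c("ACDE", "ACD")), "equal length")
  expect_error(multiple_alignment(c("ACDE", "AC!E")), "invalid character")
  expect_error(multiple_alignment(c("ACDE", "----")), "all gaps")
  msa <- pad_alignment(c("ACDE", "AC"))
  expect_equal(msa$n_columns, 4L)
  expect_identical(msa$rows[2], "AC--")
})

test_that("profile emissions follow the pseudocount arithmetic", {
  msa <- toy_msa(c("AA", "AA", "CA", "CA"))
  p <- build_profile(msa, pseudocount = 1)
  # column 1 is "AACC": emission(A) = (2 + 1/20) / (4 + 1) = 0.41
  expect_equal(unname(p$emission["A", 1]), 0.41)
  expect_equal(unname(p$emission["C", 1]), 0.41)
  expect_equal(unname(p$emission["D", 1]), 0.05 / 5)
  expect_equal(unname(colSums(p$emission)), rep(1, 2), tolerance = 1e-9)
  expect_true(all(p$emission > 0))

  # pseudocount 0 concentrates on the observed residue
  p0 <- build_profile(msa, pseudocount = 0)
  expect_equal(unname(p0$emission["A", 2]), 1)
})

test_that("gap fraction at the threshold excludes a match column", {
  msa <- toy_msa(c("AA", "A-", "A-", "AA"))   # col2 gap fraction = 0.5
  p <- build_profile(msa, match_gap_threshold = 0.5)
  expect_identical(p$match_columns, 1L)
  expect_error(build_profile(toy_msa(c("A-", "-A")), 0.5), "no match columns")
})

test_that("consensus applies plurality, the 0.5 case rule and tie-break", {
  # >0.5 upper case
  p <- build_profile(toy_msa(c("AC", "AC", "AC", "TC")), pseudocount = 0)
  cs <- consensus(p)
  expect_identical(cs$sequence, "AC")
  # max emission at 0.5 or below: lower case
  p2 <- build_profile(toy_msa(c("AA", "AA", "CC", "TT")), pseudocount = 0)
  expect_identical(consensus(p2)$sequence, "aa")
  # exact tie A = C = 0.5: alphabetical winner, lower case
  p3 <- build_profile(toy_msa(c("CA", "CA", "AC", "AC")), pseudocount = 0)
  expect_identical(consensus(p3)$residues, c("A", "A"))
  expect_identical(consensus(p3)$sequence, "aa")
})

test_that("column entropy matches the Shannon formula and its bounds", {
  expect_equal(column_entropy("AAAA"), 0)
  expect_equal(column_entropy("AACC"), 1)
  expect_equal(column_entropy(paste(AA20, collapse = "")), log2(20))
  expect_equal(column_entropy(c("A", "A", "-", "-", "C", "C")), 1)
  expect_error(column_entropy("----"), "all-gap")
  # counts interface
  expect_equal(column_entropy(c(A = 2, C = 2)), 1)
  set.seed(42)
  for (k in seq_len(20)) {
    col <- paste(sample(AA20, 12, replace = TRUE), collapse = "")
    h <- column_entropy(col)
    expect_gte(h, 0)
    expect_lte(h, log2(20) + 1e-12)
  }
})

test_that("entropy profile is per-column, permutation-invariant, NA on gaps", {
  rows <- c("AAAA", "AAC-", "AACC")
  msa <- toy_msa(rows)
  ep <- entropy_profile(msa)
  expect_length(ep, 4L)
  expect_equal(ep[1], 0)
  expect_equal(entropy_profile(toy_msa(rows[c(3, 1, 2)])), ep)
  # identical rows: all-zero profile
  expect_equal(entropy_profile(toy_msa(c("ACD", "ACD", "ACD"))),
               rep(0, 3))
  msa_gap <- multiple_alignment(c("A-", "C-"))
  expect_true(is.na(entropy_profile(msa_gap)[2]))
})

test_that("information content follows R = log2(20) - H", {
  expect_equal(information_content("AAAA")$bits, log2(20))
  expect_equal(information_content(paste(AA20, collapse = ""))$bits, 0,
               tolerance = 1e-12)
  ic <- information_content("AACC")
  expect_equal(ic$bits, log2(20) - 1)
  expect_equal(unname(ic$heights["A"]), 0.5 * (log2(20) - 1))
  expect_equal(sum(ic$heights), ic$bits)
})

test_that("profile scoring reproduces the log-odds sum on a gapless path", {
  s <- "GDSGVGKTACDEFGHIKL"
  p <- build_profile(pad_alignment(c(s, s)), pseudocount = 1)
  al <- score_sequence(p, s)
  expected <- sum(log2(p$emission[cbind(match(strsplit(s, "")[[1]], AA20),
                                        seq_len(nchar(s)))] / 0.05))
  expect_equal(al$bits, expected, tolerance = 1e-9)
  expect_equal(al$coverage, 1)
  expect_equal(al$span, c(1L, nchar(s)))
  expect_false(anyNA(al$path$column))

  # any single-point mutant scores no better
  set.seed(7)
  for (k in seq_len(5)) {
    pos <- sample(nchar(s), 1)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- sample(setdiff(AA20, ch[pos]), 1)
    expect_lte(score_sequence(p, paste(ch, collapse = ""))$bits, al$bits)
  }
})

test_that("nonstandard letters score as background (0 bits)", {
  s <- "ACDEFGHIKL"
  p <- build_profile(pad_alignment(c(s, s)), pseudocount = 1)
  full <- score_sequence(p, s)$bits
  with_x <- score_sequence(p, "ACDEXGHIKL")$bits
  drop_one <- sum(log2(p$emission[cbind(match(strsplit(s, "")[[1]], AA20),
                                        1:10)] / 0.05)[-5])
  expect_equal(with_x, drop_one, tolerance = 1e-9)
  expect_lt(with_x, full)
})

test_that("consensus maximises gap-free profile score over all strings", {
  alphabet <- c("A", "C", "D", "E")
  set.seed(11)
  for (rep in seq_len(5)) {
    ncols <- sample(2:5, 1)
    rows <- replicate(4, paste(sample(alphabet, ncols, replace = TRUE),
                               collapse = ""))
    p <- build_profile(multiple_alignment(rows), pseudocount = 0.1)
    gap_free <- function(s) {
      ch <- strsplit(s, "")[[1]]
      sum(log2(p$emission[cbind(match(ch, AA20), seq_along(ch))] / 0.05))
    }
    cons_score <- gap_free(toupper(consensus(p)$sequence))
    grid <- do.call(expand.grid, rep(list(alphabet), ncols))
    all_scores <- apply(grid, 1, function(r)
      gap_free(paste(r, collapse = "")))
    expect_gte(cons_score + 1e-12, max(all_scores))
  }
})

test_that("duplicating all rows preserves the model up to pseudocount", {
  rows <- c("ACDE", "ACD-", "TCDE")
  # exact equivariance without pseudocounts (pure frequencies)
  p1 <- build_profile(toy_msa(rows), pseudocount = 0)
  p2 <- build_profile(toy_msa(rep(rows, 2)), pseudocount = 0)
  expect_equal(p1$emission, p2$emission)
  expect_identical(p1$match_columns, p2$match_columns)
  # with a pseudocount, match columns, consensus and entropies are unchanged
  q1 <- build_profile(toy_msa(rows))
  q2 <- build_profile(toy_msa(rep(rows, 2)))
  expect_identical(q1$match_columns, q2$match_columns)
  expect_identical(consensus(q1)$sequence, consensus(q2)$sequence)
  expect_equal(entropy_profile(toy_msa(rows)),
               entropy_profile(toy_msa(rep(rows, 2))))
})

test_that("profiles survive a TSV round-trip", {
  p <- build_profile(pad_alignment(c("ACDEFG", "ACDE", "ACDEFG")),
                     family_name = "toy")
  path <- tempfile(fileext = ".tsv")
  write_profile(p, path)
  q <- read_profile(path)
  expect_identical(q$family_name, "toy")
  expect_identical(q$match_columns, p$match_columns)
  expect_equal(q$emission, p$emission, tolerance = 1e-8)
  expect_equal(q$background, p$background)
})

test_that("family scores separate the family from random sequences", {
  bb <- get_small_bundle()
  rab <- bb$train$Rab$sequence
  fam_scores <- vapply(rab[1:8], function(s)
    score_sequence(bb$bundle$family_profiles$Rab, s)$bits, 0)
  set.seed(99)
  rnd_scores <- vapply(seq_len(8), function(k)
    score_sequence(bb$bundle$family_profiles$Rab,
                   random_protein(190, AA20))$bits, 0)
  expect_lt(mean(rnd_scores), min(fam_scores))
  expect_lt(mean(rnd_scores), mean(fam_scores))
})
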