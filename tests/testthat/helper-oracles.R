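# Independent oracles and fixture builders used across the test files.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Exhaustive affine-gap global alignment score by plain recursion over all
# alignments (no memoisation, independent of the Gotoh implementation).
# A gap run of length L costs gap_open + L * gap_extend; `state` tracks
# whether the previous column opened a gap in a ("X") or b ("Y").
oracle_global_score <- function(a, b, m, gap_open, gap_extend) {
  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  n <- length(ach)
  mm <- length(bch)
  rec <- function(i, j, state) {
    if (i > n && j > mm) return(0)
    best <- -Inf
    if (i <= n && j <= mm) {
      s <- m[ach[i], bch[j]] + rec(i + 1L, j + 1L, "M")
      if (s > best) best <- s
    }
    if (i <= n) {
      cost <- if (state == "X") gap_extend else gap_open + gap_extend
      s <- -cost + rec(i + 1L, j, "X")
      if (s > best) best <- s
    }
    if (j <= mm) {
      cost <- if (state == "Y") gap_extend else gap_open + gap_extend
      s <- -cost + rec(i, j + 1L, "Y")
      if (s > best) best <- s
    }
    best
  }
  rec(1L, 1L, "M")
}

# Exhaustive local score: best global score over all nonempty substring
# pairs, floored at 0 (the empty alignment).
oracle_local_score <- function(a, b, m, gap_open, gap_extend) {
  na <- nchar(a)
  nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      s <- oracle_global_score(substr(a, i1, i2), substr(b, j1, j2),
                               m, gap_open, gap_extend)
      if (s > best) best <- s
    }
  best
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Uniform-ish random proper rotation matrix (QR of a Gaussian matrix with
# sign fix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Minimal fixed-column PDB ATOM line (C-alpha unless stated otherwise).
pdb_atom_line <- function(serial, resno, x, y, z, chain = "A", alt = " ",
                          icode = " ", resname = "ALA", record = "ATOM  ",
                          name = " CA ") {
  paste0(record, sprintf("%5d", serial), " ", name, alt,
         sprintf("%-3s", resname), " ", chain, sprintf("%4d", resno),
         icode, "   ", sprintf("%8.3f%8.3f%8.3f", x, y, z),
         sprintf("%6.2f%6.2f", 1, 0), "          ", " C")
}

pdb_text <- function(coords, resno = seq_len(nrow(coords)), chain = "A",
                     alt = rep(" ", nrow(coords)),
                     icode = rep(" ", nrow(coords))) {
  c(vapply(seq_len(nrow(coords)), function(k)
    pdb_atom_line(k, resno[k], coords[k, 1], coords[k, 2], coords[k, 3],
                  chain = chain, alt = alt[k], icode = icode[k]), ""),
    "END")
}

# Small shared model bundle: built once per test run, reused across files.
small_bundle_env <- new.env()
get_small_bundle <- function() {
  if (is.null(small_bundle_env$bb))
    small_bundle_env$bb <- build_demo_bundle(seed = 7, n_train = 12)
  small_bundle_env$bb
}
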