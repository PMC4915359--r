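test_that("PDB parsing keeps ordered C-alphas with stated selection rules", {
  xyz <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, byrow = TRUE)
  cs <- read_ca_coordinates(pdb_text(xyz, resno = c(5, 6, 7)))
  expect_equal(nrow(cs), 3L)
  expect_equal(cs$resno, c(5, 6, 7))
  expect_equal(cs$x, c(0, 3.8, 7.6))

  # altloc: keep blank or A, one coordinate per residue
  lines <- c(pdb_atom_line(1, 1, 0, 0, 0, alt = "A"),
             pdb_atom_line(2, 1, 9, 9, 9, alt = "B"),
             pdb_atom_line(3, 2, 1, 1, 1),
             "END")
  cs2 <- read_ca_coordinates(lines)
  expect_equal(nrow(cs2), 2L)
  expect_equal(cs2$x[1], 0)

  # HETATM-only input has no C-alpha ATOM records
  het <- c(pdb_atom_line(1, 1, 0, 0, 0, record = "HETATM"), "END")
  expect_error(read_ca_coordinates(het), "C-alpha")

  # multi-model: model selection
  mm <- c("MODEL     1", pdb_atom_line(1, 1, 0, 0, 0),
          pdb_atom_line(2, 2, 1, 0, 0), pdb_atom_line(3, 3, 2, 0, 0),
          "ENDMDL",
          "MODEL     2", pdb_atom_line(4, 1, 5, 5, 5),
          pdb_atom_line(5, 2, 6, 5, 5), pdb_atom_line(6, 3, 7, 5, 5),
          "ENDMDL", "END")
  m1 <- read_ca_coordinates(mm, model = 1)
  m2 <- read_ca_coordinates(mm, model = 2)
  expect_equal(m1$x, c(0, 1, 2))
  expect_equal(m2$x, c(5, 6, 7))
  expect_error(read_ca_coordinates(mm, model = 3), "models")
})

test_that("Kabsch recovers rigid motions exactly", {
  set.seed(21)
  A <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-9)

  # 37-degree rotation about z plus translation: rmsd 0
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  B <- A %*% t(Rz) + matrix(c(1, 2, 3), nrow(A), 3, byrow = TRUE)
  sup <- kabsch_superpose(A, B)
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(sup$rotation, Rz, tolerance = 1e-6)
  expect_equal(sup$translation, c(1, 2, 3), tolerance = 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(sup$rotation), diag(3), tolerance = 1e-8)

  # applying the fit transforms a onto b
  expect_equal(apply_superposition(sup, A), B, tolerance = 1e-6)
})

test_that("RMSD is invariant under rigid motions of either set", {
  set.seed(22)
  A <- matrix(rnorm(24, sd = 4), ncol = 3)
  B <- A + matrix(rnorm(24, sd = 0.5), ncol = 3)
  base <- kabsch_superpose(A, B)$rmsd
  for (k in seq_len(5)) {
    Q <- random_rotation()
    tr <- matrix(runif(3, -10, 10), nrow(A), 3, byrow = TRUE)
    expect_equal(kabsch_superpose(A %*% t(Q) + tr, B)$rmsd, base,
                 tolerance = 1e-9)
    expect_equal(kabsch_superpose(A, B %*% t(Q) + tr)$rmsd, base,
                 tolerance = 1e-9)
  }
})

test_that("Kabsch beats dense random-rotation search on 5-point sets", {
  set.seed(23)
  for (rep in seq_len(3)) {
    A <- matrix(rnorm(15, sd = 3), ncol = 3)
    B <- matrix(rnorm(15, sd = 3), ncol = 3)
    k_rmsd <- kabsch_superpose(A, B)$rmsd
    A0 <- sweep(A, 2, colMeans(A))
    B0 <- sweep(B, 2, colMeans(B))
    best <- Inf
    for (k in seq_len(10000)) {
      Q <- random_rotation()
      r <- sqrt(mean(rowSums((A0 %*% t(Q) - B0)^2)))
      if (r < best) best <- r
    }
    expect_lte(k_rmsd, best + 1e-9)
  }
})

test_that("reflection is corrected: det(R) = +1 on mirror-image inputs", {
  set.seed(24)
  A <- matrix(rnorm(21, sd = 5), ncol = 3)
  B <- A
  B[, 1] <- -B[, 1]                  # mirrored copy
  sup <- kabsch_superpose(A, B)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
  expect_gt(sup$rmsd, 0)             # a proper rotation cannot fit a mirror
})

test_that("degenerate inputs are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "3 corresponding")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  pair <- demo_structure_pair(seed = 5, n = 40, noise_sd = 0.4)
  ours <- kabsch_superpose(pair$a, pair$b)$rmsd
  xyz_a <- as.vector(t(as.matrix(pair$a[, c("x", "y", "z")])))
  xyz_b <- as.vector(t(as.matrix(pair$b[, c("x", "y", "z")])))
  ref <- bio3d::rmsd(xyz_a, xyz_b, fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("motif columns map through alignment paths to residue numbers", {
  motifs <- list(motif_definition("m1", 3:5, rep(list("A"), 3)))
  # identity path, sequential numbering
  path <- data.frame(column = 1:10, position = 1:10)
  coords <- data.frame(resno = 1:10, insert = "", resid = "ALA",
                       x = 0, y = 0, z = 0)
  mp <- map_motifs_to_structure(path, motifs, coords)
  expect_equal(mp$resno, 3:5)
  expect_true(all(mp$mapped))

  # numbering offset +100
  coords100 <- transform(coords, resno = resno + 100L)
  expect_equal(map_motifs_to_structure(path, motifs, coords100)$resno,
               103:105)

  # a deletion inside the motif leaves that column unmapped
  path_del <- path
  path_del$position[4] <- NA
  mp2 <- map_motifs_to_structure(path_del, motifs, coords)
  expect_false(mp2$mapped[2])
  expect_true(all(mp2$mapped[c(1, 3)]))
})

test_that("synthetic structure pairs carry the planted motion", {
  pair <- demo_structure_pair(seed = 9, n = 50, noise_sd = 0)
  sup <- kabsch_superpose(pair$a, pair$b)
  expect_lt(sup$rmsd, 1e-8)
  expect_equal(sup$rotation, pair$rotation, tolerance = 1e-6)
  noisy <- demo_structure_pair(seed = 9, n = 50, noise_sd = 0.25)
  r <- kabsch_superpose(noisy$a, noisy$b)$rmsd
  expect_gt(r, 0.1)
  expect_lt(r, 1.0)
})
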