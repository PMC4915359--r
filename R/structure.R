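#' Read C-alpha coordinates from PDB-format text
#'
#' Parses ATOM records (via bio3d), keeping C-alpha atoms of the requested
#' chain from the requested model only, with blank or `'A'` alternate
#' locations; insertion-code residues keep their file order.  HETATM records
#' are ignored.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param chain Chain identifier; default the first chain seen.
#' @param model Model index (1-based) for multi-model files; default 1.
#' @return Object of class `coordinate_set`: data frame with `resno`,
#'   `insert`, `resid`, `x`, `y`, `z` plus attributes `chain` and `source`.
#' @export
read_ca_coordinates <- function(pdb, chain = NULL, model = 1) {
  src <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb))
    "file" else "text"
  lines <- if (src == "file") readLines(pdb)
           else unlist(strsplit(pdb, "\n", fixed = TRUE))
  starts <- which(startsWith(lines, "MODEL"))
  if (length(starts)) {
    if (model > length(starts))
      stop(sprintf("model %d requested but file has %d models",
                   model, length(starts)), call. = FALSE)
    ends <- which(startsWith(lines, "ENDMDL"))
    lines <- lines[(starts[model] + 1L):(ends[model] - 1L)]
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(lines, "END"), tmp)
  p <- tryCatch(bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE),
                error = function(e)
                  stop("no ATOM records could be parsed", call. = FALSE))
  a <- p$atom
  keep <- a$type == "ATOM" & a$elety == "CA" &
    (is.na(a$alt) | a$alt %in% c("", "A"))
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) stop("no C-alpha atoms found", call. = FALSE)
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain %in% chain, , drop = FALSE]
  if (!nrow(a))
    stop(sprintf("no C-alpha atoms in chain '%s'", chain), call. = FALSE)
  same_res <- duplicated(a[, c("resno", "insert")])
  a <- a[!same_res, , drop = FALSE]
  df <- data.frame(resno = a$resno,
                   insert = ifelse(is.na(a$insert), "", a$insert),
                   resid = a$resid, x = a$x, y = a$y, z = a$z,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (is.unsorted(df$resno))
    stop("residue numbers are not increasing within the chain",
         call. = FALSE)
  structure(df, class = c("coordinate_set", "data.frame"),
            chain = chain, source = if (src == "file") pdb else "text")
}

coords_matrix <- function(x) {
  if (inherits(x, "coordinate_set") || is.data.frame(x))
    return(as.matrix(x[, c("x", "y", "z")]))
  stopifnot(is.matrix(x), ncol(x) == 3L)
  unname(x)
}

#' Kabsch least-squares superposition of two coordinate sets
#'
#' Finds the proper rotation `R` (SVD with reflection correction, so
#' `det(R) = +1` even for mirror-image inputs) and translation `t`
#' minimising the RMSD between corresponding C-alpha atoms, transforming
#' `a` onto `b`.
#'
#' @param a,b `coordinate_set`s or n x 3 coordinate matrices (Angstrom).
#' @param correspondence Two-column integer matrix of (index in a, index in
#'   b) pairs; `NULL` (default) uses the positional pairing of equal-length
#'   sets.
#' @return Object of class `superposition_result`: `rotation` (3 x 3,
#'   orthonormal, determinant +1), `translation` (length-3), `rmsd`
#'   (Angstrom), `n_atoms`, `correspondence`.
#' @export
kabsch_superpose <- function(a, b, correspondence = NULL) {
  A <- coords_matrix(a)
  B <- coords_matrix(b)
  if (is.null(correspondence)) {
    if (nrow(A) != nrow(B))
      stop("sets differ in length; supply an explicit correspondence",
           call. = FALSE)
    correspondence <- cbind(seq_len(nrow(A)), seq_len(nrow(A)))
  }
  correspondence <- as.matrix(correspondence)
  stopifnot(ncol(correspondence) == 2L)
  if (nrow(correspondence) < 3L)
    stop("at least 3 corresponding atom pairs are required", call. = FALSE)
  A <- A[correspondence[, 1], , drop = FALSE]
  B <- B[correspondence[, 2], , drop = FALSE]
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("coordinates must be finite", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2L)
    stop("corresponding atoms are collinear; superposition is degenerate",
         call. = FALSE)
  H <- crossprod(A0, B0)              # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cb - R %*% ca)
  diff <- A0 %*% t(R) - B0
  structure(list(rotation = R, translation = tr,
                 rmsd = sqrt(mean(rowSums(diff^2))),
                 n_atoms = nrow(A), correspondence = correspondence),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: RMSD %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param result A `superposition_result`.
#' @param coords `coordinate_set` or n x 3 matrix to transform (the `a`
#'   frame).
#' @return Object of the same shape with transformed coordinates.
#' @export
apply_superposition <- function(result, coords) {
  M <- coords_matrix(coords)
  Mt <- M %*% t(result$rotation) +
    matrix(result$translation, nrow(M), 3, byrow = TRUE)
  if (inherits(coords, "coordinate_set") || is.data.frame(coords)) {
    coords$x <- Mt[, 1]; coords$y <- Mt[, 2]; coords$z <- Mt[, 3]
    coords
  } else Mt
}

#' Map motif profile columns onto structure residue numbers
#'
#' Follows a profile-to-sequence alignment path to translate each motif
#' match column into a sequence position, then into the residue number of
#' the corresponding C-alpha (assuming the coordinate set lists one C-alpha
#' per sequence residue, in order).  Columns aligned to a gap, or beyond the
#' coordinate set, are reported unmapped.
#'
#' @param path `profile_alignment` from [score_sequence()] (or its `path`
#'   data frame).
#' @param motifs List of [motif_definition()]s.
#' @param coords `coordinate_set` for the scored sequence.
#' @return Data frame: `motif`, `profile_column`, `seq_position`, `resno`,
#'   `mapped`.
#' @export
map_motifs_to_structure <- function(path, motifs, coords) {
  p <- if (inherits(path, "profile_alignment")) path$path else path
  stopifnot(is.data.frame(p), all(c("column", "position") %in% names(p)))
  ncol_max <- max(p$column, na.rm = TRUE)
  pos_of_column <- rep(NA_integer_, ncol_max)
  m <- !is.na(p$column) & !is.na(p$position)
  pos_of_column[p$column[m]] <- p$position[m]
  rows <- lapply(motifs, function(mo) {
    pos <- ifelse(mo$columns <= ncol_max, pos_of_column[mo$columns],
                  NA_integer_)
    resno <- ifelse(!is.na(pos) & pos <= nrow(coords),
                    coords$resno[pmin(pos, nrow(coords))], NA_integer_)
    data.frame(motif = mo$name, profile_column = mo$columns,
               seq_position = pos, resno = resno,
               mapped = !is.na(resno), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
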