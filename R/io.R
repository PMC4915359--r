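#' Write sequence records to FASTA
#'
#' Headers are `id species=<tag>`; sequences wrapped at 60 columns.
#'
#' @param records Data frame with columns `id`, `species`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- sprintf("%s species=%s", records$id, records$species)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read sequence records from FASTA
#'
#' @param path FASTA path (plain or aligned; gaps are preserved).
#' @return Data frame with columns `id`, `species` (parsed from a
#'   `species=` tag when present, else `"NA"`), `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  species <- ifelse(grepl("species=", hdr),
                    sub("^.*species=(\\S+).*$", "\\1", hdr), NA_character_)
  data.frame(id = id, species = species,
             sequence = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @rdname write_fasta
#' @param truth Truth data frame from [generate_dataset()].
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a profile model as a tab-separated matrix file
#'
#' Header metadata lines (prefixed `#`) record the family name, pseudocount
#' and background; the body has one row per match column with the MSA column
#' index and the 20 emission probabilities.
#'
#' @param profile A [build_profile()] model.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# family\t%s", profile$family_name),
    sprintf("# pseudocount\t%.10g", profile$pseudocount),
    sprintf("# background\t%s",
            paste(sprintf("%s=%.10g", RESIDUES, profile$background),
                  collapse = ";")),
    sprintf("# msa_columns\t%d", profile$n_alignment_columns)), con)
  df <- data.frame(match_column = profile$match_columns,
                   t(profile$emission), check.names = FALSE)
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile model written by [write_profile()]
#'
#' @param path Profile TSV path.
#' @return A `profile_model`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    l <- meta[startsWith(meta, paste0("# ", key))]
    sub("^#\\s*\\S+\\t", "", l[1])
  }
  bg_parts <- strsplit(strsplit(get_meta("background"), ";")[[1]], "=")
  background <- stats::setNames(
    vapply(bg_parts, function(p) as.numeric(p[2]), 0),
    vapply(bg_parts, `[[`, "", 1))[RESIDUES]
  body <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                            check.names = FALSE)
  emission <- t(as.matrix(body[, RESIDUES]))
  dimnames(emission) <- list(RESIDUES, NULL)
  structure(list(match_columns = as.integer(body$match_column),
                 emission = emission, background = background,
                 pseudocount = as.numeric(get_meta("pseudocount")),
                 family_name = get_meta("family"),
                 n_alignment_columns = as.integer(get_meta("msa_columns")),
                 n_sequences = NA_integer_),
            class = "profile_model")
}
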