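#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end run with their defaults; any
#' subset can be overridden in a YAML config file or a named list.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return Nested named list.
#' @export
default_config <- function(seed = 42, outdir = "results") {
  list(seed = seed, outdir = outdir,
       n_train = 30, n_test = 50, n_negatives = 100,
       mutation_rate = 0.10, subfamily_rate = 0.05,
       match_gap_threshold = 0.5, pseudocount = 1,
       profile_gap_open = 4, profile_gap_extend = 0.25,
       align_gap_open = 10, align_gap_extend = 0.5,
       structure_n = 80, structure_noise_sd = 0.25,
       thresholds = default_thresholds(),
       stages = list(generate = TRUE, profiles = TRUE, classify = TRUE,
                     conservation = TRUE, structure = TRUE))
}

flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) out <- c(out, flatten_config(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

#' Validate a pipeline configuration against the defaults
#'
#' Merges the supplied configuration over [default_config()] and reports,
#' machine-readably, every parameter with its value and provenance: `set`
#' (supplied), `default` (filled in), or `unknown` (supplied key that is not
#' a pipeline parameter; also raises a warning).  A supplied value whose type
#' contradicts the default's raises an error naming the key.
#'
#' @param config Named list (possibly nested), e.g. from [read_config()].
#' @return List: `config` (merged), `report` (data frame `key`, `value`,
#'   `status`).
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  flat_def <- flatten_config(defaults)
  flat_usr <- flatten_config(config)
  unknown <- setdiff(names(flat_usr), names(flat_def))
  if (length(unknown))
    warning("unknown configuration keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  for (key in intersect(names(flat_usr), names(flat_def))) {
    d <- flat_def[[key]]; u <- flat_usr[[key]]
    if (is.numeric(d) && !is.numeric(u))
      stop(sprintf("configuration key '%s' must be numeric, got %s",
                   key, class(u)[1]), call. = FALSE)
    if (is.logical(d) && !is.logical(u))
      stop(sprintf("configuration key '%s' must be logical, got %s",
                   key, class(u)[1]), call. = FALSE)
  }
  merged <- utils::modifyList(defaults, config)
  flat <- flatten_config(merged)
  status <- ifelse(names(flat) %in% names(flat_usr), "set", "default")
  extra <- if (length(unknown))
    data.frame(key = unknown,
               value = vapply(flat_usr[unknown], function(v)
                 paste(format(v), collapse = ","), ""),
               status = "unknown", stringsAsFactors = FALSE)
  else NULL
  report <- rbind(
    data.frame(key = names(flat),
               value = vapply(flat, function(v)
                 paste(format(v), collapse = ","), ""),
               status = status, stringsAsFactors = FALSE),
    extra)
  rownames(report) <- NULL
  list(config = merged, report = report)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order - generate synthetic
#' data, build profiles, classify, family-level conservation analyses,
#' structural superposition - writing TSV/FASTA reports and a JSON manifest
#' (package version, flattened configuration, seed, md5 checksum per output
#' file) into the output directory.  All randomness derives from the master
#' seed, so an identical configuration yields byte-identical outputs and
#' checksums.
#'
#' @param config Named list or path to a YAML file; merged over
#'   [default_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  v <- validate_config(config)
  cf <- v$config
  out <- cf$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  report <- v$report
  # the report must not depend on where the results land
  report$value[report$key == "outdir"] <- "(outdir)"
  add(write_tsv(report, file.path(out, "config_report.tsv")))

  dataset <- NULL
  if (cf$stages$generate) {
    dataset <- demo_test_dataset(
      seed = cf$seed, n_test = cf$n_test, mutation_rate = cf$mutation_rate,
      n_negatives = cf$n_negatives,
      fasta = file.path(out, "dataset.fasta"),
      truth = file.path(out, "dataset_truth.tsv"))
    add(file.path(out, "dataset.fasta"))
    add(file.path(out, "dataset_truth.tsv"))
  }

  built <- NULL
  if (cf$stages$profiles) {
    built <- build_demo_bundle(
      seed = cf$seed, n_train = cf$n_train,
      mutation_rate = cf$mutation_rate, subfamily_rate = cf$subfamily_rate,
      thresholds = cf$thresholds)
    for (f in names(built$bundle$family_profiles))
      add(write_profile(built$bundle$family_profiles[[f]],
                        file.path(out, sprintf("profile_%s.tsv", f))))
    consensi <- lapply(built$bundle$family_profiles, consensus)
    cons_df <- data.frame(
      id = names(consensi), species = "consensus",
      sequence = vapply(consensi, `[[`, "", "sequence"))
    add(write_fasta(cons_df, file.path(out, "consensus.fasta")))
  }

  results <- NULL
  if (cf$stages$classify) {
    if (is.null(built) || is.null(dataset))
      stop("classify stage requires the generate and profiles stages",
           call. = FALSE)
    results <- classify_sequences(dataset$records, built$bundle)
    add(write_tsv(results, file.path(out, "classification.tsv")))
    add(write_tsv(phylo_profile(results),
                  file.path(out, "phylo_profile.tsv")))
  }

  if (cf$stages$conservation) {
    if (is.null(built))
      stop("conservation stage requires the profiles stage", call. = FALSE)
    consensi <- lapply(built$bundle$family_profiles, consensus)
    fs <- family_similarity_matrix(
      consensi, gap_open = cf$align_gap_open,
      gap_extend = cf$align_gap_extend)
    add(write_tsv(similarity_long(fs),
                  file.path(out, "similarity_matrix.tsv")))
    add(write_tsv(
      motif_conservation_table(built$bundle$family_profiles,
                               built$bundle$motif_definitions),
      file.path(out, "motif_conservation.tsv")))
    rab_msa <- pad_alignment(built$train$Rab$sequence,
                             ids = built$train$Rab$id)
    ent <- entropy_profile(rab_msa)
    add(write_tsv(data.frame(column = seq_along(ent), entropy_bits = ent),
                  file.path(out, "entropy_profile.tsv")))
    if (!is.null(dataset)) {
      add(write_tsv(cterm_report(dataset$records, dataset$truth$domain_end),
                    file.path(out, "cterm_report.tsv")))
    }
  }

  if (cf$stages$structure) {
    pair <- demo_structure_pair(cf$seed, n = cf$structure_n,
                                noise_sd = cf$structure_noise_sd)
    sup <- kabsch_superpose(pair$a, pair$b)
    sup_df <- data.frame(
      quantity = c("rmsd_angstrom", "n_atoms",
                   sprintf("rotation_%d%d", rep(1:3, each = 3), rep(1:3, 3)),
                   sprintf("translation_%d", 1:3)),
      value = c(sup$rmsd, sup$n_atoms, as.numeric(t(sup$rotation)),
                sup$translation))
    add(write_tsv(sup_df, file.path(out, "superposition.tsv")))
    if (!is.null(built)) {
      rab_prof <- built$bundle$family_profiles$Rab
      anc <- ancestral_sequence(built$specs$Rab)
      al <- score_sequence(rab_prof, anc)
      n_dom <- nchar(anc)
      coords <- demo_structure_pair(cf$seed, n = n_dom,
                                    noise_sd = 0)$a
      add(write_tsv(
        map_motifs_to_structure(al, built$bundle$motif_definitions, coords),
        file.path(out, "motif_structure_map.tsv")))
    }
  }

  manifest <- list(
    package = "rabscan",
    version = as.character(utils::packageVersion("rabscan")),
    seed = cf$seed,
    config = flatten_config(cf),
    files = as.list(stats::setNames(
      unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
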