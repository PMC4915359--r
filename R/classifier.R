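#' Motif definition in profile match-column coordinates
#'
#' A RabF-style motif: an ordered set of match-column ordinals of the Rab
#' family profile, each with its allowed residue set (the consensus residue
#' plus conservative alternatives).
#'
#' @param name Motif name (for example `RabF1`).
#' @param columns Increasing integer vector of match-column ordinals.
#' @param allowed List of allowed residue sets, one per column.
#' @return Object of class `motif_definition`.
#' @export
motif_definition <- function(name, columns, allowed) {
  stopifnot(length(columns) >= 1L, !is.unsorted(columns, strictly = TRUE),
            is.list(allowed), length(allowed) == length(columns))
  structure(list(name = name, columns = as.integer(columns),
                 allowed = lapply(allowed, toupper)),
            class = "motif_definition")
}

#' Derive motif definitions from planted blocks and a profile
#'
#' Maps scaffold motif blocks (1-based scaffold positions; for padded
#' star-topology alignments scaffold position equals MSA column) onto the
#' profile's match-column ordinals and builds per-position allowed sets from
#' the profile consensus residue plus, optionally, its BLOSUM62-positive
#' alternatives.
#'
#' @param profile Rab-family `profile_model`.
#' @param blocks List of blocks (`name`, `start`, `consensus`).
#' @param include_similar Add BLOSUM62-positive alternatives of the consensus
#'   residue to each allowed set (default TRUE).
#' @return List of [motif_definition()]s, in block order.
#' @export
motifs_from_profile <- function(profile, blocks, include_similar = TRUE) {
  cons <- consensus(profile)
  lapply(blocks, function(b) {
    pos <- b$start:(b$start + nchar(b$consensus) - 1L)
    ord <- match(pos, profile$match_columns)
    if (anyNA(ord))
      stop(sprintf("motif '%s' spans non-match columns", b$name),
           call. = FALSE)
    allowed <- lapply(ord, function(o) {
      r <- cons$residues[o]
      if (include_similar) similar_residues(r) else r
    })
    motif_definition(b$name, ord, allowed)
  })
}

default_thresholds <- function() {
  list(stage1_min_bits = 0, stage1_min_coverage = 0.5,
       stage2_margin_bits = 5, stage3_min_bits = 0, min_rabf_matches = 3)
}

#' Bundle of models and thresholds for the three-stage classifier
#'
#' @param superfamily_profile Profile of the whole RAS superfamily (G-domain
#'   detector).
#' @param family_profiles Named list of family profiles (must contain
#'   `motif_family`).
#' @param subfamily_profiles Named list of Rab subfamily profiles (may be
#'   empty).
#' @param motif_definitions List of [motif_definition()]s on the
#'   `motif_family` profile.
#' @param motif_family Family whose profile anchors motif scanning and the
#'   subfamily stage; default `"Rab"`.
#' @param thresholds Named list overriding the defaults
#'   `stage1_min_bits = 0`, `stage1_min_coverage = 0.5`,
#'   `stage2_margin_bits = 5`, `stage3_min_bits = 0`,
#'   `min_rabf_matches = 3`.
#' @param motif_rescue Allow an ambiguous family call to be rescued to
#'   `Rab-like` when at least `min_rabf_matches` RabF motifs match
#'   (default FALSE).
#' @param gap_open,gap_extend Profile-scoring gap penalties in bits.
#' @return Object of class `model_bundle`.
#' @export
model_bundle <- function(superfamily_profile, family_profiles,
                         subfamily_profiles = list(),
                         motif_definitions = list(),
                         motif_family = "Rab", thresholds = list(),
                         motif_rescue = FALSE,
                         gap_open = 4, gap_extend = 0.25) {
  stopifnot(inherits(superfamily_profile, "profile_model"),
            length(family_profiles) >= 1L,
            !is.null(names(family_profiles)))
  if (!(motif_family %in% names(family_profiles)))
    stop(sprintf("family_profiles must contain motif family '%s'",
                 motif_family), call. = FALSE)
  th <- utils::modifyList(default_thresholds(), thresholds)
  bad <- !vapply(th, function(v) is.numeric(v) && is.finite(v), TRUE)
  if (any(bad))
    stop("non-finite threshold: ", paste(names(th)[bad], collapse = ", "),
         call. = FALSE)
  structure(list(superfamily_profile = superfamily_profile,
                 family_profiles = family_profiles,
                 subfamily_profiles = subfamily_profiles,
                 motif_definitions = motif_definitions,
                 motif_family = motif_family, thresholds = th,
                 motif_rescue = motif_rescue,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(paste0("model_bundle: superfamily + %d families (%s), ",
                     "%d subfamilies, %d motifs\n"),
              length(x$family_profiles),
              paste(names(x$family_profiles), collapse = ", "),
              length(x$subfamily_profiles), length(x$motif_definitions)))
  invisible(x)
}

#' Stage 1: G-domain detection
#'
#' A sequence passes when its log-odds score against the superfamily profile
#' reaches `stage1_min_bits` and the fraction of match columns aligned to a
#' residue reaches `stage1_min_coverage`.
#'
#' @param s Sequence string.
#' @param bundle A [model_bundle()].
#' @return List: `score` (bits), `coverage`, `pass`, `span` (matched region,
#'   1-based inclusive).
#' @export
detect_g_domain <- function(s, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  al <- score_sequence(bundle$superfamily_profile, s,
                       bundle$gap_open, bundle$gap_extend)
  th <- bundle$thresholds
  list(score = al$bits, coverage = al$coverage,
       pass = al$bits >= th$stage1_min_bits &&
              al$coverage >= th$stage1_min_coverage,
       span = al$span)
}

#' Stage 2: family assignment within the RAS superfamily
#'
#' Scores the sequence against every family profile; the best-scoring family
#' wins when its margin over the runner-up reaches `stage2_margin_bits`,
#' otherwise the call is `"ambiguous"`.  Score ties are broken by family
#' name.
#'
#' @inheritParams detect_g_domain
#' @return List: `scores` (named, sorted decreasing), `best`, `runner_up`,
#'   `margin`, `family` (label or `"ambiguous"`).
#' @export
assign_family <- function(s, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  fams <- sort(names(bundle$family_profiles))
  scores <- vapply(fams, function(f)
    score_sequence(bundle$family_profiles[[f]], s,
                   bundle$gap_open, bundle$gap_extend)$bits, 0)
  ord <- order(-scores, fams)
  scores <- scores[ord]
  margin <- if (length(scores) > 1L) scores[1] - scores[2] else Inf
  list(scores = scores, best = names(scores)[1],
       runner_up = if (length(scores) > 1L) names(scores)[2] else NA_character_,
       margin = margin,
       family = if (margin >= bundle$thresholds$stage2_margin_bits)
         names(scores)[1] else "ambiguous")
}

#' Count RabF motif matches in a sequence
#'
#' Aligns the sequence to the motif family profile and checks every motif
#' position: a motif matches iff each of its match columns is aligned to a
#' residue (no gap) contained in that position's allowed set.
#'
#' @inheritParams detect_g_domain
#' @return List: `flags` (named logical per motif), `count`.
#' @export
count_rabf_motifs <- function(s, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!length(bundle$motif_definitions))
    return(list(flags = logical(0), count = 0L))
  al <- score_sequence(bundle$family_profiles[[bundle$motif_family]], s,
                       bundle$gap_open, bundle$gap_extend)
  ch <- seq_chars(toupper(s))
  pos_of_column <- rep(NA_integer_, length(bundle$family_profiles[[
    bundle$motif_family]]$match_columns))
  m <- !is.na(al$path$column) & !is.na(al$path$position)
  pos_of_column[al$path$column[m]] <- al$path$position[m]
  flags <- vapply(bundle$motif_definitions, function(mo) {
    pos <- pos_of_column[mo$columns]
    if (anyNA(pos)) return(FALSE)
    all(mapply(function(p, allow) ch[p] %in% allow, pos, mo$allowed))
  }, TRUE)
  names(flags) <- vapply(bundle$motif_definitions, `[[`, "", "name")
  list(flags = flags, count = as.integer(sum(flags)))
}

#' Stage 3: Rab subfamily assignment
#'
#' The stage-3 score of a subfamily is its log-odds margin over the generic
#' Rab family model (subfamily bits minus family bits), so the default
#' threshold of 0 reads "more similar to this subfamily than to the family
#' average".  The best subfamily is assigned when its margin reaches
#' `stage3_min_bits`, otherwise `none` - the Rab-like outcome.
#'
#' @inheritParams detect_g_domain
#' @return List: `margins` (named, sorted decreasing; empty when no
#'   subfamily profiles), `subfamily` (label or `NA`).
#' @export
assign_subfamily <- function(s, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!length(bundle$subfamily_profiles))
    return(list(margins = numeric(0), subfamily = NA_character_))
  fam_bits <- score_sequence(bundle$family_profiles[[bundle$motif_family]], s,
                             bundle$gap_open, bundle$gap_extend)$bits
  subs <- sort(names(bundle$subfamily_profiles))
  margins <- vapply(subs, function(f)
    score_sequence(bundle$subfamily_profiles[[f]], s,
                   bundle$gap_open, bundle$gap_extend)$bits - fam_bits, 0)
  ord <- order(-margins, subs)
  margins <- margins[ord]
  list(margins = margins,
       subfamily = if (margins[1] >= bundle$thresholds$stage3_min_bits)
         names(margins)[1] else NA_character_)
}

#' Run the full three-stage classification of one sequence
#'
#' Consecutive stages: (1) G-domain detection against the superfamily
#' profile; (2) family assignment within the RAS superfamily; (3) for
#' Rab-family sequences, RabF motif counting and subfamily assignment.
#' Final labels: `non-GTPase` (stage 1 fails), the family label or
#' `ambiguous` (stage 2), `Rab:<subfamily>` (stage 3 assigns) or `Rab-like`
#' (Rab family, no subfamily sufficiently similar).  With `motif_rescue` an
#' ambiguous stage-2 call carrying at least `min_rabf_matches` RabF motifs is
#' also labelled `Rab-like`.
#'
#' @inheritParams detect_g_domain
#' @param id Optional sequence identifier carried into the result.
#' @return Object of class `classification_result` with fields `id`,
#'   `stage1`, `stage2`, `rabf`, `stage3`, `final`.  Later stages are `NULL`
#'   when an earlier stage failed.
#' @export
classify <- function(s, bundle, id = NA_character_) {
  stage1 <- detect_g_domain(s, bundle)
  if (!stage1$pass)
    return(structure(list(id = id, stage1 = stage1, stage2 = NULL,
                          rabf = NULL, stage3 = NULL, final = "non-GTPase"),
                     class = "classification_result"))
  stage2 <- assign_family(s, bundle)
  is_rab <- identical(stage2$family, bundle$motif_family)
  rabf <- NULL
  stage3 <- NULL
  if (is_rab || (bundle$motif_rescue && identical(stage2$family, "ambiguous")))
    rabf <- count_rabf_motifs(s, bundle)
  if (is_rab) {
    stage3 <- assign_subfamily(s, bundle)
    final <- if (!is.na(stage3$subfamily))
      paste0(bundle$motif_family, ":", stage3$subfamily) else "Rab-like"
  } else if (bundle$motif_rescue && identical(stage2$family, "ambiguous") &&
             !is.null(rabf) &&
             rabf$count >= bundle$thresholds$min_rabf_matches) {
    final <- "Rab-like"
  } else {
    final <- stage2$family
  }
  structure(list(id = id, stage1 = stage1, stage2 = stage2, rabf = rabf,
                 stage3 = stage3, final = final),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("classification '%s': %s\n",
              if (is.na(x$id)) "<unnamed>" else x$id, x$final))
  cat(sprintf("  stage1: %.1f bits, coverage %.2f, %s\n", x$stage1$score,
              x$stage1$coverage, if (x$stage1$pass) "pass" else "fail"))
  if (!is.null(x$stage2))
    cat(sprintf("  stage2: best %s (margin %.1f bits) -> %s\n",
                x$stage2$best, x$stage2$margin, x$stage2$family))
  if (!is.null(x$rabf))
    cat(sprintf("  RabF motifs: %d/%d\n", x$rabf$count, length(x$rabf$flags)))
  if (!is.null(x$stage3) && length(x$stage3$margins))
    cat(sprintf("  stage3: best %s (margin %.1f bits) -> %s\n",
                names(x$stage3$margins)[1], x$stage3$margins[1],
                if (is.na(x$stage3$subfamily)) "none" else x$stage3$subfamily))
  invisible(x)
}

#' Classify a set of sequence records
#'
#' @param records Data frame with `id`, `species`, `sequence` columns (as
#'   from [read_fasta()] or [generate_dataset()]).
#' @param bundle A [model_bundle()].
#' @return Data frame, one row per sequence: stage scores, coverage, best
#'   family and margin, RabF count, subfamily and `final_label`; suitable for
#'   TSV export.
#' @export
classify_sequences <- function(records, bundle) {
  rows <- lapply(seq_len(nrow(records)), function(k) {
    r <- classify(records$sequence[k], bundle, id = records$id[k])
    data.frame(
      id = records$id[k],
      species = records$species[k],
      stage1_bits = r$stage1$score,
      stage1_coverage = r$stage1$coverage,
      stage1_pass = r$stage1$pass,
      best_family = if (is.null(r$stage2)) NA_character_ else r$stage2$best,
      family_margin_bits = if (is.null(r$stage2)) NA_real_ else r$stage2$margin,
      family = if (is.null(r$stage2)) NA_character_ else r$stage2$family,
      rabf_count = if (is.null(r$rabf)) NA_integer_ else r$rabf$count,
      subfamily = if (is.null(r$stage3)) NA_character_ else r$stage3$subfamily,
      final_label = r$final,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
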