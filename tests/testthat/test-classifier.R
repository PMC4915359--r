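bb <- get_small_bundle()
bundle <- bb$bundle
rab_anc <- ancestral_sequence(bb$specs$Rab)

test_that("G-domain detection accepts family members, rejects random", {
  s1 <- detect_g_domain(rab_anc, bundle)
  expect_true(s1$pass)
  expect_gt(s1$score, 100)
  expect_gte(s1$coverage, 0.9)

  # the superfamily consensus is (near-)maximal and must pass
  cons <- toupper(consensus(bundle$superfamily_profile)$sequence)
  expect_true(detect_g_domain(cons, bundle)$pass)

  set.seed(31)
  rejected <- vapply(seq_len(30), function(k)
    !detect_g_domain(random_protein(sample(150:220, 1), AA20),
                     bundle)$pass, TRUE)
  expect_gte(mean(rejected), 0.95)
})

test_that("family assignment recovers planted families with clear margins", {
  specs <- demo_family_specs(n_sequences = 6, mutation_rate = 0.05, seed = 7)
  for (fam in c("Rab", "Ras", "Ran")) {
    sp <- specs[[fam]]
    sp$seed <- derive_seed(1234, fam)
    recs <- generate_family(sp)$records
    got <- vapply(recs$sequence, function(s)
      assign_family(s, bundle)$family, "")
    expect_true(all(got == fam),
                info = sprintf("%s -> %s", fam, paste(got, collapse = ",")))
  }
})

test_that("insufficient margin yields an ambiguous family call", {
  strict <- model_bundle(bundle$superfamily_profile,
                         bundle$family_profiles,
                         bundle$subfamily_profiles,
                         bundle$motif_definitions,
                         thresholds = list(stage2_margin_bits = 1e6))
  expect_identical(assign_family(rab_anc, strict)$family, "ambiguous")
})

test_that("RabF motif counting sees 5 planted motifs and ablations", {
  rf <- count_rabf_motifs(rab_anc, bundle)
  expect_equal(rf$count, 5L)
  expect_true(all(rf$flags))

  # randomising one motif outside its allowed sets drops exactly that motif
  blocks <- rabf_blocks()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    mo <- bundle$motif_definitions[[bi]]
    pos <- b$start:(b$start + nchar(b$consensus) - 1L)
    abl <- ablate_motif(rab_anc, pos, mo$allowed, seed = bi)
    rfa <- count_rabf_motifs(abl, bundle)
    expect_equal(rfa$count, 4L, info = b$name)
    expect_false(rfa$flags[[mo$name]])
  }
})

test_that("motif count never increases along an ablation series", {
  blocks <- rabf_blocks()
  s <- rab_anc
  counts <- integer(0)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    mo <- bundle$motif_definitions[[bi]]
    pos <- b$start:(b$start + nchar(b$consensus) - 1L)
    s <- ablate_motif(s, pos, mo$allowed, seed = 100 + bi)
    counts <- c(counts, count_rabf_motifs(s, bundle)$count)
  }
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0L)
})

test_that("subfamily stage recovers subfamilies and rejects Rab-like", {
  sub_specs <- demo_subfamily_specs(n_sequences = 4, mutation_rate = 0.05,
                                    seed = 7)
  for (sf in names(sub_specs)) {
    sp <- sub_specs[[sf]]
    sp$seed <- derive_seed(777, sf)
    recs <- generate_family(sp)$records
    got <- vapply(recs$sequence, function(s)
      assign_subfamily(s, bundle)$subfamily, "")
    expect_true(all(got == sf), info = sf)
  }
  # archaeal-mode sequences carry no subfamily signal
  rl <- demo_rablike_spec(6, 0.10, seed = 7)
  rl$seed <- derive_seed(888, "RabL")
  got <- vapply(generate_family(rl)$records$sequence, function(s)
    assign_subfamily(s, bundle)$subfamily, "")
  expect_true(all(is.na(got)))

  # without subfamily profiles the stage reports none
  nosub <- model_bundle(bundle$superfamily_profile, bundle$family_profiles,
                        motif_definitions = bundle$motif_definitions)
  expect_true(is.na(assign_subfamily(rab_anc, nosub)$subfamily))
})

test_that("classify produces consistent final labels by construction", {
  # random negative
  set.seed(55)
  neg <- classify(random_protein(180, AA20), bundle)
  expect_identical(neg$final, "non-GTPase")
  expect_null(neg$stage2)
  expect_null(neg$rabf)
  expect_null(neg$stage3)

  # archaeal-mode Rab: all motifs, no subfamily -> Rab-like
  rl <- demo_rablike_spec(4, 0.10, seed = 7)
  rl$seed <- derive_seed(999, "RabL")
  labs <- vapply(generate_family(rl)$records$sequence, function(s)
    classify(s, bundle)$final, "")
  expect_true(all(labs == "Rab-like"))

  # subfamily member -> Rab:<subfamily>
  sp <- demo_subfamily_specs(3, 0.05, seed = 7)$RabSF2
  sp$seed <- derive_seed(1001, "RabSF2")
  labs <- vapply(generate_family(sp)$records$sequence, function(s)
    classify(s, bundle)$final, "")
  expect_true(all(labs == "Rab:RabSF2"))

  # non-Rab family keeps its family label
  ras <- demo_family_specs(3, 0.05, seed = 7)$Ras
  ras$seed <- derive_seed(1002, "Ras")
  labs <- vapply(generate_family(ras)$records$sequence, function(s)
    classify(s, bundle)$final, "")
  expect_true(all(labs == "Ras"))

  # determinism
  r1 <- classify(rab_anc, bundle)
  r2 <- classify(rab_anc, bundle)
  expect_equal(r1[setdiff(names(r1), "id")], r2[setdiff(names(r2), "id")])
})

test_that("nonstandard letters are tolerated through the full classifier", {
  s <- paste0(substr(rab_anc, 1, 100), "X", substr(rab_anc, 102, nchar(rab_anc)))
  r <- classify(s, bundle)
  expect_true(r$stage1$pass)
  expect_identical(r$stage2$family, "Rab")
})

test_that("classify_sequences returns one labelled row per record", {
  sp <- demo_family_specs(3, 0.05, seed = 7)$Rho
  sp$seed <- derive_seed(1003, "Rho")
  recs <- generate_family(sp)$records
  df <- classify_sequences(recs, bundle)
  expect_equal(nrow(df), 3L)
  expect_identical(df$id, recs$id)
  expect_true(all(df$final_label == "Rho"))
  expect_true(all(df$stage1_pass))
})
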